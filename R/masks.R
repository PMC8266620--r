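## Fixed phosphoramidite coupling order for maskless array synthesis.
CYCLE_ORDER <- c("A", "C", "G", "T")

## ON-cycle indices (0-based) for one sequence synthesised 3'->5' under the
## A->C->G->T flow order: the j-th coupled base waits until its next slot.
.on_cycles <- function(sequence) {
  b <- rev(strsplit(sequence, "", fixed = TRUE)[[1]])  # 3'->5' order
  idx <- match(b, CYCLE_ORDER) - 1L
  if (anyNA(idx)) stop("invalid characters in sequence: ", sequence)
  n <- length(idx)
  cyc <- integer(n)
  cyc[1] <- idx[1]
  if (n > 1) {
    waits <- ((idx[-1] - idx[-n] - 1L) %% 4L) + 1L
    cyc <- cumsum(c(idx[1], waits))
  }
  cyc
}

#' Number of synthesis cycles required for a sequence
#'
#' Bases are flowed in the fixed order A->C->G->T (then back to A) and a
#' sequence is synthesised 3'->5'; each base must wait for its next slot in
#' the flow order. The cycle count is the 0-based index of the last coupling
#' cycle plus one.
#'
#' @param sequence A 5'->3' A/C/G/T string (or vector of them).
#' @return Integer vector of cycle counts.
#' @examples
#' cycles_required("A")    # 1
#' cycles_required("AC")   # 5: C couples at cycle 1, A at cycle 4
#' cycles_required("GGG")  # 11: waits 3 + 4 + 4
#' @export
cycles_required <- function(sequence) {
  vapply(sequence, function(s) {
    .check_dna(s)
    .on_cycles(s)[nchar(s)] + 1L
  }, 1L, USE.NAMES = FALSE)
}

#' Generate the per-cycle photomask stack for a layout
#'
#' For every synthesis cycle, a feature's mirrors are ON exactly when the
#' next unsynthesised base of its assigned oligo (3'->5') equals the base
#' flowed at that cycle. The number of cycles is the maximum
#' [cycles_required()] over assigned oligos; trailing all-OFF cycles are
#' trimmed by construction.
#'
#' @param layout An `array_layout` with every feature assigned an oligo.
#' @param library An `oligo_library` (or data.frame with `id`, `sequence`).
#' @return A `mask_stack`: list with `n_cycles`, `base` (per-cycle flowed
#'   base), `on_features` (per-cycle character vectors of ON feature ids)
#'   and `feature_cycles` (per-feature integer vectors of ON cycle indices,
#'   0-based, named by feature id).
#' @export
generate_masks <- function(layout, library) {
  if (anyNA(layout$oligo_id))
    stop("unassigned feature(s): ",
         paste(utils::head(layout$feature_id[is.na(layout$oligo_id)], 3),
               collapse = ", "))
  seqs <- library$sequence[match(layout$oligo_id, library$id)]
  if (anyNA(seqs))
    stop("oligo id(s) in layout missing from library")
  fc <- lapply(seqs, .on_cycles)
  names(fc) <- layout$feature_id
  n_cycles <- max(vapply(fc, function(x) x[length(x)], 1L)) + 1L
  base <- CYCLE_ORDER[(seq_len(n_cycles) - 1L) %% 4L + 1L]
  fid <- rep(layout$feature_id, lengths(fc))
  cyc <- unlist(fc, use.names = FALSE)
  on_features <- split(fid, factor(cyc, levels = 0:(n_cycles - 1L)))
  names(on_features) <- NULL
  structure(list(n_cycles = n_cycles, base = base,
                 on_features = on_features, feature_cycles = fc),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  on_counts <- lengths(x$on_features)
  cat("Mask stack:", x$n_cycles, "cycles (order A->C->G->T),",
      length(x$feature_cycles), "features\n")
  cat("ON features per cycle: median", stats::median(on_counts),
      "range", min(on_counts), "-", max(on_counts), "\n")
  invisible(x)
}

#' Reconstruct each feature's sequence from its mask schedule
#'
#' Decodes the flowed base of every ON cycle of a feature, in cycle order,
#' giving the synthesised 3'->5' base string; returned 5'->3'. Round-trips
#' with [generate_masks()].
#'
#' @param stack A `mask_stack`.
#' @return Named character vector of 5'->3' sequences, one per feature.
#' @export
decode_masks <- function(stack) {
  vapply(stack$feature_cycles, function(cyc) {
    paste(rev(stack$base[cyc + 1L]), collapse = "")
  }, "", USE.NAMES = TRUE)
}

#' Write / read a mask stack as plain PBM bitmaps
#'
#' One P1 (plain text, 1-bit) portable bitmap per cycle, pixel value 1
#' (black) = mirror ON, dimensions equal to the DMD mirror grid. The flowed
#' base and cycle index are recorded in a header comment, so
#' `read_masks(dir, layout)` restores the stack exactly.
#'
#' @param stack A `mask_stack`.
#' @param layout The `array_layout` the stack was generated from.
#' @param directory Output directory (created if missing).
#' @return `write_masks` invisibly returns the file paths; `read_masks`
#'   returns a `mask_stack`.
#' @export
write_masks <- function(stack, layout, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  g <- attr(layout, "geometry")
  paths <- character(stack$n_cycles)
  for (ci in seq_len(stack$n_cycles)) {
    img <- matrix(0L, nrow = g$rows, ncol = g$cols)
    on <- stack$on_features[[ci]]
    if (length(on) > 0) {
      i <- match(on, layout$feature_id)
      for (jj in i) {
        img[layout$row[jj] + seq_len(layout$height[jj]),
            layout$col[jj] + seq_len(layout$width[jj])] <- 1L
      }
    }
    path <- file.path(directory, sprintf("cycle_%03d.pbm", ci - 1L))
    con <- file(path, "w")
    writeLines(c("P1",
                 sprintf("# cycle %d base %s", ci - 1L, stack$base[ci]),
                 paste(g$cols, g$rows)), con)
    utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
    close(con)
    paths[ci] <- path
  }
  invisible(paths)
}

#' @rdname write_masks
#' @param directory Directory holding `cycle_*.pbm` files.
#' @export
read_masks <- function(directory, layout) {
  files <- sort(list.files(directory, pattern = "^cycle_\\d+\\.pbm$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no mask files in ", directory)
  g <- attr(layout, "geometry")
  base <- character(length(files))
  on_features <- vector("list", length(files))
  for (ci in seq_along(files)) {
    lines <- readLines(files[ci])
    if (lines[1] != "P1") stop("not a plain PBM file: ", files[ci])
    hdr <- grep("^#", lines, value = TRUE)
    base[ci] <- sub(".*base ([ACGT]).*", "\\1", hdr[1])
    dimline <- lines[!grepl("^(P1|#)", lines)][1]
    dims <- as.integer(strsplit(trimws(dimline), "\\s+")[[1]])
    if (dims[1] != g$cols || dims[2] != g$rows)
      stop("mask dimension mismatch in ", files[ci], ": ", dims[1], "x",
           dims[2], " vs DMD ", g$cols, "x", g$rows)
    body <- lines[!grepl("^(P1|#)", lines)][-1]
    px <- as.integer(unlist(strsplit(trimws(body), "\\s+")))
    img <- matrix(px, nrow = g$rows, ncol = g$cols, byrow = TRUE)
    # a feature is ON iff its top-left mirror is set
    on <- layout$feature_id[img[cbind(layout$row + 1L, layout$col + 1L)] == 1L]
    on_features[[ci]] <- on
  }
  fc <- split(rep(seq_along(on_features) - 1L, lengths(on_features)),
              factor(unlist(on_features),
                     levels = layout$feature_id))
  fc <- lapply(fc, as.integer)
  structure(list(n_cycles = length(files), base = base,
                 on_features = on_features, feature_cycles = fc),
            class = "mask_stack")
}
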