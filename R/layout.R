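#' DMD geometry
#'
#' Describes the digital micromirror device: mirror grid dimensions, mirror
#' pitch and the gap between mirrors. Defaults are the XGA device used for
#' maskless array synthesis: 1024 x 768 mirrors, 14 um pitch, ~1 um gap.
#'
#' @param rows,cols Mirror grid dimensions.
#' @param mirror_pitch Mirror pitch in micrometres.
#' @param mirror_gap Gap between adjacent mirrors in micrometres.
#' @return A `dmd_geometry` object.
#' @export
dmd_geometry <- function(rows = 768L, cols = 1024L,
                         mirror_pitch = 14, mirror_gap = 1) {
  stopifnot(rows > 0, cols > 0, mirror_pitch > mirror_gap, mirror_gap > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 mirror_pitch = mirror_pitch, mirror_gap = mirror_gap),
            class = "dmd_geometry")
}

## Per-design block size and street width (mirrors).
.design_params <- function(design) {
  switch(design,
         "2SZ" = list(block = 4L, street = 2L),
         "4SZ" = list(block = 2L, street = 4L),
         "CB"  = list(block = 1L, street = NA_integer_),
         stop("unknown design: ", design, " (expected 2SZ, 4SZ or CB)"))
}

#' Place features on the DMD grid
#'
#' Features are square mirror blocks tiled on a regular grid of
#' (block + street) unit cells anchored at the origin (top-left), row-major;
#' leftover border mirrors are unused. The 2SZ design uses 4x4 blocks with
#' 2-mirror streets, 4SZ uses 2x2 blocks with 4-mirror streets, and CB places
#' single-mirror features on one parity of the mirror checkerboard (or on
#' every mirror with `cb_full = TRUE`). Oligos are assigned to features by a
#' seeded random permutation.
#'
#' @param design `"2SZ"`, `"4SZ"` or `"CB"`.
#' @param geometry A [dmd_geometry()].
#' @param n_features Number of features to place (must not exceed capacity).
#' @param oligo_ids Optional character vector of oligo ids to assign
#'   (length `n_features`); randomly permuted over features.
#' @param seed Seed for the assignment permutation.
#' @param cb_full For CB only: occupy every mirror instead of one parity.
#' @param n_areas Number of concentric areas used to annotate features
#'   (default 4; area 1 is the centre, area `n_areas` the corners).
#' @return An `array_layout`: a data.frame with one row per feature
#'   (`feature_id`, `row`, `col` top-left mirror 0-based, `height`, `width`,
#'   `grid_row`, `grid_col`, `area`, `oligo_id`), with the geometry, design
#'   name, street width and feature-grid dimensions as attributes.
#' @export
build_layout <- function(design, geometry = dmd_geometry(), n_features,
                         oligo_ids = NULL, seed = 1L, cb_full = FALSE,
                         n_areas = 4L) {
  p <- .design_params(design)
  if (design == "CB") {
    if (cb_full) {
      cap <- geometry$rows * geometry$cols
      idx <- seq_len(cap) - 1L
      rows <- idx %/% geometry$cols
      cols <- idx %% geometry$cols
    } else {
      all_idx <- seq_len(geometry$rows * geometry$cols) - 1L
      r <- all_idx %/% geometry$cols
      c <- all_idx %% geometry$cols
      keep <- (r + c) %% 2L == 0L
      rows <- r[keep]; cols <- c[keep]
      cap <- length(rows)
    }
    if (n_features > cap)
      stop("capacity exceeded: ", design, " on ", geometry$rows, "x",
           geometry$cols, " holds at most ", cap, " features")
    rows <- rows[seq_len(n_features)]
    cols <- cols[seq_len(n_features)]
    grid_row <- rows; grid_col <- cols
    block <- 1L
  } else {
    block <- p$block
    unit <- p$block + p$street
    gr <- geometry$rows %/% unit
    gc <- geometry$cols %/% unit
    cap <- gr * gc
    if (n_features > cap)
      stop("capacity exceeded: ", design, " on ", geometry$rows, "x",
           geometry$cols, " holds at most ", cap, " features")
    idx <- seq_len(n_features) - 1L
    grid_row <- idx %/% gc
    grid_col <- idx %% gc
    rows <- grid_row * unit
    cols <- grid_col * unit
  }
  ids <- sprintf("f%06d", seq_len(n_features))
  lay <- data.frame(feature_id = ids, row = as.integer(rows),
                    col = as.integer(cols), height = block, width = block,
                    grid_row = as.integer(grid_row),
                    grid_col = as.integer(grid_col),
                    stringsAsFactors = FALSE)
  if (!is.null(oligo_ids)) {
    stopifnot(length(oligo_ids) == n_features)
    set.seed(seed)
    lay$oligo_id <- sample(oligo_ids)
  } else {
    lay$oligo_id <- NA_character_
  }
  out <- structure(lay, geometry = geometry, design = design,
                   street = p$street, n_areas = as.integer(n_areas),
                   class = c("array_layout", "data.frame"))
  out$area <- concentric_area_of(out, n_areas = n_areas)
  out
}

#' @export
print.array_layout <- function(x, ...) {
  g <- attr(x, "geometry")
  cat("Array layout:", attr(x, "design"), "design,", nrow(x), "features on",
      g$rows, "x", g$cols, "mirrors\n")
  cat("Feature block:", x$height[1], "x", x$width[1], "mirrors (",
      feature_edge_um(x), "um edge ), street:", attr(x, "street"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more\n")
  invisible(x)
}

#' Physical feature edge length
#'
#' @param layout An `array_layout`.
#' @return Feature edge in micrometres (block size times mirror pitch).
#' @export
feature_edge_um <- function(layout) {
  g <- attr(layout, "geometry")
  layout$height[1] * g$mirror_pitch
}

#' Fraction of mirrors used for synthesis
#'
#' For a design name, returns the unit-cell (infinite-tiling) ratio: 16/36
#' for 2SZ, 4/36 for 4SZ, 1/2 for CB (1 for full-density CB). For a built
#' layout, returns the fraction of mirrors inside feature blocks over the
#' mirrors of the tiled region actually spanned by the feature grid.
#'
#' @param x An `array_layout` or a design name (`"2SZ"`, `"4SZ"`, `"CB"`).
#' @param cb_full For `"CB"` by name: full density instead of one parity.
#' @return A fraction in (0, 1].
#' @export
active_mirror_fraction <- function(x, cb_full = FALSE) {
  if (is.character(x)) {
    p <- .design_params(x)
    if (x == "CB") return(if (cb_full) 1 else 0.5)
    unit <- p$block + p$street
    return(p$block^2 / unit^2)
  }
  stopifnot(inherits(x, "array_layout"))
  design <- attr(x, "design")
  if (design == "CB") {
    g <- attr(x, "geometry")
    return(nrow(x) / (g$rows * g$cols))
  }
  unit <- x$height[1] + attr(x, "street")
  span <- (max(x$grid_row) + 1L) * (max(x$grid_col) + 1L) * unit^2
  sum(x$height * x$width) / span
}

#' Concentric-area index of features
#'
#' Partitions the array into `n_areas` concentric rectangular rings of equal
#' normalised width: area 1 is the innermost rectangle around the array
#' centre, area `n_areas` the outermost ring including the corners. The ring
#' is determined by the max-norm (Chebyshev) distance of the feature centre
#' from the array centre, normalised by the half-extent in each axis.
#'
#' @param layout An `array_layout`.
#' @param feature_id Optional feature id(s); default all features in layout
#'   order.
#' @param n_areas Number of rings (default 4).
#' @return Integer vector of area indices in 1..n_areas.
#' @export
concentric_area_of <- function(layout, feature_id = NULL, n_areas = 4L) {
  g <- attr(layout, "geometry")
  df <- as.data.frame(layout)
  if (!is.null(feature_id)) {
    i <- match(feature_id, df$feature_id)
    if (anyNA(i)) stop("unknown feature id(s): ",
                       paste(feature_id[is.na(i)], collapse = ", "))
    df <- df[i, , drop = FALSE]
  }
  rc <- df$row + df$height / 2
  cc <- df$col + df$width / 2
  r0 <- g$rows / 2; c0 <- g$cols / 2
  d <- pmax(abs(rc - r0) / r0, abs(cc - c0) / c0)
  a <- pmin(n_areas, floor(d * n_areas) + 1L)
  as.integer(a)
}
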