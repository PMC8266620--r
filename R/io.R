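#' Write / read an oligo panel as FASTA
#'
#' @param lib An `oligo_library` or data.frame with `id`, `sequence`.
#' @param file FASTA path.
#' @return `write_panel_fasta` invisibly returns `file`;
#'   `read_panel_fasta` returns a data.frame with `id` and `sequence`.
#' @export
write_panel_fasta <- function(lib, file) {
  x <- Biostrings::DNAStringSet(lib$sequence)
  names(x) <- lib$id
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  data.frame(id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE)
}

#' Write / read simulated reads as FASTQ
#'
#' Reads are written with a constant quality symbol (there is no per-base
#' quality model). The truth table linking reads to features travels
#' separately as TSV (see [truth_table()]).
#'
#' @param readset A `read_set` (or data.frame with `read_id`, `sequence`).
#' @param file FASTQ path.
#' @param quality_char Constant quality character (default `"I"`).
#' @return `write_reads_fastq` invisibly returns `file`;
#'   `read_reads_fastq` returns a data.frame with `read_id`, `sequence`.
#' @export
write_reads_fastq <- function(readset, file, quality_char = "I") {
  x <- Biostrings::DNAStringSet(readset$sequence)
  names(x) <- readset$read_id
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(readset$sequence)))
  Biostrings::writeXStringSet(x, file, format = "fastq", qualities = q)
  invisible(file)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  data.frame(read_id = sub(" .*", "", names(x)), sequence = as.character(x),
             stringsAsFactors = FALSE)
}

#' Write / read a layout as TSV
#'
#' Columns: feature_id, row, col, height, width, grid_row, grid_col,
#' oligo_id, area (coordinates 0-based).
#'
#' @param layout An `array_layout`.
#' @param file TSV path.
#' @export
write_layout_tsv <- function(layout, file) {
  utils::write.table(as.data.frame(layout), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_layout_tsv
#' @export
read_layout_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Ingest aligned reads from a SAM file
#'
#' Parses SAM text records (CIGAR operations M, =, X, I, D, S; the MD tag
#' supplies substituted reference bases within M blocks) into the flat
#' event structure consumed by [error_profile()]. Reference positions
#' outside the aligned span are treated as clipped. Unmapped records
#' (flag 0x4 or `*` reference) are skipped with a message.
#'
#' @param file SAM path.
#' @param references Named character vector or `oligo_library` giving the
#'   panel (used for reference lengths and identity checks).
#' @param truth Optional truth data.frame (`read_id`, `feature_id`) to
#'   attach feature ids.
#' @return A list suitable for `error_profile(events = ...)`: `flat`
#'   (events/offsets/insertions/clip5), `read_id`, `reference_id`,
#'   `feature_id`.
#' @export
read_sam <- function(file, references, truth = NULL) {
  refseq <- if (is.data.frame(references))
    stats::setNames(references$sequence, references$id) else references
  lines <- readLines(file)
  rec <- lines[!startsWith(lines, "@")]
  if (length(rec) == 0) stop("no alignment records in ", file)
  events_l <- list(); ins_read <- integer(0); ins_pos <- integer(0)
  ins_seq <- character(0); clip5 <- integer(0)
  read_id <- character(0); reference_id <- character(0)
  n_skip <- 0L
  for (li in seq_along(rec)) {
    f <- strsplit(rec[li], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop("malformed SAM record at line ",
           which(!startsWith(lines, "@"))[li], " (", length(f), " fields)")
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L || f[3] == "*") { n_skip <- n_skip + 1L; next }
    rname <- f[3]
    if (!rname %in% names(refseq))
      stop("SAM reference ", rname, " not in panel")
    m <- nchar(refseq[[rname]])
    pos <- as.integer(f[4])
    cigar <- f[6]; seq <- f[10]
    md <- sub("^MD:Z:", "", grep("^MD:Z:", f, value = TRUE)[1])
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    if (length(ops) == 0) stop("unparsable CIGAR '", cigar, "' at record ", li)
    lens <- as.integer(sub("[A-Z=]", "", ops))
    typ <- sub("\\d+", "", ops)
    ev <- rep(6L, m)
    rp <- pos  # 1-based ref cursor
    qp <- 1L   # 1-based read cursor
    this_ins_pos <- integer(0); this_ins_seq <- character(0)
    for (oi in seq_along(typ)) {
      L <- lens[oi]
      switch(typ[oi],
             "S" = { qp <- qp + L },
             "H" = NULL,
             "M" = , "=" = { ev[rp:(rp + L - 1L)] <- 0L
                             rp <- rp + L; qp <- qp + L },
             "X" = { obs <- strsplit(substr(seq, qp, qp + L - 1L), "")[[1]]
                     ev[rp:(rp + L - 1L)] <- match(obs, BASES)
                     rp <- rp + L; qp <- qp + L },
             "I" = { this_ins_pos <- c(this_ins_pos, rp - 1L)
                     this_ins_seq <- c(this_ins_seq,
                                       substr(seq, qp, qp + L - 1L))
                     qp <- qp + L },
             "D" = , "N" = { ev[rp:(rp + L - 1L)] <- 5L; rp <- rp + L },
             stop("unsupported CIGAR op ", typ[oi], " at record ", li))
    }
    # MD tag: refine M blocks into matches and substitutions
    if (!is.na(md) && nzchar(md)) {
      toks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1]]
      # walk MD over the non-inserted, non-clipped read-consuming positions
      ref_cursor <- pos
      for (tk in toks) {
        if (grepl("^\\d+$", tk)) {
          n <- as.integer(tk)
          # skip matched stretch (already 0), but jump over deletions that
          # MD encodes separately
          adv <- 0L
          while (adv < n) {
            if (ev[ref_cursor] != 5L) adv <- adv + 1L
            ref_cursor <- ref_cursor + 1L
          }
        } else if (startsWith(tk, "^")) {
          ref_cursor <- ref_cursor + nchar(tk) - 1L
        } else {
          while (ev[ref_cursor] == 5L) ref_cursor <- ref_cursor + 1L
          # substituted position: observed base from the read
          # locate read base for this reference position
          obs <- .read_base_at(typ, lens, pos, seq, ref_cursor)
          ev[ref_cursor] <- match(obs, BASES)
          ref_cursor <- ref_cursor + 1L
        }
      }
    }
    events_l[[length(events_l) + 1L]] <- ev
    k <- length(events_l)
    if (length(this_ins_pos) > 0) {
      ins_read <- c(ins_read, rep(k, length(this_ins_pos)))
      ins_pos <- c(ins_pos, this_ins_pos)
      ins_seq <- c(ins_seq, this_ins_seq)
    }
    clip5 <- c(clip5, pos - 1L)
    read_id <- c(read_id, f[1])
    reference_id <- c(reference_id, rname)
  }
  if (n_skip > 0) message("skipped ", n_skip, " unmapped record(s)")
  offsets <- c(0L, cumsum(lengths(events_l)))
  flat <- list(events = unlist(events_l), offsets = offsets,
               ins_read = ins_read, ins_pos = ins_pos, ins_seq = ins_seq,
               score = rep(NA_real_, length(events_l)), clip5 = clip5)
  feature_id <- NULL
  if (!is.null(truth)) {
    i <- match(read_id, truth$read_id)
    feature_id <- truth$feature_id[i]
  }
  list(flat = flat, read_id = read_id, reference_id = reference_id,
       feature_id = feature_id)
}

## Read base aligned to a given 1-based reference position, from CIGAR.
.read_base_at <- function(typ, lens, pos, seq, ref_target) {
  rp <- pos; qp <- 1L
  for (oi in seq_along(typ)) {
    L <- lens[oi]
    if (typ[oi] %in% c("S")) qp <- qp + L
    else if (typ[oi] %in% c("M", "=", "X")) {
      if (ref_target < rp + L) return(substr(seq, qp + ref_target - rp,
                                             qp + ref_target - rp))
      rp <- rp + L; qp <- qp + L
    } else if (typ[oi] == "I") qp <- qp + L
    else if (typ[oi] %in% c("D", "N")) rp <- rp + L
  }
  stop("reference position ", ref_target, " not covered by CIGAR")
}
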