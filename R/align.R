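#' Alignment scoring parameters
#'
#' Defaults: match +1, mismatch -2, gap open -4, gap extend -1 (a gap of
#' length L costs open + L * extend). With `clip_truncations` the leading
#' deletion run of the optimal global alignment -- the signature of a read
#' missing the reference 5' prefix, i.e. a truncated molecule (synthesis
#' runs 3'->5') -- is reclassified as a soft-clip; clipped positions are
#' excluded from error denominators. The alignment and its score are
#' unaffected.
#'
#' @param match,mismatch,gap_open,gap_extend Scores.
#' @param clip_truncations Soft-clip the leading deletion run
#'   (default TRUE).
#' @return A list of scoring parameters.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = -4,
                          gap_extend = -1, clip_truncations = TRUE) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, clip_truncations = isTRUE(clip_truncations))
}

## Batch alignment; returns the flat event structure shared with SAM
## ingestion: events (int, concatenated over reads; 0 match, 1..4 observed
## substitution base, 5 deletion, 6 clipped), offsets, insertion records,
## score and clip length per read.
.align_batch <- function(reads, refs, scoring = align_scoring()) {
  stopifnot(length(reads) == length(refs))
  .align_batch_cpp(reads, refs, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend,
                   scoring$clip_truncations)
}

#' Align one read to its reference
#'
#' Optimal global alignment with affine gaps under the configured scoring,
#' deterministic tie-breaking (substitution preferred over indel; indels
#' left-aligned within homopolymers). Degenerate (empty) reads yield
#' all-deletion events.
#'
#' @param read,reference Single 5'->3' A/C/G/T strings (read may be empty).
#' @param scoring See [align_scoring()].
#' @return An `alignment_events` object: `events` (one of `"match"`,
#'   `"sub:A"`..`"sub:T"`, `"deletion"`, `"clipped"` per reference
#'   position), `insertions` (data.frame `after_ref_pos`, `sequence`),
#'   `score`, `clip5`, plus the read and reference.
#' @export
align_read <- function(read, reference, scoring = align_scoring()) {
  if (nchar(read) > 0) .check_dna(read)
  .check_dna(reference)
  b <- .align_batch(read, reference, scoring)
  labels <- c("match", "sub:A", "sub:C", "sub:G", "sub:T", "deletion",
              "clipped")
  structure(list(events = labels[b$events + 1L],
                 insertions = data.frame(after_ref_pos = b$ins_pos,
                                         sequence = b$ins_seq,
                                         stringsAsFactors = FALSE),
                 score = b$score[1], clip5 = b$clip5[1],
                 read = read, reference = reference),
            class = "alignment_events")
}

#' @export
print.alignment_events <- function(x, ...) {
  n <- length(x$events)
  cat("Alignment: read", nchar(x$read), "nt vs reference", n, "nt; score",
      x$score, "\n")
  cat("  matches:", sum(x$events == "match"),
      " subs:", sum(startsWith(x$events, "sub")),
      " deleted:", sum(x$events == "deletion"),
      " inserted:", sum(nchar(x$insertions$sequence)),
      " clipped:", x$clip5, "\n")
  invisible(x)
}

#' Classify alignment events into counts with context
#'
#' Turns per-position events into an event summary: substitution records
#' (position, expected, observed), deletion runs (start position and
#' length; a run of two is one record, not two singles), and insertion
#' records carrying the flanking reference bases (3' flank = the reference
#' base after the insertion point, synthesised earlier; 5' flank = the base
#' before it) for wait-number analysis.
#'
#' @param aln An `alignment_events` from [align_read()].
#' @return List with `n_match`, `substitutions`, `deletion_runs`,
#'   `insertions` (with `flank_3p`, `flank_5p`, `NA` at sequence ends) and
#'   `n_clipped`.
#' @export
classify_events <- function(aln) {
  stopifnot(inherits(aln, "alignment_events"))
  ev <- aln$events
  refc <- strsplit(aln$reference, "", fixed = TRUE)[[1]]
  m <- length(ev)
  subs_i <- which(startsWith(ev, "sub"))
  subs <- data.frame(position = subs_i, expected = refc[subs_i],
                     observed = sub("sub:", "", ev[subs_i]),
                     stringsAsFactors = FALSE)
  del_i <- which(ev == "deletion")
  if (length(del_i) > 0) {
    new_run <- c(TRUE, diff(del_i) != 1L)
    run_id <- cumsum(new_run)
    runs <- data.frame(start = del_i[new_run],
                       length = as.integer(tabulate(run_id)))
  } else {
    runs <- data.frame(start = integer(0), length = integer(0))
  }
  ins <- aln$insertions
  ins$flank_5p <- ifelse(ins$after_ref_pos >= 1,
                         refc[pmax(ins$after_ref_pos, 1)], NA)
  ins$flank_3p <- ifelse(ins$after_ref_pos < m,
                         refc[pmin(ins$after_ref_pos + 1L, m)], NA)
  list(n_match = sum(ev == "match"), substitutions = subs,
       deletion_runs = runs, insertions = ins,
       n_clipped = sum(ev == "clipped"))
}

#' Synthesis cycle of each base of a sequence
#'
#' The 0-based coupling cycle at which each base of a 5'->3' sequence is
#' synthesised under the A->C->G->T flow order (synthesis proceeds 3'->5').
#' Consistent with [cycles_required()]: the 5'-terminal base's cycle + 1
#' equals the cycle count.
#'
#' @param sequence A 5'->3' A/C/G/T string.
#' @param position Optional 1-based position(s); default all.
#' @return Integer cycle indices.
#' @examples
#' coupling_cycle_index("AC")  # c(4, 1): C couples at cycle 1, A at cycle 4
#' @export
coupling_cycle_index <- function(sequence, position = NULL) {
  .check_dna(sequence)
  cyc <- rev(.on_cycles(sequence))  # 5'->3' positions
  if (is.null(position)) return(cyc)
  if (any(position < 1 | position > nchar(sequence)))
    stop("position out of range")
  cyc[position]
}

#' Wait number between the flanking bases of an insertion
#'
#' The number of coupling cycles elapsing between the 3'-flanking base
#' (synthesised first) and the 5'-flanking base under the fixed A->C->G->T
#' order: ((index(base_5p) - index(base_3p) - 1) mod 4) + 1, in 1..4. A
#' repeat (e.g. A then A) waits a full round of 4; adjacent bases in flow
#' order wait 1.
#'
#' @param base_3p,base_5p Flanking bases (vectorised).
#' @return Integer wait numbers in 1..4.
#' @examples
#' wait_number("A", "C")  # 1
#' wait_number("A", "A")  # 4
#' wait_number("T", "A")  # 1 (wrap-around)
#' @export
wait_number <- function(base_3p, base_5p) {
  i3 <- match(base_3p, BASES) - 1L
  i5 <- match(base_5p, BASES) - 1L
  if (anyNA(i3) || anyNA(i5)) stop("bases must be A, C, G or T")
  as.integer(((i5 - i3 - 1L) %% 4L) + 1L)
}
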