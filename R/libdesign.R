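#' Specify an oligonucleotide panel design
#'
#' A design asks for `n_oligos` unique sequences of length `oligo_len` such
#' that every k-mer of length `k` occurs in at least `min_oligo_coverage`
#' distinct oligos, while no homopolymer run in the variable region exceeds
#' `max_homopolymer`. When `k > max_homopolymer`, k-mers that themselves
#' contain a forbidden homopolymer run cannot occur and are exempt from the
#' coverage floor; all other ("admissible") k-mers must meet it. Constant
#' 5' and 3' handles (e.g. poly-dC / poly-dA primer stubs) can be
#' requested; they are excluded from k-mer coverage and homopolymer
#' accounting.
#'
#' Feasibility requires `n_oligos * (variable_len - k + 1) >=
#' min_oligo_coverage * 4^k`, i.e. there must be at least as many k-mer
#' windows as coverage slots demanded.
#'
#' @param n_oligos Number of unique oligos.
#' @param oligo_len Total oligo length in nt, fixed ends included.
#' @param k k-mer length for the coverage constraint.
#' @param min_oligo_coverage Minimum number of distinct oligos each k-mer
#'   must appear in (counted on variable regions only).
#' @param max_homopolymer Longest allowed single-base run in the variable
#'   region (default 3).
#' @param fixed_5p,fixed_3p Constant 5'/3' end sequences over A/C/G/T
#'   (default empty).
#' @param seed RNG seed; the same spec always yields the same library.
#' @return An object of class `design_spec`.
#' @seealso [design_library()]
#' @export
design_spec <- function(n_oligos, oligo_len, k, min_oligo_coverage,
                        max_homopolymer = 3L, fixed_5p = "", fixed_3p = "",
                        seed = 1L) {
  stopifnot(n_oligos >= 1, oligo_len >= 1, k >= 1, min_oligo_coverage >= 0,
            max_homopolymer >= 1)
  .check_dna(fixed_5p, allow_empty = TRUE)
  .check_dna(fixed_3p, allow_empty = TRUE)
  var_len <- oligo_len - nchar(fixed_5p) - nchar(fixed_3p)
  if (var_len < 1)
    stop("fixed ends leave no variable region (variable length ", var_len, ")")
  if (k > var_len)
    stop("k (", k, ") exceeds the variable region length (", var_len, ")")
  windows <- n_oligos * (var_len - k + 1)
  demand <- min_oligo_coverage * 4^k
  if (windows < demand)
    stop("infeasible design: n_oligos*(variable_len-k+1) = ", windows,
         " < min_oligo_coverage*4^k = ", demand)
  structure(list(n_oligos = as.integer(n_oligos),
                 oligo_len = as.integer(oligo_len),
                 k = as.integer(k),
                 min_oligo_coverage = as.integer(min_oligo_coverage),
                 max_homopolymer = as.integer(max_homopolymer),
                 fixed_5p = fixed_5p, fixed_3p = fixed_3p,
                 var_len = as.integer(var_len),
                 seed = as.integer(seed)),
            class = "design_spec")
}

BASES <- c("A", "C", "G", "T")

.check_dna <- function(x, allow_empty = FALSE) {
  if (length(x) != 1L || is.na(x)) stop("expected a single sequence string")
  if (nchar(x) == 0L) {
    if (allow_empty) return(invisible(TRUE))
    stop("empty sequence")
  }
  if (grepl("[^ACGT]", x)) stop("invalid characters in sequence: ", x)
  invisible(TRUE)
}

#' Longest homopolymer run of a sequence
#'
#' @param seq A single non-empty A/C/G/T string.
#' @return Integer length of the longest single-letter run.
#' @examples
#' max_homopolymer_run("ACGT")   # 1
#' max_homopolymer_run("AAACAA") # 3
#' @export
max_homopolymer_run <- function(seq) {
  .check_dna(seq)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

## Character matrix (oligos x positions) of the variable regions.
.var_char_matrix <- function(seqs, fixed_5p = "", fixed_3p = "") {
  v <- substr(seqs, nchar(fixed_5p) + 1L,
              nchar(seqs[1]) - nchar(fixed_3p))
  do.call(rbind, strsplit(v, "", fixed = TRUE))
}

## Integer k-mer codes (base-4, A=0..T=3) for every window of every row.
## Returns a list(oligo = integer index, code = integer code).
.kmer_codes <- function(mat, k) {
  n <- nrow(mat); L <- ncol(mat)
  stopifnot(k <= L)
  num <- matrix(match(mat, BASES) - 1L, nrow = n)
  nw <- L - k + 1L
  code <- matrix(0, nrow = n, ncol = nw)
  for (i in seq_len(k))
    code <- code + num[, i:(i + nw - 1L), drop = FALSE] * 4^(k - i)
  list(oligo = rep(seq_len(n), times = nw),
       code = as.integer(code) + 1L)  # 1-based codes
}

#' Count, for every k-mer, the distinct oligos containing it
#'
#' Counting is per-oligo presence (an oligo containing a k-mer twice counts
#' once). For an `oligo_library`, only the variable regions are scanned and
#' k-mers spanning into the fixed ends are ignored.
#'
#' @param lib An `oligo_library`, or a character vector of equal-length
#'   sequences.
#' @param k k-mer length.
#' @return Named integer vector mapping each observed k-mer to the number of
#'   distinct oligos containing it. k-mers absent from every oligo are not
#'   included.
#' @export
kmer_oligo_coverage <- function(lib, k) {
  if (inherits(lib, "oligo_library")) {
    seqs <- lib$sequence
    f5 <- lib$spec$fixed_5p; f3 <- lib$spec$fixed_3p
  } else {
    seqs <- lib; f5 <- ""; f3 <- ""
  }
  if (length(seqs) == 0L) stop("empty library")
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must be equal length")
  mat <- .var_char_matrix(seqs, f5, f3)
  if (k > ncol(mat)) stop("k exceeds the (variable) sequence length")
  kc <- .kmer_codes(mat, k)
  pair <- unique(kc$oligo * (4^k + 1) + kc$code)  # distinct (oligo, kmer)
  codes <- as.integer(pair %% (4^k + 1))
  counts <- tabulate(codes, nbins = 4^k)
  present <- which(counts > 0L)
  stats::setNames(counts[present], .decode_kmers(present, k))
}

.decode_kmers <- function(codes1, k) {
  # codes1 are 1-based base-4 codes
  c0 <- codes1 - 1L
  out <- character(length(c0))
  m <- matrix("", nrow = length(c0), ncol = k)
  for (i in k:1) {
    m[, i] <- BASES[c0 %% 4 + 1L]
    c0 <- c0 %/% 4
  }
  apply(m, 1, paste0, collapse = "")
}

.encode_kmer <- function(kmer) {
  as.integer(sum((match(strsplit(kmer, "")[[1]], BASES) - 1L) *
                   4^((nchar(kmer) - 1):0)) + 1L)
}

## 1-based codes of the k-mers whose own longest homopolymer run does not
## exceed maxrun: only these can occur in a capped library, so only these
## are subject to the coverage floor.
.admissible_kmer_codes <- function(k, maxrun) {
  if (k <= maxrun) return(seq_len(4^k))
  codes <- seq_len(4^k)
  runs <- vapply(.decode_kmers(codes, k),
                 function(s) max(rle(strsplit(s, "")[[1]])$lengths), 1L)
  codes[runs <= maxrun]
}

## Sample an n x L matrix of bases whose rows respect the homopolymer cap,
## including continuity with a fixed 5' end and a fixed 3' end.
.sample_var_matrix <- function(n, L, maxrun, fixed_5p, fixed_3p) {
  mat <- matrix("", nrow = n, ncol = L)
  # run-length state carried in from the fixed 5' end
  if (nchar(fixed_5p) > 0) {
    tail5 <- rle(strsplit(fixed_5p, "")[[1]])
    run_base <- rep(tail5$values[length(tail5$values)], n)
    run_len <- rep(tail5$lengths[length(tail5$lengths)], n)
  } else {
    run_base <- rep(NA_character_, n)
    run_len <- rep(0L, n)
  }
  for (j in seq_len(L)) {
    draw <- sample(BASES, n, replace = TRUE)
    bad <- !is.na(run_base) & draw == run_base & run_len >= maxrun
    while (any(bad)) {
      draw[bad] <- sample(BASES, sum(bad), replace = TRUE)
      bad <- bad & draw == run_base & run_len >= maxrun
    }
    ext <- !is.na(run_base) & draw == run_base
    run_len <- ifelse(ext, run_len + 1L, 1L)
    run_base <- draw
    mat[, j] <- draw
  }
  # guard the junction with the fixed 3' end: the last variable base may not
  # extend a run that, joined with fixed_3p's head, would exceed the cap
  if (nchar(fixed_3p) > 0) {
    head3 <- rle(strsplit(fixed_3p, "")[[1]])
    b3 <- head3$values[1]; l3 <- head3$lengths[1]
    repeat {
      tail_run <- .trailing_run(mat, b3)
      viol <- which(tail_run + l3 > maxrun & tail_run > 0)
      if (length(viol) == 0L) break
      for (i in viol) {
        jj <- L - tail_run[i] + 1L  # first position of the offending run
        prev <- if (jj > 1L) mat[i, jj - 1L] else
          if (nchar(fixed_5p) > 0) substr(fixed_5p, nchar(fixed_5p),
                                          nchar(fixed_5p)) else NA
        cand <- setdiff(BASES, c(b3, prev))
        mat[i, jj] <- cand[sample.int(length(cand), 1L)]
      }
    }
  }
  mat
}

.trailing_run <- function(mat, base) {
  n <- nrow(mat); L <- ncol(mat)
  run <- integer(n)
  alive <- rep(TRUE, n)
  for (j in L:1) {
    alive <- alive & mat[, j] == base
    run[alive] <- run[alive] + 1L
    if (!any(alive)) break
  }
  run
}

.row_max_run <- function(mat) {
  apply(mat, 1, function(r) max(rle(r)$lengths))
}

#' Generate an oligonucleotide panel satisfying a design spec
#'
#' Randomised generation with repair: sequences are sampled base by base
#' under the homopolymer cap, duplicates are resampled, and k-mers still
#' below the coverage floor are greedily patched into randomly chosen oligos
#' (re-checking the homopolymer and uniqueness constraints after each patch).
#' Generation is bounded by `max_rounds` repair rounds and raises, reporting
#' the worst-covered k-mer, if the floor cannot be met.
#'
#' @param spec A [design_spec()].
#' @param max_rounds Repair round budget (default 50).
#' @return An `oligo_library`: a data.frame with columns `id` and `sequence`
#'   (5'->3'), carrying the spec as attribute `spec`.
#' @examples
#' lib <- design_library(design_spec(16, 5, k = 2, min_oligo_coverage = 1))
#' length(kmer_oligo_coverage(lib, 2))  # all 16 dinucleotides present
#' @export
design_library <- function(spec, max_rounds = 50L) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(spec$seed)
  n <- spec$n_oligos; L <- spec$var_len; k <- spec$k
  m <- spec$min_oligo_coverage; maxrun <- spec$max_homopolymer

  mat <- .sample_var_matrix(n, L, maxrun, spec$fixed_5p, spec$fixed_3p)

  assemble <- function(mat) {
    paste0(spec$fixed_5p, apply(mat, 1, paste0, collapse = ""), spec$fixed_3p)
  }

  # resample duplicated rows until all unique
  for (r in seq_len(max_rounds)) {
    seqs <- assemble(mat)
    dup <- which(duplicated(seqs))
    if (length(dup) == 0L) break
    mat[dup, ] <- .sample_var_matrix(length(dup), L, maxrun,
                                     spec$fixed_5p, spec$fixed_3p)
  }
  if (anyDuplicated(assemble(mat)))
    stop("could not generate ", n, " unique sequences of variable length ", L)

  coverage_counts <- function(mat) {
    kc <- .kmer_codes(mat, k)
    pair <- unique(kc$oligo * (4^k + 1) + kc$code)
    tabulate(as.integer(pair %% (4^k + 1)), nbins = 4^k)
  }

  # homopolymer check for a patched variable region, with junction context
  # trimmed to maxrun so runs wholly inside a fixed end are not charged
  tail5 <- substr(spec$fixed_5p,
                  max(1L, nchar(spec$fixed_5p) - maxrun + 1L),
                  nchar(spec$fixed_5p))
  head3 <- substr(spec$fixed_3p, 1L, min(nchar(spec$fixed_3p), maxrun))
  fits <- function(row, jj, kmer_chars) {
    cand <- row
    cand[jj:(jj + k - 1L)] <- kmer_chars
    ctx <- paste0(tail5, paste0(cand, collapse = ""), head3)
    max(rle(strsplit(ctx, "")[[1]])$lengths) <= maxrun
  }

  admissible <- .admissible_kmer_codes(k, maxrun)
  for (round in seq_len(max_rounds)) {
    counts <- coverage_counts(mat)
    short <- intersect(which(counts < m), admissible)
    if (length(short) == 0L) break
    for (code in short) {
      need <- m - counts[code]
      kmer_chars <- strsplit(.decode_kmers(code, k), "")[[1]]
      tries <- 0L
      while (need > 0L && tries < 200L) {
        tries <- tries + 1L
        i <- sample.int(n, 1L)
        jj <- sample.int(L - k + 1L, 1L)
        old <- mat[i, ]
        if (!fits(old, jj, kmer_chars)) next
        cand <- old
        cand[jj:(jj + k - 1L)] <- kmer_chars
        newseq <- paste0(spec$fixed_5p, paste0(cand, collapse = ""),
                         spec$fixed_3p)
        if (newseq %in% assemble(mat)[-i]) next
        # only accept if the oligo did not already contain the k-mer
        had <- any(.kmer_codes(matrix(old, nrow = 1), k)$code == code)
        if (had) next
        mat[i, ] <- cand
        need <- need - 1L
      }
    }
  }
  counts <- coverage_counts(mat)
  if (any(counts[admissible] < m)) {
    worst <- admissible[which.min(counts[admissible])]
    stop("coverage floor not reached after ", max_rounds, " rounds; ",
         "worst-covered k-mer ", .decode_kmers(worst, k), " in ",
         counts[worst], " oligos (need ", m, ")")
  }

  seqs <- assemble(mat)
  lib <- data.frame(id = sprintf("oligo_%05d", seq_len(n)),
                    sequence = seqs, stringsAsFactors = FALSE)
  structure(lib, spec = spec, class = c("oligo_library", "data.frame"))
}

#' @export
print.oligo_library <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("Oligo library:", nrow(x), "sequences of", spec$oligo_len, "nt",
      sprintf("(variable %d nt, k = %d, coverage floor %d, max run %d)\n",
              spec$var_len, spec$k, spec$min_oligo_coverage,
              spec$max_homopolymer))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more\n")
  invisible(x)
}

#' @export
`$.oligo_library` <- function(x, name) {
  if (name == "spec") return(attr(x, "spec"))
  NextMethod()
}

#' Validate an oligo library against its design spec
#'
#' Checks uniqueness, lengths, the homopolymer cap on variable regions, and
#' the k-mer coverage floor.
#'
#' @param lib An `oligo_library`.
#' @return Invisibly `TRUE`; raises on the first violated constraint.
#' @export
validate_library <- function(lib) {
  spec <- attr(lib, "spec")
  stopifnot(inherits(lib, "oligo_library"), !is.null(spec))
  if (anyDuplicated(lib$sequence)) stop("duplicated sequences")
  if (anyDuplicated(lib$id)) stop("duplicated ids")
  if (!all(nchar(lib$sequence) == spec$oligo_len))
    stop("sequence length != oligo_len")
  runs <- .row_max_run(.var_char_matrix(lib$sequence, spec$fixed_5p,
                                        spec$fixed_3p))
  if (any(runs > spec$max_homopolymer))
    stop("homopolymer cap exceeded in ", sum(runs > spec$max_homopolymer),
         " variable regions")
  cov <- kmer_oligo_coverage(lib, spec$k)
  full <- integer(4^spec$k)
  full[vapply(names(cov), .encode_kmer, 1L)] <- cov
  adm <- .admissible_kmer_codes(spec$k, spec$max_homopolymer)
  if (any(full[adm] < spec$min_oligo_coverage)) {
    worst <- adm[which.min(full[adm])]
    stop("k-mer coverage floor violated: ", .decode_kmers(worst, spec$k),
         " covered by ", full[worst], " < ", spec$min_oligo_coverage)
  }
  invisible(TRUE)
}
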