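#' Profile synthesis errors from reads aligned to their references
#'
#' The central estimator of the package. Aligns every read to its intended
#' reference (global, affine gaps; truncations soft-clipped at the
#' reference 5' prefix) and aggregates the per-position event stream into
#' the synthesis error profile: per-bp deletion / insertion / substitution
#' rates, the substitution and match matrices, deletion run-length rates,
#' per-cycle and per-position profiles, the insertion wait-number
#' histogram, the observed dinucleotide distribution, per-feature
#' aggregates for spatial analysis, and the sufficient statistics for
#' stepwise coupling-efficiency estimation.
#'
#' Reads whose alignment identity (matches over non-clipped reference
#' positions) falls below `min_identity` are flagged unreadable and
#' excluded from all rate denominators; all rates are percentages per
#' reference bp of readable alignments.
#'
#' @param reads A `read_set` from [simulate_synthesis()], or a data.frame
#'   with `read_id`, `sequence` and `reference_id` columns, or a character
#'   vector of read sequences (then paired to the best-scoring panel
#'   reference; intended for small inputs only).
#' @param references An `oligo_library` or named character vector of
#'   reference sequences (5'->3').
#' @param layout Optional `array_layout`; enables area-stratified
#'   per-position profiles (features are matched via the reads'
#'   `feature_id`).
#' @param scoring See [align_scoring()].
#' @param min_identity Readability threshold (default 0.5).
#' @param events Internal: a precomputed flat event structure (as from SAM
#'   ingestion via [read_sam()]); bypasses alignment.
#' @return An object of class `error_profile`; see Details. Methods:
#'   [print()], [summary()], [coef()] (stepwise coupling efficiencies),
#'   [plot()].
#' @details Fields include `rates` (named deletion/insertion/substitution/
#'   total, % per bp), `substitution_matrix` (4x4, % per bp),
#'   `match_matrix` (A/C/G/T rows over A/C/G/T/deletion, rows sum to 1),
#'   `deletion_runs` (% per bp by run length 1/2/3+, both run- and
#'   base-counted), `per_cycle`, `per_position`, `wait_histogram`,
#'   `dinucleotide_matrix`, `per_feature`, `n_reads`, `n_readable`,
#'   `denominator`.
#' @export
error_profile <- function(reads, references, layout = NULL,
                          scoring = align_scoring(), min_identity = 0.5,
                          events = NULL) {
  refseq <- if (inherits(references, "oligo_library") ||
                is.data.frame(references)) {
    stats::setNames(references$sequence, references$id)
  } else {
    if (is.null(names(references))) stop("references must be named")
    references
  }

  if (is.null(events)) {
    if (is.character(reads)) {
      reads <- data.frame(read_id = sprintf("read_%06d", seq_along(reads)),
                          sequence = reads,
                          reference_id = .pair_reads(reads, refseq, scoring),
                          stringsAsFactors = FALSE)
    }
    stopifnot(all(c("read_id", "sequence", "reference_id") %in%
                    colnames(reads)))
    if (!all(reads$reference_id %in% names(refseq)))
      stop("reads reference unknown panel sequences")
    refs_per_read <- unname(refseq[reads$reference_id])
    flat <- .align_batch(reads$sequence, refs_per_read, scoring)
    read_ids <- reads$read_id
    feature_ids <- if ("feature_id" %in% colnames(reads))
      reads$feature_id else reads$reference_id
  } else {
    flat <- events$flat
    refs_per_read <- unname(refseq[events$reference_id])
    read_ids <- events$read_id
    feature_ids <- if (!is.null(events$feature_id)) events$feature_id else
      events$reference_id
    reads <- NULL
  }

  chem <- attr(reads, "chem")
  capped <- if (!is.null(chem)) isTRUE(chem$capping_enabled) else NA

  out <- .profile_from_events(flat, refs_per_read, read_ids, feature_ids,
                              layout, min_identity)
  out$capped <- capped
  out$scoring <- scoring
  out$call <- match.call()
  out
}

## Best-scoring panel reference per read (exhaustive; toy scale only).
.pair_reads <- function(seqs, refseq, scoring) {
  vapply(seqs, function(s) {
    b <- .align_batch(rep(s, length(refseq)), unname(refseq), scoring)
    names(refseq)[which.max(b$score)]
  }, "", USE.NAMES = FALSE)
}

NEXT_BASE <- c(A = "C", C = "G", G = "T", T = "A")  # flow order successor

.profile_from_events <- function(flat, refs_per_read, read_ids, feature_ids,
                                 layout, min_identity) {
  N <- length(refs_per_read)
  ev <- flat$events
  nref <- diff(flat$offsets)
  read_idx <- rep.int(seq_len(N), nref)
  ref_chars <- unlist(strsplit(refs_per_read, "", fixed = TRUE),
                      use.names = FALSE)
  ref_code <- match(ref_chars, BASES)
  stopifnot(length(ref_code) == length(ev))

  matches <- tabulate(read_idx[ev == 0L], nbins = N)
  covered <- tabulate(read_idx[ev != 6L], nbins = N)
  identity <- ifelse(covered > 0, matches / pmax(covered, 1L), 0)
  readable <- identity >= min_identity & covered > 0

  mask <- readable[read_idx] & ev != 6L
  denom <- sum(mask)
  if (denom == 0) stop("no readable alignments")

  is_del <- ev == 5L & mask
  is_sub <- ev >= 1L & ev <= 4L & mask
  is_match <- ev == 0L & mask

  ins_ok <- readable[flat$ins_read]
  ins_read <- flat$ins_read[ins_ok]
  ins_pos <- flat$ins_pos[ins_ok]
  ins_seq <- flat$ins_seq[ins_ok]
  ins_bases <- sum(nchar(ins_seq))

  del_ct <- sum(is_del); sub_ct <- sum(is_sub)
  rates <- 100 * c(deletion = del_ct, insertion = ins_bases,
                   substitution = sub_ct) / denom
  rates <- c(rates, total = sum(rates))

  # substitution matrix (% per bp) and match matrix (row-normalised)
  sub_tab <- matrix(0, 4, 4, dimnames = list(expected = BASES,
                                             observed = BASES))
  if (sub_ct > 0) {
    t2 <- table(factor(ref_code[is_sub], 1:4), factor(ev[is_sub], 1:4))
    sub_tab[] <- as.numeric(t2)
  }
  substitution_matrix <- 100 * sub_tab / denom

  mm <- matrix(0, 4, 5, dimnames = list(expected = BASES,
                                        observed = c(BASES, "deletion")))
  if (any(is_match)) {
    mt <- tabulate(ref_code[is_match], 4)
    mm[cbind(1:4, 1:4)] <- mt
  }
  mm[, 1:4] <- mm[, 1:4] + sub_tab
  if (del_ct > 0)
    mm[, 5] <- tabulate(ref_code[is_del], 4)
  row_tot <- rowSums(mm)
  match_matrix <- mm / ifelse(row_tot > 0, row_tot, 1)

  # deletion runs (within-read consecutive reference positions)
  gpos <- which(is_del)
  if (length(gpos) > 0) {
    new_run <- c(TRUE, diff(gpos) != 1L |
                   read_idx[gpos[-1]] != read_idx[gpos[-length(gpos)]])
    run_len <- tabulate(cumsum(new_run))
    runs_by_len <- c(sum(run_len == 1L), sum(run_len == 2L),
                     sum(run_len >= 3L))
    bases_by_len <- c(sum(run_len[run_len == 1L]),
                      sum(run_len[run_len == 2L]),
                      sum(run_len[run_len >= 3L]))
    mean_del_len <- mean(run_len)
  } else {
    runs_by_len <- bases_by_len <- c(0, 0, 0)
    mean_del_len <- NA_real_
  }
  deletion_runs <- list(
    runs = stats::setNames(100 * runs_by_len / denom, c("x1", "x2", "x3")),
    bases = stats::setNames(100 * bases_by_len / denom, c("x1", "x2", "x3")))

  # wait-number histogram (insertions with both flanks; one record each)
  wait_histogram <- stats::setNames(integer(4), 1:4)
  if (length(ins_pos) > 0) {
    m_per <- nref[ins_read]
    inner <- ins_pos >= 1L & ins_pos < m_per
    if (any(inner)) {
      off <- flat$offsets[ins_read[inner]]   # 0-based start of each read
      b5 <- ref_chars[off + ins_pos[inner]]        # position p
      b3 <- ref_chars[off + ins_pos[inner] + 1L]   # position p + 1
      w <- wait_number(b3, b5)
      wait_histogram <- stats::setNames(tabulate(w, 4), 1:4)
    }
  }
  mean_ins_len <- if (length(ins_seq) > 0) mean(nchar(ins_seq)) else NA_real_

  # per-cycle profile
  cyc_by_ref <- lapply(unique(refs_per_read), coupling_cycle_index)
  names(cyc_by_ref) <- unique(refs_per_read)
  cyc <- unlist(cyc_by_ref[refs_per_read], use.names = FALSE)
  n_cycles <- max(cyc) + 1L
  cden <- tabulate(cyc[mask] + 1L, n_cycles)
  cdel <- tabulate(cyc[is_del] + 1L, n_cycles)
  csub <- tabulate(cyc[is_sub] + 1L, n_cycles)
  cins <- integer(n_cycles)
  if (length(ins_pos) > 0) {
    flank3 <- pmin(ins_pos + 1L, nref[ins_read])  # attribute to 3' flank
    flank3 <- pmax(flank3, 1L)
    ic <- cyc[flat$offsets[ins_read] + flank3]
    cins <- tabulate(ic + 1L, n_cycles)
  }
  per_cycle <- data.frame(cycle = 0:(n_cycles - 1L),
                          base = CYCLE_ORDER[(0:(n_cycles - 1L)) %% 4L + 1L],
                          n = cden,
                          deletion = 100 * cdel / pmax(cden, 1L),
                          insertion = 100 * cins / pmax(cden, 1L),
                          substitution = 100 * csub / pmax(cden, 1L))
  per_cycle <- per_cycle[per_cycle$n > 0, ]

  # per-position profile (uniform reference length only)
  per_position <- NULL
  per_position_by_area <- NULL
  if (length(unique(nref)) == 1L) {
    L <- nref[1]
    pos <- rep.int(seq_len(L), N)[seq_along(ev)]
    pos <- unlist(lapply(nref, seq_len), use.names = FALSE)
    area_per_read <- NULL
    if (!is.null(layout) && !is.null(feature_ids)) {
      ai <- match(feature_ids, layout$feature_id)
      area_per_read <- layout$area[ai]
    }
    per_position <- .per_position_table(pos, ev, mask, ins_read, ins_pos,
                                        nref, L, NULL, NULL)
    if (!is.null(area_per_read) && !anyNA(area_per_read)) {
      per_position_by_area <- lapply(sort(unique(area_per_read)),
        function(a) {
          sel <- area_per_read == a
          .per_position_table(pos, ev, mask & sel[read_idx],
                              ins_read, ins_pos, nref, L,
                              which(sel), NULL)
        })
      names(per_position_by_area) <- paste0("area", sort(unique(area_per_read)))
    }
  }

  # observed dinucleotide states (consecutive reference positions)
  obs_state <- ifelse(ev == 0L, ref_code, ifelse(ev == 5L, 5L, ev))
  gsel <- which(mask)
  if (length(gsel) > 1) {
    consec <- diff(gsel) == 1L & read_idx[gsel[-1]] == read_idx[gsel[-length(gsel)]]
    first <- gsel[-length(gsel)][consec]
    dtab <- table(factor(obs_state[first], 1:5),
                  factor(obs_state[first + 1L], 1:5))
    dmat <- matrix(as.numeric(dtab), 5, 5,
                   dimnames = list(first = c(BASES, "deletion"),
                                   second = c(BASES, "deletion")))
    rt <- rowSums(dmat)
    dinucleotide_matrix <- dmat / ifelse(rt > 0, rt, 1)
  } else {
    dinucleotide_matrix <- matrix(NA_real_, 5, 5)
  }

  # coupling-efficiency sufficient statistics
  prev_code <- c(NA_integer_, ref_code[-length(ref_code)])
  starts <- flat$offsets[seq_len(N)] + 1L        # first position per read
  prev_code[starts] <- NA_integer_
  next_code_of <- c(2L, 3L, 4L, 1L)              # A->C->G->T->A
  coupling_stats <- data.frame(base = BASES, n = 0L, sub_to_next = 0L,
                               context_open = 0L)
  for (b in 1:4) {
    selb <- mask & ref_code == b
    coupling_stats$n[b] <- sum(selb)
    coupling_stats$sub_to_next[b] <- sum(ev[selb] == next_code_of[b])
    coupling_stats$context_open[b] <-
      sum(is.na(prev_code[selb]) | prev_code[selb] != next_code_of[b])
  }

  # per-feature aggregates
  per_feature <- NULL
  if (!is.null(feature_ids)) {
    f <- factor(feature_ids)
    fr <- factor(feature_ids[read_idx], levels = levels(f))
    per_feature <- data.frame(
      feature_id = levels(f),
      reads = as.integer(table(f)),
      readable = as.integer(tapply(readable, f, sum, default = 0L)),
      ref_bases = as.integer(tapply(mask, fr, sum, default = 0L)),
      del = as.integer(tapply(is_del, fr, sum, default = 0L)),
      sub = as.integer(tapply(is_sub, fr, sum, default = 0L)),
      ins = 0L, stringsAsFactors = FALSE)
    if (length(ins_read) > 0) {
      fi <- factor(feature_ids[ins_read], levels = levels(f))
      per_feature$ins <- as.integer(tapply(nchar(ins_seq), fi, sum,
                                           default = 0L))
    }
    per_feature[is.na(per_feature)] <- 0L
  }

  structure(list(
    n_reads = N, n_readable = sum(readable),
    n_unreadable = sum(!readable), denominator = denom,
    rates = rates,
    substitution_matrix = substitution_matrix,
    match_matrix = match_matrix,
    deletion_runs = deletion_runs,
    mean_deletion_length = mean_del_len,
    mean_insertion_length = mean_ins_len,
    wait_histogram = wait_histogram,
    per_cycle = per_cycle,
    per_position = per_position,
    per_position_by_area = per_position_by_area,
    dinucleotide_matrix = dinucleotide_matrix,
    coupling_stats = coupling_stats,
    per_feature = per_feature,
    min_identity = min_identity), class = "error_profile")
}

.per_position_table <- function(pos, ev, mask, ins_read, ins_pos, nref, L,
                                read_subset, unused) {
  den <- tabulate(pos[mask], L)
  dmatch <- tabulate(pos[mask & ev == 0L], L)
  ddel <- tabulate(pos[mask & ev == 5L], L)
  dsub <- tabulate(pos[mask & ev >= 1L & ev <= 4L], L)
  dins <- integer(L)
  if (length(ins_read) > 0) {
    keep <- if (is.null(read_subset)) rep(TRUE, length(ins_read)) else
      ins_read %in% read_subset
    slot <- pmax(pmin(ins_pos[keep] + 1L, L), 1L)
    if (length(slot) > 0) dins <- tabulate(slot, L)
  }
  data.frame(position = seq_len(L), n = den,
             match = 100 * dmatch / pmax(den, 1L),
             deletion = 100 * ddel / pmax(den, 1L),
             insertion = 100 * dins / pmax(den, 1L),
             substitution = 100 * dsub / pmax(den, 1L))
}

#' Per-bp error rates of a profile
#'
#' @param profile An `error_profile`.
#' @return Named numeric: deletion, insertion, substitution, total
#'   (% per bp; total is their sum by construction).
#' @export
per_bp_rates <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  profile$rates
}

#' Deletion run-length rates
#'
#' @param profile An `error_profile`.
#' @param count `"bases"` (default; a run of length L contributes L bases,
#'   so x1 + x2 + x3 equals the total deletion rate) or `"runs"` (one count
#'   per run).
#' @return Named numeric (`x1`, `x2`, `x3` = runs of length 3 or more),
#'   % per bp.
#' @export
deletion_run_lengths <- function(profile, count = c("bases", "runs")) {
  stopifnot(inherits(profile, "error_profile"))
  profile$deletion_runs[[match.arg(count)]]
}

#' Expected rate of length-L deletion runs under independence
#'
#' If single-base deletions occur independently at rate p, a run of L
#' consecutive deletions is expected at rate p^L. Observed multi-deletion
#' rates in excess of this prediction indicate a correlated mechanism
#' (chain blocking, degradation, dead mirrors).
#'
#' @param single_rate Single-deletion rate as a percentage per bp (e.g. 4).
#' @param run_length Run length L.
#' @return Predicted rate in % per bp: 100 * (single_rate/100)^L.
#' @examples
#' predicted_run_rate(4, 2)  # 0.16
#' predicted_run_rate(4, 3)  # 0.0064
#' @export
predicted_run_rate <- function(single_rate, run_length) {
  stopifnot(single_rate >= 0, single_rate <= 100, run_length >= 1)
  100 * (single_rate / 100)^run_length
}

#' Linear density scaling of the global-scatter insertion rate
#'
#' Global scatter is proportional to the total light directed at the
#' surface, hence to the active-mirror density; the insertion rate it
#' drives scales linearly with density.
#'
#' @param rate Insertion rate (% per bp) measured at density `from`.
#' @param from,to Active mirror densities as fractions (e.g. 0.44, 0.50).
#' @return Predicted insertion rate at density `to`.
#' @examples
#' scale_insertion_rate(0.6, 0.44, 0.50)  # ~0.68
#' @export
scale_insertion_rate <- function(rate, from, to) {
  stopifnot(rate >= 0, from > 0, to > 0)
  rate * to / from
}

#' Substitution matrix accessor
#' @param profile An `error_profile`.
#' @return 4x4 matrix (% per bp), expected base in rows, observed in
#'   columns, zero diagonal.
#' @export
substitution_matrix <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  profile$substitution_matrix
}

#' Match matrix accessor
#' @param profile An `error_profile`.
#' @return 4x5 matrix, rows A/C/G/T (expected), columns A/C/G/T/deletion;
#'   rows sum to 1.
#' @export
match_matrix <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  profile$match_matrix
}

#' Insertion wait-number histogram accessor
#' @param profile An `error_profile`.
#' @return Integer counts named "1".."4" (cycles elapsed between the
#'   flanking couplings); insertions at sequence ends are excluded.
#' @export
insertion_wait_histogram <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  profile$wait_histogram
}

#' Per-cycle error rates accessor
#' @param profile An `error_profile`.
#' @return data.frame with cycle, flowed base, denominator and per-cycle
#'   deletion/insertion/substitution rates (%).
#' @export
per_cycle_rates <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  profile$per_cycle
}

#' Per-position error rates accessor
#' @param profile An `error_profile`.
#' @param area Optional concentric area index (profile must have been built
#'   with a layout).
#' @return data.frame of match/deletion/insertion/substitution rates (%)
#'   by reference position (5'->3').
#' @export
per_position_rates <- function(profile, area = NULL) {
  stopifnot(inherits(profile, "error_profile"))
  if (is.null(area)) return(profile$per_position)
  if (is.null(profile$per_position_by_area))
    stop("profile was built without a layout; no area stratification")
  profile$per_position_by_area[[paste0("area", area)]]
}

#' Observed dinucleotide distribution accessor
#' @param profile An `error_profile`.
#' @return 5x5 row-normalised matrix over consecutive observed states
#'   (A/C/G/T/deletion).
#' @export
dinucleotide_distribution <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  profile$dinucleotide_matrix
}

#' Estimate stepwise coupling efficiencies from substitution order
#'
#' Under the fixed A->C->G->T flow, a failed coupling of base B without
#' capping is rescued by the next flowed base next(B), so the observed
#' B->next(B) substitution rate informs on B's coupling efficiency. The
#' naive estimate is 100 - rate(B->next(B)). The context-corrected estimate
#' divides the observed rate by the probability that the reference base
#' synthesised after B (its 5' neighbour) differs from next(B): when it
#' equals next(B), the failure is absorbed as a deletion instead of a
#' substitution and would otherwise be missed.
#'
#' @param profile An `error_profile` built from uncapped data. With capped
#'   data the substitution channel is suppressed and the estimator is
#'   invalid: a warning is issued and only the naive estimate is returned.
#' @return data.frame with `base`, `naive` and `corrected` stepwise
#'   efficiencies in percent (corrected is `NA` under capping).
#' @export
estimate_coupling_efficiencies <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  cs <- profile$coupling_stats
  obs <- ifelse(cs$n > 0, cs$sub_to_next / cs$n, 0)
  naive <- 100 * (1 - obs)
  p_open <- ifelse(cs$n > 0, cs$context_open / cs$n, NA)
  corrected <- 100 * (1 - obs / p_open)
  if (isTRUE(profile$capped)) {
    warning("profile comes from capped synthesis; substitution-order ",
            "estimator invalid, returning naive estimate only")
    corrected <- rep(NA_real_, 4)
  }
  data.frame(base = cs$base, naive = naive, corrected = corrected)
}
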