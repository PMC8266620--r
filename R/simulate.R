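#' Chemistry parameters for the synthesis simulator
#'
#' Per-base stepwise coupling efficiencies default to >99.9% for A, C and T
#' and 99.7% for G (the least efficient phosphoramidite). Capping models an
#' attempted coupling with a 5'-DMTr-protected monomer after each regular
#' coupling: unreacted 5'-OH groups are permanently blocked, truncating the
#' molecule instead of letting the next flowed base substitute. The blocking
#' rate is a per-cycle, per-molecule probability of irreversible chain loss
#' (chemical degradation, dead mirrors) and produces excess multi-base
#' deletion runs. The baseline substitution rate is a flat sequencing-noise
#' floor applied to finished reads.
#'
#' An optional two-stage discontinuity (synthesis interrupted and resumed)
#' raises the blocking rate and scales down coupling efficiencies for all
#' cycles at or after `stage2_after_cycle`.
#'
#' @param coupling_efficiency Named fractions for A, C, G, T.
#' @param capping_enabled Cap unreacted 5'-OH after each coupling.
#' @param capping_efficiency Capping success probability (default 0.999).
#' @param baseline_substitution_rate Per-base sequencing-noise substitution
#'   probability applied to reads (default 5e-4).
#' @param block_rate Per-cycle, per-molecule blocking probability
#'   (default 0).
#' @param molecules_per_feature Molecules simulated per feature.
#' @param stage2_after_cycle 0-based cycle at which the second synthesis
#'   stage starts (`NA` = single stage, the default).
#' @param stage2_block_rate Blocking rate in the second stage.
#' @param stage2_coupling_factor Multiplier on coupling efficiencies in the
#'   second stage.
#' @return A `chem_params` object.
#' @export
chem_params <- function(coupling_efficiency = c(A = 0.9995, C = 0.9995,
                                                G = 0.997, T = 0.9995),
                        capping_enabled = FALSE,
                        capping_efficiency = 0.999,
                        baseline_substitution_rate = 5e-4,
                        block_rate = 0,
                        molecules_per_feature = 100L,
                        stage2_after_cycle = NA_integer_,
                        stage2_block_rate = 0,
                        stage2_coupling_factor = 1) {
  stopifnot(all(sort(names(coupling_efficiency)) == c("A", "C", "G", "T")),
            all(coupling_efficiency >= 0 & coupling_efficiency <= 1),
            capping_efficiency >= 0, capping_efficiency <= 1,
            baseline_substitution_rate >= 0, baseline_substitution_rate < 1,
            block_rate >= 0, block_rate <= 1,
            molecules_per_feature >= 1,
            stage2_block_rate >= 0, stage2_block_rate <= 1,
            stage2_coupling_factor >= 0, stage2_coupling_factor <= 1)
  structure(list(coupling_efficiency = coupling_efficiency[c("A", "C",
                                                             "G", "T")],
                 capping_enabled = isTRUE(capping_enabled),
                 capping_efficiency = capping_efficiency,
                 baseline_substitution_rate = baseline_substitution_rate,
                 block_rate = block_rate,
                 molecules_per_feature = as.integer(molecules_per_feature),
                 stage2_after_cycle = stage2_after_cycle,
                 stage2_block_rate = stage2_block_rate,
                 stage2_coupling_factor = stage2_coupling_factor),
            class = "chem_params")
}

#' Simulate maskless array synthesis per molecule
#'
#' Monte-Carlo of the coupling cycle for every molecule on every feature.
#' At cycle c flowing base B: (1) exposure -- a protected terminus on an ON
#' feature is deprotected with probability `photolysis_yield(nominal *
#' illumination_factor, k)`; on an OFF feature, with the yield of the stray
#' dose (global scatter + neighbour leakage + reflection); (2) coupling --
#' phosphoramidite B floods the whole cell, so any free 5'-OH couples B with
#' the base-specific efficiency and returns to the protected state;
#' (3) capping -- a still-free terminus is permanently capped with the
#' capping efficiency, if enabled; (4) blocking -- any live molecule is
#' irreversibly blocked with the blocking rate. A missed ON-cycle
#' deprotection skips that base (deletion); a stray OFF-cycle deprotection
#' inserts B; a failed coupling without capping is rescued by the next
#' flowed base (cycle-order substitution).
#'
#' Reads are the synthesised 3'->5' strings reversed to 5'->3', then passed
#' through the flat sequencing-noise substitution floor. One RNG stream is
#' derived per feature from the master seed, so results do not depend on
#' feature iteration order. Deterministic for a fixed seed.
#'
#' @param library An `oligo_library` (columns `id`, `sequence`).
#' @param layout An `array_layout` with oligos assigned.
#' @param stack The `mask_stack` from [generate_masks()].
#' @param photo A [photochem_params()].
#' @param chem A [chem_params()].
#' @param seed Master seed.
#' @return A `read_set`: data.frame with `read_id`, `sequence` (5'->3'),
#'   `feature_id`, `reference_id`, carrying the parameters as attributes.
#' @export
simulate_synthesis <- function(library, layout, stack,
                               photo = photochem_params(),
                               chem = chem_params(), seed = 1L) {
  nfeat <- nrow(layout)
  if (!all(layout$feature_id %in% names(stack$feature_cycles)))
    stop("mask stack does not cover all layout features")
  refs <- library$sequence[match(layout$oligo_id, library$id)]
  if (anyNA(refs)) stop("layout references oligos missing from the library")
  n_cycles <- stack$n_cycles
  k <- photo$k_rate
  M <- chem$molecules_per_feature

  p_on <- photolysis_yield(photo$nominal_exposure *
                             illumination_factor(layout, params = photo), k)

  # per-cycle, per-feature stray dose (matrix features x cycles), built only
  # from the terms that are switched on
  any_stray <- photo$global_scatter_coeff > 0 || photo$side_leak > 0 ||
    photo$corner_leak > 0 || photo$reflection_enabled
  if (any_stray) {
    block_area <- layout$height * layout$width
    g <- attr(layout, "geometry")
    total_mirrors <- g$rows * g$cols
    gi <- .grid_index(layout)
    D <- matrix(0, nrow = nfeat, ncol = n_cycles)
    for (ci in seq_len(n_cycles)) {
      on_ids <- stack$on_features[[ci]]
      on_flag <- layout$feature_id %in% on_ids
      f_on <- sum(block_area[on_flag]) / total_mirrors
      d <- rep(photo$global_scatter_coeff * f_on, nfeat)
      if (photo$side_leak > 0 || photo$corner_leak > 0) {
        nb <- .neighbour_on_counts(gi, on_flag)
        pos <- cbind(layout$grid_row + 1L, layout$grid_col + 1L)
        d <- d + photo$side_leak * nb$side_m[pos] / 4 +
          photo$corner_leak * nb$corner_m[pos] / 4
      }
      d <- d + .reflection_dose_fraction(layout, photo, ci - 1L, n_cycles)
      d[on_flag] <- 0  # ON features receive the intended dose instead
      D[, ci] <- d * photo$nominal_exposure
    }
    p_stray <- photolysis_yield(D, k)
  } else {
    p_stray <- NULL
  }

  base_code <- match(stack$base, BASES)
  eff <- unname(chem$coupling_efficiency)
  stage2 <- !is.na(chem$stage2_after_cycle)
  out_seq <- vector("list", nfeat)
  out_id <- vector("list", nfeat)

  for (f in seq_len(nfeat)) {
    set.seed((seed + f * 1000003L) %% 2147483647L)
    on_vec <- rep(FALSE, n_cycles)
    on_vec[stack$feature_cycles[[layout$feature_id[f]]] + 1L] <- TRUE
    term <- integer(M)            # 0 protected, 1 free, 2 capped, 3 blocked
    nsyn <- integer(M)
    synth <- matrix(0L, nrow = n_cycles, ncol = M)
    pf_on <- p_on[f]
    for (ci in seq_len(n_cycles)) {
      in_stage2 <- stage2 && (ci - 1L) >= chem$stage2_after_cycle
      brate <- if (in_stage2) chem$stage2_block_rate else chem$block_rate
      p_dep <- if (on_vec[ci]) pf_on else
        if (is.null(p_stray)) 0 else p_stray[f, ci]
      if (p_dep == 0 && brate == 0 && !any(term == 1L)) next
      if (p_dep > 0) {
        prot <- which(term == 0L)
        if (length(prot) > 0) {
          dep <- prot[stats::runif(length(prot)) < p_dep]
          term[dep] <- 1L
        }
      }
      free <- which(term == 1L)
      if (length(free) > 0) {
        e <- eff[base_code[ci]]
        if (in_stage2) e <- e * chem$stage2_coupling_factor
        cp <- free[stats::runif(length(free)) < e]
        if (length(cp) > 0) {
          synth[cbind(nsyn[cp] + 1L, cp)] <- base_code[ci]
          nsyn[cp] <- nsyn[cp] + 1L
          term[cp] <- 0L
        }
        if (chem$capping_enabled) {
          still <- setdiff(free, cp)
          if (length(still) > 0) {
            capped <- still[stats::runif(length(still)) <
                              chem$capping_efficiency]
            term[capped] <- 2L
          }
        }
      }
      if (brate > 0) {
        live <- which(term <= 1L)
        if (length(live) > 0) {
          blk <- live[stats::runif(length(live)) < brate]
          term[blk] <- 3L
        }
      }
    }
    out_seq[[f]] <- vapply(seq_len(M), function(m) {
      if (nsyn[m] == 0L) return("")
      paste(BASES[synth[nsyn[m]:1L, m]], collapse = "")
    }, "")
    out_id[[f]] <- sprintf("%s_m%04d", layout$feature_id[f], seq_len(M))
  }

  rs <- data.frame(read_id = unlist(out_id),
                   sequence = unlist(out_seq),
                   feature_id = rep(layout$feature_id, each = M),
                   reference_id = rep(layout$oligo_id, each = M),
                   stringsAsFactors = FALSE)
  if (chem$baseline_substitution_rate > 0) {
    set.seed((seed + 777L) %% 2147483647L)
    rs$sequence <- add_sequencing_noise(rs$sequence,
                                        chem$baseline_substitution_rate)
  }
  structure(rs, photo = photo, chem = chem, seed = seed,
            class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set:", nrow(x), "reads from",
      length(unique(x$feature_id)), "features; mean length",
      round(mean(nchar(x$sequence)), 1), "nt\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more\n")
  invisible(x)
}

#' Apply a flat substitution-noise floor to reads
#'
#' Each base is independently replaced by one of the three other bases
#' (uniformly) with the given probability. Models residual sequencing error.
#'
#' @param reads Character vector of A/C/G/T strings (or a `read_set`, whose
#'   `sequence` column is modified).
#' @param rate Per-base substitution probability in `[0, 1)`.
#' @return Same shape as `reads`, with substitutions applied. Uses the
#'   current RNG state; seed externally for reproducibility.
#' @export
add_sequencing_noise <- function(reads, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (inherits(reads, "read_set")) {
    reads$sequence <- add_sequencing_noise(reads$sequence, rate)
    return(reads)
  }
  if (rate == 0) return(reads)
  lens <- nchar(reads)
  total <- sum(lens)
  if (total == 0) return(reads)
  n_hit <- stats::rbinom(1, total, rate)
  if (n_hit == 0) return(reads)
  pos <- sort(sample.int(total, n_hit))
  ends <- cumsum(lens)
  read_i <- findInterval(pos - 1L, ends) + 1L  # which read each base is in
  within <- pos - c(0L, ends)[read_i]
  for (j in seq_along(pos)) {
    i <- read_i[j]; p <- within[j]
    old <- substr(reads[i], p, p)
    new <- sample(setdiff(BASES, old), 1L)
    substr(reads[i], p, p) <- new
  }
  reads
}

#' Truth table for a simulated read set
#'
#' One row per read with its feature, reference and array coordinates; the
#' join key between reads and the spatial layout.
#'
#' @param readset A `read_set`.
#' @param layout The `array_layout` the reads were simulated on.
#' @return data.frame with `read_id`, `feature_id`, `reference_id`, `row`,
#'   `col`.
#' @export
truth_table <- function(readset, layout) {
  i <- match(readset$feature_id, layout$feature_id)
  if (anyNA(i)) stop("reads reference unknown features")
  data.frame(read_id = readset$read_id,
             feature_id = readset$feature_id,
             reference_id = readset$reference_id,
             row = layout$row[i], col = layout$col[i],
             stringsAsFactors = FALSE)
}
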