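# Build a flat event structure by hand (the same shape .align_batch
# returns) so rate arithmetic can be checked against exact counts.
flat_events <- function(events_per_read, ins = NULL) {
  offsets <- c(0L, cumsum(lengths(events_per_read)))
  list(events = as.integer(unlist(events_per_read)), offsets = offsets,
       ins_read = if (is.null(ins)) integer(0) else ins$read,
       ins_pos = if (is.null(ins)) integer(0) else ins$pos,
       ins_seq = if (is.null(ins)) character(0) else ins$seq,
       score = rep(0, length(events_per_read)),
       clip5 = rep(0L, length(events_per_read)))
}

test_that("per-bp rates reproduce exact constructed counts", {
  # 1000 reads x 100 bp = 100 000 reference bases; plant 4650 deletions,
  # 970 substitutions and 580 single-base insertions
  set.seed(77)
  refs <- random_dna(10, 100)
  ref_of_read <- rep(1:10, each = 100)
  ev <- lapply(1:1000, function(i) integer(100))
  slots <- data.frame(read = rep(1:1000, each = 100), pos = rep(1:100, 1000))
  pick <- sample(nrow(slots), 4650 + 970)
  del_slots <- slots[pick[1:4650], ]
  sub_slots <- slots[pick[4651:5620], ]
  for (k in seq_len(nrow(del_slots)))
    ev[[del_slots$read[k]]][del_slots$pos[k]] <- 5L
  for (k in seq_len(nrow(sub_slots))) {
    i <- sub_slots$read[k]; p <- sub_slots$pos[k]
    refb <- match(substr(refs[ref_of_read[i]], p, p), c("A", "C", "G", "T"))
    ev[[i]][p] <- (refb %% 4L) + 1L  # any base different from the reference
  }
  ins <- list(read = sample(1:1000, 580, replace = TRUE),
              pos = sample(1:99, 580, replace = TRUE),
              seq = random_dna(580, 1))
  prof <- lithoseq:::.profile_from_events(
    flat_events(ev, ins), refs[ref_of_read],
    sprintf("r%04d", 1:1000), sprintf("f%03d", ref_of_read),
    NULL, min_identity = 0.5)
  expect_equal(unname(prof$rates["deletion"]), 4.65)
  expect_equal(unname(prof$rates["insertion"]), 0.58)
  expect_equal(unname(prof$rates["substitution"]), 0.97)
  expect_equal(unname(prof$rates["total"]), 6.20)
  expect_equal(prof$denominator, 100000L)
  # conservation: rates from one event stream satisfy total = del+ins+sub
  expect_equal(unname(prof$rates["total"]),
               sum(prof$rates[c("deletion", "insertion", "substitution")]))
})

test_that("zero-error input gives zero rates and identity matrices", {
  refs <- random_dna(5, 30)
  prof <- error_profile(stats::setNames(refs, NULL),
                        stats::setNames(refs, paste0("o", 1:5)))
  expect_equal(unname(prof$rates), c(0, 0, 0, 0))
  expect_true(all(prof$substitution_matrix == 0))
  expect_equal(unname(diag(prof$match_matrix[, 1:4])), rep(1, 4))
  expect_true(all(prof$match_matrix[, 5] == 0))
  expect_equal(unname(insertion_wait_histogram(prof)), rep(0L, 4))
  expect_equal(unname(deletion_run_lengths(prof)), c(0, 0, 0))
  # perfect data on a panel: dinucleotide rows are flat over A/C/G/T
  expect_true(all(abs(prof$dinucleotide_matrix[1:4, 5]) < 1e-12))
})

test_that("event conservation holds per read on random alignments", {
  set.seed(12)
  for (i in 1:50) {
    rd <- random_dna(1, sample(5:15, 1))
    rf <- random_dna(1, sample(5:15, 1))
    a <- align_read(rd, rf)
    ce <- classify_events(a)
    expect_equal(ce$n_match + nrow(ce$substitutions) +
                   sum(ce$deletion_runs$length) + ce$n_clipped,
                 nchar(rf))
  }
})

test_that("unreadable reads are excluded from denominators but counted", {
  refs <- stats::setNames(random_dna(3, 40), paste0("o", 1:3))
  reads <- data.frame(read_id = c("good1", "good2", "junk"),
                      sequence = c(refs[1], refs[2],
                                   strrep("A", 40)),
                      reference_id = c("o1", "o2", "o3"))
  prof <- error_profile(reads, refs)
  expect_equal(prof$n_readable, 2L)
  expect_equal(prof$n_unreadable, 1L)
  expect_equal(prof$denominator, 80L)
})

test_that("deletion run-length accounting: bases sum to the deletion rate", {
  ev <- list(c(0L, 5L, 0L, 5L, 5L, 0L, 0L, 5L, 5L, 5L),
             rep(0L, 10))
  refs <- random_dna(2, 10)
  prof <- lithoseq:::.profile_from_events(flat_events(ev), refs,
                                          c("a", "b"), c("f1", "f2"), NULL,
                                          0.3)
  runs <- deletion_run_lengths(prof, "runs")
  bases <- deletion_run_lengths(prof, "bases")
  expect_equal(unname(runs), 100 * c(1, 1, 1) / 20)
  expect_equal(unname(bases), 100 * c(1, 2, 3) / 20)
  expect_equal(sum(bases), unname(prof$rates["deletion"]))
  expect_equal(prof$mean_deletion_length, 2)
})

test_that("independence predictions for multi-deletion runs", {
  expect_equal(predicted_run_rate(4, 2), 0.16)
  expect_equal(predicted_run_rate(4, 3), 0.0064)
  expect_equal(predicted_run_rate(0, 2), 0)
})

test_that("uniform random insertions follow flank-pair frequencies (null)", {
  # insert one uniform base at uniform interior points: expected wait-class
  # counts are proportional to the frequencies of flanking dinucleotides,
  # which are near-uniform for random panels => roughly equal classes
  set.seed(21)
  refs <- stats::setNames(random_dna(40, 50), sprintf("o%02d", 1:40))
  reads <- character(2000); rid <- character(2000)
  for (i in 1:2000) {
    k <- sample(40, 1)
    s <- refs[[k]]
    p <- sample(1:49, 1)
    reads[i] <- paste0(substr(s, 1, p), sample(c("A", "C", "G", "T"), 1),
                       substr(s, p + 1, 50))
    rid[i] <- names(refs)[k]
  }
  prof <- error_profile(data.frame(read_id = as.character(1:2000),
                                   sequence = reads, reference_id = rid),
                        refs)
  wh <- insertion_wait_histogram(prof)
  # flank-pair classes are balanced; no wait class dominates
  expect_gt(stats::chisq.test(wh)$p.value, 1e-6)
  expect_true(all(wh > 0))
})

test_that("deletion recovery: 95% photolysis profiles at ~5% per bp", {
  w <- toy_world(n = 30, len = 67, rows = 240, cols = 240, seed = 15)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(0.95),
                           perfect_chem(molecules_per_feature = 80),
                           seed = 16)
  prof <- error_profile(rs, w$lib, layout = w$lay)
  expect_lt(abs(prof$rates[["deletion"]] - 5), 0.3)
  # per-cycle and per-position deletion profiles are flat (no trend)
  pc <- per_cycle_rates(prof)
  expect_lt(abs(stats::cor(pc$cycle, pc$deletion)), 0.35)
  pp <- per_position_rates(prof)
  expect_lt(abs(stats::cor(pp$position[5:26], pp$deletion[5:26])), 0.45)
})

test_that("G coupling shortfall appears as G->T and is corrected back", {
  w <- toy_world(n = 40, len = 40, rows = 240, cols = 240, seed = 25)
  chem <- chem_params(coupling_efficiency = c(A = 0.9995, C = 0.9995,
                                              G = 0.99, T = 0.9995),
                      baseline_substitution_rate = 0,
                      molecules_per_feature = 150)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(yield = 1),
                           chem, seed = 26)
  prof <- error_profile(rs, w$lib)
  sm <- substitution_matrix(prof)
  expect_equal(which.max(sm), which(rownames(sm) == "G") +
                 4 * (which(colnames(sm) == "T") - 1))
  # G row has the lowest diagonal of the match matrix
  mm <- match_matrix(prof)
  expect_equal(which.min(diag(mm[, 1:4])), c(G = 3L))
  eff <- estimate_coupling_efficiencies(prof)
  expect_lt(abs(eff$corrected[eff$base == "G"] - 99), 0.15)
  expect_true(all(eff$corrected[eff$base != "G"] > 99.85))
  # naive underestimates the shortfall whenever next-base contexts mask it
  expect_gt(eff$naive[eff$base == "G"], eff$corrected[eff$base == "G"])
})

test_that("capping suppresses G->T substitution but not indels", {
  w <- toy_world(n = 40, len = 40, rows = 240, cols = 240, seed = 35)
  base_chem <- list(coupling_efficiency = c(A = 0.9995, C = 0.9995,
                                            G = 0.99, T = 0.9995),
                    baseline_substitution_rate = 0,
                    molecules_per_feature = 120)
  photo <- photochem_params(k_rate = calibrate_photolysis_rate(0.95, 3),
                            global_scatter_coeff = 0.02, side_leak = 0,
                            corner_leak = 0, edge_falloff_amplitude = 0)
  rs_u <- simulate_synthesis(w$lib, w$lay, w$stack, photo,
                             do.call(chem_params, base_chem), seed = 36)
  rs_c <- simulate_synthesis(w$lib, w$lay, w$stack, photo,
                             do.call(chem_params,
                                     c(base_chem, capping_enabled = TRUE)),
                             seed = 36)
  prof_u <- error_profile(rs_u, w$lib)
  prof_c <- error_profile(rs_c, w$lib)
  gt_u <- substitution_matrix(prof_u)["G", "T"]
  gt_c <- substitution_matrix(prof_c)["G", "T"]
  expect_lt(gt_c, gt_u / 3)
  # deletion and insertion rates unchanged within 3 Monte-Carlo sigma
  for (metric in c("deletion", "insertion")) {
    r_u <- prof_u$rates[[metric]] / 100
    r_c <- prof_c$rates[[metric]] / 100
    se <- sqrt(r_u * (1 - r_u) / prof_u$denominator +
                 r_c * (1 - r_c) / prof_c$denominator)
    expect_lt(abs(r_u - r_c), 3 * se + 3e-4)
  }
  # capped profiles refuse the corrected estimator
  expect_warning(estimate_coupling_efficiencies(prof_c), "capped")
})

test_that("per-cycle substitution peaks recur at G cycles (period 4)", {
  w <- toy_world(n = 40, len = 40, rows = 240, cols = 240, seed = 45)
  chem <- chem_params(coupling_efficiency = c(A = 0.9995, C = 0.9995,
                                              G = 0.98, T = 0.9995),
                      baseline_substitution_rate = 0,
                      molecules_per_feature = 100)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(yield = 1),
                           chem, seed = 46)
  prof <- error_profile(rs, w$lib)
  pc <- per_cycle_rates(prof)
  pc <- pc[pc$n > 500, ]
  expect_gt(mean(pc$substitution[pc$base == "G"]),
            2 * mean(pc$substitution[pc$base != "G"]))
})

test_that("dinucleotide distribution flags correlated deletions and GG dips", {
  w <- toy_world(n = 30, len = 30, rows = 240, cols = 240, seed = 55)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(0.97),
                           perfect_chem(molecules_per_feature = 80,
                                        block_rate = 0.02), seed = 56)
  # analyse truncations as deletion runs (no soft-clipping) so chain loss
  # shows up as correlated consecutive deletions
  prof <- error_profile(rs, w$lib,
                        scoring = align_scoring(clip_truncations = FALSE))
  dm <- dinucleotide_distribution(prof)
  # blocking: a deletion is most likely followed by another deletion
  expect_equal(unname(which.max(dm["deletion", ])), 5L)
  expect_gt(dm["deletion", "deletion"], 0.3)
})

test_that("two-stage synthesis steps indel rates up after the boundary", {
  w <- toy_world(n = 30, len = 30, rows = 240, cols = 240, seed = 65)
  chem <- chem_params(molecules_per_feature = 60,
                      baseline_substitution_rate = 0,
                      stage2_after_cycle = 45L,
                      stage2_block_rate = 0.03,
                      stage2_coupling_factor = 0.98)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(0.95), chem,
                           seed = 66)
  prof <- error_profile(rs, w$lib)
  pc <- per_cycle_rates(prof)
  early <- pc$deletion[pc$cycle < 45 & pc$n > 200]
  late <- pc$deletion[pc$cycle >= 50 & pc$n > 200]
  expect_gt(mean(late), mean(early) + 1)
})

test_that("SAM ingestion reproduces hand-constructed event positions", {
  ref <- "ACGTACGTACGTACGTACGT"  # 20 nt
  refs <- c(panel1 = ref)
  # record 1: 5S10M2D5M with one substitution at reference position 4
  #   read: 5 clipped bases + ref[1:10] with pos 4 changed + ref[13:17]
  seq1 <- paste0("NNNNN", "ACGAACGTAC", "TACGT")
  rec1 <- paste("r1", 0, "panel1", 1, 60, "5S10M2D5M", "*", 0, 0, seq1,
                "*", "MD:Z:3T6^GT5", sep = "\t")
  # record 2: clean insertion: 8M1I12M
  seq2 <- paste0(substr(ref, 1, 8), "G", substr(ref, 9, 20))
  rec2 <- paste("r2", 0, "panel1", 1, 60, "8M1I12M", "*", 0, 0, seq2,
                "*", "MD:Z:20", sep = "\t")
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:panel1\tLN:20", rec1, rec2)
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  ing <- read_sam(f, refs)
  ev1 <- ing$flat$events[1:20]
  expect_equal(ev1[4], 1L)                  # T->A substitution observed A
  expect_equal(ev1[c(1:3, 5:10)], rep(0L, 9))
  expect_equal(ev1[11:12], c(5L, 5L))       # the 2D block
  expect_equal(ev1[13:17], rep(0L, 5))
  expect_equal(ev1[18:20], rep(6L, 3))      # beyond the aligned span
  expect_equal(ing$flat$ins_pos, 8L)
  expect_equal(ing$flat$ins_seq, "G")
  prof <- error_profile(NULL, refs, events = ing)
  expect_equal(prof$n_reads, 2L)
  expect_gt(prof$rates[["deletion"]], 0)
  # malformed records raise with a line number
  writeLines(c("@HD\tVN:1.6", "r3\t0\tpanel1"), f)
  expect_error(read_sam(f, refs), "malformed SAM record at line 2")
})
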