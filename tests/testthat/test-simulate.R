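test_that("perfect chemistry reproduces every reference exactly", {
  w <- toy_world(n = 10, len = 14)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(yield = 1),
                           perfect_chem(molecules_per_feature = 30), seed = 2)
  refs <- w$lib$sequence[match(rs$reference_id, w$lib$id)]
  expect_identical(rs$sequence, refs)
})

test_that("simulation is deterministic for a fixed seed", {
  w <- toy_world(n = 6, len = 12)
  chem <- chem_params(molecules_per_feature = 20)
  rs1 <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(), chem,
                            seed = 9)
  rs2 <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(), chem,
                            seed = 9)
  expect_identical(as.data.frame(rs1), as.data.frame(rs2))
  rs3 <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(), chem,
                            seed = 10)
  expect_false(identical(rs1$sequence, rs3$sequence))
})

test_that("95% photolysis yields ~5% missing bases per read", {
  w <- toy_world(n = 40, len = 30, rows = 120, cols = 120)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(0.95),
                           perfect_chem(molecules_per_feature = 100),
                           seed = 4)
  # each scheduled coupling succeeds iff its own deprotection fired: the
  # shortfall in total synthesised bases is binomial(n_bases, 0.05)
  n_bases <- 40 * 100 * 30
  missing <- n_bases - sum(nchar(rs$sequence))
  se <- sqrt(n_bases * 0.05 * 0.95)
  expect_lt(abs(missing - 0.05 * n_bases), 3 * se)
})

test_that("a failed G coupling is rescued by the next flowed base (oracle)", {
  # single feature, sequence 5'-TG-3': G couples first (cycle 2), then T
  # (cycle 3). With e_G = 0.9, e_T = 1, perfect photolysis and no capping,
  # exhaustive enumeration of the event tree gives
  #   P(read "TG") = 0.9          (G coupled, then T)
  #   P(read "T")  = 0.1          (G failed; the T flow at cycle 3 rescues
  #                                the free terminus exactly once)
  lib <- data.frame(id = "o1", sequence = "TG")
  lay <- build_layout("2SZ", dmd_geometry(rows = 6, cols = 6),
                      n_features = 1, oligo_ids = "o1")
  st <- generate_masks(lay, lib)
  expect_equal(st$feature_cycles[["f000001"]], c(2L, 3L))
  M <- 4000
  rs <- simulate_synthesis(lib, lay, st, quiet_photo(yield = 1),
                           chem_params(coupling_efficiency =
                                         c(A = 1, C = 1, G = 0.9, T = 1),
                                       baseline_substitution_rate = 0,
                                       molecules_per_feature = M), seed = 3)
  p_hat <- mean(rs$sequence == "T")
  se <- sqrt(0.1 * 0.9 / M)
  expect_lt(abs(p_hat - 0.1), 3 * se)
  expect_setequal(unique(rs$sequence), c("TG", "T"))
})

test_that("sequencing noise is a uniform per-base substitution floor", {
  set.seed(31)
  reads <- random_dna(2000, 50)
  expect_identical(add_sequencing_noise(reads, 0), reads)
  rate <- 0.01
  noisy <- add_sequencing_noise(reads, rate)
  expect_equal(nchar(noisy), nchar(reads))
  o <- unlist(strsplit(reads, "")); nn <- unlist(strsplit(noisy, ""))
  n_sub <- sum(o != nn)
  n <- length(o)
  expect_lt(abs(n_sub - n * rate), 3 * sqrt(n * rate * (1 - rate)))
  # substitutions uniform over the three alternatives
  tab <- table(factor(nn[o != nn], c("A", "C", "G", "T")),
               factor(o[o != nn], c("A", "C", "G", "T")))
  off <- tab[row(tab) != col(tab)]
  expect_gt(stats::chisq.test(off)$p.value, 1e-4)
})

test_that("truth tables join reads to layout coordinates", {
  w <- toy_world(n = 8, len = 10)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(),
                           chem_params(molecules_per_feature = 5), seed = 1)
  tt <- truth_table(rs, w$lay)
  expect_equal(nrow(tt), nrow(rs))
  expect_true(all(tt$feature_id %in% w$lay$feature_id))
  i <- match(tt$feature_id, w$lay$feature_id)
  expect_equal(tt$row, w$lay$row[i])
  expect_equal(tt$col, w$lay$col[i])
})

test_that("capping truncates: shorter reads, absorbed capped state", {
  w <- toy_world(n = 20, len = 25, rows = 120, cols = 120)
  chem_u <- chem_params(coupling_efficiency = c(A = 0.97, C = 0.97,
                                                G = 0.97, T = 0.97),
                        baseline_substitution_rate = 0,
                        molecules_per_feature = 100)
  chem_c <- chem_params(coupling_efficiency = c(A = 0.97, C = 0.97,
                                                G = 0.97, T = 0.97),
                        baseline_substitution_rate = 0, capping_enabled = TRUE,
                        molecules_per_feature = 100)
  rs_u <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(yield = 1),
                             chem_u, seed = 5)
  rs_c <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(yield = 1),
                             chem_c, seed = 5)
  expect_lt(mean(nchar(rs_c$sequence)), mean(nchar(rs_u$sequence)))
})

test_that("blocking produces excess long deletion runs", {
  w <- toy_world(n = 20, len = 25, rows = 120, cols = 120)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, quiet_photo(yield = 1),
                           perfect_chem(molecules_per_feature = 50,
                                        block_rate = 0.01), seed = 6)
  # blocked molecules stop early: read lengths spread far below the full 25
  expect_gt(sum(nchar(rs$sequence) < 20), 0.1 * nrow(rs))
})

test_that("wait-number mechanism: stray insertions accumulate with waits", {
  # constant global scatter; insertion chance between two couplings grows
  # with the number of intervening exposure cycles
  w <- toy_world(n = 30, len = 25, rows = 120, cols = 120)
  photo <- photochem_params(global_scatter_coeff = 0.05, side_leak = 0,
                            corner_leak = 0, edge_falloff_amplitude = 0)
  rs <- simulate_synthesis(w$lib, w$lay, w$stack, photo,
                           perfect_chem(molecules_per_feature = 60), seed = 8)
  prof <- error_profile(rs, w$lib)
  wh <- insertion_wait_histogram(prof)
  expect_true(all(diff(wh) > 0))  # strictly increasing from wait 1 to 4
})
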