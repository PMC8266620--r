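test_that("active mirror fractions match the design geometry", {
  expect_equal(active_mirror_fraction("2SZ"), 16 / 36)
  expect_equal(active_mirror_fraction("4SZ"), 4 / 36)
  expect_equal(active_mirror_fraction("CB"), 0.5)
  expect_equal(active_mirror_fraction("CB", cb_full = TRUE), 1)
  # exact factor-of-four density contrast between the two street designs
  expect_equal(active_mirror_fraction("2SZ") / active_mirror_fraction("4SZ"),
               4)
})

test_that("layouts tile the grid within capacity and without overlap", {
  geom <- dmd_geometry()  # 1024 x 768
  expect_equal(geom$rows * geom$cols, 786432)
  lay <- build_layout("2SZ", geom, n_features = 200,
                      oligo_ids = sprintf("o%03d", 1:200), seed = 1)
  expect_equal(nrow(lay), 200)
  expect_true(all(lay$height == 4 & lay$width == 4))
  expect_equal(feature_edge_um(lay), 56)
  # blocks in bounds and pairwise non-overlapping (unit-cell tiling)
  expect_true(all(lay$row + lay$height <= geom$rows))
  expect_true(all(lay$col + lay$width <= geom$cols))
  expect_false(anyDuplicated(lay[, c("row", "col")]) > 0)
  expect_true(all(diff(sort(unique(lay$col))) >= 6))
  # 12x12 grid holds exactly 4 features at deterministic positions
  small <- build_layout("2SZ", dmd_geometry(rows = 12, cols = 12),
                        n_features = 4, oligo_ids = paste0("o", 1:4))
  expect_equal(small$row, c(0L, 0L, 6L, 6L))
  expect_equal(small$col, c(0L, 6L, 0L, 6L))
  expect_error(build_layout("2SZ", dmd_geometry(rows = 12, cols = 12),
                            n_features = 5), "capacity")
  # full-density checkerboard holds one feature per mirror
  cb <- build_layout("CB", dmd_geometry(rows = 8, cols = 8),
                     n_features = 64, cb_full = TRUE)
  expect_equal(nrow(cb), 64)
  expect_equal(active_mirror_fraction(cb), 1)
  # parity checkerboard: no two features share a side
  cb2 <- build_layout("CB", dmd_geometry(rows = 8, cols = 8), n_features = 32)
  expect_true(all((cb2$row + cb2$col) %% 2 == 0))
})

test_that("oligo assignment is a seeded random permutation", {
  lay1 <- build_layout("4SZ", dmd_geometry(rows = 60, cols = 60),
                       n_features = 50, oligo_ids = sprintf("o%02d", 1:50),
                       seed = 3)
  lay2 <- build_layout("4SZ", dmd_geometry(rows = 60, cols = 60),
                       n_features = 50, oligo_ids = sprintf("o%02d", 1:50),
                       seed = 3)
  expect_identical(lay1$oligo_id, lay2$oligo_id)
  expect_setequal(lay1$oligo_id, sprintf("o%02d", 1:50))
  lay3 <- build_layout("4SZ", dmd_geometry(rows = 60, cols = 60),
                       n_features = 50, oligo_ids = sprintf("o%02d", 1:50),
                       seed = 4)
  expect_false(identical(lay1$oligo_id, lay3$oligo_id))
})

test_that("concentric areas partition features from centre to corners", {
  lay <- build_layout("2SZ", dmd_geometry(rows = 120, cols = 120),
                      n_features = 400,
                      oligo_ids = sprintf("o%03d", 1:400))
  expect_setequal(unique(lay$area), 1:4)
  centre <- lay$feature_id[which.min((lay$row - 58)^2 + (lay$col - 58)^2)]
  expect_equal(concentric_area_of(lay, centre), 1L)
  expect_equal(concentric_area_of(lay, lay$feature_id[1]), 4L)  # corner
})

test_that("cycles_required follows the A->C->G->T wait arithmetic", {
  expect_equal(cycles_required("A"), 1L)
  expect_equal(cycles_required("AC"), 5L)
  expect_equal(cycles_required("GGG"), 11L)
  expect_equal(cycles_required(c("T", "ACGT")), c(4L, 13L))
  expect_error(cycles_required("ACX"), "invalid characters")
})

test_that("mask stacks obey the flow order and round-trip sequences", {
  lib <- data.frame(id = c("o1", "o2"), sequence = c("T", "AC"))
  lay <- build_layout("2SZ", dmd_geometry(rows = 12, cols = 12),
                      n_features = 2, oligo_ids = c("o1", "o2"), seed = 1)
  st <- generate_masks(lay, lib)
  f_t <- lay$feature_id[lay$oligo_id == "o1"]
  f_ac <- lay$feature_id[lay$oligo_id == "o2"]
  expect_equal(st$feature_cycles[[f_t]], 3L)           # T at cycle 3
  expect_equal(st$feature_cycles[[f_ac]], c(1L, 4L))   # C then A
  expect_equal(st$n_cycles, 5L)
  expect_equal(st$base, c("A", "C", "G", "T", "A"))
  dec <- decode_masks(st)
  expect_equal(unname(dec[c(f_t, f_ac)]), c("T", "AC"))
})

test_that("mask/sequence duality holds on random libraries (property)", {
  for (seed in c(2, 13)) {
    w <- toy_world(n = 16, len = 18, seed = seed)
    dec <- decode_masks(w$stack)
    refs <- w$lib$sequence[match(w$lay$oligo_id, w$lib$id)]
    expect_equal(unname(dec[w$lay$feature_id]), refs)
    # cycles_required equals last ON cycle + 1
    last_on <- vapply(w$stack$feature_cycles, function(x) x[length(x)], 1L)
    expect_equal(unname(last_on[w$lay$feature_id] + 1L),
                 cycles_required(w$lib$sequence[match(w$lay$oligo_id,
                                                      w$lib$id)]))
  }
})

test_that("PBM mask files round-trip and recount ON mirrors", {
  w <- toy_world(n = 4, len = 6, rows = 12, cols = 12)
  dir <- withr::local_tempdir()
  paths <- write_masks(w$stack, w$lay, dir)
  expect_length(paths, w$stack$n_cycles)
  st2 <- read_masks(dir, w$lay)
  expect_equal(st2$n_cycles, w$stack$n_cycles)
  expect_equal(st2$base, w$stack$base)
  expect_equal(lapply(st2$on_features, sort),
               lapply(w$stack$on_features, sort))
  expect_equal(st2$feature_cycles[order(names(st2$feature_cycles))],
               w$stack$feature_cycles[order(names(w$stack$feature_cycles))])
  # pixel sum of mask c = ON mirror count of cycle c
  px <- vapply(paths, function(p) {
    lines <- readLines(p)
    sum(as.integer(unlist(strsplit(trimws(
      lines[!grepl("^(P1|#)", lines)][-1]), "\\s+"))))
  }, 1)
  expect_equal(unname(px), lengths(w$stack$on_features) * 16)
  expect_error(read_masks(dir, build_layout("2SZ", dmd_geometry(18, 18),
                                            n_features = 4,
                                            oligo_ids = w$lib$id[1:4])),
               "dimension mismatch")
})
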