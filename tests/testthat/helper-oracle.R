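# Independent brute-force alignment oracle: plain recursion over edit
# operations with memoisation on (i, j, previous op). Gap run of length L
# costs gap_open + L * gap_extend. Only used on short pairs.
oracle_align_score <- function(read, reference, match = 1, mismatch = -2,
                               gap_open = -4, gap_extend = -1) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(reference, "")[[1]]
  n <- length(rd); m <- length(rf)
  memo <- new.env(hash = TRUE)
  # ops: "s" diagonal, "d" gap in read (deletion), "i" gap in ref (insertion)
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      sc <- if (rd[i + 1] == rf[j + 1]) match else mismatch
      best <- max(best, sc + rec(i + 1, j + 1, "s"))
    }
    if (j < m) {
      cost <- gap_extend + if (prev == "d") 0 else gap_open
      best <- max(best, cost + rec(i, j + 1, "d"))
    }
    if (i < n) {
      cost <- gap_extend + if (prev == "i") 0 else gap_open
      best <- max(best, cost + rec(i + 1, j, "i"))
    }
    memo[[key]] <- best
    best
  }
  rec(0, 0, "x")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# Small assembled test world: panel + layout + masks.
toy_world <- function(n = 12, len = 15, design = "2SZ", rows = 48, cols = 48,
                      seed = 7) {
  spec <- design_spec(n, len, k = 2, min_oligo_coverage = 1, seed = seed)
  lib <- design_library(spec)
  geom <- dmd_geometry(rows = rows, cols = cols)
  lay <- build_layout(design, geom, n_features = n, oligo_ids = lib$id,
                      seed = seed)
  list(lib = lib, lay = lay, stack = generate_masks(lay, lib), geom = geom)
}

# Photochemistry with every stray channel off and flat illumination.
quiet_photo <- function(yield = 0.95, ...) {
  photochem_params(k_rate = if (yield >= 1) 1e9 else
    calibrate_photolysis_rate(yield, 3),
    global_scatter_coeff = 0, side_leak = 0, corner_leak = 0,
    edge_falloff_amplitude = 0, ...)
}

perfect_chem <- function(...) {
  chem_params(coupling_efficiency = c(A = 1, C = 1, G = 1, T = 1),
              baseline_substitution_rate = 0, ...)
}
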