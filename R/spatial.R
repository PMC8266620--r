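#' Map per-feature error profiles onto array coordinates
#'
#' Joins the per-feature aggregates of an [error_profile()] with the layout:
#' one record per layout feature with its grid coordinates, concentric area
#' index, read counts and per-bp rates. Features with fewer than `min_reads`
#' readable reads are flagged low-coverage (their rates are reported but
#' should be interpreted with care); features with no reads at all are
#' flagged missing.
#'
#' @param profile An `error_profile` built from reads carrying feature ids.
#' @param layout The `array_layout`.
#' @param min_reads Minimum readable reads per feature (default 5).
#' @return A `spatial_error_map`: data.frame with `feature_id`, `grid_row`,
#'   `grid_col`, `area`, `reads`, `readable`, `deletion`, `insertion`,
#'   `substitution` (% per bp), `low_coverage`, `missing`.
#' @export
feature_profiles <- function(profile, layout, min_reads = 5L) {
  stopifnot(inherits(profile, "error_profile"))
  pf <- profile$per_feature
  if (is.null(pf)) stop("profile carries no per-feature aggregates")
  unknown <- setdiff(pf$feature_id, layout$feature_id)
  if (length(unknown) > 0)
    warning(length(unknown), " feature id(s) in reads not present in layout")
  i <- match(layout$feature_id, pf$feature_id)
  reads <- ifelse(is.na(i), 0L, pf$reads[i])
  readable <- ifelse(is.na(i), 0L, pf$readable[i])
  den <- ifelse(is.na(i), 0L, pf$ref_bases[i])
  rate <- function(cnt) ifelse(den > 0, 100 * cnt / pmax(den, 1L), NA_real_)
  out <- data.frame(
    feature_id = layout$feature_id,
    grid_row = layout$grid_row, grid_col = layout$grid_col,
    area = layout$area,
    reads = reads, readable = readable, ref_bases = den,
    deletion = rate(ifelse(is.na(i), 0L, pf$del[i])),
    insertion = rate(ifelse(is.na(i), 0L, pf$ins[i])),
    substitution = rate(ifelse(is.na(i), 0L, pf$sub[i])),
    low_coverage = readable < min_reads,
    missing = reads == 0L,
    stringsAsFactors = FALSE)
  structure(out, min_reads = as.integer(min_reads),
            class = c("spatial_error_map", "data.frame"))
}

#' @export
print.spatial_error_map <- function(x, ...) {
  cat("Spatial error map:", nrow(x), "features;",
      sum(x$missing), "missing,", sum(x$low_coverage), "low-coverage\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more\n")
  invisible(x)
}

#' Concentric-area error summary
#'
#' Per-area mean rates, weighted by the per-feature reference-base
#' denominators (so aggregating all areas reproduces the global rates),
#' plus feature, missing and low-coverage counts.
#'
#' @param map A `spatial_error_map`.
#' @return data.frame with one row per area.
#' @export
area_summary <- function(map) {
  stopifnot(inherits(map, "spatial_error_map"))
  areas <- sort(unique(map$area))
  do.call(rbind, lapply(areas, function(a) {
    s <- map[map$area == a, ]
    w <- s$ref_bases
    wm <- function(v) if (sum(w) > 0)
      sum(v * w, na.rm = TRUE) / sum(w[!is.na(v)]) else NA_real_
    data.frame(area = a, features = nrow(s),
               reads = sum(s$reads), readable = sum(s$readable),
               missing = sum(s$missing),
               low_coverage = sum(s$low_coverage),
               deletion = wm(s$deletion), insertion = wm(s$insertion),
               substitution = wm(s$substitution))
  }))
}

#' Detect unreadable features and spatial blobs of them
#'
#' A feature is unreadable when it has fewer than `min_reads` readable
#' alignments. Spatially contiguous groups (4-connectivity on the feature
#' grid) of at least `min_blob` unreadable features are reported with their
#' bounding boxes -- the signature of a locally failed region (e.g. an air
#' meniscus in the UV-absorber backfill).
#'
#' @param map A `spatial_error_map`.
#' @param min_reads Readable-read threshold (default 5).
#' @param min_blob Minimum features per reported blob (default 4).
#' @return List with `features` (character vector of unreadable feature
#'   ids) and `blobs` (data.frame `blob`, `n`, `row_min`, `row_max`,
#'   `col_min`, `col_max` in feature-grid coordinates).
#' @export
detect_unreadable <- function(map, min_reads = 5L, min_blob = 4L) {
  stopifnot(inherits(map, "spatial_error_map"))
  bad <- map$readable < min_reads
  feats <- map$feature_id[bad]
  blobs <- data.frame(blob = integer(0), n = integer(0),
                      row_min = integer(0), row_max = integer(0),
                      col_min = integer(0), col_max = integer(0))
  if (any(bad)) {
    gr <- max(map$grid_row) + 1L; gc <- max(map$grid_col) + 1L
    lab <- matrix(0L, gr, gc)
    badm <- matrix(FALSE, gr, gc)
    badm[cbind(map$grid_row + 1L, map$grid_col + 1L)] <- bad
    nlab <- 0L
    for (r in seq_len(gr)) for (cc in seq_len(gc)) {
      if (!badm[r, cc] || lab[r, cc] != 0L) next
      nlab <- nlab + 1L
      queue <- matrix(c(r, cc), ncol = 2)
      lab[r, cc] <- nlab
      while (nrow(queue) > 0) {
        cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- cur[1] + d[1]; c2 <- cur[2] + d[2]
          if (rr >= 1 && rr <= gr && c2 >= 1 && c2 <= gc &&
              badm[rr, c2] && lab[rr, c2] == 0L) {
            lab[rr, c2] <- nlab
            queue <- rbind(queue, c(rr, c2))
          }
        }
      }
    }
    if (nlab > 0) {
      blobs <- do.call(rbind, lapply(seq_len(nlab), function(b) {
        w <- which(lab == b, arr.ind = TRUE)
        data.frame(blob = b, n = nrow(w),
                   row_min = min(w[, 1]) - 1L, row_max = max(w[, 1]) - 1L,
                   col_min = min(w[, 2]) - 1L, col_max = max(w[, 2]) - 1L)
      }))
      blobs <- blobs[blobs$n >= min_blob, , drop = FALSE]
    }
  }
  list(features = feats, blobs = blobs)
}

#' Export a spatial metric as a grid
#'
#' Arranges one metric of a `spatial_error_map` on the feature grid,
#' optionally log10-scaled (useful for read counts), with missing features
#' encoded as `NA` (written as the string `NA` in the TSV).
#'
#' @param map A `spatial_error_map`.
#' @param metric One of `"deletion"`, `"insertion"`, `"substitution"`,
#'   `"reads"`.
#' @param file Optional TSV path; when given, the grid is written and the
#'   path returned invisibly.
#' @param log10 Log10-transform the values (zeros become `NA`).
#' @return The grid matrix (feature-grid rows x columns).
#' @export
export_heatmap <- function(map, metric = c("deletion", "insertion",
                                           "substitution", "reads"),
                           file = NULL, log10 = FALSE) {
  stopifnot(inherits(map, "spatial_error_map"))
  metric <- match.arg(metric)
  gr <- max(map$grid_row) + 1L; gc <- max(map$grid_col) + 1L
  grid <- matrix(NA_real_, gr, gc)
  v <- map[[metric]]
  if (log10) v <- ifelse(v > 0, log10(v), NA_real_)
  grid[cbind(map$grid_row + 1L, map$grid_col + 1L)] <- v
  if (!is.null(file)) {
    utils::write.table(grid, file, sep = "\t", row.names = FALSE,
                       col.names = FALSE, na = "NA")
    return(invisible(grid))
  }
  grid
}

#' Read a heatmap grid back from TSV
#'
#' Round-trips with [export_heatmap()].
#'
#' @param file TSV path.
#' @return Numeric matrix with `NA` for missing features.
#' @export
read_heatmap <- function(file) {
  as.matrix(utils::read.table(file, sep = "\t", na.strings = "NA",
                              header = FALSE))
}

#' Permutation test for an area rate contrast
#'
#' Tests whether the read-weighted mean of a metric differs between two
#' concentric areas beyond what random relabelling of features explains.
#' Under flat illumination the contrast should be null; under edge
#' fall-off, deletion rates in the outer area exceed the centre.
#'
#' @param map A `spatial_error_map`.
#' @param metric Metric column name (default `"deletion"`).
#' @param areas Two area indices to contrast (default `c(1, 4)`).
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @return List with `observed` (area2 minus area1 weighted mean),
#'   `p_value` (two-sided) and `n_perm`.
#' @export
area_permutation_test <- function(map, metric = "deletion",
                                  areas = c(1, 4), n_perm = 999L,
                                  seed = 1L) {
  stopifnot(inherits(map, "spatial_error_map"), length(areas) == 2)
  s <- map[map$area %in% areas & !map$missing & !is.na(map[[metric]]), ]
  if (nrow(s) < 4) stop("too few features in the contrasted areas")
  v <- s[[metric]]; w <- s$ref_bases; a <- s$area
  contrast <- function(a) {
    m2 <- sum(v[a == areas[2]] * w[a == areas[2]]) / sum(w[a == areas[2]])
    m1 <- sum(v[a == areas[1]] * w[a == areas[1]]) / sum(w[a == areas[1]])
    m2 - m1
  }
  obs <- contrast(a)
  set.seed(seed)
  null <- replicate(n_perm, contrast(sample(a)))
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p_value = p, n_perm = n_perm)
}
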