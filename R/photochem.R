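#' Photochemistry and stray-light parameters
#'
#' Collects the dose model for maskless array synthesis. Photodeprotection
#' follows first-order kinetics in radiant exposure: yield(E) = 1 - exp(-kE).
#' The default rate constant is calibrated so a 3 J/cm2 exposure removes
#' ~95% of the photolabile 5'-protecting groups. Stray light received by an
#' OFF feature during one exposure event has three terms: global scatter
#' proportional to the ON-mirror fraction of the mask, side/corner leakage
#' from adjacent ON features, and an optional uniform reflection dose over a
#' configurable rectangle (modelling loss of the UV-absorbing backfill, e.g.
#' an air meniscus in one corner), optionally active only after a fraction
#' of the synthesis.
#'
#' @param k_rate Photolysis rate constant per (J/cm2); default calibrated to
#'   95% yield at 3 J/cm2.
#' @param nominal_exposure Radiant exposure per intended exposure event in
#'   J/cm2 (default 3).
#' @param global_scatter_coeff Stray dose per unit ON-mirror fraction, as a
#'   fraction of the nominal dose (default 0; see [calibrate_scatter()]).
#' @param side_leak Fraction of the nominal dose leaked into a side-adjacent
#'   feature per full exposure (default 0.005, i.e. ~0.5%).
#' @param corner_leak Same for corner-adjacent features (default 0.0005).
#' @param edge_falloff_amplitude,edge_falloff_exponent Illumination profile
#'   1 - a * r^b over the normalised radial distance r from the array
#'   centre (defaults a = 0.1, b = 4: flat centre, fall-off near the border).
#' @param reflection_enabled Enable the reflection term.
#' @param reflection_extra_dose Reflection dose as a fraction of nominal.
#' @param reflection_region Rectangle `c(row0, col0, row1, col1)` in mirror
#'   coordinates (0-based, inclusive) affected by reflection.
#' @param reflection_after_fraction Reflection active only in cycles after
#'   this fraction of the run (default 0 = whole run).
#' @param numerical_aperture,wavelength Informational optics constants
#'   (defaults 0.08 and 365 nm).
#' @return A `photochem_params` object.
#' @export
photochem_params <- function(k_rate = calibrate_photolysis_rate(0.95, 3),
                             nominal_exposure = 3,
                             global_scatter_coeff = 0,
                             side_leak = 0.005,
                             corner_leak = 0.0005,
                             edge_falloff_amplitude = 0.1,
                             edge_falloff_exponent = 4,
                             reflection_enabled = FALSE,
                             reflection_extra_dose = 0,
                             reflection_region = c(0L, 0L, 0L, 0L),
                             reflection_after_fraction = 0,
                             numerical_aperture = 0.08,
                             wavelength = 365) {
  stopifnot(k_rate > 0, nominal_exposure >= 0,
            global_scatter_coeff >= 0, global_scatter_coeff <= 1,
            side_leak >= 0, side_leak <= 1,
            corner_leak >= 0, corner_leak <= 1,
            edge_falloff_amplitude >= 0, edge_falloff_amplitude <= 1,
            reflection_extra_dose >= 0, reflection_extra_dose <= 1,
            reflection_after_fraction >= 0, reflection_after_fraction <= 1)
  structure(as.list(environment()), class = "photochem_params")
}

#' Calibrate the photolysis rate constant
#'
#' Inverts first-order kinetics: given a measured deprotection yield at a
#' known radiant exposure, k = -log(1 - yield) / exposure, so that
#' [photolysis_yield()] round-trips.
#'
#' @param yield Deprotection yield in (0, 1).
#' @param exposure Radiant exposure in J/cm2 (> 0).
#' @return Rate constant per (J/cm2).
#' @examples
#' calibrate_photolysis_rate(0.95, 3)  # ~0.9986
#' @export
calibrate_photolysis_rate <- function(yield, exposure) {
  if (!is.numeric(yield) || yield <= 0 || yield >= 1)
    stop("yield must be in (0, 1)")
  stopifnot(exposure > 0)
  -log(1 - yield) / exposure
}

#' Photodeprotection yield under first-order kinetics
#'
#' @param exposure Radiant exposure in J/cm2 (>= 0; vectorised).
#' @param k_rate Rate constant per (J/cm2).
#' @return Fraction deprotected, 1 - exp(-k * E).
#' @examples
#' k <- calibrate_photolysis_rate(0.95, 3)
#' photolysis_yield(6, k)  # ~0.9975
#' @export
photolysis_yield <- function(exposure, k_rate) {
  if (any(exposure < 0)) stop("negative exposure")
  1 - exp(-k_rate * exposure)
}

#' Relative illumination of a feature
#'
#' Parametric flat-top profile 1 - a * r^b, where r is the normalised
#' radial distance of the feature centre from the array centre (Euclidean
#' in axis-normalised coordinates, scaled so the corners sit at r = 1):
#' 1 at the centre, strictly lower at edge midpoints than at the centre,
#' minimum at the corners.
#'
#' @param layout An `array_layout`.
#' @param feature_id Feature id(s); default all features in layout order.
#' @param params A [photochem_params()] (supplies a and b).
#' @return Relative intensity in (0, 1].
#' @export
illumination_factor <- function(layout, feature_id = NULL,
                                params = photochem_params()) {
  g <- attr(layout, "geometry")
  df <- as.data.frame(layout)
  if (!is.null(feature_id)) {
    i <- match(feature_id, df$feature_id)
    if (anyNA(i)) stop("unknown feature id(s)")
    df <- df[i, , drop = FALSE]
  }
  r0 <- g$rows / 2; c0 <- g$cols / 2
  r <- sqrt(((df$row + df$height / 2 - r0) / r0)^2 +
              ((df$col + df$width / 2 - c0) / c0)^2) / sqrt(2)
  1 - params$edge_falloff_amplitude * r^params$edge_falloff_exponent
}

## ON-mirror fraction of one cycle's mask.
.mask_on_fraction <- function(layout, on_ids) {
  g <- attr(layout, "geometry")
  i <- match(on_ids, layout$feature_id)
  sum(layout$height[i] * layout$width[i]) / (g$rows * g$cols)
}

## Feature-grid neighbour lookup: index matrix by (grid_row, grid_col).
.grid_index <- function(layout) {
  gr <- max(layout$grid_row) + 1L
  gc <- max(layout$grid_col) + 1L
  m <- matrix(NA_integer_, nrow = gr, ncol = gc)
  m[cbind(layout$grid_row + 1L, layout$grid_col + 1L)] <- seq_len(nrow(layout))
  m
}

## Counts of ON side/corner neighbours for every feature given ON flags.
.neighbour_on_counts <- function(grid_idx, on_flag) {
  gr <- nrow(grid_idx); gc <- ncol(grid_idx)
  onm <- matrix(FALSE, gr, gc)
  filled <- !is.na(grid_idx)
  onm[filled] <- on_flag[grid_idx[filled]]
  pad <- matrix(FALSE, gr + 2L, gc + 2L)
  pad[2:(gr + 1L), 2:(gc + 1L)] <- onm
  side <- pad[1:gr, 2:(gc + 1L)] + pad[3:(gr + 2L), 2:(gc + 1L)] +
    pad[2:(gr + 1L), 1:gc] + pad[2:(gr + 1L), 3:(gc + 2L)]
  corner <- pad[1:gr, 1:gc] + pad[1:gr, 3:(gc + 2L)] +
    pad[3:(gr + 2L), 1:gc] + pad[3:(gr + 2L), 3:(gc + 2L)]
  list(side_m = side, corner_m = corner)
}

#' Stray dose received by an OFF feature during one exposure
#'
#' dose = nominal * (g * f_ON + side_leak * n_side_ON / 4 +
#' corner_leak * n_corner_ON / 4 + reflection term), where f_ON is the
#' ON-mirror fraction of the mask, n_side_ON / n_corner_ON count ON
#' neighbours in the feature grid, and the reflection term applies when
#' enabled and the feature lies in the affected rectangle.
#'
#' @param layout An `array_layout`.
#' @param stack A `mask_stack`.
#' @param cycle 0-based cycle index of the exposure event.
#' @param feature_id A single feature id, OFF at that cycle.
#' @param params A [photochem_params()].
#' @return Stray dose in J/cm2.
#' @export
stray_dose <- function(layout, stack, cycle, feature_id, params) {
  on_ids <- stack$on_features[[cycle + 1L]]
  if (feature_id %in% on_ids)
    stop("feature ", feature_id, " is ON at cycle ", cycle,
         ": stray dose undefined (intended dose applies)")
  i <- match(feature_id, layout$feature_id)
  if (is.na(i)) stop("unknown feature id: ", feature_id)
  f_on <- .mask_on_fraction(layout, on_ids)
  gi <- .grid_index(layout)
  on_flag <- layout$feature_id %in% on_ids
  nb <- .neighbour_on_counts(gi, on_flag)
  pos <- cbind(layout$grid_row[i] + 1L, layout$grid_col[i] + 1L)
  n_side <- nb$side_m[pos]
  n_corner <- nb$corner_m[pos]
  refl <- .reflection_dose_fraction(layout, params, cycle, stack$n_cycles)[i]
  params$nominal_exposure *
    (params$global_scatter_coeff * f_on +
       params$side_leak * n_side / 4 +
       params$corner_leak * n_corner / 4 +
       refl)
}

## Per-feature reflection dose fraction at a given cycle (vector over
## features); zero when disabled or before the activation fraction.
.reflection_dose_fraction <- function(layout, params, cycle, n_cycles) {
  out <- numeric(nrow(layout))
  if (!params$reflection_enabled) return(out)
  if (n_cycles > 0 &&
      cycle < params$reflection_after_fraction * n_cycles) return(out)
  rg <- params$reflection_region
  inside <- layout$row >= rg[1] & layout$col >= rg[2] &
    (layout$row + layout$height - 1L) <= rg[3] &
    (layout$col + layout$width - 1L) <= rg[4]
  out[inside] <- params$reflection_extra_dose
  out
}

#' Calibrate the global scatter coefficient against a target insertion rate
#'
#' Runs small pilot simulations through the full simulate -> align ->
#' profile path. The insertion rate is modelled as baseline + slope * g:
#' the baseline (diffraction leakage, reflection, noise) is measured once
#' at g = 0, then the coefficient is rescaled on the excess over baseline
#' (global-scatter insertion pressure is approximately proportional to the
#' coefficient) until the target is met.
#'
#' @param target_insertion_rate Target insertion rate in % per bp
#'   (e.g. 0.6). Must exceed the zero-scatter baseline rate.
#' @param library,layout,stack Panel, layout and mask stack defining the
#'   density context (typically a 2SZ-like toy array).
#' @param photo,chem Parameter objects; `photo$global_scatter_coeff` is the
#'   value being calibrated (its current value seeds the search).
#' @param molecules_per_feature Pilot simulation depth (default 50).
#' @param seed RNG seed.
#' @param iterations Number of scale-and-rerun refinements (default 2).
#' @return Calibrated `global_scatter_coeff`.
#' @export
calibrate_scatter <- function(target_insertion_rate, library, layout, stack,
                              photo = photochem_params(),
                              chem = chem_params(),
                              molecules_per_feature = 50L, seed = 1L,
                              iterations = 2L) {
  stopifnot(target_insertion_rate > 0)
  chem$molecules_per_feature <- as.integer(molecules_per_feature)
  pilot <- function(g) {
    photo$global_scatter_coeff <- g
    rs <- simulate_synthesis(library, layout, stack, photo, chem,
                             seed = seed)
    unname(error_profile(rs, library)$rates["insertion"])
  }
  r0 <- pilot(0)
  if (target_insertion_rate <= r0)
    stop("target insertion rate ", target_insertion_rate,
         "% is at or below the zero-scatter baseline (", round(r0, 3),
         "%): nothing for global scatter to contribute")
  g <- if (photo$global_scatter_coeff > 0) photo$global_scatter_coeff else 0.01
  for (it in seq_len(iterations)) {
    r <- pilot(g)
    if (r <= r0) { g <- g * 4; next }
    g <- g * (target_insertion_rate - r0) / (r - r0)
  }
  g
}
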