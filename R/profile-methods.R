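#' @export
print.error_profile <- function(x, ...) {
  cat("Synthesis error profile\n")
  cat(sprintf("  reads: %d (%d readable, %d unreadable at identity < %g)\n",
              x$n_reads, x$n_readable, x$n_unreadable, x$min_identity))
  cat(sprintf("  reference bases (denominator): %d\n", x$denominator))
  r <- x$rates
  cat(sprintf("  error rates (%% per bp): total %.2f = deletion %.2f + insertion %.2f + substitution %.2f\n",
              r["total"], r["deletion"], r["insertion"], r["substitution"]))
  gt <- x$substitution_matrix["G", "T"]
  cat(sprintf("  G->T substitution: %.2f%% per bp\n", gt))
  invisible(x)
}

#' @export
summary.error_profile <- function(object, ...) {
  structure(list(profile = object), class = "summary.error_profile")
}

#' @export
print.summary.error_profile <- function(x, ...) {
  p <- x$profile
  print(p)
  cat("\nDeletion runs (% per bp, base-counted): x1",
      sprintf("%.3f", p$deletion_runs$bases["x1"]), " x2",
      sprintf("%.3f", p$deletion_runs$bases["x2"]), " x3+",
      sprintf("%.3f", p$deletion_runs$bases["x3"]), "\n")
  cat(sprintf("Mean deletion length: %.2f nt; mean insertion length: %.2f nt\n",
              p$mean_deletion_length, p$mean_insertion_length))
  cat("\nMatch matrix (rows sum to 1):\n")
  print(round(p$match_matrix, 3))
  cat("\nSubstitution matrix (% per bp):\n")
  print(round(p$substitution_matrix, 4))
  cat("\nInsertion wait-number histogram (cycles between flanking couplings):\n")
  print(p$wait_histogram)
  eff <- estimate_coupling_efficiencies(p)
  cat("\nStepwise coupling efficiencies (%):\n")
  print(eff, digits = 5)
  invisible(x)
}

#' Stepwise coupling-efficiency estimates of a profile
#'
#' @param object An `error_profile`.
#' @param type `"corrected"` (default) or `"naive"`; see
#'   [estimate_coupling_efficiencies()].
#' @param ... Unused.
#' @return Named numeric vector of per-base efficiencies in percent.
#' @export
coef.error_profile <- function(object, type = c("corrected", "naive"), ...) {
  type <- match.arg(type)
  eff <- estimate_coupling_efficiencies(object)
  stats::setNames(eff[[type]], eff$base)
}

#' Plot an error profile
#'
#' Base-graphics panels of the per-position and per-cycle deletion,
#' insertion and substitution rates.
#'
#' @param x An `error_profile`.
#' @param which `"position"` or `"cycle"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.error_profile <- function(x, which = c("position", "cycle"), ...) {
  which <- match.arg(which)
  if (which == "position") {
    pp <- x$per_position
    if (is.null(pp)) stop("no per-position profile (unequal reference lengths)")
    graphics::matplot(pp$position,
                      pp[, c("deletion", "insertion", "substitution")],
                      type = "l", lty = 1, col = c("firebrick", "steelblue",
                                                   "darkorange"),
                      xlab = "position (5'->3')", ylab = "% per position",
                      main = "Error rate by reference position", ...)
  } else {
    pc <- x$per_cycle
    graphics::matplot(pc$cycle,
                      pc[, c("deletion", "insertion", "substitution")],
                      type = "l", lty = 1, col = c("firebrick", "steelblue",
                                                   "darkorange"),
                      xlab = "synthesis cycle", ylab = "% per cycle",
                      main = "Error rate by synthesis cycle", ...)
  }
  graphics::legend("topright", c("deletion", "insertion", "substitution"),
                   lty = 1, col = c("firebrick", "steelblue", "darkorange"),
                   bty = "n")
  invisible(x)
}
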