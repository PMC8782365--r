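#' @export
print.pgg_trajectory <- function(x, ...) {
  ext <- attr(x, "extinction_generation")
  last <- x[nrow(x), ]
  cat(sprintf("<pgg_trajectory> seed %d, %d generations recorded\n",
              attr(x, "seed"), nrow(x) - 1L))
  if (!is.na(ext)) {
    cat(sprintf("  extinct at generation %d\n", ext))
  } else {
    cat(sprintf("  final cohort: N = %d (%.1f%% selfish), mean phi %.3f\n",
                last$N, 100 * last$frac_S, last$mean_phi))
  }
  invisible(x)
}

#' @export
print.pgg_ensemble <- function(x, ...) {
  cat(sprintf("<pgg_ensemble> %d realizations, T = %d, master seed %d\n",
              x$n_realizations, x$config$T, x$master_seed))
  cat(sprintf("  survived: %d/%d", sum(x$survived), x$n_realizations))
  if (any(!x$survived))
    cat(sprintf(" (mean extinction generation %.1f)",
                mean(x$extinction_generation[!x$survived])))
  cat("\n")
  invisible(x)
}

#' @describeIn run_ensemble equilibrium summary of an ensemble (see
#'   [equilibrium_summary()]).
#' @param object,... method arguments.
#' @param window_fraction equilibrium window passed on.
#' @export
summary.pgg_ensemble <- function(object, window_fraction = 0.10, ...) {
  equilibrium_summary(object, window_fraction)
}

#' Simulate ensembles directly from a configuration
#'
#' `simulate()` on a [pgg_config()] runs `nsim` independent realizations,
#' so a configuration behaves like any other R model object that can be
#' simulated from.
#'
#' @param object a `pgg_config`.
#' @param nsim number of realizations.
#' @param seed master seed (required for reproducibility; defaults to 1).
#' @param ... ignored.
#' @return a `pgg_ensemble`.
#' @importFrom stats simulate
#' @export
simulate.pgg_config <- function(object, nsim = 1, seed = 1, ...) {
  run_ensemble(object, n_realizations = nsim,
               master_seed = if (is.null(seed)) 1 else seed)
}

#' Plot ensemble mean trajectories
#'
#' Draws the per-generation cross-realization means of the population size,
#' the selfish fraction and the transmission rates `phi_SS` / `phi_GG`
#' (means over realizations still alive at each generation).
#'
#' @param x a `pgg_ensemble`.
#' @param which subset of `c("N", "composition", "rates")`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pgg_ensemble <- function(x, which = c("N", "composition", "rates"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  m <- x$mean
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  if ("N" %in% which)
    graphics::plot(m$t, m$N, type = "l", xlab = "generation",
                   ylab = "population size", main = "Mean population size", ...)
  if ("composition" %in% which) {
    graphics::plot(m$t, m$frac_S, type = "l", ylim = c(0, 1), col = "firebrick",
                   xlab = "generation", ylab = "fraction",
                   main = "Phenotype composition", ...)
    graphics::lines(m$t, 1 - m$frac_S, col = "goldenrod")
    graphics::legend("topright", legend = c("selfish", "generous"),
                     col = c("firebrick", "goldenrod"), lty = 1, bty = "n")
  }
  if ("rates" %in% which) {
    graphics::plot(m$t, m$mean_phi_SS, type = "l", ylim = c(0, 1),
                   col = "firebrick", xlab = "generation",
                   ylab = "transmission rate",
                   main = "phi_SS (red) and phi_GG (yellow)", ...)
    graphics::lines(m$t, m$mean_phi_GG, col = "goldenrod")
  }
  invisible(x)
}

#' Plot a sweep as an equilibrium map
#'
#' Heatmap of the equilibrium population size over the mortality-by-cost
#' grid (one panel per environment), with the generous percentage printed
#' in each surviving cell; extinct cells are blank.
#'
#' @param x a [pgg_sweep()] result.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.pgg_sweep <- function(x, ...) {
  axes <- attr(x, "axes")
  old <- graphics::par(mfrow = c(1, length(axes$e)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  for (ev in axes$e) {
    sub <- x[x$e == ev, ]
    z <- matrix(NA_real_, length(axes$m_S), length(axes$lam))
    for (i in seq_along(axes$m_S))
      for (j in seq_along(axes$lam)) {
        row <- sub[sub$m_S == axes$m_S[i] & sub$lam == axes$lam[j], ]
        if (nrow(row) && !row$all_extinct) z[i, j] <- row$N
      }
    graphics::image(seq_along(axes$m_S), seq_along(axes$lam), z,
                    col = grDevices::hcl.colors(25, "Blues", rev = TRUE),
                    axes = FALSE, xlab = "m_S", ylab = "lambda",
                    main = sprintf("e = %g", ev))
    graphics::axis(1, seq_along(axes$m_S), axes$m_S)
    graphics::axis(2, seq_along(axes$lam), axes$lam)
    for (i in seq_along(axes$m_S))
      for (j in seq_along(axes$lam)) {
        row <- sub[sub$m_S == axes$m_S[i] & sub$lam == axes$lam[j], ]
        if (nrow(row) && !row$all_extinct)
          graphics::text(i, j, sprintf("%.0f%%", 100 * row$frac_G))
      }
  }
  invisible(x)
}
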