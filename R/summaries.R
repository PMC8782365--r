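#' Equilibrium statistics of an ensemble
#'
#' Time-averages every recorded observable over the final fraction of the
#' run (default: the last 10% of generations) within each surviving
#' realization, then averages across the surviving realizations.  Also
#' reports cross-realization standard errors, the fraction of realizations
#' extinct before `T` and the mean extinction generation among those.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param window_fraction fraction of the run, counted from the end, to
#'   average over; in `(0, 1]`.
#' @return an object of class `pgg_equilibrium`: a list with `stats` and
#'   `se` (named numeric vectors over `N`, `frac_S`, `frac_G`, `mean_phi`,
#'   `mean_gamma`, `mean_omega`, `mean_phi_SS`, `mean_phi_GG`, `pot`),
#'   `extinct_fraction`, `mean_extinction_generation`, `all_extinct`,
#'   `n_surviving`, `window` (first and last generation averaged) and
#'   `window_fraction`.  When every realization is extinct the equilibrium
#'   fields are `NA`.
#' @export
equilibrium_summary <- function(ensemble, window_fraction = 0.10) {
  stopifnot(inherits(ensemble, "pgg_ensemble"),
            window_fraction > 0, window_fraction <= 1)
  T_ <- ensemble$config$T
  t0 <- floor((1 - window_fraction) * T_)
  fields <- c("N", "frac_S", "mean_phi", "mean_gamma", "mean_omega",
              "mean_phi_SS", "mean_phi_GG", "pot")
  surv <- which(ensemble$survived)
  per_real <- NULL
  if (length(surv)) {
    per_real <- t(vapply(ensemble$trajectories[surv], function(tr) {
      w <- tr[tr$t >= t0, fields, drop = FALSE]
      colMeans(as.matrix(w), na.rm = TRUE)
    }, numeric(length(fields))))
    colnames(per_real) <- fields
  }
  k <- length(surv)
  if (k > 0L) {
    stats <- colMeans(per_real)
    se <- apply(per_real, 2, stats::sd) / sqrt(k)
    stats <- c(stats[c("N", "frac_S")], frac_G = unname(1 - stats[["frac_S"]]),
               stats[setdiff(fields, c("N", "frac_S"))])
    se <- c(se[c("N", "frac_S")], frac_G = unname(se[["frac_S"]]),
            se[setdiff(fields, c("N", "frac_S"))])
  } else {
    nm <- c("N", "frac_S", "frac_G", setdiff(fields, c("N", "frac_S")))
    stats <- se <- stats::setNames(rep(NA_real_, length(nm)), nm)
  }
  ext <- ensemble$extinction_generation
  structure(
    list(stats = stats, se = se,
         extinct_fraction = mean(!ensemble$survived),
         mean_extinction_generation =
           if (any(!ensemble$survived)) mean(ext[!ensemble$survived]) else NA_real_,
         all_extinct = !any(ensemble$survived),
         n_surviving = k,
         window = c(t0, T_),
         window_fraction = window_fraction),
    class = "pgg_equilibrium")
}

#' @export
print.pgg_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium summary (generations %d-%d, %d surviving realizations)\n",
              x$window[1], x$window[2], x$n_surviving))
  if (x$all_extinct) {
    cat(sprintf("  all realizations extinct; mean extinction generation %.1f\n",
                x$mean_extinction_generation))
    return(invisible(x))
  }
  s <- x$stats
  cat(sprintf("  population size %.1f; selfish %.1f%%, generous %.1f%%\n",
              s[["N"]], 100 * s[["frac_S"]], 100 * s[["frac_G"]]))
  cat(sprintf("  phi %.3f, gamma %.3f, omega %.3f; phi_SS %.3f, phi_GG %.3f\n",
              s[["mean_phi"]], s[["mean_gamma"]], s[["mean_omega"]],
              s[["mean_phi_SS"]], s[["mean_phi_GG"]]))
  cat(sprintf("  extinct fraction %.2f", x$extinct_fraction))
  if (!is.na(x$mean_extinction_generation))
    cat(sprintf(" (mean extinction generation %.1f)",
                x$mean_extinction_generation))
  cat("\n")
  invisible(x)
}

#' Parameter sweep over mortality, community cost and environment
#'
#' Runs one ensemble per grid cell (with cell-specific derived seeds) and
#' summarizes each at equilibrium, reproducing the structure of the
#' published mortality-by-community-cost equilibrium maps.  A cell is
#' classified extinct when every one of its realizations dies before `T`.
#'
#' @param base a [pgg_config()] used for every non-swept parameter.
#' @param m_S,lam,e axis value vectors (each defaults to the base value).
#' @param n_realizations realizations per cell.
#' @param master_seed integer; cell seeds derive from it via
#'   [realization_seeds()] with one offset per cell.
#' @param window_fraction equilibrium window, as in [equilibrium_summary()].
#' @param keep_ensembles logical; retain the full ensembles in the result
#'   (memory-heavy for long runs).
#' @param verbose logical; one progress line per cell.
#' @return an object of class `pgg_sweep`: a data frame with one row per
#'   cell (`m_S`, `lam`, `e`, equilibrium statistics, `extinct_fraction`,
#'   `all_extinct`, `mean_extinction_generation`, `n_surviving`) with the
#'   ensembles in `attr(, "ensembles")` if kept.
#' @export
pgg_sweep <- function(base, m_S = base$m_S, lam = base$lam, e = base$e,
                      n_realizations = 20, master_seed = 1,
                      window_fraction = 0.10, keep_ensembles = FALSE,
                      verbose = FALSE) {
  stopifnot(inherits(base, "pgg_config"))
  grid <- expand.grid(m_S = m_S, lam = lam, e = e,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  ensembles <- if (keep_ensembles) vector("list", nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    raw <- unclass(base)
    raw$m_S <- grid$m_S[i]
    raw$lam <- grid$lam[i]
    raw$e <- grid$e[i]
    raw$e_tot <- raw$e * raw$N0
    cfg <- build_config(raw)
    cell_seed <- realization_seeds(master_seed, 1L, offset = i)
    ens <- run_ensemble(cfg, n_realizations, master_seed = cell_seed)
    eq <- equilibrium_summary(ens, window_fraction)
    rows[[i]] <- data.frame(
      m_S = grid$m_S[i], lam = grid$lam[i], e = grid$e[i],
      as.list(eq$stats),
      extinct_fraction = eq$extinct_fraction,
      all_extinct = eq$all_extinct,
      mean_extinction_generation = eq$mean_extinction_generation,
      n_surviving = eq$n_surviving)
    if (keep_ensembles) ensembles[[i]] <- ens
    if (verbose)
      message(sprintf("cell %d/%d (m_S = %g, lam = %g, e = %g): %s",
                      i, nrow(grid), grid$m_S[i], grid$lam[i], grid$e[i],
                      if (eq$all_extinct) "extinct" else
                        sprintf("N = %.0f, S = %.0f%%", eq$stats[["N"]],
                                100 * eq$stats[["frac_S"]])))
  }
  out <- do.call(rbind, rows)
  attr(out, "axes") <- list(m_S = m_S, lam = lam, e = e)
  attr(out, "n_realizations") <- n_realizations
  attr(out, "master_seed") <- master_seed
  attr(out, "window_fraction") <- window_fraction
  if (keep_ensembles) attr(out, "ensembles") <- ensembles
  class(out) <- c("pgg_sweep", "data.frame")
  out
}
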