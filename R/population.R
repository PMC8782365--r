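#' Construct the initial population
#'
#' Creates the generation-0 cohort: `N0` agents of which exactly
#' `round(S0 * N0)` are selfish risk-seekers (a deterministic count rather
#' than a per-agent Bernoulli draw, which would add initial-composition
#' variance the model does not call for).  Every agent starts with the same
#' transmission components `(phi0, gamma0, omega0)`.
#'
#' @param config a [pgg_config()] object.
#' @return an object of class `pgg_population` — a list with elements
#'   `t` (generation index, 0), `selfish` (logical vector, one per agent),
#'   `phi`, `gamma`, `omega` (numeric vectors), `prev_contrib` (mean
#'   contribution rate of the previous generation's participants, `NA` at
#'   t = 0) and `extinct` (logical).
#' @examples
#' pop <- init_population(pgg_config())
#' sum(pop$selfish)   # 25
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "pgg_config"))
  n <- config$N0
  n_s <- as.integer(round(config$S0 * n))
  new_population(
    t = 0L,
    selfish = c(rep(TRUE, n_s), rep(FALSE, n - n_s)),
    phi = rep(config$phi0, n),
    gamma = rep(config$gamma0, n),
    omega = rep(config$omega0, n)
  )
}

new_population <- function(t, selfish, phi, gamma, omega, prev_contrib = NA_real_) {
  structure(
    list(t = as.integer(t), selfish = selfish, phi = phi, gamma = gamma,
         omega = omega, prev_contrib = prev_contrib,
         extinct = length(selfish) == 0L),
    class = "pgg_population")
}

#' @export
print.pgg_population <- function(x, ...) {
  n <- length(x$selfish)
  if (x$extinct) {
    cat(sprintf("<pgg_population> generation %d: extinct\n", x$t))
  } else {
    cat(sprintf(
      "<pgg_population> generation %d: %d agents (%d S, %d G), mean phi %.3f\n",
      x$t, n, sum(x$selfish), n - sum(x$selfish), mean(x$phi)))
  }
  invisible(x)
}

#' Hand-built miniature populations for oracle tests
#'
#' Deterministic 1-4 agent populations, each paired with a small
#' configuration, used to exercise a single generation against exhaustive
#' enumeration and conservation checks.  The configurations set `N0` to the
#' fixture's size so `e_tot = e * N0` keeps the per-capita offer at `e`, and
#' disable mutation and mortality so a generation is deterministic up to the
#' offspring phenotype draws.
#'
#' @param name one of `"tiny_mixed"` (1 S + 1 G with default transmission
#'   components), `"all_generous"`, `"all_selfish"` (3 agents each) or
#'   `"neutral_symmetric"` (1 S + 1 G, `phi = 0.5`, `gamma = omega = 0`,
#'   equal harvest/contribution rates for the two phenotypes).
#' @return a list with elements `config` and `population`.
#' @export
make_fixture <- function(name = c("tiny_mixed", "all_generous",
                                  "all_selfish", "neutral_symmetric")) {
  name <- match.arg(name)
  base <- list(T = 1L, I = 1L, m_S = 0, lam = 0,
               mutation_enabled = FALSE,
               sigma2_phi = 0, sigma2_gamma = 0, sigma2_omega = 0)
  fixture <- switch(name,
    tiny_mixed = list(
      config = c(base, list(N0 = 2L, S0 = 0.5)),
      selfish = c(TRUE, FALSE), phi = 0.1, gamma = 0.01, omega = 0.01),
    all_generous = list(
      config = c(base, list(N0 = 3L, S0 = 0)),
      selfish = rep(FALSE, 3), phi = 0.1, gamma = 0.01, omega = 0.01),
    all_selfish = list(
      config = c(base, list(N0 = 3L, S0 = 1)),
      selfish = rep(TRUE, 3), phi = 0.1, gamma = 0.01, omega = 0.01),
    neutral_symmetric = list(
      config = c(base, list(N0 = 2L, S0 = 0.5, h_S = 0.5, h_G = 0.5,
                            c_S = 1)),
      selfish = c(TRUE, FALSE), phi = 0.5, gamma = 0, omega = 0))
  cfg <- build_config(fixture$config)
  n <- length(fixture$selfish)
  pop <- new_population(
    t = 0L, selfish = fixture$selfish,
    phi = rep(fixture$phi, length.out = n),
    gamma = rep(fixture$gamma, length.out = n),
    omega = rep(fixture$omega, length.out = n))
  list(config = cfg, population = pop)
}
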