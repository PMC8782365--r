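#' Build a validated model configuration
#'
#' Assembles the full parameter set of the simulation, applying published
#' defaults for anything not supplied, deriving the dependent quantities
#' (`e_tot = e * N0`, `M = s * o + s`) and validating every value.  The
#' returned object is the single source of truth for a run: every phase of
#' the life cycle reads its parameters from it.
#'
#' @details
#' The model describes a population of two phenotypes: selfish risk-seeking
#' agents (`S`) that harvest aggressively (`h_S`), contribute little to the
#' communal pot (`c_S`) and risk death while harvesting (`m_S`), and generous
#' risk-averse agents (`G`) that harvest moderately (`h_G`), contribute
#' everything (or conditionally, under the conditional-cooperation variant)
#' and never die while harvesting (`m_G = 0`).
#'
#' Offspring phenotypes are drawn from a 2x2 parent-to-offspring transmission
#' matrix built from three heritable components: `phi`, the population
#' baseline propensity to produce selfish offspring; `gamma`, the additional
#' effect of a selfish parent; and `omega`, the effect of a generous parent:
#' `phi_SS = phi + gamma`, `phi_GS = phi - omega` (and complements).  All
#' three mutate every generation by zero-mean Gaussian noise unless
#' `mutation_enabled` is `FALSE`.
#'
#' @param ... named parameters overriding the defaults.  Recognised names:
#'   \describe{
#'     \item{N0}{initial population size (250).}
#'     \item{T}{number of generations (10000).}
#'     \item{I}{number of independent realizations (100).}
#'     \item{e}{environmental offer, resource units per initial agent per
#'       generation; 4.5 = abundant, 1.2 = scarce (default 4.5).}
#'     \item{e_tot}{total resources offered each generation; derived as
#'       `e * N0` unless overridden.  Fixed for the whole run regardless of
#'       the current population size.}
#'     \item{e_max}{maximum harvest per agent per generation (4.5).}
#'     \item{rho}{public-goods-game pot multiplier (1.5).}
#'     \item{lam}{community cost level, a percentage in \{0, 50, 100\}:
#'       `lam/100` resource units are removed from the pot per selfish
#'       participant before multiplication (default 0).}
#'     \item{S0}{initial fraction of selfish agents (0.10).}
#'     \item{h_S, h_G}{harvest fractions of the per-capita offer (0.8, 0.5).}
#'     \item{c_S}{contribution fraction of selfish agents (0.2).}
#'     \item{m_S, m_G}{per-generation mortality probability during harvesting
#'       (default 0.25 and 0).}
#'     \item{o}{maximum offspring count (10).}
#'     \item{s}{survival threshold in resource units (1).}
#'     \item{phi0, gamma0, omega0}{initial transmission components
#'       (0.1, 0.01, 0.01).}
#'     \item{sigma2_phi, sigma2_gamma, sigma2_omega}{mutation variances
#'       (each 0.01).}
#'     \item{alpha}{individual cost paid by each selfish agent after
#'       redistribution; defaults to 0.1 when `individual_cost` is on and 0
#'       otherwise.}
#'     \item{conditional_cooperation}{logical; generous agents copy the
#'       previous generation's mean contribution rate (FALSE).}
#'     \item{individual_cost}{logical; selfish agents pay `alpha` (FALSE).}
#'     \item{perfect_transmission}{logical; offspring always inherit the
#'       parental phenotype (FALSE).}
#'     \item{mutation_enabled}{logical; mutate `phi`, `gamma`, `omega` each
#'       generation (TRUE).}
#'   }
#'
#' @return an object of class `pgg_config`: a named list of validated
#'   parameters including the derived `e_tot` and `M`.
#' @examples
#' cfg <- pgg_config()                      # published defaults
#' cfg$e_tot                                # 1125
#' cfg$M                                    # 11
#' scarce <- pgg_config(e = 1.2, m_S = 0.5)
#' @export
pgg_config <- function(...) {
  raw <- list(...)
  if (length(raw) == 1L && is.null(names(raw)) && is.list(raw[[1L]]))
    raw <- raw[[1L]]
  build_config(raw)
}

pgg_defaults <- function() {
  list(
    N0 = 250L, T = 10000L, I = 100L,
    e = 4.5, e_tot = NULL, e_max = 4.5,
    rho = 1.5, lam = 0,
    S0 = 0.10,
    h_S = 0.8, h_G = 0.5,
    c_S = 0.2,
    m_S = 0.25, m_G = 0,
    o = 10L, s = 1,
    phi0 = 0.1, gamma0 = 0.01, omega0 = 0.01,
    sigma2_phi = 0.01, sigma2_gamma = 0.01, sigma2_omega = 0.01,
    alpha = NULL,
    conditional_cooperation = FALSE,
    individual_cost = FALSE,
    perfect_transmission = FALSE,
    mutation_enabled = TRUE
  )
}

#' Build a configuration from a raw name/value list
#'
#' Lower-level constructor behind [pgg_config()]: takes a plain named list
#' (for example one read from a YAML or JSON file), fills in defaults,
#' derives `e_tot` and `M`, and validates.  Re-validating an already valid
#' configuration returns it unchanged.
#'
#' @param raw named list supplying any subset of the parameters documented
#'   in [pgg_config()].
#' @return a `pgg_config` object.
#' @export
build_config <- function(raw = list()) {
  stopifnot(is.list(raw))
  if (length(raw) && (is.null(names(raw)) || any(!nzchar(names(raw)))))
    stop("all configuration entries must be named")
  defaults <- pgg_defaults()
  known <- c(names(defaults), "M")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration parameter(s): ", paste(unknown, collapse = ", "))

  cfg <- defaults
  cfg[names(raw)] <- raw

  # derived quantities (explicit overrides win for e_tot; M is always derived)
  if (is.null(cfg$e_tot)) cfg$e_tot <- cfg$e * cfg$N0
  if (is.null(cfg$alpha)) cfg$alpha <- if (isTRUE(cfg$individual_cost)) 0.1 else 0
  cfg$M <- cfg$s * cfg$o + cfg$s

  for (nm in c("N0", "T", "I", "o"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  for (nm in c("conditional_cooperation", "individual_cost",
               "perfect_transmission", "mutation_enabled"))
    cfg[[nm]] <- isTRUE(as.logical(cfg[[nm]]))

  validate_config(cfg)
  structure(cfg, class = "pgg_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, nm, why) {
    if (!isTRUE(ok)) stop(sprintf("invalid configuration: %s %s", nm, why),
                          call. = FALSE)
  }
  num1 <- function(nm) {
    v <- cfg[[nm]]
    chk(is.numeric(v) && length(v) == 1L && is.finite(v), nm,
        "must be a single finite number")
    v
  }
  for (nm in c("S0", "h_S", "h_G", "c_S", "m_S", "m_G")) {
    v <- num1(nm)
    chk(v >= 0 && v <= 1, nm, "must lie in [0, 1]")
  }
  for (nm in c("e", "e_tot", "e_max", "rho", "alpha", "s",
               "sigma2_phi", "sigma2_gamma", "sigma2_omega")) {
    v <- num1(nm)
    chk(v >= 0, nm, "must be non-negative")
  }
  chk(cfg$lam >= 0, "lam", "must be non-negative")
  for (nm in c("N0", "T", "I", "o")) {
    v <- cfg[[nm]]
    chk(is.numeric(v) && length(v) == 1L && !is.na(v), nm, "must be an integer")
  }
  chk(cfg$N0 >= 1, "N0", "must be at least 1")
  chk(cfg$I >= 1, "I", "must be at least 1")
  chk(cfg$T >= 0, "T", "must be non-negative")
  chk(cfg$o >= 1, "o", "must be at least 1")
  chk(isTRUE(all.equal(cfg$M, cfg$s * cfg$o + cfg$s)), "M",
      "must equal s * o + s")
  for (nm in c("phi0", "gamma0", "omega0")) {
    v <- num1(nm)
    chk(v >= 0 && v <= 1, nm, "must lie in [0, 1]")
  }
  chk(cfg$gamma0 <= 1 - cfg$phi0, "gamma0", "must not exceed 1 - phi0")
  chk(cfg$omega0 <= cfg$phi0, "omega0", "must not exceed phi0")
  invisible(cfg)
}

#' @export
print.pgg_config <- function(x, ...) {
  cat("Public goods game model configuration\n")
  cat(sprintf("  population: N0 = %d, S0 = %g, T = %d generations, I = %d realizations\n",
              x$N0, x$S0, x$T, x$I))
  cat(sprintf("  environment: e = %g (e_tot = %g), e_max = %g\n",
              x$e, x$e_tot, x$e_max))
  cat(sprintf("  game: rho = %g, lam = %g%%, h_S = %g, h_G = %g, c_S = %g\n",
              x$rho, x$lam, x$h_S, x$h_G, x$c_S))
  cat(sprintf("  mortality: m_S = %g, m_G = %g; reproduction: o = %d, s = %g, M = %g\n",
              x$m_S, x$m_G, x$o, x$s, x$M))
  cat(sprintf("  transmission: phi0 = %g, gamma0 = %g, omega0 = %g; variances %g/%g/%g\n",
              x$phi0, x$gamma0, x$omega0,
              x$sigma2_phi, x$sigma2_gamma, x$sigma2_omega))
  variants <- c(
    if (x$conditional_cooperation) "conditional cooperation",
    if (x$individual_cost) sprintf("individual cost (alpha = %g)", x$alpha),
    if (x$perfect_transmission) "perfect transmission",
    if (!x$mutation_enabled) "no mutation")
  cat("  variants:", if (length(variants)) paste(variants, collapse = ", ")
      else "none (baseline)", "\n")
  invisible(x)
}
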