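#' Parent-to-offspring phenotype transmission matrix
#'
#' Builds the 2x2 matrix of phenotype-transmission probabilities from the
#' three heritable components: `phi_GG = 1 - phi + omega`,
#' `phi_GS = phi - omega`, `phi_SS = phi + gamma`, `phi_SG = 1 - phi - gamma`.
#' Rows (one per parental phenotype) sum to 1 by construction.  All arguments
#' are vectorized over agents.
#'
#' @param phi baseline propensity to produce selfish offspring, in `[0, 1]`.
#' @param gamma selfish-parent effect, in `[0, 1 - phi]`.
#' @param omega generous-parent effect, in `[0, phi]`.
#' @return a list with numeric elements `phi_GG`, `phi_GS`, `phi_SS`,
#'   `phi_SG`, each the length of the inputs.
#' @examples
#' reproduction_matrix(0.1, 0.01, 0.01)  # phi_GG = 0.91, phi_SS = 0.11
#' @export
reproduction_matrix <- function(phi, gamma, omega) {
  if (any(gamma < 0 | gamma > 1 - phi) || any(omega < 0 | omega > phi))
    stop("transmission components violate 0 <= gamma <= 1 - phi, 0 <= omega <= phi")
  list(phi_GG = 1 - phi + omega, phi_GS = phi - omega,
       phi_SS = phi + gamma, phi_SG = 1 - phi - gamma)
}

#' Mutate the transmission components of every agent
#'
#' Adds independent zero-mean Gaussian noise (variances `sigma2_phi`,
#' `sigma2_gamma`, `sigma2_omega`) to each agent's `phi`, `gamma` and
#' `omega`, then clips to the admissible region in a fixed order: `phi` into
#' `[0, 1]` first, then `gamma` into `[0, 1 - phi]` and `omega` into
#' `[0, phi]` against the clipped `phi`, so the resulting transmission
#' matrix always has entries in `[0, 1]`.
#'
#' Draw order (part of the reproducibility contract): `eta_phi` for all
#' agents in agent order, then `eta_gamma`, then `eta_omega`.  Identity when
#' `mutation_enabled` is off.
#'
#' @param pop a `pgg_population`.
#' @param config a [pgg_config()] object.
#' @return the population with mutated, clipped components.
#' @export
mutate_probabilities <- function(pop, config) {
  if (!config$mutation_enabled) return(pop)
  n <- length(pop$phi)
  if (n == 0L) return(pop)
  phi <- pop$phi + stats::rnorm(n, 0, sqrt(config$sigma2_phi))
  gamma <- pop$gamma + stats::rnorm(n, 0, sqrt(config$sigma2_gamma))
  omega <- pop$omega + stats::rnorm(n, 0, sqrt(config$sigma2_omega))
  phi <- pmin(pmax(phi, 0), 1)
  pop$phi <- phi
  pop$gamma <- pmin(pmax(gamma, 0), 1 - phi)
  pop$omega <- pmin(pmax(omega, 0), phi)
  pop
}

#' Harvesting with mortality
#'
#' The risky first phase of a generation.  Each selfish agent independently
#' dies with probability `m_S` (generous agents with `m_G`, 0 by default)
#' before harvesting; the dead harvest nothing, contribute nothing and leave
#' no offspring.  Each survivor of phenotype `p` then harvests
#' `min(h_p * e_t, e_max)` where the per-capita offer `e_t = e_tot / N_t`
#' uses the head-count at the start of the phase (pre-mortality).
#'
#' Mortality draws are one uniform per selfish agent in agent order (then
#' per generous agent when `m_G > 0`).
#'
#' @param pop a non-extinct `pgg_population`.
#' @param config a [pgg_config()] object.
#' @return a list: `alive` (logical per agent), `harvest` (numeric per
#'   agent, 0 for the dead) and `e_t` (the per-capita offer used).
#' @export
harvest_phase <- function(pop, config) {
  n <- length(pop$selfish)
  if (n == 0L) stop("cannot run the harvest phase on an extinct population")
  e_t <- config$e_tot / n
  alive <- rep(TRUE, n)
  if (config$m_S > 0 && any(pop$selfish)) {
    idx <- which(pop$selfish)
    alive[idx] <- stats::runif(length(idx)) >= config$m_S
  }
  if (config$m_G > 0 && any(!pop$selfish)) {
    idx <- which(!pop$selfish)
    alive[idx] <- stats::runif(length(idx)) >= config$m_G
  }
  h <- rep.int(config$h_G, n)
  h[pop$selfish] <- config$h_S
  harvest <- pmin(h * e_t, config$e_max)
  harvest[!alive] <- 0
  list(alive = alive, harvest = harvest, e_t = e_t)
}

#' Per-agent contribution rates
#'
#' Selfish agents always contribute the fraction `c_S` of their harvest.
#' Generous agents contribute everything (rate 1) in the baseline model; as
#' conditional cooperators they contribute 1 in generation 0 and thereafter
#' the mean contribution rate of all agents that took part in the public
#' goods game of the previous generation (`pop$prev_contrib`).
#'
#' @param pop a `pgg_population` (its `t` and `prev_contrib` drive the
#'   conditional rule).
#' @param config a [pgg_config()] object.
#' @return numeric vector of contribution fractions, one per agent.
#' @export
contribution_rates <- function(pop, config) {
  c_G <- 1
  if (config$conditional_cooperation && pop$t >= 1L) {
    if (is.na(pop$prev_contrib))
      stop("conditional cooperation at t >= 1 requires the previous ",
           "generation's mean contribution rate")
    c_G <- pop$prev_contrib
  }
  rates <- rep.int(c_G, length(pop$selfish))
  rates[pop$selfish] <- config$c_S
  rates
}

#' Public goods game: pooling, community cost and redistribution
#'
#' Each participant contributes `c_i * r_i` to the communal pot.  Before
#' multiplication, the community pays a cost proportional to the number of
#' selfish participants — `lam/100` resource units per selfish agent — and
#' the pot is floored at zero.  The pot is then multiplied by `rho` and
#' split equally among the `N` participants regardless of contribution:
#' `f_i = C * rho / N + r_i * (1 - c_i)`, minus the individual cost `alpha`
#' for selfish agents when that variant is on.  Fitness may be negative;
#' the offspring rule then yields zero offspring.
#'
#' @param harvests numeric vector of participant harvests `r_i`.
#' @param selfish logical vector, `TRUE` for selfish participants.
#' @param rates numeric vector of contribution fractions `c_i`.
#' @param config a [pgg_config()] object.
#' @return a list: `fitness` (numeric per participant) and `pot` (the pot
#'   `C_t` after the community cost, before multiplication).
#' @export
public_goods_phase <- function(harvests, selfish, rates, config) {
  n <- length(harvests)
  if (n == 0L) stop("the public goods game needs at least one participant")
  pot <- sum(rates * harvests) - (config$lam / 100) * sum(selfish)
  pot <- max(pot, 0)
  fitness <- pot * config$rho / n + harvests * (1 - rates)
  if (config$individual_cost)
    fitness <- fitness - config$alpha * selfish
  list(fitness = fitness, pot = pot)
}

#' Offspring count from fitness
#'
#' Fitness-proportional fecundity with a survival threshold: an agent with
#' fitness `f <= s` leaves no offspring; fitness `f >= M = s*o + s` yields
#' the maximum `o`; in between the count is `ceiling(o/(M - s) * (f - s))`.
#' Vectorized over agents.
#'
#' @param f numeric vector of fitness values.
#' @param config a [pgg_config()] object.
#' @return integer vector of offspring counts in `[0, o]`.
#' @examples
#' cfg <- pgg_config()
#' offspring_count(c(0.5, 1, 5.1075, 11, 20), cfg)  # 0 0 5 10 10
#' @export
offspring_count <- function(f, config) {
  stopifnot(all(is.finite(f)))
  mid <- as.integer(ceiling(config$o / (config$M - config$s) * (f - config$s)))
  n <- ifelse(f <= config$s, 0L, ifelse(f >= config$M, config$o, mid))
  as.integer(n)
}

#' Draw offspring for the reproducing participants
#'
#' Each parent `i` produces `n[i]` offspring.  Every offspring's phenotype
#' is an independent draw from the parent's personal transmission matrix:
#' selfish with probability `phi_SS = phi + gamma` for a selfish parent and
#' `phi_GS = phi - omega` for a generous parent.  Offspring copy the
#' parent's `(phi, gamma, omega)` verbatim; mutation happens at the start of
#' the generation in which they themselves reproduce.  Under
#' `perfect_transmission` offspring always express the parental phenotype.
#'
#' Phenotype draws are one uniform per offspring, parents in agent order.
#'
#' @param selfish,phi,gamma,omega parallel vectors describing the parents.
#' @param n integer vector of offspring counts per parent.
#' @param config a [pgg_config()] object.
#' @return a list with vectors `selfish`, `phi`, `gamma`, `omega` over the
#'   `sum(n)` offspring.
#' @export
draw_offspring <- function(selfish, phi, gamma, omega, n, config) {
  stopifnot(length(n) == length(selfish), all(n >= 0L), all(n <= config$o))
  total <- sum(n)
  if (total == 0L)
    return(list(selfish = logical(0), phi = numeric(0),
                gamma = numeric(0), omega = numeric(0)))
  parent <- rep.int(seq_along(n), n)
  if (config$perfect_transmission) {
    kid_selfish <- selfish[parent]
  } else {
    p_S <- phi - omega
    p_S[selfish] <- phi[selfish] + gamma[selfish]
    kid_selfish <- stats::runif(total) < p_S[parent]
  }
  list(selfish = kid_selfish, phi = phi[parent],
       gamma = gamma[parent], omega = omega[parent])
}
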