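REC_FIELDS <- c("t", "N", "n_S", "frac_S", "mean_phi", "mean_gamma",
                "mean_omega", "mean_phi_SS", "mean_phi_GG", "pot", "c_G")

#' Advance one generation
#'
#' Applies the four phases in their published order — mutation of the
#' transmission components, harvesting with mortality, contribution and the
#' public goods game (community cost, redistribution, individual cost),
#' then fitness-proportional reproduction — and replaces the parents with
#' their offspring (generations do not overlap).  Also records the
#' generation's observables and stores the participants' mean contribution
#' rate for the conditional-cooperation rule of the next generation.
#'
#' Random draws occur in a fixed order (mutation noise, mortality uniforms,
#' offspring phenotype uniforms, each in stable agent order), so a run is
#' bit-reproducible for a given seed.
#'
#' @param pop a non-extinct `pgg_population`.
#' @param config a [pgg_config()] object.
#' @return a list: `population` (the offspring cohort, generation `t + 1`)
#'   and `record` (named numeric vector: population size and selfish count /
#'   fraction at the start of the generation, post-mutation means of `phi`,
#'   `gamma`, `omega` and of the transmission rates `phi_SS`, `phi_GG`, the
#'   pot `C_t` after the community cost, and the generous contribution rate
#'   `c_G` used; `pot` and `c_G` are `NA` when every agent died before the
#'   game).
#' @export
step_generation <- function(pop, config) {
  if (pop$extinct) stop("cannot step an extinct population")
  pop <- mutate_probabilities(pop, config)
  n <- length(pop$selfish)
  n_s <- sum(pop$selfish)

  rec <- c(t = as.numeric(pop$t), N = n, n_S = n_s, frac_S = n_s / n,
           mean_phi = mean(pop$phi), mean_gamma = mean(pop$gamma),
           mean_omega = mean(pop$omega),
           mean_phi_SS = mean(pop$phi + pop$gamma),
           mean_phi_GG = mean(1 - pop$phi + pop$omega),
           pot = NA_real_, c_G = NA_real_)

  hv <- harvest_phase(pop, config)
  alive <- hv$alive
  if (!any(alive)) {
    empty <- new_population(pop$t + 1L, logical(0), numeric(0), numeric(0),
                            numeric(0))
    return(list(population = empty, record = rec))
  }

  rates_all <- contribution_rates(pop, config)
  sel <- pop$selfish[alive]
  rates <- rates_all[alive]
  pg <- public_goods_phase(hv$harvest[alive], sel, rates, config)
  rec[["pot"]] <- pg$pot
  rec[["c_G"]] <- unique_generous_rate(pop, config)

  n_off <- offspring_count(pg$fitness, config)
  kids <- draw_offspring(sel, pop$phi[alive], pop$gamma[alive],
                         pop$omega[alive], n_off, config)
  nxt <- new_population(pop$t + 1L, kids$selfish, kids$phi, kids$gamma,
                        kids$omega, prev_contrib = mean(rates))
  list(population = nxt, record = rec)
}

# rate a generous agent would use this generation (recorded even when the
# cohort happens to contain no generous agent)
unique_generous_rate <- function(pop, config) {
  if (config$conditional_cooperation && pop$t >= 1L) pop$prev_contrib else 1
}

#' Run a single realization
#'
#' Seeds the random stream, builds the initial population and iterates
#' [step_generation()] until generation `T` or extinction, whichever comes
#' first.  One stream drives the whole realization; the in-generation draw
#' order is documented in [step_generation()].
#'
#' @param config a [pgg_config()] object.
#' @param seed integer seed for this realization.
#' @return an object of class `pgg_trajectory`: a data frame with one row
#'   per generation from `t = 0` to `min(T, extinction)` and the columns of
#'   the generation record (`N`, `n_S`, `frac_S`, means of the transmission
#'   components and rates, `pot`, `c_G`).  The final row describes the last
#'   cohort without stepping it (`pot` and `c_G` are `NA` there).
#'   Attributes: `seed`, `config` and `extinction_generation` (`NA` if the
#'   population survived to `T`).
#' @export
run_realization <- function(config, seed) {
  stopifnot(inherits(config, "pgg_config"))
  set.seed(as.integer(seed))
  pop <- init_population(config)
  T_ <- config$T
  rec <- matrix(NA_real_, nrow = T_ + 1L, ncol = length(REC_FIELDS),
                dimnames = list(NULL, REC_FIELDS))
  t_done <- 0L
  while (pop$t < T_ && !pop$extinct) {
    stepped <- step_generation(pop, config)
    rec[pop$t + 1L, ] <- stepped$record
    pop <- stepped$population
    t_done <- pop$t
  }
  # closing row: the standing (or empty) cohort at t = min(T, extinction)
  n <- length(pop$selfish)
  rec <- rec[seq_len(t_done + 1L), , drop = FALSE]
  rec[t_done + 1L, ] <- c(pop$t, n, sum(pop$selfish),
                          if (n > 0L) mean(pop$selfish) else NA_real_,
                          if (n > 0L) mean(pop$phi) else NA_real_,
                          if (n > 0L) mean(pop$gamma) else NA_real_,
                          if (n > 0L) mean(pop$omega) else NA_real_,
                          if (n > 0L) mean(pop$phi + pop$gamma) else NA_real_,
                          if (n > 0L) mean(1 - pop$phi + pop$omega) else NA_real_,
                          NA_real_, NA_real_)
  out <- as.data.frame(rec)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "config") <- config
  attr(out, "extinction_generation") <-
    if (pop$extinct) pop$t else NA_integer_
  class(out) <- c("pgg_trajectory", "data.frame")
  out
}

#' Derive per-realization seeds from a master seed
#'
#' Affine counter scheme: `seed_i = (master * 48271 + offset + i) mod
#' (2^31 - 1) + 1`, exact in double precision, yielding distinct,
#' reproducible seeds for every realization of an ensemble (and, via
#' `offset`, for every cell of a sweep).
#'
#' @param master_seed integer master seed.
#' @param n number of seeds.
#' @param offset integer stream offset (sweeps use one per cell).
#' @return integer vector of `n` seeds in `[1, 2^31 - 1]`.
#' @export
realization_seeds <- function(master_seed, n, offset = 0) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(offset) * 65537 +
                seq_len(n)) %% 2147483647 + 1)
}

#' Run an ensemble of independent realizations
#'
#' Repeats the simulation over `n_realizations` independent random streams
#' with seeds derived from `master_seed` via [realization_seeds()], and
#' aggregates per-generation cross-realization means.  Means at generation
#' `t` are taken over the realizations still alive at `t` (extinct
#' realizations drop out from their extinction generation onward, matching
#' trajectory plots that continue past individual extinctions).
#'
#' @param config a [pgg_config()] object.
#' @param n_realizations number of realizations (defaults to `config$I`).
#' @param master_seed integer master seed.
#' @param verbose logical; print one line per realization.
#' @return an object of class `pgg_ensemble`: a list with `trajectories`
#'   (list of [run_realization()] results), `mean` (data frame of
#'   per-generation cross-realization means plus `n_surviving`),
#'   `extinction_generation` (integer per realization, `NA` if survived),
#'   `survived` (logical per realization), `config`, `n_realizations`,
#'   `master_seed`.
#' @examples
#' \donttest{
#' cfg <- pgg_config(T = 200, N0 = 100)
#' ens <- run_ensemble(cfg, n_realizations = 3, master_seed = 1)
#' summary(ens)
#' }
#' @export
run_ensemble <- function(config, n_realizations = config$I, master_seed = 1,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pgg_config"), n_realizations >= 1)
  seeds <- realization_seeds(master_seed, n_realizations)
  trajectories <- vector("list", n_realizations)
  for (i in seq_len(n_realizations)) {
    trajectories[[i]] <- run_realization(config, seeds[i])
    if (verbose)
      message(sprintf("realization %d/%d: %s", i, n_realizations,
                      if (is.na(attr(trajectories[[i]], "extinction_generation")))
                        "survived" else
                        sprintf("extinct at t = %d",
                                attr(trajectories[[i]], "extinction_generation"))))
  }
  ext <- vapply(trajectories, function(tr)
    as.integer(attr(tr, "extinction_generation")), integer(1))
  structure(
    list(trajectories = trajectories,
         mean = ensemble_mean(trajectories, config$T),
         extinction_generation = ext,
         survived = is.na(ext),
         config = config,
         n_realizations = as.integer(n_realizations),
         master_seed = as.integer(master_seed)),
    class = "pgg_ensemble")
}

# per-generation means over realizations that are alive at each t
ensemble_mean <- function(trajectories, T_) {
  fields <- setdiff(REC_FIELDS, "t")
  nt <- T_ + 1L
  acc <- matrix(0, nrow = nt, ncol = length(fields),
                dimnames = list(NULL, fields))
  cnt <- matrix(0L, nrow = nt, ncol = length(fields))
  for (tr in trajectories) {
    live <- tr$N > 0
    rows <- which(live)
    m <- as.matrix(tr[rows, fields, drop = FALSE])
    ok <- !is.na(m)
    m[!ok] <- 0
    acc[rows, ] <- acc[rows, ] + m
    cnt[rows, ] <- cnt[rows, ] + ok
  }
  out <- acc / ifelse(cnt > 0, cnt, NA)
  data.frame(t = 0:T_, out, n_surviving = cnt[, 1L])
}
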