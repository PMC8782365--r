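# Independent single-generation oracle.
#
# Recomputes one generation of the model by direct arithmetic (no calls into
# the package's lifecycle code) and enumerates every offspring-phenotype
# assignment exhaustively.  Only valid for deterministic settings: mutation
# disabled and no harvesting mortality.

oracle_one_generation <- function(config, population, t = 0L,
                                  prev_contrib = NA_real_) {
  stopifnot(!config$mutation_enabled || (config$sigma2_phi == 0 &&
              config$sigma2_gamma == 0 && config$sigma2_omega == 0),
            config$m_S == 0, config$m_G == 0)
  sel <- population$selfish
  n <- length(sel)
  e_t <- config$e_tot / n
  r <- numeric(n)
  r[sel] <- min(config$h_S * e_t, config$e_max)
  r[!sel] <- min(config$h_G * e_t, config$e_max)
  c_G <- if (config$conditional_cooperation && t >= 1L) prev_contrib else 1
  cc <- numeric(n)
  cc[sel] <- config$c_S
  cc[!sel] <- c_G
  pot <- max(sum(cc * r) - (config$lam / 100) * sum(sel), 0)
  f <- pot * config$rho / n + r * (1 - cc)
  if (config$individual_cost) f[sel] <- f[sel] - config$alpha
  n_off <- integer(n)
  for (i in seq_len(n)) {
    n_off[i] <- if (f[i] <= config$s) 0L
      else if (f[i] >= config$M) config$o
      else as.integer(ceiling(config$o / (config$M - config$s) *
                                (f[i] - config$s)))
  }
  # probability that each offspring is selfish, per parent
  p_S <- numeric(n)
  p_S[sel] <- population$phi[sel] + population$gamma[sel]
  p_S[!sel] <- population$phi[!sel] - population$omega[!sel]
  if (config$perfect_transmission) p_S <- as.numeric(sel)

  slot_p <- rep(p_S, n_off)           # one entry per offspring slot
  k <- length(slot_p)
  if (k == 0L) {
    return(list(fitness = f, pot = pot, offspring = n_off,
                expected_S = 0, expected_N = 0L, var_S = 0))
  }
  # exhaustive enumeration over all 2^k phenotype assignments
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  probs <- apply(grid, 1, function(a) prod(ifelse(a == 1, slot_p, 1 - slot_p)))
  s_counts <- rowSums(grid)
  list(fitness = f, pot = pot, offspring = n_off,
       expected_S = sum(probs * s_counts),
       expected_N = k,
       var_S = sum(probs * s_counts^2) - sum(probs * s_counts)^2)
}

# random valid populations for property tests
random_population <- function(n, seed) {
  set.seed(seed)
  phi <- runif(n)
  pggevol:::new_population(
    t = 0L, selfish = runif(n) < 0.5, phi = phi,
    gamma = runif(n) * (1 - phi), omega = runif(n) * phi)
}
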