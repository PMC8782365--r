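cfg0 <- pgg_config()   # published defaults, m_S = 0.25

test_that("harvesting splits the offer by phenotype and respects the cap", {
  pop <- init_population(pgg_config(m_S = 0))
  hv <- harvest_phase(pop, pgg_config(m_S = 0))
  expect_equal(hv$e_t, 4.5)                       # e_tot / N0 = 1125 / 250
  expect_equal(unique(hv$harvest[pop$selfish]), 3.6)    # 0.8 * 4.5
  expect_equal(unique(hv$harvest[!pop$selfish]), 2.25)  # 0.5 * 4.5
  expect_true(all(hv$alive))

  # half-sized population: offer doubles and the cap binds for both types
  half <- pggevol:::new_population(0L, rep(c(TRUE, FALSE), c(25, 100)),
                                   rep(0.1, 125), rep(0.01, 125),
                                   rep(0.01, 125))
  hv <- harvest_phase(half, pgg_config(m_S = 0))
  expect_equal(hv$e_t, 9)
  expect_true(all(hv$harvest == 4.5))             # min(0.8*9, 4.5) = min(0.5*9, 4.5)
})

test_that("harvest mortality only strikes selfish agents, at rate m_S", {
  pop <- init_population(pgg_config(S0 = 0.5))
  set.seed(42)
  deaths <- replicate(200, {
    hv <- harvest_phase(pop, pgg_config(S0 = 0.5, m_S = 0.5))
    c(sum(!hv$alive[pop$selfish]), sum(!hv$alive[!pop$selfish]))
  })
  expect_equal(sum(deaths[2, ]), 0)               # generous never die
  p_hat <- mean(deaths[1, ]) / sum(pop$selfish)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / (200 * sum(pop$selfish))))
  # dead agents harvest nothing
  set.seed(1)
  hv <- harvest_phase(pop, pgg_config(S0 = 0.5, m_S = 0.9))
  expect_true(all(hv$harvest[!hv$alive] == 0))
})

test_that("contribution rates follow the conditional-cooperation rule", {
  pop <- init_population(cfg0)
  expect_equal(unique(contribution_rates(pop, cfg0)[pop$selfish]), 0.2)
  expect_equal(unique(contribution_rates(pop, cfg0)[!pop$selfish]), 1)

  ccfg <- pgg_config(conditional_cooperation = TRUE)
  expect_equal(unique(contribution_rates(pop, ccfg)[!pop$selfish]), 1)  # t = 0

  later <- pop
  later$t <- 5L
  later$prev_contrib <- mean(c(1, 1, 0.2, 0.2))   # previous generation's rates
  expect_equal(unique(contribution_rates(later, ccfg)[!later$selfish]), 0.6)
  later$prev_contrib <- 0.2                        # all-selfish previous cohort
  expect_equal(unique(contribution_rates(later, ccfg)[!later$selfish]), 0.2)
  later$prev_contrib <- NA_real_
  expect_error(contribution_rates(later, ccfg), "previous")
  # baseline model ignores history entirely
  expect_equal(unique(contribution_rates(later, cfg0)[!later$selfish]), 1)
})

test_that("public goods game reproduces the two-agent worked example", {
  # 1 selfish (r = 3.6, c = 0.2) + 1 generous (r = 2.25, c = 1)
  r <- c(3.6, 2.25); sel <- c(TRUE, FALSE); cc <- c(0.2, 1)
  pg <- public_goods_phase(r, sel, cc, pgg_config(lam = 0))
  expect_equal(pg$pot, 2.97)
  expect_equal(pg$fitness, c(5.1075, 2.2275))

  pg50 <- public_goods_phase(r, sel, cc, pgg_config(lam = 50))
  expect_equal(pg50$pot, 2.97 - 0.5)               # one selfish participant

  pgA <- public_goods_phase(r, sel, cc,
                            pgg_config(lam = 0, individual_cost = TRUE))
  expect_equal(pgA$fitness, c(5.1075 - 0.1, 2.2275))

  # pot floored at zero under a crushing community cost
  pg100 <- public_goods_phase(c(0.5, 0.5), c(TRUE, TRUE), c(0.2, 0.2),
                              pgg_config(lam = 100))
  expect_equal(pg100$pot, 0)
  expect_equal(pg100$fitness, c(0.4, 0.4))         # retained harvest only
})

test_that("resources are conserved through the game when lam = alpha = 0", {
  cfg <- pgg_config(lam = 0)
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(1:400, 1)
    r <- runif(n, 0, 4.5)
    sel <- runif(n) < 0.5
    cc <- ifelse(sel, 0.2, 1)
    pg <- public_goods_phase(r, sel, cc, cfg)
    expect_equal(sum(pg$fitness), cfg$rho * pg$pot + sum(r * (1 - cc)),
                 tolerance = 1e-9)
  }
})

test_that("offspring counts follow the threshold/ceiling/saturation rule", {
  expect_equal(offspring_count(c(-2, 0, 1), cfg0), c(0L, 0L, 0L))    # f <= s
  expect_equal(offspring_count(c(11, 50), cfg0), c(10L, 10L))        # f >= M
  expect_equal(offspring_count(5.1075, cfg0), 5L)                    # ceil(4.1075)
  expect_equal(offspring_count(c(1.0001, 2, 2.0001), cfg0), c(1L, 1L, 2L))
  # monotone non-decreasing in fitness and bounded by o
  f <- seq(-1, 15, by = 0.01)
  n <- offspring_count(f, cfg0)
  expect_true(all(diff(n) >= 0))
  expect_true(all(n >= 0 & n <= cfg0$o))
})

test_that("transmission matrix rows are stochastic for any valid input", {
  m <- reproduction_matrix(0.5, 0, 0)
  expect_equal(m$phi_GS, 0.5)
  expect_equal(m$phi_SS, 0.5)
  set.seed(99)
  phi <- runif(500); gamma <- runif(500) * (1 - phi); omega <- runif(500) * phi
  m <- reproduction_matrix(phi, gamma, omega)
  expect_true(all(abs(m$phi_GG + m$phi_GS - 1) < 1e-12))
  expect_true(all(abs(m$phi_SS + m$phi_SG - 1) < 1e-12))
  expect_true(all(m$phi_GG >= 0 & m$phi_GG <= 1 & m$phi_SS >= 0 &
                    m$phi_SS <= 1 & m$phi_GS >= 0 & m$phi_SG >= 0))
  expect_error(reproduction_matrix(0.1, 0.95, 0.01), "components")
})

test_that("offspring inherit components verbatim and draw phenotypes independently", {
  empty <- draw_offspring(TRUE, 0.1, 0.01, 0.01, 0L, cfg0)
  expect_length(empty$selfish, 0)

  pt <- pgg_config(perfect_transmission = TRUE)
  kids <- draw_offspring(c(TRUE, FALSE), c(0.1, 0.2), c(0.01, 0.01),
                         c(0.01, 0.02), c(10L, 4L), pt)
  expect_equal(kids$selfish, rep(c(TRUE, FALSE), c(10, 4)))
  expect_equal(kids$phi, rep(c(0.1, 0.2), c(10, 4)))
  expect_equal(kids$omega, rep(c(0.01, 0.02), c(10, 4)))

  # a generous parent at the defaults produces selfish offspring at rate
  # phi - omega = 0.09; Monte-Carlo check against the binomial expectation
  set.seed(7)
  draws <- 10000L
  tot <- replicate(draws / 10L,
    sum(draw_offspring(FALSE, 0.1, 0.01, 0.01, 10L, cfg0)$selfish))
  p_hat <- sum(tot) / draws
  expect_lt(abs(p_hat - 0.09), 3 * sqrt(0.09 * 0.91 / draws))
})

test_that("mutation adds the drawn noise and clips in the documented order", {
  # zero variance: identity
  frozen <- pgg_config(sigma2_phi = 0, sigma2_gamma = 0, sigma2_omega = 0)
  pop <- random_population(50, seed = 3)
  expect_equal(mutate_probabilities(pop, frozen), pop)
  # mutation disabled: identity even with nonzero variances
  off <- pgg_config(mutation_enabled = FALSE)
  expect_equal(mutate_probabilities(pop, off), pop)

  # replicate the engine's draws independently and apply the clipping rules:
  # phi into [0,1] first, then gamma against 1 - phi, omega against phi
  pop <- pggevol:::new_population(0L, c(TRUE, FALSE, FALSE),
                                  phi = c(0.99, 0.5, 0.02),
                                  gamma = c(0.05, 0.2, 0.9),
                                  omega = c(0.5, 0.2, 0.01))
  big <- pgg_config(sigma2_phi = 0.25, sigma2_gamma = 0.25, sigma2_omega = 0.25)
  set.seed(11)
  eta_phi <- rnorm(3, 0, 0.5); eta_gam <- rnorm(3, 0, 0.5)
  eta_om <- rnorm(3, 0, 0.5)
  phi_exp <- pmin(pmax(pop$phi + eta_phi, 0), 1)
  gam_exp <- pmin(pmax(pop$gamma + eta_gam, 0), 1 - phi_exp)
  om_exp <- pmin(pmax(pop$omega + eta_om, 0), phi_exp)
  set.seed(11)
  mut <- mutate_probabilities(pop, big)
  expect_identical(mut$phi, phi_exp)
  expect_identical(mut$gamma, gam_exp)
  expect_identical(mut$omega, om_exp)

  # clipping keeps every agent inside the admissible region, whatever the noise
  set.seed(12)
  pop <- random_population(2000, seed = 12)
  mut <- mutate_probabilities(pop, big)
  expect_true(all(mut$phi >= 0 & mut$phi <= 1))
  expect_true(all(mut$gamma >= 0 & mut$gamma <= 1 - mut$phi))
  expect_true(all(mut$omega >= 0 & mut$omega <= mut$phi))
})

test_that("mutation noise is mean-zero away from the boundaries", {
  n <- 100000L
  pop <- pggevol:::new_population(0L, rep(FALSE, n), rep(0.5, n),
                                  rep(0.2, n), rep(0.2, n))
  set.seed(5)
  mut <- mutate_probabilities(pop, cfg0)
  se <- sqrt(cfg0$sigma2_phi / n)
  expect_lt(abs(mean(mut$phi) - 0.5), 3 * se)
  expect_lt(abs(mean(mut$gamma) - 0.2), 3 * sqrt(cfg0$sigma2_gamma / n))
  expect_lt(abs(mean(mut$omega) - 0.2), 3 * sqrt(cfg0$sigma2_omega / n))
})
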