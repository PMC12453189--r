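# Persistence/detection link functions, the marginalized likelihood and
# its enumeration oracle, diagnostics, posterior summaries.

test_that("annual persistence follows the logistic link", {
  cov1 <- tibble::tibble(ecoregion = "a", h = 0.5, w = 0.5, v = 0.5)
  expect_equal(annual_persistence(cjs_params(alpha = c(a = 0)), cov1), 0.5,
               ignore_attr = TRUE)
  p_hs <- cjs_params(alpha = c(a = 0), beta_hs = 2.856)
  expect_equal(
    annual_persistence(p_hs, tibble::tibble(ecoregion = "a", h = 1, w = 0, v = 0)),
    plogis(2.856), ignore_attr = TRUE, tolerance = 1e-12)
  # monotone in w when beta_rain > 0
  p_r <- cjs_params(alpha = c(a = 0), beta_rain = 4)
  covs <- tibble::tibble(ecoregion = "a", h = 0, w = seq(0, 1, 0.1), v = 0)
  expect_true(all(diff(annual_persistence(p_r, covs)) > 0))
  expect_error(
    annual_persistence(p_hs, tibble::tibble(ecoregion = "zz", h = 0, w = 0, v = 0)),
    "unknown ecoregion")
})

test_that("detection probability reproduces the intercept and trend", {
  prm <- cjs_params(alpha = c(a = 0), gamma0 = qlogis(0.014),
                    beta_trend = 0.019, beta_effort = 0.279)
  expect_equal(detection_prob(prm, 1987, 0), 0.014, tolerance = 1e-12)
  expect_true(all(diff(detection_prob(prm, 1950:2024, 0)) > 0))
  flat <- cjs_params(alpha = c(a = 0), gamma0 = -2)
  expect_equal(detection_prob(flat, 1950:2024, runif(75)),
               rep(plogis(-2), 75))
})

test_that("hand-enumerable worked examples are exact", {
  # detection only in year 1, phi = p = 0.5, T = 3
  expect_equal(exp(cjs_marginal_loglik(c(1, 0, 0), rep(0.5, 3), 0.5)),
               0.34375, tolerance = 1e-12)
  expect_equal(persistence_posterior(c(1, 0, 0), rep(0.5, 3), 0.5),
               1 / 11, tolerance = 1e-12)
  # certain detection, all detected: must survive both transitions
  phi <- 0.7
  expect_equal(exp(cjs_marginal_loglik(c(1, 1, 1), rep(1 - 1e-12, 3), phi)),
               phi^2, tolerance = 1e-9)
  # detected in the final year: persistence is exactly 1
  expect_identical(persistence_posterior(c(0, 1), c(0.3, 0.3), 0.5), 1)
  # phi -> 1: persistence approaches 1 regardless of history
  expect_equal(persistence_posterior(c(1, 0, 0, 0), rep(0.4, 4), 1 - 1e-12),
               1, tolerance = 1e-8)
})

test_that("marginal likelihood equals brute-force enumeration", {
  set.seed(101)
  for (rep in 1:60) {
    T <- sample(2:8, 1)
    inst <- random_instance(T)
    got <- cjs_marginal_loglik(inst$y, inst$p, inst$phi, inst$L)
    expect_equal(got, log(brute_force_lik(inst$y, inst$p, inst$phi)),
                 tolerance = 1e-12)
    expect_equal(persistence_posterior(inst$y, inst$p, inst$phi, inst$L),
                 brute_force_persist(inst$y, inst$p, inst$phi),
                 tolerance = 1e-12)
  }
})

test_that("the C++ bulk evaluator agrees with the R single-population path", {
  set.seed(102)
  N <- 25; T <- 12
  eco <- sample(1:3, N, replace = TRUE)
  X <- cbind(runif(N), runif(N), runif(N))
  e <- matrix(rnorm(N * T), N, T)
  y <- matrix(rbinom(N * T, 1, 0.15), N, T)
  L <- apply(y, 1, function(r) if (any(r > 0)) max(which(r > 0)) else 1L)
  for (i in 1:N) if (L[i] < T) y[i, (L[i] + 1):T] <- 0L
  theta <- c(0.5, 1, 1.5, 2.8, 4, -1.5, -4.2, 0.02, 0.28)
  years <- seq_len(T) + 1999
  res <- popersist:::cjs_eval_cpp(theta[1:3], theta[4], theta[5], theta[6],
                                  theta[7], theta[8], theta[9], X, eco,
                                  y, e, as.integer(L), years - 2005, TRUE)
  prm <- cjs_params(alpha = c(e1 = 0.5, e2 = 1, e3 = 1.5), beta_hs = 2.8,
                    beta_rain = 4, beta_imp = -1.5, gamma0 = -4.2,
                    beta_trend = 0.02, beta_effort = 0.28)
  for (i in 1:N) {
    covi <- tibble::tibble(ecoregion = paste0("e", eco[i]),
                           h = X[i, 1], w = X[i, 2], v = X[i, 3])
    phi <- annual_persistence(prm, covi)
    p <- detection_prob(prm, years, e[i, ], t_ref = 2005)
    expect_equal(res$loglik_pop[i],
                 cjs_marginal_loglik(y[i, ], p, phi, L[i]),
                 tolerance = 1e-10)
    expect_equal(res$persist[i],
                 persistence_posterior(y[i, ], p, phi, L[i]),
                 tolerance = 1e-10)
  }
  expect_equal(res$loglik, sum(res$loglik_pop), tolerance = 1e-8)
})

test_that("persistence posterior is monotone in last detection and phi", {
  T <- 20
  p <- rep(0.2, T)
  vals_L <- vapply(1:T, function(L) {
    y <- integer(T); y[L] <- 1L
    persistence_posterior(y, p, 0.8, L)
  }, numeric(1))
  expect_true(all(diff(vals_L) >= 0))
  y <- integer(T); y[5] <- 1L
  vals_phi <- vapply(seq(0.1, 0.95, 0.05), function(phi)
    persistence_posterior(y, p, phi, 5L), numeric(1))
  expect_true(all(diff(vals_phi) >= 0))
})

test_that("split-chain diagnostic matches a direct formula and calibrates", {
  # fixed toy arrays against a hand computation
  x <- cbind(par = c(1, 2, 3, 4, 2, 3, 4, 5))
  chain <- rep(1:2, each = 4)
  halves <- list(c(1, 2), c(3, 4), c(2, 3), c(4, 5))
  W <- mean(vapply(halves, var, numeric(1)))
  B <- 2 * var(vapply(halves, mean, numeric(1)))
  expect_equal(gelman_rubin(x, chain)$rhat,
               sqrt(((2 - 1) / 2 * W + B / 2) / W), tolerance = 1e-12)
  # same-distribution chains converge
  set.seed(103)
  big <- cbind(a = rnorm(15000), b = rexp(15000))
  r <- gelman_rubin(big, rep(1:3, each = 5000))
  expect_true(all(r$rhat > 0.99 & r$rhat < 1.05))
  # separated chains are flagged by a large value
  sep <- cbind(a = c(rnorm(2000), rnorm(2000) + 5))
  expect_gt(gelman_rubin(sep, rep(1:2, each = 2000))$rhat, 1.1)
  # constant chains at different values are degenerate
  const <- cbind(a = c(rep(1, 100), rep(2, 100)))
  expect_true(gelman_rubin(const, rep(1:2, each = 100))$degenerate)
})

test_that("posterior summaries use exact percentiles and flag importance", {
  set.seed(104)
  v <- rnorm(1000, 2, 1)
  m <- cbind(beta_pos = abs(v) + 0.1, beta_mixed = v - 2)
  s <- summarize_posterior(m)
  srt <- sort(m[, 1])
  expect_equal(s$q025[1], quantile(srt, 0.025, names = FALSE))
  expect_true(s$important[s$parameter == "beta_pos"])
  expect_false(s$important[s$parameter == "beta_mixed"])
  expect_equal(s$mean[2], mean(v) - 2, tolerance = 1e-12)
})

test_that("prior-only sampling recovers the prior", {
  # no populations: the posterior is the Normal(0, 10) prior
  det <- structure(list(
    y = matrix(0L, 0, 30, dimnames = list(NULL, 1991:2020)),
    years = 1991:2020, L = integer(0),
    last_detection_year = integer(0), last_record_year = integer(0),
    known_before_start = logical(0),
    first_detection_year = integer(0)), class = "detection_matrix")
  eff <- structure(list(e_raw = matrix(0L, 0, 30), e = matrix(0, 0, 30),
                        scaling = list(name = "none", center = 0, scale = 1),
                        years = 1991:2020, n_events_outside = 0L),
                   class = "effort_matrix")
  cov0 <- tibble::tibble(pop_id = character(0), ecoregion = character(0),
                         h = numeric(0), w = numeric(0), v = numeric(0))
  fit <- run_mcmc(det, eff, cov0,
                  model_spec(chains = 2, iterations = 30000,
                             burn_in = 5000, thin = 5, seed = 9,
                             t_ref = 2005),
                  persistence_draws = 10)
  s <- summarize_posterior(fit$draws)
  base <- s[!startsWith(s$parameter, "mu_"), ]
  expect_true(all(abs(base$mean) < 1.5))
  expect_true(all(base$sd > 7 & base$sd < 13))
})

test_that("identical seeds give identical retained samples", {
  sim <- simulate_histories(sim_truth(n_pops = 40), seed = 30)
  spec <- model_spec(chains = 2, iterations = 600, burn_in = 300,
                     thin = 3, seed = 77)
  f1 <- run_mcmc(sim$det, sim$eff, sim$covariates, spec,
                 persistence_draws = 50)
  f2 <- run_mcmc(sim$det, sim$eff, sim$covariates, spec,
                 persistence_draws = 50)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$persistence, f2$persistence)
})

test_that("persistence is exactly 1 for populations detected in the final year", {
  sim <- simulate_histories(sim_truth(n_pops = 60), seed = 31)
  fit <- run_mcmc(sim$det, sim$eff, sim$covariates,
                  model_spec(chains = 2, iterations = 1000, burn_in = 500,
                             thin = 5, seed = 8), persistence_draws = 100)
  final <- sim$det$y[, ncol(sim$det$y)] == 1L
  if (any(final)) {
    expect_true(all(fit$persistence$persist_mean[final] == 1))
  }
  expect_true(all(fit$persistence$persist_mean >= 0 &
                    fit$persistence$persist_mean <= 1))
})

test_that("posterior predictive checks behave at the extremes", {
  sim <- simulate_histories(sim_truth(n_pops = 30), seed = 32)
  dat <- popersist:::prepare_model_data(sim$det, sim$eff, sim$covariates)
  mkfit <- function(theta) {
    draws <- matrix(rep(theta, each = 50), 50)
    colnames(draws) <- popersist:::theta_names(dat$eco_levels)
    structure(list(draws = draws, chain = rep(1:2, 25), data = dat,
                   spec = model_spec(seed = 1), eco_levels = dat$eco_levels),
              class = "cjs_fit")
  }
  # p == 0: simulated statistic is 0 in every window
  mute <- mkfit(c(rep(2, 3), 0, 0, 0, -40, 0, 0))
  res <- posterior_predictive_check(mute, ndraws = 20, seed = 2)
  expect_true(all(res$sim_mean == 0))
  # certain detection of an extant population in a single-year window
  det1 <- sim$det; det1$y[] <- 0L; det1$y[, 75] <- 1L
  det1$L <- rep(75L, 30)
  dat1 <- popersist:::prepare_model_data(det1, sim$eff, sim$covariates)
  sure <- mkfit(c(rep(40, 3), 0, 0, 0, 40, 0, 0))
  sure$data <- dat1
  res1 <- posterior_predictive_check(sure, windows = list(c(2024, 2024)),
                                     ndraws = 10, seed = 3)
  expect_equal(res1$sim_mean, 30)
  expect_equal(res1$observed, 30)
  expect_error(posterior_predictive_check(mute, windows = list(c(1900, 1910))),
               "outside modeled years")
})
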