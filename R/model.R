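## Modified Cormack-Jolly-Seber persistence model.  A population's latent
## extant/extirpated state over 1950-2024 is a monotone Bernoulli process:
## extant populations persist each year with probability phi_i
## (logit-linear in habitat suitability, scaled winter precipitation and
## imperviousness, with an ecoregion intercept) and are detected with
## probability p_it (logit-linear in calendar year and scaled search
## effort).  The latent extirpation time is summed out analytically, giving
## an exact marginal likelihood (see src/cjs.cpp for the formula), which an
## adaptive Metropolis-within-Gibbs sampler explores under Normal(0, 10)
## priors on all logit-scale parameters.

#' Model parameters
#'
#' @param alpha named numeric vector of logit-scale persistence intercepts,
#'   one per ecoregion
#' @param beta_hs,beta_rain,beta_imp persistence effects per unit of the
#'   `[0, 1]` covariates (habitat suitability, scaled winter precipitation,
#'   imperviousness)
#' @param gamma0 logit-scale detection intercept (at the reference year and
#'   zero scaled effort)
#' @param beta_trend detection trend per year
#' @param beta_effort detection effect per scaled effort unit
#' @return object of class `cjs_params`
#' @export
cjs_params <- function(alpha, beta_hs = 0, beta_rain = 0, beta_imp = 0,
                       gamma0 = 0, beta_trend = 0, beta_effort = 0) {
  if (is.null(names(alpha))) names(alpha) <- paste0("eco", seq_along(alpha))
  structure(list(alpha = alpha, beta_hs = beta_hs, beta_rain = beta_rain,
                 beta_imp = beta_imp, gamma0 = gamma0,
                 beta_trend = beta_trend, beta_effort = beta_effort),
            class = "cjs_params")
}

theta_names <- function(eco_levels) {
  c(sprintf("alpha_%s", eco_levels), "beta_hs", "beta_rain", "beta_imp",
    "gamma0", "beta_trend", "beta_effort")
}

params_to_theta <- function(params) {
  c(params$alpha, params$beta_hs, params$beta_rain, params$beta_imp,
    params$gamma0, params$beta_trend, params$beta_effort)
}

theta_to_params <- function(theta, eco_levels) {
  R <- length(eco_levels)
  cjs_params(alpha = setNames(theta[seq_len(R)], eco_levels),
             beta_hs = theta[R + 1], beta_rain = theta[R + 2],
             beta_imp = theta[R + 3], gamma0 = theta[R + 4],
             beta_trend = theta[R + 5], beta_effort = theta[R + 6])
}

#' Annual persistence probability
#'
#' `phi_i = plogis(alpha[ecoregion_i] + beta_hs * h + beta_rain * w +
#' beta_imp * v)`: the probability that an extant population is still
#' extant one year later.
#'
#' @param params a [cjs_params()]
#' @param covariates data frame with columns `ecoregion`, `h`, `w`, `v`
#' @return numeric vector of annual persistence probabilities in (0, 1)
#' @export
annual_persistence <- function(params, covariates) {
  idx <- match(covariates$ecoregion, names(params$alpha))
  if (anyNA(idx)) {
    stop("unknown ecoregion label(s): ",
         paste(unique(covariates$ecoregion[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  unname(plogis(params$alpha[idx] + params$beta_hs * covariates$h +
                  params$beta_rain * covariates$w +
                  params$beta_imp * covariates$v))
}

#' Annual detection probability
#'
#' `p = plogis(gamma0 + beta_trend * (year - t_ref) + beta_effort *
#' effort)`: the probability that an extant population is detected in a
#' given year, given the (scaled) search effort expended there.
#'
#' @param params a [cjs_params()]
#' @param year calendar year (vectorized)
#' @param effort scaled effort (vectorized)
#' @param t_ref reference year at which `gamma0` is the logit detection
#'   rate (default 1987, the midpoint of 1950-2024)
#' @return detection probabilities in (0, 1)
#' @export
detection_prob <- function(params, year, effort = 0, t_ref = 1987) {
  plogis(params$gamma0 + params$beta_trend * (year - t_ref) +
           params$beta_effort * effort)
}

#' Exact marginal log-likelihood of one detection history
#'
#' Sums the complete-data likelihood over all monotone latent state
#' histories compatible with the data (the population must be extant
#' through its last detection), i.e. over the extirpation year.  Detection
#' factors are included for every year in which the population is extant --
#' including pre-first-detection zeros, since presence at the start of the
#' period is assumed.
#'
#' @param y binary detection vector of length `T`
#' @param p detection probabilities, length `T`
#' @param phi scalar annual persistence probability
#' @param L index of the last detection (1 when the population was never
#'   detected during the modeled period)
#' @return log-likelihood (scalar)
#' @export
cjs_marginal_loglik <- function(y, p, phi, L = if (any(y > 0)) max(which(y > 0)) else 1L) {
  T <- length(y)
  stopifnot(length(p) == T, L >= 1, L <= T)
  ld <- ifelse(y > 0, log(p), log1p(-p))
  cumld <- cumsum(ld)
  k <- seq(L, T)
  lt <- (k - 1) * log(phi) + ifelse(k < T, log1p(-phi), 0) + cumld[k]
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

#' Persistence posterior at fixed parameters
#'
#' Probability that the population is still extant in the final modeled
#' year, given its detection history and parameter values: the
#' survived-throughout term of the marginal likelihood divided by the
#' whole sum.  Equals 1 exactly when the population was detected in the
#' final year.
#'
#' @inheritParams cjs_marginal_loglik
#' @return probability in `[0, 1]`
#' @export
persistence_posterior <- function(y, p, phi, L = if (any(y > 0)) max(which(y > 0)) else 1L) {
  T <- length(y)
  ld <- ifelse(y > 0, log(p), log1p(-p))
  cumld <- cumsum(ld)
  k <- seq(L, T)
  lt <- (k - 1) * log(phi) + ifelse(k < T, log1p(-phi), 0) + cumld[k]
  m <- max(lt)
  exp(lt[length(lt)] - m) / sum(exp(lt - m))
}

#' Marginal log-likelihood of one population from model inputs
#'
#' Convenience wrapper assembling `phi` and `p` from parameters and
#' covariates, then calling [cjs_marginal_loglik()].
#'
#' @param y,effort length-`T` detection and scaled-effort vectors
#' @param params a [cjs_params()]
#' @param covariates one-row data frame (`ecoregion`, `h`, `w`, `v`)
#' @param years calendar years of the columns
#' @param t_ref detection reference year
#' @param L index of last detection
#' @return log-likelihood (scalar)
#' @export
population_loglik <- function(y, effort, params, covariates,
                              years, t_ref = 1987,
                              L = if (any(y > 0)) max(which(y > 0)) else 1L) {
  phi <- annual_persistence(params, covariates)
  p <- detection_prob(params, years, effort, t_ref)
  cjs_marginal_loglik(y, p, phi, L)
}

#' MCMC settings
#'
#' Defaults follow the analysis protocol: three chains of 100,000
#' iterations, discarding the first 50,000 and retaining every third
#' iteration thereafter (16,667 samples per chain).
#'
#' @param chains number of chains (>= 2)
#' @param iterations iterations per chain
#' @param burn_in discarded initial iterations
#' @param thin retain every `thin`-th post-burn-in iteration
#' @param prior_sd standard deviation of the Normal(0, sd) prior applied to
#'   every logit-scale parameter
#' @param t_ref detection reference year
#' @param seed RNG seed for the run
#' @return object of class `model_spec`
#' @export
model_spec <- function(chains = 3, iterations = 100000, burn_in = 50000,
                       thin = 3, prior_sd = 10, t_ref = 1987, seed = 1) {
  stopifnot(chains >= 2, iterations > burn_in, thin >= 1, prior_sd > 0)
  structure(list(chains = chains, iterations = iterations,
                 burn_in = burn_in, thin = thin, prior_sd = prior_sd,
                 t_ref = t_ref, seed = seed),
            class = "model_spec")
}

## Assemble aligned model matrices from pipeline objects.
prepare_model_data <- function(det, eff, covariates) {
  pops <- rownames(det$y)
  idx <- match(pops, covariates$pop_id)
  if (anyNA(idx)) stop("covariate table misses population(s): ",
                       paste(pops[is.na(idx)], collapse = ", "), call. = FALSE)
  cov <- covariates[idx, ]
  eco_levels <- sort(unique(cov$ecoregion))
  list(y = det$y, e = eff$e, L = det$L, years = det$years,
       X = cbind(h = cov$h, w = cov$w, v = cov$v),
       eco = match(cov$ecoregion, eco_levels),
       eco_levels = eco_levels, pop_id = pops)
}

## Log posterior (total marginal log-likelihood + Normal priors).
make_log_posterior <- function(dat, prior_sd, t_ref) {
  tcov <- dat$years - t_ref
  R <- length(dat$eco_levels)
  ymat <- matrix(as.integer(dat$y), nrow(dat$y), ncol(dat$y))
  function(theta) {
    res <- cjs_eval_cpp(theta[seq_len(R)], theta[R + 1], theta[R + 2],
                        theta[R + 3], theta[R + 4], theta[R + 5],
                        theta[R + 6], dat$X, dat$eco, ymat, dat$e,
                        dat$L, tcov, FALSE)
    res$loglik + sum(dnorm(theta, 0, prior_sd, log = TRUE))
  }
}

## One adaptive Metropolis-within-Gibbs chain (C++ core; see src/cjs.cpp).
## Proposal scales adapt in batches of 50 during burn-in toward 35%
## acceptance (within the 30-45% band appropriate for one-dimensional
## updates), then stay fixed so the retained samples come from a
## fixed-kernel chain.
mwg_chain <- function(dat, spec, theta0, scales0 = NULL) {
  R <- length(dat$eco_levels)
  tcov <- dat$years - spec$t_ref
  ymat <- matrix(as.integer(dat$y), nrow(dat$y), ncol(dat$y))
  lp0 <- cjs_eval_cpp(theta0[seq_len(R)], theta0[R + 1], theta0[R + 2],
                      theta0[R + 3], theta0[R + 4], theta0[R + 5],
                      theta0[R + 6], dat$X, dat$eco, ymat, dat$e, dat$L,
                      tcov, FALSE)$loglik
  tries <- 0
  while (!is.finite(lp0) && tries < 20) {
    theta0 <- theta0 + rnorm(length(theta0), 0, 0.5)
    lp0 <- cjs_eval_cpp(theta0[seq_len(R)], theta0[R + 1], theta0[R + 2],
                        theta0[R + 3], theta0[R + 4], theta0[R + 5],
                        theta0[R + 6], dat$X, dat$eco, ymat, dat$e, dat$L,
                        tcov, FALSE)$loglik
    tries <- tries + 1
  }
  if (!is.finite(lp0)) stop("log-posterior not finite at initialization",
                            call. = FALSE)
  res <- cjs_mwg_cpp(theta0, dat$X, dat$eco, ymat, dat$e, dat$L, tcov,
                     spec$prior_sd, spec$iterations, spec$burn_in,
                     spec$thin, scales0 %||% rep(0.2, length(theta0)), 0.35)
  list(draws = res$draws, acceptance = as.numeric(res$acceptance))
}

## Latent-state-augmented chain: alternates exact sampling of each
## population's last extant year from its discrete full conditional with
## Metropolis-within-Gibbs parameter updates under the complete-data
## likelihood.  Targets the same posterior as the marginalized chain.
augmented_chain <- function(dat, spec, theta0) {
  R <- length(dat$eco_levels)
  K <- R + 6L
  N <- nrow(dat$y)
  T <- ncol(dat$y)
  tcov <- dat$years - spec$t_ref
  Lmin <- pmin(pmax(dat$L, 1L), T)
  term_matrix <- function(theta) {
    phi <- plogis(theta[dat$eco] + theta[R + 1] * dat$X[, 1] +
                    theta[R + 2] * dat$X[, 2] + theta[R + 3] * dat$X[, 3])
    p <- plogis(outer(rep(theta[R + 4], N), theta[R + 5] * tcov, `+`) +
                  theta[R + 6] * dat$e)
    ld <- dat$y * log(p) + (1 - dat$y) * log1p(-p)
    cumld <- t(apply(ld, 1, cumsum))
    kk <- matrix(seq_len(T), N, T, byrow = TRUE)
    lt <- (kk - 1) * log(phi) + (kk < T) * log1p(-phi) + cumld
    lt[kk < Lmin] <- -Inf
    lt
  }
  complete_lp <- function(theta, kvec) {
    phi <- plogis(theta[dat$eco] + theta[R + 1] * dat$X[, 1] +
                    theta[R + 2] * dat$X[, 2] + theta[R + 3] * dat$X[, 3])
    p <- plogis(outer(rep(theta[R + 4], N), theta[R + 5] * tcov, `+`) +
                  theta[R + 6] * dat$e)
    ld <- dat$y * log(p) + (1 - dat$y) * log1p(-p)
    cumld <- t(apply(ld, 1, cumsum))
    sum((kvec - 1) * log(phi) + (kvec < T) * log1p(-phi) +
          cumld[cbind(seq_len(N), kvec)]) +
      sum(dnorm(theta, 0, spec$prior_sd, log = TRUE))
  }
  theta <- theta0
  lt <- term_matrix(theta)
  gumbel <- function() -log(-log(matrix(runif(N * T), N, T)))
  kvec <- max.col(lt + gumbel(), ties.method = "first")
  lp <- complete_lp(theta, kvec)
  keep_at <- seq(spec$burn_in + 1, spec$iterations, by = spec$thin)
  draws <- matrix(NA_real_, length(keep_at), K)
  persist_acc <- numeric(N)
  scales <- rep(0.2, K)
  batch_acc <- numeric(K)
  s <- 0L
  for (it in seq_len(spec$iterations)) {
    kvec <- max.col(term_matrix(theta) + gumbel(), ties.method = "first")
    lp <- complete_lp(theta, kvec)
    for (k in seq_len(K)) {
      cand <- theta
      cand[k] <- cand[k] + rnorm(1, 0, scales[k])
      lpc <- complete_lp(cand, kvec)
      if (is.finite(lpc) && log(runif(1)) < lpc - lp) {
        theta <- cand
        lp <- lpc
        batch_acc[k] <- batch_acc[k] + 1
      }
    }
    if (it <= spec$burn_in && it %% 50L == 0) {
      scales <- pmin(pmax(scales * exp(batch_acc / 50 - 0.35), 1e-4), 25)
      batch_acc[] <- 0
    }
    if (s < length(keep_at) && it == keep_at[s + 1L]) {
      s <- s + 1L
      draws[s, ] <- theta
      persist_acc <- persist_acc + (kvec == T)
    }
  }
  list(draws = draws, persist = persist_acc / length(keep_at))
}

#' Fit the persistence model by MCMC
#'
#' Samples the posterior of the seven structural parameters (ecoregion
#' intercepts, three persistence effects, detection intercept, trend and
#' effort slope) and computes each population's posterior probability of
#' persisting in the final modeled year.
#'
#' @param det a `detection_matrix` from [build_detection_matrix()]
#' @param eff an `effort_matrix` from [build_effort_matrix()]
#' @param covariates tibble with `pop_id`, `ecoregion`, `h`, `w`, `v`
#'   aligned to the populations of `det`
#' @param spec a [model_spec()]
#' @param method `"marginal"` (default; latent extirpation time summed out
#'   analytically) or `"augmented"` (latent states sampled explicitly; same
#'   posterior, used for cross-validation of the sampler)
#' @param persistence_draws number of retained draws (evenly spaced across
#'   chains) over which per-population persistence posteriors are averaged
#' @return a `cjs_fit`: list with `draws` (matrix, labelled columns),
#'   `chain`, `persistence` tibble (`pop_id`, mean, sd, 2.5/97.5
#'   percentiles, `last_detection_year`), `acceptance`, `spec`, `method`,
#'   `data` (prepared model inputs) and `eco_levels`
#' @export
run_mcmc <- function(det, eff, covariates, spec = model_spec(),
                     method = c("marginal", "augmented"),
                     persistence_draws = 3000) {
  method <- match.arg(method)
  dat <- prepare_model_data(det, eff, covariates)
  K <- length(dat$eco_levels) + 6L
  set.seed(spec$seed)
  # chains start overdispersed around the posterior mode, with jitter
  # scaled by the local curvature; this removes the initialization
  # transient that plagues random-walk samplers started far from the mass
  lp_fun <- make_log_posterior(dat, spec$prior_sd, spec$t_ref)
  th0 <- rep(0, K)
  if (nrow(dat$y) > 0) {
    th0[length(dat$eco_levels) + 4L] <- qlogis(max(mean(dat$y), 1e-3))
  }
  opt <- tryCatch(
    optim(th0, function(th) -lp_fun(th), method = "BFGS",
          control = list(maxit = 300), hessian = TRUE),
    error = function(e) NULL)
  if (!is.null(opt) && all(is.finite(opt$par))) {
    mode <- opt$par
    jitter_sd <- tryCatch({
      sds <- sqrt(diag(solve(opt$hessian)))
      ifelse(is.finite(sds) & sds > 0, 2 * sds, 0.2)
    }, error = function(e) rep(0.2, K))
  } else {
    mode <- th0
    jitter_sd <- rep(0.2, K)
  }
  init <- function() mode + rnorm(K, 0, jitter_sd)
  chains <- vector("list", spec$chains)
  acc <- vector("list", spec$chains)
  persist_aug <- NULL
  if (method == "marginal") {
    scales0 <- pmin(pmax(jitter_sd, 1e-3), 5)
    for (c in seq_len(spec$chains)) {
      res <- mwg_chain(dat, spec, init(), scales0)
      chains[[c]] <- res$draws
      acc[[c]] <- res$acceptance
    }
  } else {
    persist_aug <- numeric(nrow(dat$y))
    for (c in seq_len(spec$chains)) {
      res <- augmented_chain(dat, spec, init())
      chains[[c]] <- res$draws
      persist_aug <- persist_aug + res$persist / spec$chains
      acc[[c]] <- NA_real_
    }
  }
  draws <- do.call(rbind, chains)
  colnames(draws) <- theta_names(dat$eco_levels)
  chain <- rep(seq_len(spec$chains), vapply(chains, nrow, integer(1)))
  fit <- structure(list(draws = draws, chain = chain, spec = spec,
                        method = method, data = dat,
                        eco_levels = dat$eco_levels,
                        acceptance = do.call(rbind, acc)),
                   class = "cjs_fit")
  fit$persistence <- persistence_table(fit, persistence_draws,
                                       aug_mean = persist_aug)
  fit$persistence$last_detection_year <- det$last_detection_year
  fit$persistence$last_record_year <- det$last_record_year
  fit
}

## Per-population persistence posterior, averaged over retained draws.
persistence_table <- function(fit, persistence_draws = 3000,
                              aug_mean = NULL) {
  dat <- fit$data
  R <- length(dat$eco_levels)
  S <- nrow(fit$draws)
  use <- unique(round(seq(1, S, length.out = min(persistence_draws, S))))
  tcov <- dat$years - fit$spec$t_ref
  ymat <- matrix(as.integer(dat$y), nrow(dat$y), ncol(dat$y))
  P <- matrix(NA_real_, length(use), nrow(dat$y))
  for (s in seq_along(use)) {
    th <- fit$draws[use[s], ]
    res <- cjs_eval_cpp(th[seq_len(R)], th[R + 1], th[R + 2], th[R + 3],
                        th[R + 4], th[R + 5], th[R + 6], dat$X, dat$eco,
                        ymat, dat$e, dat$L, tcov, TRUE)
    P[s, ] <- res$persist
  }
  tibble::tibble(
    pop_id = dat$pop_id,
    persist_mean = colMeans(P),
    persist_sd = apply(P, 2, sd),
    persist_q025 = apply(P, 2, quantile, 0.025, names = FALSE),
    persist_q975 = apply(P, 2, quantile, 0.975, names = FALSE),
    persist_state_freq = if (is.null(aug_mean)) colMeans(P) else aug_mean
  )
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(sprintf("<cjs_fit> %s sampler: %d populations, %d years, %d chains, %d retained draws\n",
              x$method, nrow(x$data$y), ncol(x$data$y),
              x$spec$chains, nrow(x$draws)))
  print(summarize_posterior(x), n = Inf)
  invisible(x)
}

#' Split-chain potential scale reduction factor
#'
#' Brooks-Gelman-Rubin convergence diagnostic: each chain is split in half
#' and the between- to within-chain variance ratio is computed per
#' parameter.  Values near 1 indicate convergence; the analysis protocol
#' requires < 1.1 everywhere.
#'
#' @param draws a `cjs_fit`, or a matrix of draws
#' @param chain integer chain ids (required when `draws` is a matrix)
#' @return tibble (`parameter`, `rhat`, `degenerate`); `degenerate` marks
#'   zero within-chain variance (rhat undefined)
#' @export
gelman_rubin <- function(draws, chain = NULL) {
  if (inherits(draws, "cjs_fit")) {
    chain <- draws$chain
    draws <- draws$draws
  }
  draws <- as.matrix(draws)
  if (is.null(chain)) stop("chain ids required", call. = FALSE)
  split_one <- function(v) {
    n <- length(v)
    h <- n %/% 2L
    list(v[seq_len(h)], v[(n - h + 1):n])
  }
  out <- lapply(seq_len(ncol(draws)), function(j) {
    pieces <- unlist(lapply(split(draws[, j], chain), split_one),
                     recursive = FALSE)
    n <- min(lengths(pieces))
    pieces <- lapply(pieces, function(v) v[seq_len(n)])
    m <- length(pieces)
    means <- vapply(pieces, mean, numeric(1))
    vars <- vapply(pieces, var, numeric(1))
    W <- mean(vars)
    B <- n * var(means)
    if (!is.finite(W) || W == 0) {
      tibble::tibble(rhat = NA_real_, degenerate = TRUE)
    } else {
      tibble::tibble(rhat = sqrt(((n - 1) / n * W + B / n) / W),
                     degenerate = FALSE)
    }
  })
  dplyr::bind_cols(
    tibble::tibble(parameter = colnames(draws) %||%
                     paste0("par", seq_len(ncol(draws)))),
    dplyr::bind_rows(out)
  )
}

#' Posterior parameter summary
#'
#' Means and 95% credible intervals per parameter, with an `important`
#' flag when the interval excludes zero.  Ecoregion intercepts are also
#' reported back-transformed (`mu_<ecoregion>`, the annual persistence rate
#' at zero covariates) and the detection intercept as `mu_detection`
#' (detection rate at the reference year and zero scaled effort).
#'
#' @param fit a `cjs_fit` (or a draws matrix with labelled columns)
#' @return tibble (`parameter`, `mean`, `sd`, `q025`, `q975`, `important`)
#' @export
summarize_posterior <- function(fit) {
  draws <- if (inherits(fit, "cjs_fit")) fit$draws else as.matrix(fit)
  base <- lapply(colnames(draws), function(nm) {
    v <- draws[, nm]
    q <- quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(parameter = nm, mean = mean(v), sd = sd(v),
                   q025 = q[1], q975 = q[2],
                   important = q[1] > 0 | q[2] < 0)
  })
  trans <- list()
  for (nm in colnames(draws)) {
    if (startsWith(nm, "alpha_") || nm == "gamma0") {
      v <- plogis(draws[, nm])
      q <- quantile(v, c(0.025, 0.975), names = FALSE)
      lab <- if (nm == "gamma0") "mu_detection"
             else sub("^alpha_", "mu_", nm)
      trans[[nm]] <- tibble::tibble(parameter = lab, mean = mean(v),
                                    sd = sd(v), q025 = q[1], q975 = q[2],
                                    important = NA)
    }
  }
  dplyr::bind_rows(dplyr::bind_rows(base), dplyr::bind_rows(trans))
}

## Simulate latent states and detections given phi (length N) and p (N x T).
simulate_cjs_matrix <- function(phi, p) {
  N <- length(phi)
  T <- ncol(p)
  z <- matrix(0L, N, T)
  z[, 1] <- 1L
  alive <- rep(TRUE, N)
  for (t in seq_len(T)[-1]) {
    alive <- alive & (runif(N) < phi)
    z[, t] <- as.integer(alive)
  }
  y <- matrix(as.integer(matrix(runif(N * T), N, T) < p), N, T) * z
  list(z = z, y = y)
}

#' Posterior predictive check on detection counts
#'
#' For each retained draw, simulates latent states and detections from the
#' fitted model (with the observed effort) and compares the mean annual
#' number of populations with detections inside each time window to the
#' observed value.  The Bayesian p-value is the fraction of draws whose
#' simulated statistic is at least the observed one; values near 0 or 1
#' flag misfit.
#'
#' @param fit a `cjs_fit`
#' @param windows list of `c(start, end)` year pairs (defaults to
#'   1970-1974, 2000-2004, 2020-2024, clipped to the modeled years)
#' @param ndraws number of evenly spaced retained draws to simulate from
#' @param seed RNG seed for the simulation
#' @return tibble (`window`, `observed`, `sim_mean`, `p_value`)
#' @export
posterior_predictive_check <- function(fit,
                                       windows = list(c(1970, 1974),
                                                      c(2000, 2004),
                                                      c(2020, 2024)),
                                       ndraws = 400, seed = 1) {
  dat <- fit$data
  R <- length(dat$eco_levels)
  years <- dat$years
  for (w in windows) {
    if (w[1] < min(years) || w[2] > max(years)) {
      stop("window ", w[1], "-", w[2], " outside modeled years", call. = FALSE)
    }
  }
  S <- nrow(fit$draws)
  use <- unique(round(seq(1, S, length.out = min(ndraws, S))))
  tcov <- years - fit$spec$t_ref
  obs <- vapply(windows, function(w) {
    cols <- which(years >= w[1] & years <= w[2])
    mean(colSums(dat$y[, cols, drop = FALSE] > 0))
  }, numeric(1))
  set.seed(seed)
  sims <- matrix(NA_real_, length(use), length(windows))
  for (s in seq_along(use)) {
    th <- fit$draws[use[s], ]
    phi <- plogis(th[dat$eco] + th[R + 1] * dat$X[, 1] +
                    th[R + 2] * dat$X[, 2] + th[R + 3] * dat$X[, 3])
    p <- plogis(outer(rep(th[R + 4], nrow(dat$y)), th[R + 5] * tcov, `+`) +
                  th[R + 6] * dat$e)
    ysim <- simulate_cjs_matrix(phi, p)$y
    sims[s, ] <- vapply(windows, function(w) {
      cols <- which(years >= w[1] & years <= w[2])
      mean(colSums(ysim[, cols, drop = FALSE] > 0))
    }, numeric(1))
  }
  tibble::tibble(
    window = vapply(windows, function(w) paste(w[1], w[2], sep = "-"),
                    character(1)),
    observed = obs,
    sim_mean = colMeans(sims),
    p_value = vapply(seq_along(windows),
                     function(j) mean(sims[, j] >= obs[j]), numeric(1))
  )
}
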