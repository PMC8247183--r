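# Fast, small-model checks of the posterior evaluation and the sampler's
# exact updates.  The replicated recovery study lives in test-acceptance.R.

small_study_bits <- function() {
  ls <- flat_landscape(10, 10, seed = 21)
  sites <- data.frame(row = 5, col = 5, label = "E1")
  priors <- prior_spec(mu_theta = 100, sd_theta = 20,
                       mu_kappa = 1200, sd_kappa = 400)
  list(ls = ls, sites = sites, priors = priors)
}

test_that("log-posterior with no data reduces to the log-prior", {
  b <- small_study_bits()
  set.seed(3)
  draw <- sample_prior(b$priors, b$sites)
  sv <- survey_data()
  lp <- log_posterior(draw$params, draw$tau, p = numeric(0),
                      latent_N = integer(0), surveys = sv, ls = b$ls,
                      priors = b$priors, config = list(dt_days = 14))
  expect_equal(lp, log_prior(draw$params, draw$tau, NULL, b$priors),
               tolerance = 1e-12)
})

test_that("log-posterior is finite on-support and -Inf off-support", {
  b <- small_study_bits()
  set.seed(4)
  draw <- sample_prior(b$priors, b$sites)
  sv <- survey_data(counts = data.frame(row = 5, col = 6, year = 4, y = 3,
                                        type = "design"))
  p <- c(`4` = 0.7)
  lp <- log_posterior(draw$params, draw$tau, p, latent_N = 5L, surveys = sv,
                      ls = b$ls, priors = b$priors,
                      config = list(dt_days = 14))
  expect_true(is.finite(lp))
  expect_identical(log_posterior(draw$params, -0.2, p, 5L, sv, b$ls,
                                 b$priors, list(dt_days = 14)), -Inf)
})

test_that("with perfect detection the count term vanishes at N = y", {
  b <- small_study_bits()
  set.seed(6)
  draw <- sample_prior(b$priors, b$sites)
  sv <- survey_data(counts = data.frame(row = 5, col = 6, year = 4, y = 3,
                                        type = "design"))
  cfg <- list(dt_days = 14)
  lp1 <- log_posterior(draw$params, 0.4, c(`4` = 1), latent_N = 3L,
                       surveys = sv, ls = b$ls, priors = b$priors, config = cfg)
  # independently recompute: prior + NB pmf at the (known) intensity
  ctx <- ecodiffuse:::build_model_ctx(sv, b$ls, draw$params$epicenters,
                                      b$priors, cfg)
  sol <- ecodiffuse:::solve_process(ctx, draw$params$beta, draw$params$alpha,
                                    draw$params$gamma,
                                    draw$params$epicenters$theta,
                                    draw$params$epicenters$kappa)
  lam <- ecodiffuse:::lambda_at_obs(ctx, sol)$counts
  want <- log_prior(draw$params, 0.4, c(`4` = 1), b$priors) +
    dnbinom(3, size = 0.4, mu = lam, log = TRUE) +
    dbeta(1, 1, 1, log = TRUE)
  expect_equal(lp1, want, tolerance = 1e-10)
})

test_that("the log-posterior profile peaks at the generating growth rate", {
  # well-identified small truth: likelihood at true gamma beats gamma +/- 0.1
  st <- generate_study(seed = 31, config = list(
    years = 0:12, design_years = c(4, 6), distribution_years = 3,
    photo_years = c(8, 10, 12)))
  tp <- st$truth$params
  ctx <- ecodiffuse:::build_model_ctx(st$surveys, st$landscape, st$epicenters,
                                      st$priors, list(dt_days = 7))
  Nmat <- st$truth$N
  cw <- cbind(ecodiffuse:::cell_id(st$surveys$counts$row,
                                   st$surveys$counts$col, st$landscape$n_rows),
              match(st$surveys$counts$year, st$truth$years))
  Ntrue <- sapply(seq_len(nrow(st$surveys$counts)),
                  function(i) Nmat[, , cw[i, 2]][cw[i, 1]])
  ll_gamma <- function(g) {
    sol <- ecodiffuse:::solve_process(ctx, tp$beta, tp$alpha, g,
                                      st$epicenters$theta, st$epicenters$kappa)
    lam <- ecodiffuse:::lambda_at_obs(ctx, sol)
    ecodiffuse:::nb_loglik(Ntrue, lam$counts, tp$tau) +
      ecodiffuse:::nb_loglik(ctx$trues$N, lam$trues, tp$tau)
  }
  expect_gt(ll_gamma(0.29), ll_gamma(0.19))
  expect_gt(ll_gamma(0.29), ll_gamma(0.39))
})

test_that("the conjugate detection update matches the closed form", {
  # one year, perfect bookkeeping: posterior is Beta(1 + s, 1 + f)
  y <- c(4, 0, 7); N <- c(6, 1, 9)
  isu <- data.frame(year = 4, initial = c(3, 8), final = c(5, 10))
  s <- sum(y) + sum(isu$initial)
  f <- sum(N - y) + sum(isu$final - isu$initial)
  post <- detection_posterior(s, f, prior = c(1, 1))
  expect_equal(unname(post), c(1 + s, 1 + f))
  # and the sampler's p draws concentrate there on a degenerate chain
  set.seed(8)
  draws <- rbeta(4000, post[1], post[2])
  expect_lt(abs(mean(draws) - post[1] / sum(post)), 0.01)
})

test_that("identical seeds give bit-identical chains, different seeds agree", {
  b <- small_study_bits()
  sv <- survey_data()
  cfg <- list(n_iter = 400, n_burn = 100)
  f1 <- fit_diffusion(sv, b$ls, b$sites, b$priors, cfg, seed = 9)
  f2 <- fit_diffusion(sv, b$ls, b$sites, b$priors, cfg, seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_diffusion(sv, b$ls, b$sites, b$priors,
                      list(n_iter = 3000, n_burn = 500), seed = 10)
  f4 <- fit_diffusion(sv, b$ls, b$sites, b$priors,
                      list(n_iter = 3000, n_burn = 500), seed = 11)
  # prior-only chains from different seeds agree within Monte-Carlo error
  expect_lt(abs(mean(f3$draws[, "gamma"]) - mean(f4$draws[, "gamma"])), 0.004)
})

test_that("a prior-posterior simulation cycle preserves the prior (Geweke-style)", {
  # successive-conditional simulator on a tiny model: draw params | data,
  # redraw data | params, repeat; the gamma marginal must stay at its prior
  ls <- flat_landscape(6, 6, seed = 41)
  sites <- data.frame(row = 3, col = 3, label = "E1")
  priors <- prior_spec(mu_theta = 50, sd_theta = 10,
                       mu_kappa = 1000, sd_kappa = 300)
  set.seed(12)
  draw <- sample_prior(priors, sites)
  st <- list(beta = draw$params$beta, alpha = draw$params$alpha,
             gamma = draw$params$gamma,
             theta = draw$params$epicenters$theta,
             kappa = draw$params$epicenters$kappa, tau = runif(1),
             p = runif(1))
  gammas <- numeric(150)
  cells <- data.frame(row = c(3, 4), col = c(4, 3))
  for (it in seq_len(150)) {
    # simulate data under the current parameters
    epi <- epicenters(sites$row, sites$col, st$theta, st$kappa)
    delta <- motility_field(ls, st$beta)
    K <- carrying_capacity_field(ls, st$alpha)
    hom <- homogenize(ls, delta, K, 1)
    ser <- propagate(initial_intensity(ls, epi), hom, delta, st$gamma,
                     years = 3, dt_days = 30)
    lam <- ser$lambda_fine[cbind(cells$row, cells$col, 1)]
    N <- sample_abundance(lam, st$tau)
    y <- sample_count(N, st$p)
    sv <- survey_data(counts = data.frame(row = cells$row, col = cells$col,
                                          year = 3, y = y, type = "design"))
    # a few posterior transitions from the current state
    fit <- fit_diffusion(sv, ls, sites, priors,
                         config = list(n_iter = 4, n_burn = 3, dt_days = 30,
                                       adapt = FALSE, store_lambda = FALSE,
                                       store_latent = FALSE),
                         seed = 1000 + it,
                         init = list(beta = st$beta, alpha = st$alpha,
                                     gamma = st$gamma, theta = st$theta,
                                     kappa = st$kappa, tau = st$tau,
                                     p = setNames(st$p, "3")))
    d <- fit$draws[1, ]
    st$beta <- unname(d[paste0("beta", 0:7)])
    st$alpha <- unname(d[paste0("alpha", 0:2)])
    st$gamma <- unname(d["gamma"]); st$tau <- unname(d["tau"])
    st$theta <- unname(d["theta_1"]); st$kappa <- unname(d["kappa_1"])
    st$p <- unname(d["p_3"])
    gammas[it] <- st$gamma
  }
  # wide tolerance: 150 correlated cycles of a N(0.25, 0.01) marginal
  expect_lt(abs(mean(gammas) - 0.25), 0.005)
  expect_lt(abs(sd(gammas) - 0.01), 0.005)
})

test_that("posterior summaries use the (lower, mean, upper) layout", {
  x <- matrix(rep(3.5, 50), ncol = 1, dimnames = list(NULL, "gamma"))
  s <- posterior_summary(x)
  expect_equal(names(s), c("parameter", "lower", "mean", "upper"))
  expect_equal(s$lower, 3.5); expect_equal(s$mean, 3.5); expect_equal(s$upper, 3.5)

  set.seed(13)
  z <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "z"))
  s2 <- posterior_summary(z, level = 0.90)
  expect_lt(abs(s2$lower + 1.645), 0.02)
  expect_lt(abs(s2$upper - 1.645), 0.02)
  expect_error(posterior_summary(matrix(numeric(0), 0, 1)), "no posterior")
})
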