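# Metropolis-within-Gibbs sampler for the hierarchical diffusion model.
#
# Blocks per iteration:
#   1-4. random-walk Metropolis on beta, alpha (natural scale) and gamma,
#        theta, kappa (log scale); every proposal triggers a fresh PDE solve
#        under the proposed process parameters.
#   5.   tau: logit-scale random walk (no solve; the intensity is cached).
#   6.   p_t: exact conjugate beta draw given latent N and ISU records.
#   7.   latent N: exact draw from the NB remainder conditional.
# Proposal scales are adapted by Robbins-Monro during burn-in, frozen after.

default_fit_config <- function() {
  list(epsilon = 1 / 5, dt_days = 14, t0 = 0,
       n_iter = 2500, n_burn = 800,
       track_years = NULL, store_lambda = TRUE, store_latent = TRUE,
       adapt = TRUE, target_accept = 0.234)
}

# precompute everything that does not change across MCMC proposals
build_model_ctx <- function(surveys, ls, sites, priors, config) {
  cfg <- utils::modifyList(default_fit_config(), config)
  w <- which(ls$water)
  n_water <- length(w)
  pos_w <- integer(ls$n_rows * ls$n_cols); pos_w[w] <- seq_len(n_water)

  X <- motility_design(ls)
  Xa <- capacity_design(ls)

  # coarse-grid geometry (independent of parameters)
  hom0 <- homogenize(ls, delta = matrix(1, ls$n_rows, ls$n_cols),
                     K = matrix(1, ls$n_rows, ls$n_cols), epsilon = cfg$epsilon)
  wc <- which(hom0$coarse_water)
  nc_w <- length(wc)
  pos_c <- integer(hom0$n_rows * hom0$n_cols); pos_c[wc] <- seq_len(nc_w)
  grp <- pos_c[hom0$fine_to_coarse[w]]
  n_per_coarse <- as.vector(rowsum(rep(1, n_water), grp))
  L <- grid_laplacian(hom0$coarse_water, hom0$coarse_cell_size,
                      weights = hom0$n_fine / hom0$block^2)

  rcw <- id_to_rowcol(w, ls$n_rows)
  d2 <- matrix(0, n_water, nrow(sites))
  for (j in seq_len(nrow(sites)))
    d2[, j] <- ((rcw[, 1] - sites$row[j])^2 +
                (rcw[, 2] - sites$col[j])^2) * ls$cell_size^2

  counts <- surveys$counts
  trues <- surveys$true_counts
  rel_years <- sort(unique(c(counts$year, trues$year, cfg$track_years))) - cfg$t0
  if (length(rel_years) && any(rel_years <= 0))
    stop("survey/track years must be after the initial year t0")
  out_steps <- years_to_steps(rel_years, cfg$dt_days)

  obs_pos <- function(df) {
    if (!nrow(df)) return(list(wpos = integer(), yidx = integer()))
    wp <- pos_w[cell_id(df$row, df$col, ls$n_rows)]
    if (any(wp == 0L)) stop("an observation lies on a non-water cell")
    list(wpos = wp, yidx = match(df$year - cfg$t0, rel_years))
  }
  oc <- obs_pos(counts)
  ot <- obs_pos(trues)

  list(cfg = cfg, ls = ls, sites = sites, priors = priors,
       w = w, n_water = n_water, X = X, Xa = Xa,
       hom = hom0, wc = wc, nc_w = nc_w, grp = grp,
       n_per_coarse = n_per_coarse, L = L, d2 = d2,
       rel_years = rel_years, out_steps = out_steps,
       counts = counts, trues = trues, isu = surveys$isu,
       photo_years = surveys$photo_years,
       counts_wpos = oc$wpos, counts_yidx = oc$yidx,
       trues_wpos = ot$wpos, trues_yidx = ot$yidx,
       n_obs = nrow(counts) + nrow(trues),
       dt = cfg$dt_days / 365)
}

# one PDE solve under proposed process parameters; NULL signals rejection.
# `prev` carries the cached pieces of the last accepted state so that blocks
# only rebuild what they touched: beta -> motility/operator, alpha ->
# reaction, theta/kappa -> initial condition, gamma -> nothing but the solve.
solve_process <- function(ctx, beta, alpha, gamma, theta, kappa,
                          prev = NULL, changed = c("beta", "alpha", "theta",
                                                   "kappa", "gamma")) {
  if (is.null(prev)) changed <- c("beta", "alpha", "theta", "kappa", "gamma")
  out <- prev

  if ("beta" %in% changed) {
    eta_d <- drop(ctx$X %*% beta)
    if (max(eta_d) > 600) return(NULL)
    out$delta <- exp(eta_d)
    out$inv_d <- rowsum(1 / out$delta, ctx$grp)[, 1]
    out$A <- methods::as(Matrix::Diagonal(x = ctx$n_per_coarse / out$inv_d) %*%
                           ctx$L, "dgCMatrix")
  }
  if (any(c("beta", "alpha") %in% changed)) {
    eta_k <- drop(ctx$Xa %*% alpha)
    if (max(eta_k) > 600) return(NULL)
    out$reaction <- rowsum(1 / (out$delta^2 * exp(eta_k)), ctx$grp)[, 1] /
      out$inv_d
  }
  if (any(c("theta", "kappa") %in% changed)) {
    lam0 <- numeric(ctx$n_water)
    for (j in seq_along(theta)) {
      kj <- exp(-ctx$d2[, j] / kappa[j]^2)
      s <- sum(kj)
      if (!is.finite(s) || s < .Machine$double.xmin) return(NULL)
      lam0 <- lam0 + theta[j] * kj / s
    }
    out$lam0 <- lam0
  }
  if (any(c("beta", "theta", "kappa") %in% changed)) {
    out$c0 <- rowsum(out$lam0, ctx$grp)[, 1] / out$inv_d
  }

  if (!length(ctx$out_steps)) {
    out$states <- matrix(numeric(0), ctx$nc_w, 0)
    return(out)
  }
  res <- tryCatch(
    rd_propagate_cpp(out$A, out$c0, out$reaction, gamma, ctx$dt,
                     ctx$out_steps),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  out$states <- res$states
  out
}

# intensities at the observation records, from a solve_process() result
lambda_at_obs <- function(ctx, sol) {
  lam_c <- sol$states[cbind(ctx$grp[ctx$counts_wpos], ctx$counts_yidx)] /
    sol$delta[ctx$counts_wpos]
  lam_t <- sol$states[cbind(ctx$grp[ctx$trues_wpos], ctx$trues_yidx)] /
    sol$delta[ctx$trues_wpos]
  list(counts = lam_c, trues = lam_t)
}

nb_loglik <- function(N, lam, tau) {
  if (any(!is.finite(lam))) return(-Inf)
  sum(dnbinom(N, size = tau, mu = lam, log = TRUE))
}

#' Joint log-posterior density
#'
#' Evaluates the unnormalised hierarchical posterior: binomial detection
#' terms for the counts, NB abundance terms at the latent and observed true
#' abundances (with the intensity surface obtained by a fresh PDE solve under
#' `params`), ISU binomial terms, and all log-priors.  Returns `-Inf`
#' outside the prior support or when the solver fails.
#'
#' @param params an [process_params()] object.
#' @param tau NB dispersion.
#' @param p named vector of detection probabilities (names are survey years).
#' @param latent_N integer vector of latent abundances, one per row of
#'   `surveys$counts`.
#' @param surveys an [survey_data()] object.
#' @param ls an [landscape()].
#' @param priors an [prior_spec()].
#' @param config solver configuration; see [fit_diffusion()].
#' @return Log-posterior value.
#' @export
log_posterior <- function(params, tau, p, latent_N, surveys, ls, priors,
                          config = list()) {
  lp <- log_prior(params, tau, p, priors)
  if (!is.finite(lp)) return(lp)
  sites <- params$epicenters
  ctx <- build_model_ctx(surveys, ls, sites, priors, config)
  if (ctx$n_obs == 0L && !nrow(ctx$isu)) return(lp)
  sol <- solve_process(ctx, params$beta, params$alpha, params$gamma,
                       sites$theta, sites$kappa)
  if (is.null(sol)) return(-Inf)
  lam <- lambda_at_obs(ctx, sol)
  ll <- nb_loglik(latent_N, lam$counts, tau) +
    nb_loglik(ctx$trues$N, lam$trues, tau)
  if (nrow(ctx$counts)) {
    pv <- p[as.character(ctx$counts$year)]
    ll <- ll + sum(dbinom(ctx$counts$y, latent_N, pv, log = TRUE))
  }
  if (nrow(ctx$isu)) {
    for (yr in unique(ctx$isu$year)) {
      sel <- ctx$isu$year == yr
      ll <- ll + suppressMessages(isu_loglik(ctx$isu[sel, ], p[as.character(yr)]))
    }
  }
  lp + ll
}

init_state <- function(ctx, init) {
  pr <- ctx$priors
  # domain-scale heuristics for the intercepts; everything else starts at
  # prior means so chains do not depend on the data twice
  extent <- max(ctx$ls$n_rows, ctx$ls$n_cols) * ctx$ls$cell_size
  span <- max(1, diff(range(c(ctx$rel_years, 1))))
  beta <- c(log(extent^2 / span), rep(0, 7))
  alpha <- c(0, 0, 0)
  if (nrow(ctx$counts)) {
    dens <- max(tapply(ctx$counts$y, ctx$counts$year, mean))
    alpha[1] <- log(dens / 0.7 + 0.1)
  }
  st <- list(beta = beta, alpha = alpha, gamma = pr$gamma_mean,
             tau = 0.1, theta = pr$mu_theta, kappa = pr$mu_kappa,
             p = setNames(rep(0.7, length(unique(c(ctx$counts$year,
                                                   ctx$trues$year,
                                                   ctx$isu$year)))),
                          sort(unique(c(ctx$counts$year, ctx$trues$year,
                                        ctx$isu$year)))))
  if (!is.null(init)) st <- utils::modifyList(st, init)
  st
}

prior_terms <- function(ctx, st) {
  pr <- ctx$priors
  list(gamma = dnorm(st$gamma, pr$gamma_mean, pr$gamma_sd, log = TRUE) +
         (if (st$gamma <= 0) -Inf else 0),
       beta = sum(dnorm(st$beta, 0, pr$beta_sd, log = TRUE)),
       alpha = sum(dnorm(st$alpha, 0, pr$alpha_sd, log = TRUE)),
       theta = sum(dhalfnorm_log(st$theta, pr$mu_theta, pr$sd_theta)),
       kappa = sum(dhalfnorm_log(st$kappa, pr$mu_kappa, pr$sd_kappa)),
       # uniform(0,1) prior: constant inside the support, which the logit
       # random walk cannot leave
       tau = if (st$tau > 0 && st$tau < 1) 0 else -Inf)
}

#' Fit the hierarchical diffusion model by MCMC
#'
#' Metropolis-within-Gibbs sampling of the joint posterior over the process
#' parameters (`beta`, `alpha`, `gamma`, epicenter `theta`/`kappa`), the
#' observation parameters (`tau`, yearly detection `p_t`), and the latent
#' true abundances at counted cells.  Detection probabilities are updated by
#' exact conjugate beta draws; latent abundances by exact NB-remainder
#' draws; everything else by adaptive random-walk Metropolis with one PDE
#' solve per process-block proposal.
#'
#' @param surveys an [survey_data()] object.
#' @param ls an [landscape()] with standardized covariates.
#' @param sites data frame of epicenter locations (`row`, `col`, optionally
#'   `label`); locations are treated as known.
#' @param priors an [prior_spec()] whose `photo_years` mark the years that
#'   get the informative photographic detection prior.
#' @param config named list overriding the defaults: `epsilon` (coarse-scale
#'   ratio, default 1/5), `dt_days` (solver step, default 14), `t0` (year of
#'   the initial condition, default 0), `n_iter`, `n_burn`, `track_years`
#'   (years at which to accumulate total-abundance draws), `store_lambda`,
#'   `store_latent`, `adapt`, `target_accept`.
#' @param seed integer seed; chain `k` uses `seed + k - 1`.
#' @param n_chains number of independently seeded chains.
#' @param init optional named list of starting values.
#' @return An object of class `eco_fit` with elements `draws` (matrix of
#'   kept parameter draws, chains stacked), `chain` (chain index per row),
#'   `accept` (acceptance rates per block), `latent_N`, `lambda_counts`,
#'   `abundance` (total-abundance draws at `track_years`), plus the inputs
#'   needed by downstream summaries.
#' @export
fit_diffusion <- function(surveys, ls, sites, priors, config = list(),
                          seed = 1, n_chains = 1, init = NULL) {
  ctx <- build_model_ctx(surveys, ls, sites, priors, config)
  cfg <- ctx$cfg
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    chains[[ch]] <- run_one_chain(ctx, init)
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  structure(list(
    draws = draws,
    chain = rep(seq_len(n_chains), each = nrow(chains[[1]]$draws)),
    accept = lapply(chains, `[[`, "accept"),
    latent_N = do.call(rbind, lapply(chains, `[[`, "latent_N")),
    lambda_counts = do.call(rbind, lapply(chains, `[[`, "lambda_counts")),
    abundance = do.call(rbind, lapply(chains, `[[`, "abundance")),
    scales = lapply(chains, `[[`, "scales"),
    surveys = surveys, sites = sites, priors = priors, config = cfg,
    landscape = ls, n_chains = n_chains, seed = seed
  ), class = "eco_fit")
}

run_one_chain <- function(ctx, init) {
  cfg <- ctx$cfg
  pr <- ctx$priors
  st <- init_state(ctx, init)
  J <- pr$J
  have_obs <- ctx$n_obs > 0L

  sol <- solve_process(ctx, st$beta, st$alpha, st$gamma, st$theta, st$kappa)
  if (is.null(sol)) stop("PDE solve failed at the initial state")
  lam <- if (have_obs) lambda_at_obs(ctx, sol) else list(counts = numeric(0), trues = numeric(0))
  N_lat <- if (nrow(ctx$counts)) {
    pv <- st$p[as.character(ctx$counts$year)]
    draw_latent_N(ctx$counts$y, pmax(lam$counts, 1e-10), st$tau, pv)
  } else integer(0)

  cur_ll <- function(lamv, tau) {
    if (!have_obs) return(0)
    nb_loglik(N_lat, lamv$counts, tau) + nb_loglik(ctx$trues$N, lamv$trues, tau)
  }
  ll <- cur_ll(lam, st$tau)
  lp <- prior_terms(ctx, st)

  blocks <- c("beta", "alpha", "gamma", "theta", "kappa", "tau")
  lsc <- c(beta = log(0.05), alpha = log(0.08), gamma = log(0.02),
           theta = log(0.05), kappa = log(0.08), tau = log(0.5))
  acc_n <- setNames(numeric(length(blocks)), blocks)
  prop_n <- setNames(numeric(length(blocks)), blocks)

  n_keep <- cfg$n_iter - cfg$n_burn
  par_names <- c("gamma", paste0("beta", 0:7), paste0("alpha", 0:2), "tau",
                 paste0("theta_", seq_len(J)), paste0("kappa_", seq_len(J)),
                 if (length(st$p)) paste0("p_", names(st$p)))
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  latent_store <- if (cfg$store_latent && nrow(ctx$counts))
    matrix(NA_integer_, n_keep, nrow(ctx$counts)) else NULL
  lambda_store <- if (cfg$store_lambda && nrow(ctx$counts))
    matrix(NA_real_, n_keep, nrow(ctx$counts)) else NULL
  track_idx <- if (length(cfg$track_years))
    match(cfg$track_years - cfg$t0, ctx$rel_years) else integer(0)
  ab_store <- if (length(track_idx))
    matrix(NA_real_, n_keep, length(track_idx),
           dimnames = list(NULL, cfg$track_years)) else NULL

  mh_update <- function(block, proposer) {
    prop_n[block] <<- prop_n[block] + 1
    cand <- proposer(st)
    if (is.null(cand)) return(invisible(NULL))
    st2 <- cand$state
    lp2 <- prior_terms(ctx, st2)
    logr <- lp2[[block]] - lp[[block]] + cand$lqratio
    sol2 <- NULL; lam2 <- lam; ll2 <- ll
    if (is.finite(logr)) {
      if (cand$needs_solve && have_obs) {
        sol2 <- solve_process(ctx, st2$beta, st2$alpha, st2$gamma,
                              st2$theta, st2$kappa, prev = sol,
                              changed = block)
        if (is.null(sol2)) logr <- -Inf
        else {
          lam2 <- lambda_at_obs(ctx, sol2)
          ll2 <- cur_ll(lam2, st2$tau)
          logr <- logr + ll2 - ll
        }
      } else if (!cand$needs_solve) {
        ll2 <- cur_ll(lam, st2$tau)
        logr <- logr + ll2 - ll
      }
    }
    alpha_p <- if (is.finite(logr)) min(1, exp(logr)) else 0
    if (runif(1) < alpha_p) {
      st <<- st2; ll <<- ll2; lp[[block]] <<- lp2[[block]]
      if (!is.null(sol2)) { sol <<- sol2; lam <<- lam2 }
      acc_n[block] <<- acc_n[block] + 1
    }
    if (cfg$adapt && iter <= cfg$n_burn) {
      step <- min(0.25, 2 / sqrt(iter))
      lsc[block] <<- lsc[block] + step * (alpha_p - cfg$target_accept)
    }
    invisible(NULL)
  }

  for (iter in seq_len(cfg$n_iter)) {
    mh_update("beta", function(s) {
      s$beta <- s$beta + exp(lsc["beta"]) * rnorm(8)
      list(state = s, lqratio = 0, needs_solve = TRUE)
    })
    mh_update("alpha", function(s) {
      s$alpha <- s$alpha + exp(lsc["alpha"]) * rnorm(3)
      list(state = s, lqratio = 0, needs_solve = TRUE)
    })
    mh_update("gamma", function(s) {
      z <- exp(lsc["gamma"]) * rnorm(1)
      s$gamma <- s$gamma * exp(z)
      list(state = s, lqratio = z, needs_solve = TRUE)
    })
    mh_update("theta", function(s) {
      z <- exp(lsc["theta"]) * rnorm(J)
      s$theta <- s$theta * exp(z)
      list(state = s, lqratio = sum(z), needs_solve = TRUE)
    })
    mh_update("kappa", function(s) {
      z <- exp(lsc["kappa"]) * rnorm(J)
      s$kappa <- s$kappa * exp(z)
      list(state = s, lqratio = sum(z), needs_solve = TRUE)
    })
    mh_update("tau", function(s) {
      zl <- qlogis(s$tau) + exp(lsc["tau"]) * rnorm(1)
      t2 <- plogis(zl)
      s$tau <- t2
      # Jacobian of the logit transform
      list(state = s, lqratio = log(t2 * (1 - t2)) -
             log(st$tau * (1 - st$tau)), needs_solve = FALSE)
    })

    # conjugate detection update
    if (length(st$p)) {
      for (ynm in names(st$p)) {
        yr <- as.numeric(ynm)
        succ <- fail <- 0
        selc <- which(ctx$counts$year == yr)
        if (length(selc)) {
          succ <- succ + sum(ctx$counts$y[selc])
          fail <- fail + sum(N_lat[selc] - ctx$counts$y[selc])
        }
        seli <- ctx$isu$year == yr & ctx$isu$final > 0
        if (any(seli)) {
          succ <- succ + sum(ctx$isu$initial[seli])
          fail <- fail + sum(ctx$isu$final[seli] - ctx$isu$initial[seli])
        }
        prior_ab <- if (yr %in% ctx$photo_years) pr$p_photo else pr$p_default
        st$p[ynm] <- rbeta(1, prior_ab[1] + succ, prior_ab[2] + fail)
      }
    }

    # exact latent-abundance draw
    if (nrow(ctx$counts)) {
      pv <- st$p[as.character(ctx$counts$year)]
      N_lat <- draw_latent_N(ctx$counts$y, pmax(lam$counts, 1e-12), st$tau, pv)
      ll <- cur_ll(lam, st$tau)
    }

    if (iter > cfg$n_burn) {
      k <- iter - cfg$n_burn
      draws[k, ] <- c(st$gamma, st$beta, st$alpha, st$tau, st$theta, st$kappa,
                      if (length(st$p)) st$p)
      if (!is.null(latent_store)) latent_store[k, ] <- N_lat
      if (!is.null(lambda_store)) lambda_store[k, ] <- lam$counts
      if (!is.null(ab_store)) {
        for (m in seq_along(track_idx)) {
          yi <- track_idx[m]
          lam_full <- sol$states[ctx$grp, yi] / sol$delta
          yr_abs <- cfg$track_years[m]
          obs_cells <- c(ctx$counts_wpos[ctx$counts$year == yr_abs],
                         ctx$trues_wpos[ctx$trues$year == yr_abs])
          tot <- 0
          selt <- ctx$trues$year == yr_abs
          if (any(selt)) tot <- tot + sum(ctx$trues$N[selt])
          selc <- ctx$counts$year == yr_abs
          if (any(selc)) tot <- tot + sum(N_lat[selc])
          unobs <- if (length(obs_cells)) setdiff(seq_len(ctx$n_water), obs_cells)
                   else seq_len(ctx$n_water)
          tot <- tot + sum(rnbinom(length(unobs), size = st$tau,
                                   mu = lam_full[unobs]))
          ab_store[k, m] <- tot
        }
      }
    }
  }

  list(draws = draws, accept = acc_n / pmax(prop_n, 1),
       latent_N = latent_store, lambda_counts = lambda_store,
       abundance = ab_store, scales = exp(lsc))
}

#' @method print eco_fit
#' @export
print.eco_fit <- function(x, ...) {
  cat(sprintf("<eco_fit> %d kept draws x %d parameters (%d chain(s))\n",
              nrow(x$draws), ncol(x$draws), x$n_chains))
  cat("block acceptance rates (chain 1):\n")
  print(round(x$accept[[1]], 3))
  invisible(x)
}

#' Posterior summaries
#'
#' Posterior mean and equal-tailed credible interval for every sampled
#' parameter, in the column order (lower bound, mean, upper bound).
#'
#' @param fit an `eco_fit` from [fit_diffusion()], or a draws matrix.
#' @param level credible level (default 0.90).
#' @return Data frame with columns `parameter`, `lower`, `mean`, `upper`.
#' @export
posterior_summary <- function(fit, level = 0.90) {
  draws <- if (inherits(fit, "eco_fit")) fit$draws else fit
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) == 0L) stop("no posterior draws to summarise")
  a <- (1 - level) / 2
  data.frame(
    parameter = colnames(draws),
    lower = apply(draws, 2, quantile, probs = a, names = FALSE),
    mean = colMeans(draws),
    upper = apply(draws, 2, quantile, probs = 1 - a, names = FALSE),
    row.names = NULL
  )
}

# effective sample size via initial positive sequence of autocorrelations
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}
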