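#' Prior specification for the hierarchical diffusion model
#'
#' Defaults follow the priors used for the Southeast Alaska sea otter
#' analysis: an informative normal prior on the intrinsic growth rate,
#' weakly informative normals on the log-linear coefficients, half-normal
#' (positive-truncated normal) priors on the epicenter scales informed by
#' translocation records, a uniform prior on the NB dispersion, and flat
#' beta priors on detection except in photographic-survey years, which
#' receive the informative [photo_detection_prior()].
#'
#' `mu_kappa`/`sd_kappa` are in metres (the package's internal length unit);
#' the default values correspond to 10, 2, ... km.
#'
#' @param gamma_mean,gamma_sd normal prior on `gamma` (per year).
#' @param beta_sd,alpha_sd sd of iid mean-zero normal priors on `beta`,
#'   `alpha`.
#' @param mu_theta,sd_theta half-normal hyperparameters for the epicenter
#'   abundance scales (length J).
#' @param mu_kappa,sd_kappa half-normal hyperparameters for the epicenter
#'   dispersal scales, metres (length J).
#' @param p_default beta prior `c(a, b)` for detection in ordinary years.
#' @param p_photo beta prior for photographic-survey years.
#' @param photo_years years that receive `p_photo`.
#' @return An object of class `eco_priors`.
#' @export
prior_spec <- function(gamma_mean = 0.25, gamma_sd = 0.01,
                       beta_sd = 10, alpha_sd = 10,
                       mu_theta = c(100, 10, 10, 100, 10, 100, 100),
                       sd_theta = c(20, 1, 1, 20, 1, 20, 20),
                       mu_kappa = 1000 * c(10, 2, 10, 10, 2, 10, 10),
                       sd_kappa = 1000 * c(3, 1, 3, 3, 1, 3, 3),
                       p_default = c(1, 1),
                       p_photo = photo_detection_prior(),
                       photo_years = integer()) {
  J <- length(mu_theta)
  if (length(sd_theta) != J || length(mu_kappa) != J || length(sd_kappa) != J)
    stop("theta/kappa hyperparameter vectors must share one length J")
  stopifnot(all(c(gamma_sd, beta_sd, alpha_sd, sd_theta, sd_kappa) > 0))
  structure(list(gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 beta_sd = beta_sd, alpha_sd = alpha_sd,
                 mu_theta = mu_theta, sd_theta = sd_theta,
                 mu_kappa = mu_kappa, sd_kappa = sd_kappa,
                 p_default = p_default, p_photo = p_photo,
                 photo_years = photo_years, J = J),
            class = "eco_priors")
}

# log density of the positive-truncated Normal(mu, sd^2)
dhalfnorm_log <- function(x, mu, sd) {
  ifelse(x > 0,
         dnorm(x, mu, sd, log = TRUE) - pnorm(0, mu, sd, lower.tail = FALSE,
                                              log.p = TRUE),
         -Inf)
}

rhalfnorm <- function(n, mu, sd) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mu[min(i, length(mu))], sd[min(i, length(sd))])
      if (x > 0) { out[i] <- x; break }
    }
  }
  out
}

#' Joint log-prior density
#'
#' @param params an [process_params()] object (theta/kappa read from its
#'   epicenters).
#' @param tau NB dispersion in (0, 1).
#' @param p optional named vector of detection probabilities by year.
#' @param priors an [prior_spec()].
#' @return Log prior density (`-Inf` outside the support).
#' @export
log_prior <- function(params, tau, p = NULL, priors) {
  if (tau <= 0 || tau >= 1) return(-Inf)
  if (params$gamma <= 0) return(-Inf)
  th <- params$epicenters$theta
  ka <- params$epicenters$kappa
  if (length(th) != priors$J)
    stop("number of epicenters does not match the prior specification")
  lp <- dnorm(params$gamma, priors$gamma_mean, priors$gamma_sd, log = TRUE) +
    sum(dnorm(params$beta, 0, priors$beta_sd, log = TRUE)) +
    sum(dnorm(params$alpha, 0, priors$alpha_sd, log = TRUE)) +
    sum(dhalfnorm_log(th, priors$mu_theta, priors$sd_theta)) +
    sum(dhalfnorm_log(ka, priors$mu_kappa, priors$sd_kappa)) +
    dunif(tau, 0, 1, log = TRUE)
  if (!is.null(p)) {
    yrs <- as.numeric(names(p))
    for (i in seq_along(p)) {
      pr <- if (yrs[i] %in% priors$photo_years) priors$p_photo else priors$p_default
      lp <- lp + dbeta(p[i], pr[1], pr[2], log = TRUE)
    }
  }
  unname(lp)
}

#' Draw process and observation parameters from the prior
#'
#' @param priors an [prior_spec()].
#' @param epicenter_sites data frame with `row`, `col` (and optionally
#'   `label`) giving the fixed epicenter locations.
#' @return A list with an `eco_params` object and `tau`.
#' @export
sample_prior <- function(priors, epicenter_sites) {
  J <- priors$J
  if (nrow(epicenter_sites) != J)
    stop("epicenter_sites must have J rows")
  th <- rhalfnorm(J, priors$mu_theta, priors$sd_theta)
  ka <- rhalfnorm(J, priors$mu_kappa, priors$sd_kappa)
  gamma <- abs(rnorm(1, priors$gamma_mean, priors$gamma_sd))
  epi <- epicenters(epicenter_sites$row, epicenter_sites$col, th, ka,
                    label = epicenter_sites$label)
  list(params = process_params(beta = rnorm(8, 0, priors$beta_sd),
                               alpha = rnorm(3, 0, priors$alpha_sd),
                               gamma = gamma, epicenters = epi),
       tau = runif(1))
}
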