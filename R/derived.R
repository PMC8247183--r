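#' Wave-front regime of an epicenter
#'
#' The Gaussian initial condition of epicenter `j` has front steepness
#' `1/kappa_j^2`, and the shape of a propagating front is conserved.  The
#' front is *steep* when `1/kappa^2 > sqrt(gamma/delta_bar)` — the spread
#' rate then converges to the minimum `2 sqrt(delta_bar gamma)` — and *flat*
#' otherwise, in which case the asymptotic rate is the larger
#' `delta_bar/kappa^2 + gamma kappa^2`.  Equality (where the two formulas
#' coincide) is classified as steep.
#'
#' @param kappa epicenter dispersal scale(s), metres.
#' @param gamma intrinsic growth rate per year.
#' @param delta_bar reference homogenized motility (m^2/yr), e.g. the value
#'   of the coarse cell containing the epicenter.
#' @return Character vector `"steep"`/`"flat"`.
#' @export
front_regime <- function(kappa, gamma, delta_bar) {
  ifelse(1 / kappa^2 >= sqrt(gamma / delta_bar), "steep", "flat")
}

#' Asymptotic spread-rate formulas
#'
#' `spread_rate_steep()` is the minimum (Fisher) rate
#' `2 sqrt(delta_bar gamma)`; `spread_rate_flat()` is
#' `delta_bar/kappa^2 + gamma kappa^2`, which the flat rate reduces to the
#' steep rate at `kappa^2 = sqrt(delta_bar/gamma)`.  Inputs in m^2/yr, per
#' yr and m; output in km/yr.
#'
#' @param delta_bar homogenized motility (m^2/yr).
#' @param gamma growth rate per year.
#' @param kappa dispersal scale, metres.
#' @return Spread rate(s) in km/yr.
#' @export
spread_rate_steep <- function(delta_bar, gamma) {
  2 * sqrt(delta_bar * gamma) / 1000
}

#' @rdname spread_rate_steep
#' @export
spread_rate_flat <- function(delta_bar, gamma, kappa) {
  (delta_bar / kappa^2 + gamma * kappa^2) / 1000
}

#' Map of asymptotic spread rates
#'
#' Evaluates the asymptotic colonisation rate on the homogenized grid.  The
#' regime of each epicenter is assessed at the homogenized motility of the
#' coarse cell containing it; when every epicenter front is steep (the usual
#' case for point-like releases) the map is `2 sqrt(delta_bar(s) gamma)`.
#' If any front is flat, a separate flat-front map
#' `delta_bar(s)/kappa_j^2 + gamma kappa_j^2` is returned for each flat
#' epicenter.
#'
#' @param hom an [homogenize()] grid.
#' @param gamma intrinsic growth rate per year (> 0).
#' @param sites optional [epicenters()] data frame (with `kappa`); when
#'   omitted the steep-front map is returned without regime assessment.
#' @return A list of class `eco_spreadrates`: `rates` (coarse matrix,
#'   km/yr, steep-front), `regimes` (per epicenter), `flat_maps` (named
#'   list, possibly empty), and `summary` (min/median/max over coarse water
#'   cells).
#' @export
spread_rate_map <- function(hom, gamma, sites = NULL) {
  stopifnot(inherits(hom, "eco_homgrid"))
  if (gamma <= 0) stop("'gamma' must be positive for a spread-rate map")
  rates <- matrix(NA_real_, hom$n_rows, hom$n_cols)
  wc <- hom$coarse_water
  rates[wc] <- spread_rate_steep(hom$delta_bar[wc], gamma)

  regimes <- NULL
  flat_maps <- list()
  if (!is.null(sites)) {
    cr <- (sites$row - 1L) %/% hom$block + 1L
    cc <- (sites$col - 1L) %/% hom$block + 1L
    db_at <- hom$delta_bar[cbind(cr, cc)]
    regimes <- data.frame(label = sites$label, kappa = sites$kappa,
                          delta_bar = db_at,
                          regime = front_regime(sites$kappa, gamma, db_at))
    for (j in which(regimes$regime == "flat")) {
      fm <- matrix(NA_real_, hom$n_rows, hom$n_cols)
      fm[wc] <- spread_rate_flat(hom$delta_bar[wc], gamma, sites$kappa[j])
      flat_maps[[sites$label[j]]] <- fm
    }
  }
  v <- rates[wc]
  structure(list(rates = rates, regimes = regimes, flat_maps = flat_maps,
                 summary = c(min = min(v), median = median(v), max = max(v)),
                 gamma = gamma),
            class = "eco_spreadrates")
}

#' @method print eco_spreadrates
#' @export
print.eco_spreadrates <- function(x, ...) {
  cat(sprintf("<eco_spreadrates> km/yr over coarse water: min %.2f, median %.2f, max %.2f\n",
              x$summary["min"], x$summary["median"], x$summary["max"]))
  if (!is.null(x$regimes)) print(x$regimes)
  invisible(x)
}

#' Total-abundance time series
#'
#' Reconstructs total abundance per tracked year from the MCMC output: for
#' each posterior draw, the sum of (i) observed true abundances, (ii) the
#' latent-abundance draws at counted cells, and (iii) fresh NB draws at
#' cells without data — accumulated during sampling (see
#' `config$track_years` of [fit_diffusion()]).
#'
#' @param fit an `eco_fit` with tracked abundance.
#' @param level credible level for the intervals (default 0.95).
#' @return Data frame with columns `year`, `mean`, `lower`, `upper`.
#' @export
total_abundance <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "eco_fit"))
  if (is.null(fit$abundance))
    stop("fit was run without config$track_years; no abundance draws stored")
  a <- (1 - level) / 2
  data.frame(
    year = as.numeric(colnames(fit$abundance)),
    mean = colMeans(fit$abundance),
    # the NB tail at small dispersion makes the draws right-skewed, so the
    # median is reported alongside the mean
    median = apply(fit$abundance, 2, median),
    lower = apply(fit$abundance, 2, quantile, probs = a, names = FALSE),
    upper = apply(fit$abundance, 2, quantile, probs = 1 - a, names = FALSE)
  )
}

#' Posterior predictive check of the observed counts
#'
#' For each observed count and each posterior draw, simulates a replicate
#' observation `y_rep ~ Binomial(N_rep, p_t)` with
#' `N_rep ~ NB(lambda, tau)` from that draw, and reports how many observed
#' counts fall outside their equal-tailed predictive interval.  On data
#' simulated from the model itself the outside fraction should be at or
#' below the nominal level (discreteness makes the intervals conservative).
#'
#' @param fit an `eco_fit` run with `store_lambda = TRUE`.
#' @param level interval level (default 0.95).
#' @return List of class `eco_ppc`: `n_outside`, `n_total`, `fraction`, and
#'   a per-observation data frame with the interval bounds.
#' @export
posterior_predictive_check <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "eco_fit"))
  if (is.null(fit$lambda_counts))
    stop("fit was run with store_lambda = FALSE")
  counts <- fit$surveys$counts
  K <- nrow(fit$draws)
  if (K < 100)
    warning("fewer than 100 posterior draws; predictive interval endpoints are unstable")
  a <- (1 - level) / 2
  tau <- fit$draws[, "tau"]
  lo <- hi <- numeric(nrow(counts))
  outside <- logical(nrow(counts))
  pmat <- fit$draws[, paste0("p_", counts$year), drop = FALSE]
  for (i in seq_len(nrow(counts))) {
    Nrep <- rnbinom(K, size = tau, mu = fit$lambda_counts[, i])
    yrep <- rbinom(K, size = Nrep, prob = pmat[, i])
    qq <- quantile(yrep, c(a, 1 - a), names = FALSE, type = 1)
    lo[i] <- qq[1]; hi[i] <- qq[2]
    outside[i] <- counts$y[i] < qq[1] || counts$y[i] > qq[2]
  }
  structure(list(n_outside = sum(outside), n_total = nrow(counts),
                 fraction = mean(outside),
                 table = data.frame(counts, lower = lo, upper = hi,
                                    outside = outside)),
            class = "eco_ppc")
}

#' @method print eco_ppc
#' @export
print.eco_ppc <- function(x, ...) {
  cat(sprintf("<eco_ppc> %d of %d observed counts outside their %s predictive intervals (%.2f%%)\n",
              x$n_outside, x$n_total, "95%", 100 * x$fraction))
  invisible(x)
}
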