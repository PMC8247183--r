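#' Process-model parameters
#'
#' Bundles the parameters of the logistic ecological diffusion process:
#' log-motility coefficients `beta` (length 8: intercept, depth indicator,
#' distance to shore, slope x depth, shoreline complexity, town distance,
#' protected-bay and fisheries-closure indicators), log-carrying-capacity
#' coefficients `alpha` (length 3: intercept and the two management
#' indicators), the intrinsic growth rate `gamma` (per year), and the
#' [epicenters()] with their `theta`/`kappa` initial-condition parameters.
#'
#' Units: motility `delta = exp(X beta)` is in m^2/yr, carrying capacity
#' `K = exp(X alpha)` in individuals per fine grid cell, `gamma` per year.
#'
#' @param beta numeric vector of 8 log-motility coefficients.
#' @param alpha numeric vector of 3 log-carrying-capacity coefficients.
#' @param gamma intrinsic growth rate per year (> 0 for growth; 0 allowed for
#'   pure diffusion).
#' @param epicenters an [epicenters()] data frame.
#' @return An object of class `eco_params`.
#' @export
process_params <- function(beta, alpha, gamma, epicenters) {
  if (length(beta) != 8) stop("'beta' must have length 8")
  if (length(alpha) != 3) stop("'alpha' must have length 3")
  if (!all(is.finite(c(beta, alpha, gamma)))) stop("parameters must be finite")
  if (gamma < 0) stop("'gamma' must be non-negative")
  if (is.null(epicenters) || nrow(epicenters) == 0L) stop("need at least one epicenter")
  structure(list(beta = beta, alpha = alpha, gamma = gamma,
                 epicenters = epicenters), class = "eco_params")
}

field_from_design <- function(ls, X, coef, what) {
  eta <- drop(X %*% coef)
  if (any(eta > 700)) {
    i <- which.max(eta)
    stop(sprintf("%s overflow: linear predictor %.1f at water cell %d", what, eta[i], i))
  }
  out <- matrix(NA_real_, ls$n_rows, ls$n_cols)
  out[ls$water] <- exp(eta)
  out
}

#' Motility field
#'
#' Evaluates the log-linear motility (ecological diffusion coefficient)
#' `log(delta) = b0 + b1 depth + b2 dist + b3 (slope x depth) + b4 shore +
#' b5 town + b6 glba + b7 fish` on water cells.  Motility is inversely
#' proportional to residence time: animals linger where `delta` is low.
#'
#' @param ls a [landscape()] with standardized covariates.
#' @param beta length-8 coefficient vector.
#' @return Matrix of `delta` in m^2/yr (`NA` on land).
#' @export
motility_field <- function(ls, beta) {
  if (length(beta) != 8) stop("'beta' must have length 8")
  field_from_design(ls, motility_design(ls), beta, "motility")
}

#' Carrying-capacity field
#'
#' `log(K) = a0 + a1 glba + a2 fish` on water cells: local density
#' dependence, in individuals per fine grid cell.
#'
#' @param ls a [landscape()].
#' @param alpha length-3 coefficient vector.
#' @return Matrix of `K > 0` (`NA` on land).
#' @export
carrying_capacity_field <- function(ls, alpha) {
  if (length(alpha) != 3) stop("'alpha' must have length 3")
  field_from_design(ls, capacity_design(ls), alpha, "carrying capacity")
}

#' Regional nominal carrying capacity
#'
#' The integral of `K` over the water domain: the number of individuals the
#' region could nominally sustain.
#'
#' @param ls a [landscape()].
#' @param K carrying-capacity matrix from [carrying_capacity_field()]
#'   (individuals per cell).
#' @return A single number (individuals).
#' @export
nominal_carrying_capacity <- function(ls, K) {
  sum(K[ls$water])
}

# Gaussian kernel of one epicenter over the water cells; distances in metres
epicenter_kernel <- function(ls, row, col, kappa) {
  w <- which(ls$water)
  rc <- id_to_rowcol(w, ls$n_rows)
  d2 <- ((rc[, 1] - row)^2 + (rc[, 2] - col)^2) * ls$cell_size^2
  exp(-d2 / kappa^2)
}

#' Initial intensity surface from reintroduction epicenters
#'
#' Sum of scaled Gaussian kernels, one per epicenter, each normalised by its
#' discrete integral over the water domain so that epicenter `j` contributes
#' exactly `theta_j` individuals: the total initial abundance is
#' `sum(theta)`.
#'
#' @param ls a [landscape()].
#' @param epi an [epicenters()] data frame.
#' @return Matrix of expected individuals per cell (0 on land).
#' @export
initial_intensity <- function(ls, epi) {
  lam <- matrix(0, ls$n_rows, ls$n_cols)
  w <- ls$water
  for (j in seq_len(nrow(epi))) {
    k <- epicenter_kernel(ls, epi$row[j], epi$col[j], epi$kappa[j])
    Z <- sum(k)
    if (!is.finite(Z) || Z < .Machine$double.xmin)
      stop(sprintf("epicenter '%s': kernel is numerically zero over the water domain (kappa much smaller than the cell size?)",
                   epi$label[j]))
    lam[w] <- lam[w] + epi$theta[j] * k / Z
  }
  lam
}

# discrete quadrature of one epicenter kernel over water, in m^2
# (matches the closed-form pi*kappa^2 on open water when kappa >> cell size)
kernel_mass <- function(ls, row, col, kappa) {
  sum(epicenter_kernel(ls, row, col, kappa)) * ls$area_per_cell
}

#' Homogenize motility and density dependence to a coarse grid
#'
#' Analytic upscaling of the ecological diffusion operator: under the change
#' of variables `c = delta * lambda`, the fine-scale PDE is approximated on a
#' coarse grid (cells `1/epsilon` times larger) by
#' `dc/dt = delta_bar Lap(c) + gamma c (1 - c * r)`, where per coarse cell
#' `delta_bar` is the harmonic mean of `delta` over its fine water cells and
#' the reaction coefficient `r = mean(1/(delta^2 K)) / mean(1/delta)` is the
#' cell average of the logistic term under the `lambda = c/delta` downscaling
#' ansatz.  (`r` reduces to the simpler `mean(1/(delta K))` when `delta` is
#' constant within a coarse cell; the general form makes the homogenized
#' equilibrium agree with the volume-averaged fine-scale equilibrium, which
#' the fine-solver oracle confirms.)  Coarse cells containing no fine water
#' are coarse land.  Fine dimensions are padded with land when not divisible
#' by the block size.
#'
#' @param ls a [landscape()].
#' @param delta fine motility matrix (m^2/yr), e.g. from [motility_field()].
#' @param K fine carrying-capacity matrix (individuals/cell).
#' @param epsilon fine-to-coarse scale ratio; `1/epsilon` must round to an
#'   integer block size (default 1/10, i.e. 4 km blocks for 400 m cells).
#' @return An object of class `eco_homgrid`.
#' @export
homogenize <- function(ls, delta, K, epsilon = 1 / 10) {
  m <- round(1 / epsilon)
  if (m < 1L || abs(m - 1 / epsilon) > 1e-8)
    stop("1/epsilon must be a positive integer block size")
  nr <- ls$n_rows; nc <- ls$n_cols
  nrc <- ceiling(nr / m); ncc <- ceiling(nc / m)

  w <- which(ls$water)
  rc <- id_to_rowcol(w, nr)
  coarse_row <- (rc[, 1] - 1L) %/% m + 1L
  coarse_col <- (rc[, 2] - 1L) %/% m + 1L
  coarse_id <- cell_id(coarse_row, coarse_col, nrc)

  dv <- delta[w]; Kv <- K[w]
  if (any(!is.finite(dv)) || any(dv <= 0)) stop("'delta' must be positive on water")
  if (any(!is.finite(Kv)) || any(Kv <= 0)) stop("'K' must be positive on water")

  grp <- factor(coarse_id, levels = seq_len(nrc * ncc))
  n_fine <- as.vector(table(grp))
  present <- sort(unique(coarse_id))
  full_inv_d <- numeric(nrc * ncc)
  full_inv_d[present] <- rowsum(1 / dv, coarse_id)[, 1]
  full_inv_d2K <- numeric(nrc * ncc)
  full_inv_d2K[present] <- rowsum(1 / (dv^2 * Kv), coarse_id)[, 1]

  delta_bar <- matrix(NA_real_, nrc, ncc)
  reaction <- matrix(NA_real_, nrc, ncc)
  water_c <- matrix(FALSE, nrc, ncc)
  water_c[present] <- TRUE
  delta_bar[present] <- n_fine[present] / full_inv_d[present]
  reaction[present] <- full_inv_d2K[present] / full_inv_d[present]

  fine_to_coarse <- matrix(NA_integer_, nr, nc)
  fine_to_coarse[w] <- coarse_id

  structure(list(
    epsilon = epsilon, block = m,
    coarse_cell_size = ls$cell_size * m,
    delta_bar = delta_bar, reaction = reaction,
    coarse_water = water_c,
    fine_to_coarse = fine_to_coarse,
    n_fine = { nf <- matrix(0L, nrc, ncc); nf[present] <- n_fine[present]; nf },
    n_rows = nrc, n_cols = ncc,
    fine_cell_size = ls$cell_size
  ), class = "eco_homgrid")
}

#' @method print eco_homgrid
#' @export
print.eco_homgrid <- function(x, ...) {
  cat(sprintf("<eco_homgrid> epsilon = 1/%d: %d x %d coarse cells of %g m (%d water)\n",
              x$block, x$n_rows, x$n_cols, x$coarse_cell_size, sum(x$coarse_water)))
  invisible(x)
}

# map solve output years to time-step indices
years_to_steps <- function(years, dt_days) {
  steps <- as.integer(round(years * 365 / dt_days))
  if (any(years > 0 & steps < 1L)) stop("output years smaller than one time step")
  steps
}

#' Propagate the logistic ecological diffusion model (homogenized)
#'
#' Integrates `d(lambda)/dt = Lap(delta lambda) + gamma lambda (1 - lambda/K)`
#' in homogenized form: the coarse state `c = delta*lambda` is advanced with
#' an implicit (backward Euler, sparse LU) diffusion step and an exact
#' logistic reaction substep each `dt_days`, with zero-flux boundaries.  At
#' each requested output year the coarse state is downscaled to the fine grid
#' by `lambda = c / delta`, which restores the fine-scale residence-time
#' pattern.
#'
#' The coarse initial state is chosen so the downscaled surface reproduces
#' the initial abundance of every coarse cell exactly.
#'
#' @param lambda0 fine initial intensity matrix (individuals per cell), e.g.
#'   from [initial_intensity()].
#' @param hom an [homogenize()] grid.
#' @param delta fine motility matrix (m^2/yr).
#' @param gamma intrinsic growth rate per year.
#' @param years numeric vector of output times in years since the initial
#'   condition (0 allowed; returns the initial surface).
#' @param dt_days time step in days (default 1).
#' @return An `eco_intensity` object: list with `years`, `lambda_fine`
#'   (array rows x cols x years, 0 on land), `lambda_coarse` (coarse state
#'   `c` per year), `dt_days`, `hom`, and solver diagnostics.
#' @export
propagate <- function(lambda0, hom, delta, gamma, years, dt_days = 1) {
  stopifnot(inherits(hom, "eco_homgrid"))
  if (any(lambda0 < 0, na.rm = TRUE)) stop("'lambda0' must be non-negative")
  years <- sort(unique(years))

  wc <- which(hom$coarse_water)
  nc_w <- length(wc)
  pos_c <- integer(hom$n_rows * hom$n_cols); pos_c[wc] <- seq_len(nc_w)

  fine_w <- which(!is.na(hom$fine_to_coarse))
  grp <- pos_c[hom$fine_to_coarse[fine_w]]
  dv <- delta[fine_w]
  lam0v <- lambda0[fine_w]

  # c0: conserve per-coarse-cell abundance under lambda = c/delta downscaling
  sum_lam <- as.vector(rowsum(lam0v, grp))
  sum_invd <- as.vector(rowsum(1 / dv, grp))
  c0 <- sum_lam / sum_invd

  L <- grid_laplacian(hom$coarse_water, hom$coarse_cell_size,
                      weights = hom$n_fine / hom$block^2)
  A <- Matrix::Diagonal(x = hom$delta_bar[wc]) %*% L
  wvec <- hom$reaction[wc]

  dt <- dt_days / 365
  steps <- years_to_steps(years, dt_days)
  pos_steps <- steps[steps > 0L]
  res <- if (length(pos_steps)) {
    rd_propagate_cpp(methods::as(A, "dgCMatrix"), c0, wvec, gamma, dt,
                     as.integer(pos_steps))
  } else list(states = matrix(numeric(0), nc_w, 0), n_clamped = 0,
              worst_undershoot = 0)

  n_out <- length(years)
  states <- matrix(0, nc_w, n_out)
  k <- 1L
  for (i in seq_len(n_out)) {
    if (steps[i] == 0L) states[, i] <- c0
    else { states[, i] <- res$states[, k]; k <- k + 1L }
  }

  nrf <- nrow(hom$fine_to_coarse); ncf <- ncol(hom$fine_to_coarse)
  lambda_fine <- array(0, dim = c(nrf, ncf, n_out))
  lambda_coarse <- array(NA_real_, dim = c(hom$n_rows, hom$n_cols, n_out))
  for (i in seq_len(n_out)) {
    sl <- matrix(0, nrf, ncf)
    sl[fine_w] <- states[grp, i] / dv
    lambda_fine[, , i] <- sl
    cc <- matrix(NA_real_, hom$n_rows, hom$n_cols)
    cc[wc] <- states[, i]
    lambda_coarse[, , i] <- cc
  }

  structure(list(years = years, lambda_fine = lambda_fine,
                 lambda_coarse = lambda_coarse, dt_days = dt_days, hom = hom,
                 n_clamped = res$n_clamped,
                 worst_undershoot = res$worst_undershoot),
            class = "eco_intensity")
}

#' Propagate the model directly on the fine grid
#'
#' Direct fine-scale finite-difference integration of the same PDE, without
#' homogenization: `d(lambda)/dt = Lap(delta lambda) + gamma lambda (1 -
#' lambda/K)`.  Used as the reference solution for validating the homogenized
#' solver, and as the production path on small domains.
#'
#' @inheritParams propagate
#' @param water logical water mask.
#' @param cell_size fine cell size in metres.
#' @param K fine carrying-capacity matrix (required when `gamma > 0`).
#' @return An `eco_intensity` object (with `lambda_coarse = NULL`).
#' @export
propagate_fine <- function(lambda0, delta, K, gamma, years, dt_days = 1,
                           water, cell_size) {
  years <- sort(unique(years))
  w <- which(water)
  L <- grid_laplacian(water, cell_size)
  A <- L %*% Matrix::Diagonal(x = delta[w])
  wvec <- if (gamma > 0) 1 / K[w] else numeric(length(w))
  dt <- dt_days / 365
  steps <- years_to_steps(years, dt_days)
  pos_steps <- steps[steps > 0L]
  u0 <- lambda0[w]
  res <- if (length(pos_steps)) {
    rd_propagate_cpp(methods::as(A, "dgCMatrix"), u0, wvec, gamma, dt,
                     as.integer(pos_steps))
  } else list(states = matrix(numeric(0), length(w), 0), n_clamped = 0,
              worst_undershoot = 0)
  n_out <- length(years)
  lambda_fine <- array(0, dim = c(nrow(water), ncol(water), n_out))
  k <- 1L
  for (i in seq_len(n_out)) {
    sl <- matrix(0, nrow(water), ncol(water))
    if (steps[i] == 0L) sl[w] <- u0
    else { sl[w] <- res$states[, k]; k <- k + 1L }
    lambda_fine[, , i] <- sl
  }
  structure(list(years = years, lambda_fine = lambda_fine,
                 lambda_coarse = NULL, dt_days = dt_days, hom = NULL,
                 n_clamped = res$n_clamped,
                 worst_undershoot = res$worst_undershoot),
            class = "eco_intensity")
}

#' Expected abundance of one cell in one year
#'
#' The cell-integrated intensity: expected individuals in fine cell
#' (`row`, `col`) at `year`.  The fine cell is the integration unit, so this
#' is simply the stored per-cell intensity.
#'
#' @param series an `eco_intensity` from [propagate()] or [propagate_fine()].
#' @param row,col fine-grid cell indices (must be water).
#' @param year one of `series$years`.
#' @param water logical water mask used to validate the cell.
#' @return Expected abundance (individuals).
#' @export
cell_intensity <- function(series, row, col, year, water) {
  stopifnot(inherits(series, "eco_intensity"))
  i <- match(year, series$years)
  if (is.na(i)) stop("'year' is not an output year of the series")
  if (!water[row, col]) stop("cell is not water")
  series$lambda_fine[row, col, i]
}
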