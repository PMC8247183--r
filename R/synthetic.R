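# Synthetic studies: a desk-scale nearshore landscape, a known truth
# (process + observation parameters and latent abundances), and the three
# aerial survey types, so the whole analysis pipeline can be exercised and
# validated without any external data.

default_landscape_config <- function() {
  list(water_frac = 0.52, smooth_sd = 2, trend = 3, channel_center = 0.62,
       max_depth_m = 130, depth_scale_m = 5000, depth_exp = 0.65,
       depth_noise = 0.15,
       offshore_depth_m = 100, offshore_dist_m = 5000,
       n_towns = 2, retries = 20)
}

#' Generate a synthetic nearshore landscape
#'
#' Builds a fjord-like water domain from smoothed random fields with a
#' landward trend, derives depth (deepening away from shore), slope,
#' distance to shore, shoreline complexity and cumulative town distance,
#' places two disjoint management regions (a protected bay `glba_ind` and
#' fisheries closures `fish_ind`), masks open-ocean cells beyond the
#' configured depth/distance limits (the reflecting offshore boundary), and
#' standardizes the non-indicator covariates.  The water domain is the
#' largest connected component; generation is retried with perturbed seeds
#' if it collapses.
#'
#' @param seed integer seed; regeneration with the same seed is identical.
#' @param n_rows,n_cols grid dimensions (default 40 x 40).
#' @param cell_size cell edge, metres (default 400).
#' @param config named list overriding [default_landscape_config()].
#' @return A standardized [landscape()].
#' @export
generate_landscape <- function(seed, n_rows = 40, n_cols = 40,
                               cell_size = 400, config = list()) {
  cfg <- utils::modifyList(default_landscape_config(), config)
  for (try in seq_len(cfg$retries)) {
    set.seed(seed + (try - 1L) * 7919L)
    ls <- try_generate_landscape(n_rows, n_cols, cell_size, cfg)
    if (!is.null(ls)) return(ls)
  }
  stop("could not generate a connected water domain; adjust the configuration")
}

try_generate_landscape <- function(nr, nc, h, cfg) {
  # a wiggly north-south channel with islands: smoothed noise plus a
  # cross-channel trend, water being the low-score cells
  z <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), cfg$smooth_sd)
  cf <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  score <- z + cfg$trend * abs(cf - cfg$channel_center)
  water <- score < quantile(score, cfg$water_frac)
  if (!any(water) || all(water)) return(NULL)
  water <- largest_component(water)
  if (sum(water) < 0.30 * nr * nc) return(NULL)

  # fjord bathymetry: steep walls near shore, flatter basin (concave profile)
  d2land <- dist_to_cells(!water, h)
  dnoise <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), cfg$smooth_sd)
  depth <- cfg$max_depth_m * pmin(d2land / cfg$depth_scale_m, 1)^cfg$depth_exp *
    (1 + cfg$depth_noise * dnoise)
  depth <- pmax(depth, 0.5)

  # reflecting offshore boundary: open-ocean cells leave the domain
  water <- water & depth <= cfg$offshore_depth_m & d2land <= cfg$offshore_dist_m
  if (!any(water)) return(NULL)
  water <- largest_component(water)
  if (sum(water) < 0.25 * nr * nc) return(NULL)
  d2land <- dist_to_cells(!water, h)
  depth <- cfg$max_depth_m * pmin(d2land / cfg$depth_scale_m, 1)^cfg$depth_exp *
    (1 + cfg$depth_noise * dnoise)
  depth <- pmax(depth, 0.5)

  gr <- depth
  slope <- matrix(0, nr, nc)
  slope[2:(nr - 1), ] <- abs(gr[3:nr, ] - gr[1:(nr - 2), ]) / (2 * h)
  slope2 <- matrix(0, nr, nc)
  slope2[, 2:(nc - 1)] <- abs(gr[, 3:nc] - gr[, 1:(nc - 2)]) / (2 * h)
  slope <- sqrt(slope^2 + slope2^2)

  depth_ind <- (depth < 40) * 1
  shore <- shoreline_complexity(water, 1000, h)

  # towns on shoreline land cells, spread apart
  shoreline_land <- !water & adjacent4_to(water)
  cand <- which(shoreline_land)
  if (length(cand) < cfg$n_towns) return(NULL)
  rc <- id_to_rowcol(cand, nr)
  picks <- cand[round(seq(1, length(cand), length.out = cfg$n_towns + 2))[
    2:(cfg$n_towns + 1)]]
  towns <- as.data.frame(id_to_rowcol(picks, nr))
  towns$name <- paste0("town", seq_len(nrow(towns)))
  town_dist <- suppressMessages(cumulative_town_distance(water, towns, h))
  town_dist[!water] <- 0

  # disjoint management regions: protected bay in the NW, closures in the SE
  glba <- matrix(0, nr, nc)
  glba[seq_len(floor(nr * 0.35)), seq_len(floor(nc * 0.55))] <- 1
  glba <- glba * water
  fish <- matrix(0, nr, nc)
  fish[ceiling(nr * 0.65):nr, ceiling(nc * 0.40):nc] <- 1
  fish <- fish * water
  if (sum(glba) < 5 || sum(fish) < 5) return(NULL)

  ls <- landscape(water, h,
                  covariates = list(depth_ind = depth_ind,
                                    dist_shore = d2land,
                                    slope = slope,
                                    shore_complex = shore,
                                    town_dist = town_dist,
                                    glba_ind = glba, fish_ind = fish),
                  towns = towns)
  standardize_covariates(ls)
}

#' Default epicenter layout for a synthetic landscape
#'
#' Places `J` epicenters on water cells, spread across the domain (greedy
#' farthest-point placement from a seeded start), with the desk-scale
#' default `theta`/`kappa` values of [default_truth_params()].
#'
#' @param ls a generated [landscape()].
#' @param seed integer seed.
#' @param J number of epicenters (default 7).
#' @return An [epicenters()] data frame.
#' @export
default_epicenters <- function(ls, seed = 1, J = 7) {
  set.seed(seed)
  w <- which(ls$water)
  rc <- id_to_rowcol(w, ls$n_rows)
  picks <- sample(length(w), 1)
  while (length(picks) < J) {
    d <- rep(Inf, length(w))
    for (p in picks)
      d <- pmin(d, (rc[, 1] - rc[p, 1])^2 + (rc[, 2] - rc[p, 2])^2)
    picks <- c(picks, which.max(d))
  }
  tp <- default_truth_params()
  epicenters(rc[picks, 1], rc[picks, 2], tp$theta, tp$kappa,
             label = paste0("E", seq_len(J)), landscape = ls)
}

#' Desk-scale default truth parameters
#'
#' Parameter values shaped like the posterior means estimated for the
#' recolonizing Southeast Alaska sea otter population, rescaled to the
#' synthetic 16 km domain: covariate effects, growth rate and dispersion are
#' kept as estimated (`gamma = 0.29`, `tau = 0.03`), while the motility and
#' capacity intercepts and the epicenter kernel scales are rescaled so that
#' spread, growth and saturation all happen — and are observable — inside a
#' 40 x 40-cell, 20-year synthetic study.
#'
#' @return Named list with `beta`, `alpha`, `gamma`, `tau`, `theta`,
#'   `kappa` (metres).
#' @export
default_truth_params <- function() {
  list(
    beta = c(15.3, -1.77, 0.29, 0.22, 0.17, 0.45, -0.24, -1.34),
    alpha = c(0.9, 3.16, 1.87),
    gamma = 0.29,
    tau = 0.03,
    theta = c(147.53, 9.75, 9.96, 98.90, 10.01, 96.18, 98.82),
    kappa = pmax(1000 * c(28.78, 2.54, 9.11, 0.63, 2.23, 8.49, 9.23) / 15, 600)
  )
}

#' Simulate the latent truth of a synthetic study
#'
#' Builds the motility and carrying-capacity fields, the multi-epicenter
#' initial condition, propagates the logistic diffusion PDE (homogenized
#' solver, daily steps by default) and draws the latent true abundance
#' `N ~ NB(lambda, tau)` of every water cell in every output year.
#'
#' @param ls a [landscape()].
#' @param epi an [epicenters()] data frame (its `theta`/`kappa` are the
#'   truth).
#' @param params list with `beta`, `alpha`, `gamma`, `tau` (defaults from
#'   [default_truth_params()]).
#' @param years output years (default 0:20, year 0 being the release).
#' @param epsilon homogenization ratio (default 1/5).
#' @param dt_days solver step (default 1).
#' @param seed integer seed for the abundance draws.
#' @return List of class `eco_truth`: `params`, `series` (an
#'   `eco_intensity`), `N` (array rows x cols x years), plus the inputs.
#' @export
generate_truth <- function(ls, epi, params = default_truth_params(),
                           years = 0:20, epsilon = 1 / 5, dt_days = 1,
                           seed = 1) {
  set.seed(seed)
  delta <- motility_field(ls, params$beta)
  K <- carrying_capacity_field(ls, params$alpha)
  lam0 <- initial_intensity(ls, epi)
  hom <- homogenize(ls, delta, K, epsilon)
  series <- propagate(lam0, hom, delta, params$gamma, years, dt_days)
  N <- array(0L, dim = dim(series$lambda_fine))
  w <- ls$water
  for (i in seq_along(years)) {
    sl <- series$lambda_fine[, , i]
    Ns <- matrix(0L, ls$n_rows, ls$n_cols)
    Ns[w] <- sample_abundance(sl[w], params$tau)
    N[, , i] <- Ns
  }
  structure(list(params = params, epicenters = epi, landscape = ls,
                 series = series, N = N, years = years, hom = hom,
                 delta = delta, K = K, seed = seed),
            class = "eco_truth")
}

default_survey_config <- function() {
  list(p_include_fav = 0.55, p_include_other = 0.18, # ~3:1 design strata
       isu_rate = 0.2, isu_max_group = 20,
       distribution_fraction = 1)
}

truth_N_year <- function(truth, year) {
  i <- match(year, truth$years)
  if (is.na(i)) stop("'year' is not a truth output year")
  truth$N[, , i]
}

#' Simulate a design-based (stratified transect) survey
#'
#' Transects are grid columns; columns whose water cells are mostly shallow
#' (`depth_ind = 1`, the favourable stratum) are included with higher
#' probability than others (default 0.55 vs 0.18, about 3:1 effort).  Every
#' water cell of an included column is surveyed: `y ~ Binomial(N, p)`.
#' Intensive search units fire at surveyed cells holding a group of 1 to 20
#' counted animals (configurable rate); an ISU's final recount is treated as
#' the cell's true abundance, so the cell moves from the count records to
#' the true-abundance records.
#'
#' @param truth an `eco_truth` from [generate_truth()].
#' @param year survey year.
#' @param p detection probability for the year.
#' @param config overrides of [default_survey_config()].
#' @return List with `counts`, `true_counts`, `isu` data frames.
#' @export
simulate_design_survey <- function(truth, year, p, config = list()) {
  cfg <- utils::modifyList(default_survey_config(), config)
  ls <- truth$landscape
  N <- truth_N_year(truth, year)
  depth <- ls$covariates$depth_ind
  fav_col <- vapply(seq_len(ls$n_cols), function(j) {
    wj <- ls$water[, j]
    if (!any(wj)) return(NA)
    mean(depth[wj, j]) >= 0.5
  }, logical(1))
  if (!any(fav_col, na.rm = TRUE) || !any(!fav_col, na.rm = TRUE))
    stop("a design stratum is empty: no favourable (or unfavourable) transects")
  incl <- !is.na(fav_col) &
    runif(ls$n_cols) < ifelse(fav_col, cfg$p_include_fav, cfg$p_include_other)
  cells <- which(ls$water & matrix(rep(incl, each = ls$n_rows),
                                   ls$n_rows, ls$n_cols))
  rc <- id_to_rowcol(cells, ls$n_rows)
  y <- rbinom(length(cells), N[cells], p)
  isu_fire <- y >= 1 & y <= cfg$isu_max_group &
    runif(length(cells)) < cfg$isu_rate
  counts <- data.frame(row = rc[!isu_fire, 1], col = rc[!isu_fire, 2],
                       year = rep(year, sum(!isu_fire)), y = y[!isu_fire],
                       type = rep("design", sum(!isu_fire)))
  true_counts <- data.frame(row = rc[isu_fire, 1], col = rc[isu_fire, 2],
                            year = rep(year, sum(isu_fire)),
                            N = N[cells][isu_fire])
  isu <- data.frame(year = rep(year, sum(isu_fire)),
                    initial = y[isu_fire], final = N[cells][isu_fire])
  list(counts = counts, true_counts = true_counts, isu = isu)
}

#' Simulate a distribution survey
#'
#' Surveys the favourable marine habitat: all (or a configured fraction of)
#' water cells with `depth_ind = 1`, each yielding `y ~ Binomial(N, p)`.
#'
#' @inheritParams simulate_design_survey
#' @return A `counts` data frame.
#' @export
simulate_distribution_survey <- function(truth, year, p, config = list()) {
  cfg <- utils::modifyList(default_survey_config(), config)
  ls <- truth$landscape
  N <- truth_N_year(truth, year)
  cells <- which(ls$water & ls$covariates$depth_ind == 1)
  if (cfg$distribution_fraction < 1)
    cells <- cells[runif(length(cells)) < cfg$distribution_fraction]
  rc <- id_to_rowcol(cells, ls$n_rows)
  data.frame(row = rc[, 1], col = rc[, 2], year = rep(year, length(cells)),
             y = rbinom(length(cells), N[cells], p),
             type = rep("distribution", length(cells)))
}

#' Simulate an aerial photographic survey
#'
#' Photographs the protected-bay study area (all `glba_ind = 1` water
#' cells, already at the fine grid resolution) with a yearly detection
#' probability drawn once from the informative photographic beta prior.
#'
#' @inheritParams simulate_design_survey
#' @param p optional fixed detection probability; when `NULL` (default) it
#'   is drawn from [photo_detection_prior()].
#' @return List with the `counts` data frame and the realised `p`.
#' @export
simulate_photo_survey <- function(truth, year, p = NULL, config = list()) {
  ls <- truth$landscape
  N <- truth_N_year(truth, year)
  if (is.null(p)) {
    pr <- photo_detection_prior()
    p <- rbeta(1, pr[1], pr[2])
  }
  cells <- which(ls$water & ls$covariates$glba_ind == 1)
  rc <- id_to_rowcol(cells, ls$n_rows)
  list(counts = data.frame(row = rc[, 1], col = rc[, 2],
                           year = rep(year, length(cells)),
                           y = rbinom(length(cells), N[cells], p),
                           type = rep("photo", length(cells))),
       p = p)
}

default_study_config <- function() {
  list(n_rows = 40, n_cols = 40, cell_size = 400,
       years = 0:20, epsilon = 1 / 5, dt_days = 1,
       design_years = c(5, 7, 10, 13), distribution_years = 3,
       photo_years = c(16, 18, 20),
       p_range = c(0.55, 0.9),
       landscape = list(), survey = list(), params = NULL)
}

#' Generate a complete synthetic study
#'
#' End-to-end generator: landscape, epicenters, latent truth, and all three
#' survey types across eight surveyed years of a 20-year horizon, plus a
#' matched [prior_spec()] whose epicenter hyperparameters reflect the
#' study's own release records (as the real analysis' priors reflected the
#' historical translocation records).  The full generating configuration is
#' returned as a `manifest`, and `generate_study(manifest = m)` reproduces
#' the study exactly.
#'
#' @param seed integer seed driving every random choice.
#' @param config overrides of `default_study_config()`.
#' @param manifest a manifest from a previous study, overriding `seed` and
#'   `config`.
#' @return List of class `eco_study`: `landscape`, `epicenters`, `truth`,
#'   `surveys` (an [survey_data()]), `priors`, `p_true`, `seed`,
#'   `manifest`.
#' @export
generate_study <- function(seed = 1, config = list(), manifest = NULL) {
  if (!is.null(manifest)) {
    seed <- manifest$seed
    config <- manifest$config
  }
  cfg <- utils::modifyList(default_study_config(), config)
  params <- if (is.null(cfg$params)) default_truth_params() else cfg$params

  ls <- generate_landscape(seed, cfg$n_rows, cfg$n_cols, cfg$cell_size,
                           cfg$landscape)
  epi <- default_epicenters(ls, seed = seed + 1L, J = length(params$theta))
  epi$theta <- params$theta
  epi$kappa <- params$kappa
  truth <- generate_truth(ls, epi, params, cfg$years, cfg$epsilon,
                          cfg$dt_days, seed = seed + 2L)

  set.seed(seed + 3L)
  survey_years <- sort(c(cfg$design_years, cfg$distribution_years,
                         cfg$photo_years))
  p_true <- setNames(numeric(length(survey_years)), survey_years)
  counts <- list(); trues <- list(); isus <- list()
  for (yr in survey_years) {
    if (yr %in% cfg$photo_years) {
      sim <- simulate_photo_survey(truth, yr, config = cfg$survey)
      p_true[as.character(yr)] <- sim$p
      counts[[length(counts) + 1L]] <- sim$counts
    } else if (yr %in% cfg$distribution_years) {
      p <- runif(1, cfg$p_range[1], cfg$p_range[2])
      p_true[as.character(yr)] <- p
      counts[[length(counts) + 1L]] <-
        simulate_distribution_survey(truth, yr, p, cfg$survey)
    } else {
      p <- runif(1, cfg$p_range[1], cfg$p_range[2])
      p_true[as.character(yr)] <- p
      sim <- simulate_design_survey(truth, yr, p, cfg$survey)
      counts[[length(counts) + 1L]] <- sim$counts
      trues[[length(trues) + 1L]] <- sim$true_counts
      isus[[length(isus) + 1L]] <- sim$isu
    }
  }
  surveys <- survey_data(
    counts = do.call(rbind, counts),
    true_counts = if (length(trues)) do.call(rbind, trues) else NULL,
    isu = if (length(isus)) do.call(rbind, isus) else NULL,
    photo_years = cfg$photo_years
  )

  priors <- prior_spec(
    mu_theta = c(100, 10, 10, 100, 10, 100, 100),
    sd_theta = c(20, 1, 1, 20, 1, 20, 20),
    mu_kappa = params$kappa, sd_kappa = pmax(0.3 * params$kappa, 150),
    photo_years = cfg$photo_years
  )

  structure(list(landscape = ls, epicenters = epi, truth = truth,
                 surveys = surveys, priors = priors, p_true = p_true,
                 seed = seed,
                 manifest = list(seed = seed, config = cfg)),
            class = "eco_study")
}

#' @method print eco_study
#' @export
print.eco_study <- function(x, ...) {
  cat(sprintf("<eco_study> seed %d: %d x %d cells, %d water; %d counts over years {%s}\n",
              x$seed, x$landscape$n_rows, x$landscape$n_cols,
              sum(x$landscape$water), nrow(x$surveys$counts),
              paste(x$surveys$years_surveyed, collapse = ", ")))
  invisible(x)
}
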