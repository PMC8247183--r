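#' Sample latent true abundance
#'
#' Draws true abundance `N ~ NB(lambda, tau)`, parameterised by mean `lambda`
#' and size (dispersion) `tau`, so `Var(N) = lambda + lambda^2/tau`.  Small
#' `tau` means strong overdispersion (clustered rafts of animals);
#' `tau -> Inf` recovers the Poisson.  `lambda = 0` gives `N = 0`.
#'
#' @param lambda non-negative expected abundance(s).
#' @param tau positive dispersion (NB size) parameter.
#' @return Integer vector of abundances, recycled to `length(lambda)`.
#' @export
sample_abundance <- function(lambda, tau) {
  if (any(lambda < 0)) stop("'lambda' must be non-negative")
  if (tau <= 0) stop("'tau' must be positive")
  rnbinom(length(lambda), size = tau, mu = lambda)
}

#' Sample an observed count by binomial thinning
#'
#' `y ~ Binomial(N, p)`: each of the `N` animals present is detected
#' independently with probability `p` (on the surface and counted).
#'
#' @param N integer abundance(s).
#' @param p detection probability in `[0, 1]`.
#' @return Integer vector of counts.
#' @export
sample_count <- function(N, p) {
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  rbinom(length(N), size = N, prob = p)
}

#' Exact conditional of true abundance given a count
#'
#' Under `N ~ NB(lambda, tau)` and `y | N ~ Binomial(N, p)`, the conditional
#' distribution of `N` given `y` is `N = y + M` with a negative-binomial
#' remainder `M ~ NB(size = tau + y, prob = (tau + p lambda)/(tau + lambda))`.
#' (Derivation: the product of the two pmfs is, as a function of `M = N - y`,
#' proportional to an NB kernel with those parameters; verified against
#' brute-force normalisation in the test suite.)  With `p = 1` the
#' conditional is a point mass at `N = y`.
#'
#' @param y observed count(s).
#' @param lambda expected abundance(s).
#' @param tau dispersion.
#' @param p detection probability.
#' @return A list with the remainder parameters (`size`, `prob`), the
#'   conditional `mean`, and functions `d(N)` (pmf) and `r(n)` (sampler).
#' @export
latent_conditional <- function(y, lambda, tau, p) {
  if (any(y < 0)) stop("'y' must be non-negative")
  size <- tau + y
  prob <- (tau + p * lambda) / (tau + lambda)
  mean <- y + size * (1 - prob) / prob
  list(y = y, size = size, prob = prob, mean = mean,
       d = function(N) ifelse(N < y, 0, dnbinom(N - y, size = size, prob = prob)),
       r = function(n) y + rnbinom(n, size = size, prob = prob))
}

# vectorised draw of N | y for the Gibbs sampler
draw_latent_N <- function(y, lambda, tau, p) {
  prob <- (tau + p * lambda) / (tau + lambda)
  y + rnbinom(length(y), size = tau + y, prob = pmin(prob, 1))
}

#' Marginal log-likelihood of a count
#'
#' The analytically marginalised observation model: integrating the latent
#' abundance out of the NB-then-binomial hierarchy leaves
#' `y ~ NB(mean = p lambda, size = tau)`.  Used as an independent
#' cross-check of the latent-variable computations.
#'
#' @inheritParams latent_conditional
#' @return Log-likelihood value(s).
#' @export
marginal_count_loglik <- function(y, lambda, tau, p) {
  dnbinom(y, size = tau, mu = p * lambda, log = TRUE)
}

#' Log-likelihood of intensive search unit (ISU) records
#'
#' During transect surveys, groups of animals are re-counted while the
#' aircraft circles, yielding a `final` count treated as the group's true
#' size and an `initial` count modelled as `Binomial(final, p)`.  Records
#' with `final = 0` carry no information about `p` and are dropped with a
#' message.
#'
#' @param isu data frame with columns `initial` and `final`.
#' @param p detection probability.
#' @return The summed binomial log-likelihood.
#' @export
isu_loglik <- function(isu, p) {
  if (any(isu$initial > isu$final)) stop("ISU initial count exceeds final count")
  drop <- isu$final == 0
  if (any(drop)) {
    message(sprintf("dropping %d ISU record(s) with final count 0", sum(drop)))
    isu <- isu[!drop, , drop = FALSE]
  }
  sum(dbinom(isu$initial, isu$final, p, log = TRUE))
}

#' Conjugate beta posterior for a detection probability
#'
#' With a `Beta(a, b)` prior and binomial data (ISU records plus counts of
#' detected/undetected animals), the posterior of `p` is
#' `Beta(a + successes, b + failures)`.
#'
#' @param successes,failures summed binomial successes and failures.
#' @param prior length-2 vector `c(a, b)` (default flat `Beta(1, 1)`).
#' @return Length-2 vector of posterior shape parameters.
#' @export
detection_posterior <- function(successes, failures, prior = c(1, 1)) {
  c(shape1 = prior[1] + successes, shape2 = prior[2] + failures)
}

#' Informative detection prior for photographic surveys
#'
#' The beta prior used for the detection probability of aerial photographic
#' surveys, moment-matched to an external estimate of photographic detection
#' (mean about 0.767).
#'
#' @return `c(shape1, shape2)`.
#' @export
photo_detection_prior <- function() {
  c(shape1 = 44.04937, shape2 = 13.40566)
}

#' Moment-match a beta distribution
#'
#' Finds `Beta(a, b)` with the requested mean and standard deviation.
#' Infeasible moment pairs (requiring `sd^2 >= mean (1 - mean)`) are
#' rejected.
#'
#' @param mean target mean in (0, 1).
#' @param sd target standard deviation.
#' @return `c(shape1, shape2)`.
#' @export
beta_moment_match <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("'mean' must lie in (0, 1)")
  v <- sd^2
  if (v <= 0 || v >= mean * (1 - mean))
    stop("infeasible (mean, sd) for a beta distribution")
  ab <- mean * (1 - mean) / v - 1
  c(shape1 = mean * ab, shape2 = (1 - mean) * ab)
}

#' Bundle survey data
#'
#' Collects the observation records consumed by [fit_diffusion()]:
#' counts `y` (cell, year, survey type), cells where true abundance is
#' treated as known (ISU groups re-counted to completion), the ISU
#' initial/final pairs used to estimate detection, and the years whose
#' detection probability receives the informative photographic prior.
#'
#' @param counts data frame with columns `row`, `col`, `year`, `y`, `type`
#'   (one of `"design"`, `"distribution"`, `"photo"`).
#' @param true_counts data frame with columns `row`, `col`, `year`, `N`
#'   (may be empty).
#' @param isu data frame with columns `year`, `initial`, `final` (may be
#'   empty).
#' @param photo_years integer vector of years with photographic surveys.
#' @return An object of class `eco_surveys`.
#' @export
survey_data <- function(counts = NULL, true_counts = NULL, isu = NULL,
                        photo_years = integer()) {
  empty_counts <- data.frame(row = integer(), col = integer(),
                             year = numeric(), y = integer(),
                             type = character())
  empty_true <- data.frame(row = integer(), col = integer(),
                           year = numeric(), N = integer())
  empty_isu <- data.frame(year = numeric(), initial = integer(),
                          final = integer())
  counts <- if (is.null(counts)) empty_counts else counts
  true_counts <- if (is.null(true_counts)) empty_true else true_counts
  isu <- if (is.null(isu)) empty_isu else isu
  if (nrow(counts) && any(counts$y < 0)) stop("counts must be non-negative")
  if (nrow(isu) && any(isu$initial > isu$final))
    stop("ISU initial count exceeds final count")
  key <- function(df) paste(df$row, df$col, df$year)
  if (nrow(counts) && anyDuplicated(key(counts)))
    stop("duplicate (cell, year) records in counts")
  if (nrow(true_counts) && anyDuplicated(key(true_counts)))
    stop("duplicate (cell, year) records in true_counts")
  if (nrow(counts) && nrow(true_counts) &&
      any(key(counts) %in% key(true_counts)))
    stop("a (cell, year) pair appears in both counts and true_counts")
  structure(list(counts = counts, true_counts = true_counts, isu = isu,
                 photo_years = photo_years,
                 years_surveyed = sort(unique(c(counts$year, true_counts$year,
                                                isu$year)))),
            class = "eco_surveys")
}

#' @method print eco_surveys
#' @export
print.eco_surveys <- function(x, ...) {
  cat(sprintf("<eco_surveys> %d counts, %d true-abundance cells, %d ISU records over years {%s}\n",
              nrow(x$counts), nrow(x$true_counts), nrow(x$isu),
              paste(x$years_surveyed, collapse = ", ")))
  invisible(x)
}
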