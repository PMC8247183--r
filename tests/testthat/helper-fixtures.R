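# Shared fixtures and small independent oracles, built in code.

# rectangular all-water landscape with simple covariates
flat_landscape <- function(nr = 20, nc = 20, cell = 400, seed = 1,
                           standardize = TRUE) {
  set.seed(seed)
  water <- matrix(TRUE, nr, nc)
  ls <- landscape(water, cell, covariates = list(
    depth_ind = matrix(rbinom(nr * nc, 1, 0.4), nr, nc),
    dist_shore = matrix(runif(nr * nc, 0, 4000), nr, nc),
    slope = matrix(abs(rnorm(nr * nc, 0, 0.02)), nr, nc),
    shore_complex = matrix(rpois(nr * nc, 4), nr, nc),
    town_dist = matrix(runif(nr * nc, 0, 30000), nr, nc),
    glba_ind = outer(1:nr, 1:nc, function(r, c) as.numeric(r <= nr / 4)),
    fish_ind = outer(1:nr, 1:nc, function(r, c) as.numeric(r >= 3 * nr / 4))
  ))
  if (standardize) standardize_covariates(ls) else ls
}

# landscape whose covariates are all zero on water (delta = exp(beta0))
zero_landscape <- function(nr = 10, nc = 10, cell = 400, water = NULL) {
  if (is.null(water)) water <- matrix(TRUE, nr, nc)
  zero <- matrix(0, nrow(water), ncol(water))
  landscape(water, cell, covariates = list(
    depth_ind = zero, dist_shore = zero, slope = zero, shore_complex = zero,
    town_dist = zero, glba_ind = zero, fish_ind = zero))
}

# brute-force shortest paths through water (8-connected, sqrt(2) diagonals):
# Bellman-Ford style relaxation, independent of the package's graph code
oracle_grid_distance <- function(water, src_row, src_col, cell) {
  nr <- nrow(water); nc <- ncol(water)
  d <- matrix(Inf, nr, nc)
  d[src_row, src_col] <- 0
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (c in 1:nc) {
      if (!water[r, c] || !is.finite(d[r, c])) next
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs$dr[k]; c2 <- c + offs$dc[k]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !water[r2, c2]) next
        w <- cell * sqrt(offs$dr[k]^2 + offs$dc[k]^2)
        if (d[r, c] + w < d[r2, c2] - 1e-9) {
          d[r2, c2] <- d[r, c] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

# brute-force conditional pmf of N given y under NB(lambda, tau) + Bin(N, p)
oracle_latent_pmf <- function(y, lambda, tau, p, N_max) {
  N <- y:N_max
  w <- dnbinom(N, size = tau, mu = lambda) * dbinom(y, N, p)
  w / sum(w)
}

# brute-force marginal pmf of y after NB -> binomial thinning
oracle_marginal_pmf <- function(y, lambda, tau, p, N_max) {
  sum(sapply(y:N_max, function(N)
    dnbinom(N, size = tau, mu = lambda) * dbinom(y, N, p)))
}

# default epicenter sites for prior-only fits (no data): any water layout
default_sites <- function() {
  data.frame(row = c(5, 10, 20, 30, 35, 15, 25),
             col = c(5, 30, 10, 30, 5, 20, 15),
             label = paste0("E", 1:7))
}
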