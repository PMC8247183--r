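test_that("motility field evaluates the log-linear model on water cells", {
  ls <- zero_landscape(5, 5)
  # all covariates zero with zero intercept: delta is identically 1
  expect_true(all(motility_field(ls, rep(0, 8))[ls$water] == 1))

  # posterior-mean coefficients on a shallow fisheries-closure cell:
  # delta = exp(b0 + b1 + b7)
  b <- c(16.36, -1.77, 0.29, 0.22, 0.17, 0.45, -0.24, -1.34)
  ls2 <- zero_landscape(3, 3)
  ls2$covariates$depth_ind[2, 2] <- 1
  ls2$covariates$fish_ind[2, 2] <- 1
  d <- motility_field(ls2, b)
  expect_equal(d[2, 2], exp(16.36 - 1.77 - 1.34), tolerance = 1e-12)
  expect_equal(d[1, 1], exp(16.36), tolerance = 1e-12)

  # negative closure coefficient means lower motility inside closures
  expect_lt(d[2, 2], exp(16.36 - 1.77))

  # exp overflow is rejected with a diagnostic
  expect_error(motility_field(ls, c(800, rep(0, 7))), "overflow")
  expect_error(motility_field(ls, rep(0, 7)), "length 8")
})

test_that("carrying capacity follows the management covariates", {
  ls <- zero_landscape(4, 4)
  expect_true(all(carrying_capacity_field(ls, c(0, 0, 0))[ls$water] == 1))

  a <- c(-1.66, 3.16, 1.87)
  ls$covariates$glba_ind[1, 1] <- 1
  ls$covariates$fish_ind[2, 2] <- 1
  K <- carrying_capacity_field(ls, a)
  expect_equal(K[1, 1], exp(-1.66 + 3.16), tolerance = 1e-12)  # exp(1.50)
  expect_equal(K[2, 2], exp(-1.66 + 1.87), tolerance = 1e-12)  # exp(0.21)
  expect_equal(K[3, 3], exp(-1.66), tolerance = 1e-12)
  # protected bay > closures > elsewhere
  expect_true(K[1, 1] > K[2, 2] && K[2, 2] > K[3, 3])

  # nominal regional capacity equals the hand sum on a 3-cell domain
  w <- matrix(FALSE, 1, 3); w[1, ] <- TRUE
  ls3 <- zero_landscape(1, 3, water = w)
  ls3$covariates$glba_ind[1, 1] <- 1
  K3 <- carrying_capacity_field(ls3, a)
  expect_equal(nominal_carrying_capacity(ls3, K3),
               exp(-1.66 + 3.16) + 2 * exp(-1.66), tolerance = 1e-12)
})

test_that("initial intensity normalises each epicenter kernel to theta", {
  ls <- zero_landscape(15, 15)
  e1 <- epicenters(8, 8, theta = 123.4, kappa = 1200, landscape = ls)
  lam <- initial_intensity(ls, e1)
  expect_equal(sum(lam), 123.4, tolerance = 1e-10)

  # seven epicenters: total abundance is the sum of the scales
  th <- c(147.53, 9.75, 9.96, 98.90, 10.01, 96.18, 98.82)
  e7 <- epicenters(row = c(2, 4, 6, 8, 10, 12, 14),
                   col = c(14, 2, 12, 4, 10, 6, 8),
                   theta = th, kappa = rep(900, 7), landscape = ls)
  expect_equal(sum(initial_intensity(ls, e7)), sum(th), tolerance = 1e-10)

  # on open water the discrete kernel mass approaches pi * kappa^2
  lsb <- zero_landscape(60, 60)
  kap <- 3 * 400
  Z <- ecodiffuse:::kernel_mass(lsb, 30, 30, kap)
  expect_lt(abs(Z - pi * kap^2) / (pi * kap^2), 0.01)

  # kappa far below the cell size with no water cell at the centre:
  # the kernel underflows everywhere and is rejected
  woff <- matrix(TRUE, 3, 3); woff[2, 2] <- FALSE
  lso <- zero_landscape(3, 3, water = woff)
  expect_error(initial_intensity(
    ls = lso, epi = data.frame(label = "x", row = 2, col = 2, theta = 1,
                               kappa = 1e-3)), "numerically zero")
})

test_that("homogenization averages motility harmonically", {
  ls <- zero_landscape(4, 4)
  delta <- matrix(2e6, 4, 4); K <- matrix(3, 4, 4)
  hom <- homogenize(ls, delta, K, epsilon = 1 / 2)
  # constants are reproduced exactly
  expect_true(all(abs(hom$delta_bar - 2e6) < 1e-6))
  expect_true(all(abs(hom$reaction - 1 / (2e6 * 3)) < 1e-18))
  expect_equal(hom$coarse_cell_size, 800)

  # a 1/4 split of deltas 1 and 4 has harmonic mean 1.6
  d2 <- matrix(c(1, 1, 4, 4), 2, 2)
  ls2 <- zero_landscape(2, 2)
  hom2 <- homogenize(ls2, d2, matrix(1, 2, 2), epsilon = 1 / 2)
  expect_equal(unname(hom2$delta_bar[1, 1]), 1.6, tolerance = 1e-12)

  expect_error(homogenize(ls, delta, K, epsilon = 0.3), "integer")
})

test_that("propagation conserves mass under pure diffusion", {
  ls <- flat_landscape(16, 16, seed = 4)
  # also on an irregular coastline, where partial coarse blocks require the
  # finite-volume flux weighting
  lsi <- generate_landscape(2, 20, 20)
  di <- motility_field(lsi, c(14.8, -0.6, 0.2, 0.1, 0.1, 0.2, -0.1, -0.3))
  Ki <- carrying_capacity_field(lsi, c(1, 0.5, 0.3))
  epii <- default_epicenters(lsi, seed = 3, J = 7)
  li <- initial_intensity(lsi, epii)
  si <- propagate(li, homogenize(lsi, di, Ki, 1 / 5), di, gamma = 0,
                  years = 50, dt_days = 2)
  expect_lt(abs(sum(si$lambda_fine[, , 1]) - sum(epii$theta)) /
              sum(epii$theta), 1e-6)
  delta <- motility_field(ls, c(14.5, -0.5, 0.2, 0.1, 0.1, 0.2, 0, 0))
  K <- carrying_capacity_field(ls, c(1, 0.5, 0.3))
  epi <- epicenters(8, 8, 250, 1500, landscape = ls)
  lam0 <- initial_intensity(ls, epi)
  hom <- homogenize(ls, delta, K, 1 / 4)
  s <- propagate(lam0, hom, delta, gamma = 0, years = c(1, 25, 50), dt_days = 2)
  tots <- apply(s$lambda_fine, 3, sum)
  expect_true(all(abs(tots - 250) / 250 < 1e-6))
  expect_true(all(s$lambda_fine >= 0))
})

test_that("a single cell follows the logistic closed form", {
  w <- matrix(TRUE, 1, 1)
  s <- propagate_fine(matrix(10, 1, 1), matrix(1e6, 1, 1), matrix(100, 1, 1),
                      gamma = 0.29, years = 1:20, dt_days = 1,
                      water = w, cell_size = 400)
  closed <- 100 / (1 + ((100 - 10) / 10) * exp(-0.29 * (1:20)))
  expect_lt(max(abs(s$lambda_fine[1, 1, ] - closed) / closed), 1e-4)
})

test_that("the homogenized operator reduces to the fine operator at epsilon 1", {
  ls <- flat_landscape(12, 12, seed = 6)
  delta <- motility_field(ls, c(14.8, -0.8, 0.2, 0.1, 0.1, 0.2, -0.1, -0.3))
  K <- carrying_capacity_field(ls, c(1, 0.5, 0.3))
  epi <- epicenters(6, 6, 150, 1200, landscape = ls)
  lam0 <- initial_intensity(ls, epi)
  hom1 <- homogenize(ls, delta, K, epsilon = 1)
  a <- propagate(lam0, hom1, delta, 0.29, c(4, 12), dt_days = 7)
  b <- propagate_fine(lam0, delta, K, 0.29, c(4, 12), dt_days = 7,
                      water = ls$water, cell_size = 400)
  expect_equal(a$lambda_fine, b$lambda_fine, tolerance = 1e-12)
})

test_that("a closed homogeneous domain relaxes to carrying capacity", {
  w <- matrix(TRUE, 6, 6)
  delta <- matrix(5e5, 6, 6); K <- matrix(8, 6, 6)
  lam0 <- matrix(0, 6, 6); lam0[3, 3] <- 50
  s <- propagate_fine(lam0, delta, K, gamma = 0.5, years = c(5, 40),
                      dt_days = 2, water = w, cell_size = 400)
  # gamma * t = 20 >> 10: everything should sit at K
  expect_true(all(abs(s$lambda_fine[, , 2] - 8) / 8 < 1e-3))
  # and never exceeds max(K) materially on the way
  expect_lt(max(s$lambda_fine), 50 * (1 + 1e-8))
})

test_that("splitting error shrinks linearly with the time step", {
  # coupled diffusion + growth on a short corridor, judged against a
  # fine-time-step reference: halving dt should roughly halve the error
  w <- matrix(TRUE, 1, 30)
  delta <- matrix(4e6, 1, 30); K <- matrix(20, 1, 30)
  lam0 <- matrix(0, 1, 30); lam0[1, 1:3] <- 20
  sol <- function(dt) propagate_fine(lam0, delta, K, 0.4, years = 4,
                                     dt_days = dt, water = w, cell_size = 400)$lambda_fine[1, , 1]
  ref <- sol(0.25)
  e8 <- max(abs(sol(8) - ref))
  e4 <- max(abs(sol(4) - ref))
  e2 <- max(abs(sol(2) - ref))
  expect_gt(e8 / e4, 1.6); expect_lt(e8 / e4, 2.6)
  expect_gt(e4 / e2, 1.6); expect_lt(e4 / e2, 2.7)
})

test_that("cell intensity is the per-cell integral of the surface", {
  w <- matrix(TRUE, 2, 2)
  lam0 <- matrix(5, 2, 2)
  s <- propagate_fine(lam0, matrix(1e5, 2, 2), matrix(10, 2, 2), 0,
                      years = 1, dt_days = 7, water = w, cell_size = 400)
  # uniform surface stays uniform; cells partition the total
  v <- sapply(1:2, function(r) sapply(1:2, function(c)
    cell_intensity(s, r, c, 1, w)))
  expect_true(all(abs(v - 5) < 1e-9))
  expect_equal(sum(v), sum(s$lambda_fine[, , 1]))
  expect_error(cell_intensity(s, 1, 1, 99, w), "output year")
  w2 <- w; w2[1, 1] <- FALSE
  expect_error(cell_intensity(s, 1, 1, 1, w2), "not water")
})
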