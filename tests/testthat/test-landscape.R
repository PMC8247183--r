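test_that("shoreline complexity counts shoreline cells within the radius", {
  # all water: no land anywhere, so no shoreline and all counts are zero
  w <- matrix(TRUE, 6, 6)
  expect_true(all(shoreline_complexity(w, 1000, 400) == 0))

  # single interior land cell: its 4 water neighbours are the shoreline;
  # verify every cell against an exhaustive neighbourhood count
  w5 <- matrix(TRUE, 5, 5)
  w5[3, 3] <- FALSE
  got <- shoreline_complexity(w5, 400, 400)  # radius = one cell width
  shore <- matrix(FALSE, 5, 5)
  for (r in 1:5) for (c in 1:5) {
    if (!w5[r, c]) next
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 5 & nb[, 2] >= 1 & nb[, 2] <= 5, , drop = FALSE]
    shore[r, c] <- any(!w5[nb])
  }
  expect_equal(sum(shore), 4)
  want <- matrix(0, 5, 5)
  for (r in 1:5) for (c in 1:5)
    for (r2 in 1:5) for (c2 in 1:5)
      if (shore[r2, c2] && sqrt((r - r2)^2 + (c - c2)^2) <= 1)
        want[r, c] <- want[r, c] + 1
  expect_equal(got, want)

  # 1000 m radius on 400 m cells: the centre-to-centre disc of radius 2.5
  # cells (21 offsets, since sqrt(5) < 2.5 admits the knight-adjacent ring)
  offs <- expand.grid(dr = -3:3, dc = -3:3)
  in_disc <- sqrt(offs$dr^2 + offs$dc^2) <= 1000 / 400
  expect_equal(sum(in_disc), 21)
  # cross-check the disc on a lone island: exhaustive distance enumeration
  one <- matrix(TRUE, 11, 11); one[6, 6] <- FALSE
  cnt1 <- shoreline_complexity(one, 1000, 400)
  shore1 <- matrix(FALSE, 11, 11)
  shore1[cbind(c(5, 7, 6, 6), c(6, 6, 5, 7))] <- TRUE
  want1 <- matrix(0, 11, 11)
  for (r in 1:11) for (c in 1:11)
    for (r2 in 1:11) for (c2 in 1:11)
      if (shore1[r2, c2] && sqrt((r - r2)^2 + (c - c2)^2) <= 2.5)
        want1[r, c] <- want1[r, c] + 1
  expect_equal(cnt1, want1)

  expect_error(shoreline_complexity(w, 200, 400), "radius")
})

test_that("shoreline complexity is invariant to translation and rotation", {
  set.seed(3)
  w <- matrix(runif(64) > 0.4, 8, 8)
  base <- shoreline_complexity(w, 1000, 400)
  # 90 degree rotation
  rot <- t(apply(w, 2, rev))
  got_rot <- shoreline_complexity(rot, 1000, 400)
  expect_equal(got_rot, t(apply(base, 2, rev)))
  # translation within a larger frame (interior far from edges)
  big <- matrix(TRUE, 12, 12)  # embed with water frame
  big[3:10, 3:10] <- w
  shifted <- matrix(TRUE, 12, 12)
  shifted[2:9, 4:11] <- w
  b1 <- shoreline_complexity(big, 1000, 400)
  b2 <- shoreline_complexity(shifted, 1000, 400)
  expect_equal(b1[5:8, 5:8], b2[4:7, 6:9])
})

test_that("cumulative town distance follows shortest swimmable paths", {
  # straight open corridor: distance grows linearly with the cell count
  w <- matrix(TRUE, 1, 8)
  towns <- data.frame(row = 1, col = 1)
  d <- cumulative_town_distance(w, towns, 400)
  expect_equal(d[1, 8], 7 * 400)

  # a peninsula forces the path around; compare with an independent
  # Bellman-Ford oracle on the same grid
  w2 <- matrix(TRUE, 7, 7)
  w2[1:5, 4] <- FALSE
  towns2 <- data.frame(row = 1, col = 1)
  d2 <- cumulative_town_distance(w2, towns2, 400)
  oracle <- oracle_grid_distance(w2, 1, 1, 400)
  expect_equal(d2[w2], oracle[w2], tolerance = 1e-12)
  # the detour exceeds the Euclidean distance
  expect_gt(d2[1, 7], 6 * 400)

  # two towns: the raster is the sum of the single-town rasters
  t1 <- data.frame(row = 1, col = 1); t2 <- data.frame(row = 7, col = 7)
  both <- cumulative_town_distance(w2, rbind(t1, t2), 400)
  expect_equal(both, cumulative_town_distance(w2, t1, 400) +
                 cumulative_town_distance(w2, t2, 400))

  expect_error(cumulative_town_distance(w2, data.frame(), 400), "no towns")
})

test_that("town distance dominates Euclidean distance, with equality on open water", {
  w <- matrix(TRUE, 9, 9)
  towns <- data.frame(row = 5, col = 5)
  d <- cumulative_town_distance(w, towns, 400)
  eu <- outer(1:9, 1:9, function(r, c) sqrt((r - 5)^2 + (c - 5)^2)) * 400
  expect_true(all(d - eu >= -1e-9))
  # along rows, columns and exact diagonals the grid path is Euclidean
  expect_equal(d[5, ], eu[5, ])
  expect_equal(diag(d), diag(eu))
})

test_that("standardization centres and scales over water only, sparing indicators", {
  ls <- flat_landscape(10, 10, standardize = FALSE)
  raw <- ls$covariates
  s1 <- standardize_covariates(ls)
  w <- ls$water
  for (nm in c("dist_shore", "slope", "shore_complex", "town_dist")) {
    expect_equal(mean(s1$covariates[[nm]][w]), 0, tolerance = 1e-12)
    expect_equal(sd(s1$covariates[[nm]][w]), 1, tolerance = 1e-12)
  }
  # indicators returned bit-identical
  expect_identical(s1$covariates$depth_ind, raw$depth_ind)
  expect_identical(s1$covariates$glba_ind, raw$glba_ind)

  # idempotence and exact round trip
  s2 <- standardize_covariates(s1)
  expect_equal(s2$covariates$dist_shore, s1$covariates$dist_shore,
               tolerance = 1e-12)
  back <- destandardize_covariates(s2)
  expect_equal(back$covariates$dist_shore[w], raw$dist_shore[w],
               tolerance = 1e-10)

  # hand-computed standardization of a constant-plus-outlier covariate
  lsz <- zero_landscape(3, 3)
  x <- matrix(5, 3, 3); x[2, 2] <- 14
  lsz$covariates$dist_shore <- x
  sz <- standardize_covariates(lsz)
  expect_equal(sz$covariates$dist_shore[2, 2],
               (14 - mean(x)) / sd(x), tolerance = 1e-12)

  # zero-variance covariate is rejected by name
  lsc <- zero_landscape(4, 4)
  lsc$covariates$slope <- matrix(7, 4, 4)
  expect_error(standardize_covariates(lsc), "slope")
})

test_that("landscape and epicenter validation catch malformed inputs", {
  w <- matrix(TRUE, 4, 4); w[2, 2] <- FALSE
  expect_error(landscape(w, 400, covariates = list(depth_ind = matrix(0, 3, 3))),
               "dimensions")
  bad <- matrix(0, 4, 4); bad[1, 1] <- NA
  expect_error(landscape(w, 400, covariates = list(x = bad)), "finite")
  ls <- landscape(w, 400)
  expect_error(epicenters(2, 2, 10, 500, landscape = ls), "water")
  expect_error(epicenters(1, 1, -1, 500), "theta")
  e <- epicenters(1, 1, 10, 500, landscape = ls)
  expect_s3_class(e, "eco_epicenters")
})
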