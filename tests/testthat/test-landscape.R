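test_that("landscape generation is bit-reproducible and respects invariants", {
  cfg <- landscapeConfig(nrow = 40, ncol = 40)
  a <- generateLandscape(cfg, seed = 1)
  b <- generateLandscape(cfg, seed = 1)
  expect_identical(a@rasters$elev@values, b@rasters$elev@values)
  expect_identical(a@rasters$cutblk@values, b@rasters$cutblk@values)
  expect_identical(a@lines$stream@features, b@lines$stream@features)

  covSum <- a@rasters$conifer@values + a@rasters$decid@values +
    a@rasters$herb@values + a@rasters$shrub@values +
    a@rasters$burn@values + a@rasters$cutblk@values
  expect_true(all(covSum <= 1 + 1e-12))
  expect_true(all(covSum >= 0))
  expect_true(all(a@rasters$slope@values >= 0 & a@rasters$slope@values <= 90))
  expect_true(all(a@rasters$rugg@values >= 0 & a@rasters$rugg@values <= 1))
  expect_equal(a@rasters$open@values,
               1 - a@rasters$conifer@values - a@rasters$decid@values,
               tolerance = 1e-12)
  expect_error(generateLandscape(landscapeConfig(nrow = -1)), "positive")
})

test_that("zero-stream configurations leave distances undefined", {
  L0 <- generateLandscape(landscapeConfig(nrow = 30, ncol = 30, nStreams = 0),
                          seed = 2)
  expect_length(L0@lines$stream@features, 0)
  expect_error(distanceTo(L0@lines$stream, c(10, 10)), "empty feature set")
  expect_error(distanceRaster(L0@lines$stream, L0@rasters$elev),
               "empty feature set")
})

test_that("terrain derivation matches flat, tilted and brute-force cases", {
  flat <- rasterGrid(matrix(1234, 8, 8))
  tf <- deriveTerrain(flat)
  expect_true(all(tf$slope@values == 0))
  expect_true(all(tf$rugg@values == 0))

  ## plane rising one cell height per cell eastward: 45 degrees inside
  ctr <- cellCenters(flat)
  plane <- rasterGrid(matrix(rep(ctr$x, each = 8), 8, 8))
  tp <- deriveTerrain(plane)
  expect_equal(tp$slope@values[3:6, 3:6], matrix(45, 4, 4), tolerance = 1e-9)

  set.seed(5)
  z <- matrix(rnorm(15 * 15, 1500, 40), 15, 15)
  tr <- deriveTerrain(rasterGrid(z))
  ## brute-force per-cell 3x3 neighborhood SD, normalized by the grid max
  sdRaw <- matrix(NA_real_, 15, 15)
  for (i in 1:15) for (j in 1:15) {
    nb <- z[max(1, i - 1):min(15, i + 1), max(1, j - 1):min(15, j + 1)]
    sdRaw[i, j] <- sd(as.numeric(nb))
  }
  expect_equal(tr$rugg@values, sdRaw / max(sdRaw), tolerance = 1e-8)
  expect_error(deriveTerrain(rasterGrid(matrix(0, 2, 5))), "3 x 3")
})

test_that("forest edge marks both sides of the forest boundary", {
  forest <- rasterGrid(matrix(1, 10, 10))
  none <- rasterGrid(matrix(0, 10, 10))
  expect_true(all(deriveForestEdge(forest, none)@values == 0))

  checker <- rasterGrid(matrix((outer(1:10, 1:10, "+") %% 2), 10, 10))
  eg <- deriveForestEdge(checker, none)
  expect_true(all(eg@values[2:9, 2:9] == 1))

  ## 5x5 forest block in open ground: brute-force 4-neighbor oracle
  blk <- matrix(0, 12, 12); blk[4:8, 4:8] <- 1
  none12 <- rasterGrid(matrix(0, 12, 12))
  eg2 <- deriveForestEdge(rasterGrid(blk), none12)
  oracle <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    f <- blk[i, j] > 0.5
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > 12 || nb[2] < 1 || nb[2] > 12) next
      if ((blk[nb[1], nb[2]] > 0.5) != f) oracle[i, j] <- 1
    }
  }
  expect_identical(eg2@values, oracle)
  expect_error(deriveForestEdge(NULL, none), "required")
})

test_that("protected-area density steps, smooths and renormalizes", {
  tmpl <- rasterGrid(matrix(0, 50, 50))
  park <- matrix(rep(1:50 <= 20, each = 50), 50, 50)  # west 20 columns

  unif <- buildAbundancePdf(park, 1, 0, "bear", tmpl)
  expect_equal(max(abs(unif@density@values - 1 / (2500 * 900))), 0,
               tolerance = 1e-15)

  step <- buildAbundancePdf(park, 2.4, 0, "bear", tmpl)
  expect_equal(step@density@values[25, 5] / step@density@values[25, 45], 2.4,
               tolerance = 1e-9)

  sm <- buildAbundancePdf(park, 2.4, 1200, "bear", tmpl)
  tot <- sum(sm@density@values) * 900
  expect_equal(tot, 1, tolerance = 1e-9)
  ## monotone nonincreasing from park interior to exterior along a row
  prof <- sm@density@values[25, ]
  expect_true(all(diff(prof) <= 1e-15))
  expect_error(buildAbundancePdf(park, 0, 0, "bear", tmpl), "positive")
})

test_that("territory mixtures are unimodal, size-weighted and normalized", {
  tmpl <- rasterGrid(matrix(0, 60, 60))
  one <- buildWolfPdf(cbind(905, 905), 5, 300, tmpl)
  mode <- which(one@density@values == max(one@density@values), arr.ind = TRUE)
  expect_equal(as.numeric(mode[1, ]), c(31, 31))  # cell containing (905, 905)

  two <- buildWolfPdf(rbind(c(450, 450), c(1350, 1350)), c(8, 2), 150, tmpl)
  ctr <- cellCenters(tmpl)
  d1 <- outer((ctr$y - 450)^2, (ctr$x - 450)^2, "+") <= 150^2
  d2 <- outer((ctr$y - 1350)^2, (ctr$x - 1350)^2, "+") <= 150^2
  m1 <- sum(two@density@values[d1]); m2 <- sum(two@density@values[d2])
  expect_equal(m1 / m2, 4, tolerance = 0.1 * 4)
  expect_equal(sum(two@density@values) * 900, 1, tolerance = 1e-9)
  expect_error(buildWolfPdf(cbind(1, 1), 3, 0, tmpl), "bandwidth")
})
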