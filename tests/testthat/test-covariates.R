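test_that("buffer statistics match the exhaustive cell-center oracle", {
  r <- rasterGrid(matrix(6.5, 30, 30))
  expect_equal(bufferStat(r, c(450, 450), 200), 6.5)

  ## 1.3-km buffer area approximates 5.3 km^2 on a big enough grid
  big <- rasterGrid(matrix(1, 120, 120))
  ctr <- cellCenters(big)
  p <- c(ctr$x[60], ctr$y[60])
  inside <- outer((ctr$y - p[2])^2, (ctr$x - p[1])^2, "+") <= 1300^2
  areaKm2 <- sum(inside) * 900 / 1e6
  expect_lt(abs(areaKm2 - pi * 1.3^2), 2 * 900 / 1e6 + 0.05)
  expect_gt(areaKm2, 5.2); expect_lt(areaKm2, 5.4)

  rr <- randomRaster(40, 40, seed = 8)
  rr@nodata[10:12, 20] <- TRUE
  for (case in list(list(p = c(500, 700), rad = 145),
                    list(p = c(640, 333), rad = 377))) {
    cc <- cellCenters(rr)
    d2 <- outer((cc$y - case$p[2])^2, (cc$x - case$p[1])^2, "+")
    keep <- d2 <= case$rad^2 & !rr@nodata
    expect_equal(bufferStat(rr, case$p, case$rad),
                 mean(rr@values[keep]), tolerance = 1e-12)
  }
  expect_error(bufferStat(r, c(450, 450), -5), "positive")
})

test_that("segment distances agree with a densified oracle", {
  seg <- new("LinearFeatureSet",
             features = list(cbind(c(-5, 5), c(0, 0))),
             classLabel = "stream")
  expect_equal(distanceTo(seg, c(0, 0)), 0)
  expect_equal(distanceTo(seg, c(0, 10)), 10)

  set.seed(13)
  feats <- lapply(1:6, function(i) cbind(runif(3, 0, 1000), runif(3, 0, 1000)))
  fs <- new("LinearFeatureSet", features = feats, classLabel = "stream")
  for (i in 1:5) {
    p <- runif(2, 0, 1000)
    ## densify every segment at 1-m steps
    best <- Inf
    for (f in feats) for (s in seq_len(nrow(f) - 1)) {
      L <- sqrt(sum((f[s + 1, ] - f[s, ])^2))
      t <- seq(0, 1, length.out = max(2, ceiling(L)))
      px <- f[s, 1] + t * (f[s + 1, 1] - f[s, 1])
      py <- f[s, 2] + t * (f[s + 1, 2] - f[s, 2])
      best <- min(best, sqrt((px - p[1])^2 + (py - p[2])^2))
    }
    expect_lt(abs(distanceTo(fs, p) - best), 0.5)
  }
})

test_that("line density clips exactly and matches Monte Carlo", {
  far <- new("LinearFeatureSet",
             features = list(cbind(c(5000, 6000), c(5000, 5000))),
             classLabel = "motorized")
  expect_equal(linearDensity(far, c(0, 0), 100), 0)

  ## diameter-spanning line: density (2r/1000)/(pi r^2/1e6)
  thru <- new("LinearFeatureSet",
              features = list(cbind(c(-10000, 10000), c(0, 0))),
              classLabel = "motorized")
  r <- 350
  expect_equal(linearDensity(thru, c(0, 0), r),
               (2 * r / 1000) / (pi * r^2 / 1e6), tolerance = 1e-12)

  set.seed(17)
  feats <- lapply(1:4, function(i) cbind(runif(2, -400, 400), runif(2, -400, 400)))
  fs <- new("LinearFeatureSet", features = feats, classLabel = "motorized")
  got <- linearDensity(fs, c(0, 0), 300)
  ## Monte Carlo oracle: fraction of densified segment points inside disc
  tot <- 0
  for (f in feats) {
    L <- sqrt(sum((f[2, ] - f[1, ])^2))
    t <- (seq_len(1e5) - 0.5) / 1e5
    px <- f[1, 1] + t * (f[2, 1] - f[1, 1])
    py <- f[1, 2] + t * (f[2, 2] - f[1, 2])
    tot <- tot + mean(px^2 + py^2 <= 300^2) * L
  }
  want <- (tot / 1000) / (pi * 300^2 / 1e6)
  expect_equal(got, want, tolerance = 0.01 * max(want, 1))
})

test_that("the on-trail flag is inclusive at exactly 30 m", {
  tr <- new("LinearFeatureSet", features = list(cbind(c(0, 100), c(0, 0))),
            classLabel = "nonmotorized")
  expect_equal(trailUseFlag(c(50, 0), tr), 1)
  expect_equal(trailUseFlag(c(50, 30), tr), 1)
  expect_equal(trailUseFlag(c(50, 31), tr), 0)
})

test_that("design matrices honor spec order and match single-covariate calls", {
  L <- smallLandscape()
  specs <- defaultSpecs("P_pred")
  empty <- buildDesignMatrix(matrix(numeric(), 0, 2), specs, L)
  expect_equal(nrow(empty), 0)
  expect_true(all(names(specs) %in% names(empty)))

  set.seed(31)
  pts <- cbind(runif(5, 200, 1500), runif(5, 200, 1500))
  tab <- buildDesignMatrix(pts, specs, L)
  for (i in seq_len(5)) {
    expect_equal(tab$slope[i],
                 extractAtPoints(L@rasters$slope, pts[i, , drop = FALSE]))
    expect_equal(tab$conifer[i],
                 bufferStat(L@rasters$conifer, pts[i, ], 1300, "proportion"))
    expect_equal(tab$distwater[i], distanceTo(L@lines$stream, pts[i, ]))
    expect_equal(tab$roaddens[i],
                 linearDensity(L@lines$motorized, pts[i, ], 1300))
    expect_equal(tab$trailuse[i], trailUseFlag(pts[i, ], L@lines$nonmotorized))
  }
  ## permuting specs permutes columns, not values
  tab2 <- buildDesignMatrix(pts, rev(specs), L)
  expect_equal(tab2$conifer, tab$conifer)
  expect_equal(tab2$distwater, tab$distwater)
  expect_error(buildDesignMatrix(cbind(-100, -100), specs, L), "outside grid")
})

test_that("stack extraction reproduces exact values at cell centers", {
  L <- smallLandscape()
  S <- smallStacks()
  ctr <- cellCenters(L@rasters[[1]])
  pts <- cbind(ctr$x[c(10, 25, 40)], ctr$y[c(12, 30, 48)])
  exact <- buildDesignMatrix(pts, defaultSpecs("P_pred"), L)
  fast <- buildDesignMatrix(pts, defaultSpecs("P_pred"), L, stack = S$pred)
  for (nm in c("slope", "rugg", "elev", "trailuse", "conifer", "distwater"))
    expect_equal(fast[[nm]], exact[[nm]], tolerance = 1e-7)
})
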