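test_that("transect campaigns hit their length targets deterministically", {
  L <- smallLandscape()
  expect_length(generateTransects(L, 0, 2, 1), 0)
  tr <- generateTransects(L, 4, 0.8, seed = 3)
  tot <- sum(vapply(tr, `[[`, numeric(1), "lengthKm"))
  expect_lt(abs(tot - 4 * 0.8) / (4 * 0.8), 0.05)
  tr2 <- generateTransects(L, 4, 0.8, seed = 3)
  expect_identical(tr[[2]]$polyline, tr2[[2]]$polyline)
  expect_error(generateTransects(L, 4, -1, 1), "positive")
})

test_that("scat deposition hits exact per-species detected targets", {
  L <- smallLandscape(); S <- smallStacks(); tr <- truthSet()
  transects <- generateTransects(L, 4, 1.5, seed = 5)
  nt <- c(wolf = 120, cougar = 20)
  scats <- simulateScats(L, transects, tr, nt, detectP = 0.9,
                         oldFraction = 0.15, seed = 9, stack = S$pred)
  tab <- table(scats$species[scats$age_class != "old"])
  expect_equal(as.numeric(tab[c("wolf", "cougar")]), c(120, 20))
  expect_true(all(scats$elk_content == "not_analyzed"))
  ## determinism
  scats2 <- simulateScats(L, transects, tr, nt, detectP = 0.9,
                          oldFraction = 0.15, seed = 9, stack = S$pred)
  expect_identical(scats$x, scats2$x)
  ## every scat lies within 50 m of its transect
  for (i in seq_len(min(50, nrow(scats)))) {
    d <- distanceTo(transectLines(transects[scats$transect_id[i]]),
                    c(scats$x[i], scats$y[i]))
    expect_lt(d, 50 + 1e-6)
  }
  expect_error(simulateScats(L, transects, tr, c(lynx = 5), stack = S$pred),
               "lacks species")
  expect_error(simulateScats(L, transects, tr, nt, detectP = 0, stack = S$pred),
               "detectP")
})

test_that("neutral deposition matches corridor availability; true selection shifts it", {
  L <- smallLandscape(); S <- smallStacks()
  transects <- generateTransects(L, 4, 1.5, seed = 5)
  trNull <- truthSet(); trNull$rsf$wolf <- c(slope = 0)
  trSel <- truthSet(); trSel$rsf$wolf <- c(slope = -0.1)
  zstats <- numeric(0); lower <- logical(0)
  for (sd in 1:20) {
    s0 <- simulateScats(L, transects, trNull, c(wolf = 150), 1, 0,
                        seed = 100 + sd, stack = S$pred)
    s1 <- simulateScats(L, transects, trSel, c(wolf = 150), 1, 0,
                        seed = 100 + sd, stack = S$pred)
    corr <- sampleValidationPoints(L, 400, 300 + sd)  # not corridor; see below
    ## corridor reference: availability points along the surveyed lines
    av <- do.call(rbind, lapply(seq_along(transects), function(i)
      sampleAvailableLinear(list(x = transects[[i]]$polyline[1, 1],
                                 y = transects[[i]]$polyline[1, 2]),
                            transects[[i]], corridorWidth = 100,
                            corridorLength = 1e5, n = 150,
                            seed = 400 + sd * 7 + i)))
    slopeAt <- function(xy) extractAtPoints(L@rasters$slope, xy)
    m0 <- slopeAt(cbind(s0$x, s0$y)); mA <- slopeAt(av)
    z <- (mean(m0, na.rm = TRUE) - mean(mA, na.rm = TRUE)) /
      sqrt(var(m0, na.rm = TRUE) / sum(!is.na(m0)) +
             var(mA, na.rm = TRUE) / sum(!is.na(mA)))
    zstats[sd] <- z
    lower[sd] <- mean(slopeAt(cbind(s1$x, s1$y)), na.rm = TRUE) <
      mean(mA, na.rm = TRUE)
  }
  expect_lte(sum(abs(zstats) >= 3), 1)  # ~N(0,1) allows one excursion in 20
  expect_gte(sum(lower), 19)
})

test_that("the corridor rejection sampler matches a multinomial cell sampler", {
  ## 20x20 grid whose corridor covers the whole region
  cfg <- landscapeConfig(nrow = 20, ncol = 20, nStreams = 2, nRoads = 1,
                         nTrails = 2)
  L <- generateLandscape(cfg, seed = 12)
  L@exclusionMask[] <- FALSE
  S <- list(pred = covariateStack(L, defaultSpecs("P_pred")))
  ## dense transects so corridors blanket the grid
  transects <- generateTransects(L, 9, 1.2, seed = 4)
  tr <- truthSet(); tr$rsf$wolf <- c(slope = -0.05, trailuse = 1)
  cellsOf <- function(s) {
    rc <- pointToCell(L@rasters[[1]], cbind(s$x, s$y))
    (rc[, 2] - 1) * 20 + rc[, 1]
  }
  scats <- simulateScats(L, transects, tr, c(wolf = 50000), 1, 0, 31, S$pred,
                         deposition = "global")
  pS <- tabulate(cellsOf(scats), 400) / nrow(scats)

  ## independent cell-probability oracle: per-cell corridor area share
  ## (from a neutral-deposition run) times the exponential selection weight
  trNull <- tr; trNull$rsf$wolf <- c(slope = 0)
  s0 <- simulateScats(L, transects, trNull, c(wolf = 120000), 1, 0, 32, S$pred,
                      deposition = "global")
  area <- tabulate(cellsOf(s0), 400) / nrow(s0)
  lp <- tr$rsf$wolf[["slope"]] * L@rasters$slope@values +
    tr$rsf$wolf[["trailuse"]] * S$pred$trailuse@values
  w <- area * exp(as.numeric(lp))
  tv <- 0.5 * sum(abs(pS - w / sum(w)))
  expect_lt(tv, 0.05)
})

test_that("content assignment calibrates marginals and respects deciles", {
  L <- smallLandscape(); S <- smallStacks(); tr <- truthSet()
  transects <- generateTransects(L, 4, 1.5, seed = 5)
  scats <- simulateScats(L, transects, tr, c(wolf = 300), 0.9, 0.1, 21, S$pred)
  wc <- simulateScatContents(scats, tr, 0.9, seed = 2, landscape = L,
                             stacks = S$pelk)
  an <- wc[wc$elk_content %in% c("present", "absent"), ]
  phat <- mean(an$elk_content == "present")
  ci <- binom.test(sum(an$elk_content == "present"), nrow(an))$conf.int
  expect_true(ci[1] <= 0.38 && 0.38 <= ci[2])

  ## a vanishing marginal rate yields no elk-positive scats
  trZero <- tr; trZero$elkRate$wolf <- 1e-6
  wz <- simulateScatContents(scats, trZero, 0.9, seed = 2, landscape = L,
                             stacks = S$pelk)
  expect_equal(sum(wz$elk_content == "present"), 0)
  expect_error(simulateScatContents(scats, tr, 0, 1, L, S$pelk), "analyzedFraction")
})

test_that("relocations follow their utilization surface", {
  tmpl <- rasterGrid(matrix(1, 40, 40))
  rejections <- 0
  for (sd in 1:20) {
    fx <- simulateRelocations(tmpl, nAnimals = 8, nFixes = 40, seed = sd)
    qx <- (fx$x > 600) + 1; qy <- (fx$y > 600) + 1
    tab <- table(factor(qx, 1:2), factor(qy, 1:2))
    p <- suppressWarnings(chisq.test(as.numeric(tab)))$p.value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)

  point <- rasterGrid(matrix(0, 40, 40)); point@values[17, 23] <- 1
  fx <- simulateRelocations(point, nAnimals = 3, nFixes = 10, seed = 2)
  rc <- pointToCell(point, cbind(fx$x, fx$y))
  expect_true(all(rc[, 1] == 17 & rc[, 2] == 23))

  grad <- rasterGrid(matrix(rep(seq(0.1, 2, length.out = 40), each = 40), 40, 40))
  hits <- 0
  for (sd in 1:20) {
    fx <- simulateRelocations(grad, nAnimals = 6, nFixes = 40, seed = 50 + sd)
    atF <- extractAtPoints(grad, cbind(fx$x, fx$y))
    set.seed(900 + sd)
    rnd <- cbind(runif(240, 0, 1200), runif(240, 0, 1200))
    hits <- hits + (mean(atF) > mean(extractAtPoints(grad, rnd)))
  }
  expect_gte(hits, 19)
  expect_error(simulateRelocations(rasterGrid(matrix(0, 5, 5))), "all-zero")
})

test_that("kills track the risk surface and its zeros", {
  risk <- randomRaster(30, 30, seed = 40)
  risk@values[1:10, 1:10] <- 0
  kills <- simulateKills(risk, seed = 3)
  expect_equal(nrow(kills), 104)
  expect_equal(sort(as.numeric(table(kills$predator))), sort(c(42, 16, 37, 9)))
  rc <- pointToCell(risk, cbind(kills$x, kills$y))
  expect_true(all(!(rc[, 1] <= 10 & rc[, 2] <= 10)))

  big <- simulateKills(risk, composition = c(wolf = 6000), seed = 4)
  rcB <- pointToCell(risk, cbind(big$x, big$y))
  v <- risk@values[rcB]
  bins <- equalAreaBins(risk, 10)
  binOf <- attr(bins, "assignment")
  cells <- (rcB[, 2] - 1) * 30 + rcB[, 1]
  okCells <- which(!as.logical(risk@nodata))
  killBin <- binOf[match(cells, okCells)]
  freq <- as.numeric(table(factor(killBin, 1:10)))
  expect_equal(cor(1:10, freq, method = "spearman"), 1)
  expect_error(simulateKills(rasterGrid(matrix(0, 4, 4))), "all-zero")
})

test_that("old scats are excluded from downstream fitting tables", {
  L <- smallLandscape(); S <- smallStacks(); tr <- truthSet()
  transects <- generateTransects(L, 4, 1.5, seed = 5)
  scats <- simulateScats(L, transects, tr, c(wolf = 80), 0.9, 0.3, 11, S$pred)
  nOld <- sum(scats$age_class == "old")
  expect_gt(nOld, 0)
  tab <- rsfObservationTable(scats, transects, L, defaultSpecs("P_pred"),
                             stack = S$pred, nAvailable = 5, seed = 1)
  expect_equal(sum(tab$response), 80)             # used rows = non-old count
  expect_equal(nrow(tab), 80 * 6)                 # plus 5 available each
})
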