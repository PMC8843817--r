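test_that("inverse-frequency weights equalize species' weighted kill totals", {
  eq <- data.frame(predator = rep(c("bear", "wolf"), each = 6))
  expect_true(all(assignInverseFrequencyWeights(eq) == 1))

  kills <- data.frame(predator = rep(c("bear", "cougar", "wolf", "unknown"),
                                     c(42, 16, 37, 9)))
  w <- assignInverseFrequencyWeights(kills)
  expect_equal(w[kills$predator == "bear"][1], 26 / 42, tolerance = 1e-12)
  expect_equal(w[kills$predator == "cougar"][1], 1.625, tolerance = 1e-12)
  expect_equal(sum(w), 104, tolerance = 1e-12)
  tots <- tapply(w, kills$predator, sum)
  expect_true(all(abs(tots - 104 / 4) < 1e-9))
})

## build a toy strata table: S strata of one case and m controls
toyStrata <- function(S, m, beta, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in 1:S) {
    x <- rnorm(m + 1)
    eta <- beta * x
    case <- sample(m + 1, 1, prob = exp(eta))
    rows[[s]] <- data.frame(x = x, response = as.numeric(seq_len(m + 1) == case),
                            stratum = s, weight = 1)
  }
  do.call(rbind, rows)
}

test_that("the null conditional log-likelihood equals -sum w_s log(m_s + 1)", {
  tab <- toyStrata(104, 20, beta = 0.5, seed = 2)
  m <- fitConditionalLogistic(tab, response ~ x)
  expect_equal(m@recipe$null_logLik, -104 * log(21), tolerance = 1e-8)

  ## with stratum weights
  tab$weight <- rep(rep(c(0.5, 2), length.out = 104), each = 21)
  mw <- fitConditionalLogistic(tab, response ~ x)
  wPer <- rep(c(0.5, 2), length.out = 104)
  expect_equal(mw@recipe$null_logLik, -sum(wPer * log(21)), tolerance = 1e-8)
})

test_that("the maximized conditional likelihood matches hand arithmetic", {
  tab <- toyStrata(40, 5, beta = 1, seed = 3)
  m <- fitConditionalLogistic(tab, response ~ x)
  b <- unname(coef(m))
  ## hand recomputation of sum_s [x_case b - log sum_j exp(x_j b)]
  ll <- 0
  for (s in unique(tab$stratum)) {
    sub <- tab[tab$stratum == s, ]
    ll <- ll + sub$x[sub$response == 1] * b - log(sum(exp(sub$x * b)))
  }
  expect_equal(m@logLik, ll, tolerance = 1e-8)
})

test_that("unweighted fits agree exactly with survival::clogit", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  tab <- toyStrata(60, 8, beta = 0.8, seed = 4)
  tab$x2 <- rnorm(nrow(tab))
  m <- fitConditionalLogistic(tab, response ~ x + x2)
  cf <- survival::clogit(response ~ x + x2 + strata(stratum),
                         data = tab, method = "breslow")
  expect_equal(unname(coef(m)), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(m@logLik, as.numeric(logLik(cf)), tolerance = 1e-6)
})

test_that("conditional fits are invariant to within-stratum constant shifts", {
  tab <- toyStrata(30, 6, beta = 0.6, seed = 5)
  shifted <- tab
  for (s in unique(tab$stratum))
    shifted$x[shifted$stratum == s] <-
      shifted$x[shifted$stratum == s] + s * 3.7
  m1 <- fitConditionalLogistic(tab, response ~ x)
  m2 <- fitConditionalLogistic(shifted, response ~ x)
  expect_equal(coef(m1), coef(m2), tolerance = 1e-8)
  expect_equal(m1@logLik, m2@logLik, tolerance = 1e-8)
})

test_that("degenerate strata raise explicit errors", {
  tab <- toyStrata(10, 4, beta = 0, seed = 6)
  tab$x <- ave(tab$x, tab$stratum)  # constant within every stratum
  expect_error(fitConditionalLogistic(tab, response ~ x),
               "no within-stratum covariate variation")
  one <- toyStrata(1, 4, beta = 0, seed = 7)
  expect_error(fitConditionalLogistic(one, response ~ x), "two strata")
  sep <- toyStrata(25, 3, beta = 0, seed = 8)
  sep$x <- sep$response * 10  # case always has the largest x
  expect_error(fitConditionalLogistic(sep, response ~ x), "separation")
})

test_that("matched controls stay inside the disc and off masked ground", {
  L <- smallLandscape()
  kill <- list(x = 900, y = 900, id = 1L, predator = "wolf")
  st <- sampleKillControls(kill, L, n = 20, radius = 700, seed = 9)
  d <- sqrt((st$controls[, 1] - 900)^2 + (st$controls[, 2] - 900)^2)
  expect_true(all(d <= 700))
  rc <- pointToCell(L@rasters[[1]], st$controls)
  expect_true(all(!L@exclusionMask[rc]))
  st2 <- sampleKillControls(kill, L, n = 20, radius = 700, seed = 9)
  expect_identical(st$controls, st2$controls)
  expect_error(sampleKillControls(kill, L, n = 0), "control")
})

test_that("kill-model recovery and prediction preserve coefficient signs", {
  L <- smallLandscape(); S <- smallStacks(); tr <- truthSet()
  ST <- trueSurfaces(L, S, tr)
  kills <- simulateKills(ST$kill, composition = c(wolf = 80), seed = 10)
  ktab <- killStrataTable(kills, L, S$kill, n = 15, radius = 5000, seed = 11)
  m <- fitConditionalLogistic(ktab, response ~ distwater + herbfg)
  ## strong generating effects keep their signs
  expect_lt(coef(m)[["distwater"]], 0)
  expect_gt(coef(m)[["herbfg"]], 0)
  surf <- predictPrKill(m, L, S$kill)
  expect_equal(surf@component, "PR_kill")
  v <- surf@raster@values[!surf@raster@nodata]
  expect_equal(min(v), 0); expect_equal(max(v), 1)
  ## monotonicity: raising a positive-coefficient covariate raises the
  ## pre-scaled prediction
  S2 <- S$kill
  S2$herbfg@values <- S2$herbfg@values + 1
  r1 <- predictRsf(m, L, S$kill)
  r2 <- predictRsf(m, L, S2)
  expect_true(all(r2@values >= r1@values))
})
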