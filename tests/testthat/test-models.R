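test_that("corridor availability sampling respects the truncated geometry", {
  tr <- straightTransect(0, 500, 3000)
  scat <- list(x = 1500, y = 510, transect_id = 1)
  expect_equal(nrow(sampleAvailableLinear(scat, tr, n = 0)), 0)
  pts <- sampleAvailableLinear(scat, tr, n = 200, seed = 6)
  expect_true(all(pts[, 1] >= 1500 - 650 & pts[, 1] <= 1500 + 650))
  expect_true(all(abs(pts[, 2] - 500) <= 25))
  ## truncation (not reflection) at the transect start
  near <- sampleAvailableLinear(list(x = 100, y = 500, transect_id = 1),
                                tr, n = 200, seed = 7)
  expect_true(all(near[, 1] >= 0 & near[, 1] <= 750))
  short <- list(polyline = cbind(c(0, 1), c(0, 0)))
  expect_error(sampleAvailableLinear(list(x = 0, y = 0), short, n = 1,
                                     corridorLength = 0), "zero length")
})

test_that("logistic fits reproduce the intercept-only closed forms", {
  tab <- data.frame(response = c(rep(1, 10), rep(0, 100)))
  m <- fitLogistic(tab, response ~ 1)
  expect_equal(unname(coef(m)), log(10 / 100), tolerance = 1e-8)
  lnL <- 10 * log(10 / 110) + 100 * log(100 / 110)
  expect_equal(m@logLik, lnL, tolerance = 1e-8)
  want <- -2 * lnL + 2 * 1 + 2 * 1 * 2 / (110 - 1 - 1)
  expect_equal(aicc(m), want, tolerance = 1e-8)
  expect_equal(aicc(m), 69.057, tolerance = 1e-3)
})

test_that("logistic MLE matches a derivative-free optimizer on tiny data", {
  set.seed(44)
  tab <- data.frame(x1 = rnorm(10), x2 = rnorm(10),
                    response = rbinom(10, 1, 0.5))
  if (length(unique(tab$response)) < 2) tab$response[1] <- 1 - tab$response[1]
  m <- fitLogistic(tab, response ~ x1 + x2)
  negll <- function(b) {
    eta <- b[1] + b[2] * tab$x1 + b[3] * tab$x2
    -sum(tab$response * eta - log(1 + exp(eta)))
  }
  o <- optim(c(0, 0, 0), negll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(unname(coef(m)), o$par, tolerance = 1e-5)
  expect_equal(m@logLik, -o$value, tolerance = 1e-8)
})

test_that("degenerate logistic designs raise explicit errors", {
  sep <- data.frame(x = c(-3, -2, -1, 1, 2, 3), response = c(0, 0, 0, 1, 1, 1))
  expect_error(fitLogistic(sep, response ~ x), "separation")
  expect_error(fitLogistic(data.frame(response = rep(1, 5)), response ~ 1),
               "single-class")
  const <- data.frame(x = rep(2, 10), response = rep(c(0, 1), 5))
  expect_error(fitLogistic(const, response ~ x), "rank-deficient")
})

test_that("AICc selection prefers parsimonious, cleanly identified models", {
  set.seed(55)
  n <- 2000
  picks <- 0
  for (rep in 1:20) {
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.8 * x1))  # x2 has no effect
    tab <- data.frame(x1 = x1, x2 = x2, response = y)
    sel <- aiccSelect(list(response ~ x1 + x2, response ~ x1), tab)
    if (sel@formula == "response ~ x1") picks <- picks + 1
  }
  expect_gte(picks, 18)

  only <- aiccSelect(list(response ~ x1),
                     data.frame(x1 = rnorm(50),
                                response = rbinom(50, 1, 0.4)))
  expect_equal(only@formula, "response ~ x1")
  expect_error(aiccSelect(list(), data.frame()), "empty candidate")
})

test_that("parsimony screening keeps real effects and drops null ones", {
  set.seed(66)
  n <- 1500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x1))
  tab <- data.frame(x1 = x1, x2 = x2, response = y)
  sel <- parsimonySelect(tab, response ~ x1 + x2)
  expect_equal(sel@formula, "response ~ x1")
  ## nothing identified: the intercept-only candidate wins on parsimony
  y0 <- rbinom(n, 1, 0.3)
  tab0 <- data.frame(x1 = x1, x2 = x2, response = y0)
  sel0 <- parsimonySelect(tab0, response ~ x1 + x2)
  expect_equal(sel0@formula, "response ~ 1")
})

test_that("exponential RSF prediction drops the intercept and evaluates Table-style terms", {
  L <- smallLandscape()
  d <- dim(L@rasters[[1]]@values)
  mk <- function(v, nm) rasterGrid(matrix(v, d[1], d[2]), cellSize = 30,
                                   name = nm)
  stack <- list(conifer = mk(1, "conifer"), edgedens = mk(0, "edgedens"))
  cougar <- makeFittedModel(
    c("(Intercept)" = -4, conifer = -1.92, edgedens = 8.39),
    diag(3), logLik = -10, n = 100, stage = "P_pred", species = "cougar",
    formula = "response ~ conifer + edgedens")
  w <- predictRsf(cougar, L, stack)
  expect_equal(w@values[1, 1], exp(-1.92), tolerance = 1e-9)
  expect_equal(exp(-1.92), 0.1466, tolerance = 1e-3)

  flat <- makeFittedModel(c("(Intercept)" = 2), matrix(1), -5, 50,
                          "P_pred", "wolf", "response ~ 1")
  expect_true(all(predictRsf(flat, L, stack)@values == 1))
})

test_that("selection ratios are invariant to constant covariate shifts", {
  set.seed(77)
  n <- 800
  x <- rnorm(n); z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.7 * x - 0.4 * z))
  t1 <- data.frame(x = x, z = z, response = y)
  t2 <- data.frame(x = x + 5, z = z, response = y)
  m1 <- fitLogistic(t1, response ~ x + z)
  m2 <- fitLogistic(t2, response ~ x + z)
  expect_equal(coef(m1)[c("x", "z")], coef(m2)[c("x", "z")], tolerance = 1e-7)
})

test_that("elk-in-scat fits run on the analyzed/not-analyzed contrast", {
  L <- smallLandscape(); S <- smallStacks(); tr <- truthSet()
  transects <- generateTransects(L, 4, 1.5, seed = 5)
  scats <- simulateScats(L, transects, tr, c(wolf = 250), 0.9, 0.1, 13, S$pred)
  scats <- simulateScatContents(scats, tr, 0.4, 14, L, S$pelk)
  ## species buffer radii exceed the toy landscape, so use a small radius
  sp300 <- list(herbfg = covariateSpec("herbfg", "herbfg", "buffer_mean", 300))
  st300 <- covariateStack(L, sp300)
  m <- fitPelk(scats, "wolf", L, st300, response ~ herbfg, specs = sp300)
  expect_equal(m@stage, "P_elk")
  expect_equal(m@recipe$n_used + m@recipe$n_avail, m@n)
  ## all-analyzed, none with elk: single-class error
  s2 <- scats[scats$age_class != "old", ]
  s2$elk_content <- "absent"
  expect_error(fitPelk(s2, "wolf", L, st300, specs = sp300), "single-class")
})

test_that("fitted models round-trip through JSON", {
  m <- makeFittedModel(c("(Intercept)" = -1.2, slope = -0.04),
                       matrix(c(0.04, 0.001, 0.001, 0.0001), 2, 2,
                              dimnames = list(c("(Intercept)", "slope"),
                                              c("(Intercept)", "slope"))),
                       logLik = -321.5, n = 500, stage = "P_pred",
                       species = "wolf", formula = "response ~ slope",
                       recipe = list(radius = 1300))
  f <- tempfile(fileext = ".json")
  writeFittedModel(m, f)
  m2 <- readFittedModel(f)
  expect_equal(coef(m2), coef(m))
  expect_equal(m2@vcov, m@vcov)
  expect_equal(aicc(m2), aicc(m))
  expect_equal(m2@recipe$radius, 1300)
})
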