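#' Matched random controls for one kill site
#'
#' Draws n points uniformly from the disc of the given radius around the
#' kill, intersected with the study region and excluding masked cells
#' (controls are resampled until they land on usable ground).
#'
#' @param kill list/row with \code{x}, \code{y}, \code{id}, \code{predator}.
#' @param landscape Landscape.
#' @param n controls per kill, default 20.
#' @param radius disc radius (m), default 13200 (largest average daily
#'   predator movement).
#' @param seed optional integer seed.
#' @return list: \code{case} (x, y), \code{controls} (n x 2 matrix),
#'   \code{stratum_id}, \code{predator}.
#' @export
sampleKillControls <- function(kill, landscape, n = 20, radius = 13200,
                               seed = NULL) {
  if (n < 1) stop("need at least one control")
  if (radius <= 0) stop("radius must be positive")
  tmpl <- landscape@rasters[[1]]
  d <- dim(tmpl@values); h <- tmpl@cellSize
  xr <- tmpl@origin[1] + c(0, d[2] * h)
  yr <- tmpl@origin[2] + c(0, d[1] * h)
  draw <- function() {
    out <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(out) < n) {
      tries <- tries + 1
      if (tries > 200) stop("disc entirely masked or outside study region")
      m <- 4 * n
      ang <- stats::runif(m, 0, 2 * pi)
      rad <- radius * sqrt(stats::runif(m))
      px <- kill$x + rad * cos(ang); py <- kill$y + rad * sin(ang)
      keep <- px > xr[1] & px < xr[2] & py > yr[1] & py < yr[2]
      if (any(keep)) {
        rc <- pointToCell(tmpl, cbind(px[keep], py[keep]))
        keep2 <- !landscape@exclusionMask[rc]
        out <- rbind(out, cbind(px[keep][keep2], py[keep][keep2]))
      }
    }
    out[seq_len(n), , drop = FALSE]
  }
  ctrl <- if (is.null(seed)) draw() else withSeed(seed, draw())
  list(case = c(x = kill$x, y = kill$y), controls = ctrl,
       stratum_id = kill$id, predator = kill$predator)
}

#' Inverse-frequency stratum weights by predator species
#'
#' Weight for a kill of species s is (N_total / S) / n_s with S the number
#' of predator classes present, so each species' weighted total equals
#' N_total / S and the weights sum to N_total. Kills of unknown predator
#' form their own class.
#'
#' @param kills kill data.frame with a \code{predator} column.
#' @return numeric weight per kill (row order preserved).
#' @export
assignInverseFrequencyWeights <- function(kills) {
  tab <- table(kills$predator)
  if (any(tab == 0)) stop("species with zero kills")
  S <- length(tab)
  N <- nrow(kills)
  w <- (N / S) / as.numeric(tab[kills$predator])
  as.numeric(w)
}

#' Conditional logistic regression over matched strata
#'
#' Maximizes the stratum-conditional likelihood
#' \deqn{\prod_s [\exp(x_{case}'\beta) / \sum_{j \in s} \exp(x_j'\beta)]^{w_s}}
#' by Newton-Raphson (no intercept; it is absorbed by stratification).
#' Stratum weights enter as likelihood powers. Perfect within-stratum
#' separation is reported as an error.
#'
#' @param strataTable data.frame with columns \code{stratum}, \code{response}
#'   (1 = case, 0 = control), \code{weight} (constant within stratum), and
#'   covariate columns.
#' @param formula covariate formula (right-hand side only is used).
#' @param species tag, default "all".
#' @return a \linkS4class{FittedModel}, stage "PR_kill"; \code{n} is the
#'   number of strata.
#' @export
fitConditionalLogistic <- function(strataTable, formula = NULL,
                                   species = "all") {
  if (is.null(formula)) {
    covs <- setdiff(names(strataTable),
                    c("point_id", "x", "y", "response", "stratum", "weight",
                      "cluster"))
    formula <- stats::reformulate(covs, response = "response")
  }
  if (is.character(formula)) formula <- stats::as.formula(formula)
  X <- stats::model.matrix(stats::delete.response(stats::terms(formula)),
                           strataTable)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  y <- strataTable$response
  sid <- strataTable$stratum
  w <- if (!is.null(strataTable$weight)) strataTable$weight else rep(1, nrow(X))
  strata <- split(seq_len(nrow(X)), sid)
  nS <- length(strata)
  if (nS < 2) stop("need at least two strata")
  for (ix in strata) if (sum(y[ix]) != 1) stop("each stratum needs exactly one case")
  ## within-stratum variation check
  anyVar <- FALSE
  for (ix in strata) if (any(apply(X[ix, , drop = FALSE], 2,
                                   function(v) length(unique(v)) > 1))) {
    anyVar <- TRUE; break
  }
  if (!anyVar) stop("no within-stratum covariate variation")

  p <- ncol(X)
  beta <- rep(0, p)
  sdx <- apply(X, 2, stats::sd); sdx[sdx == 0] <- 1
  objective <- function(b) {
    ll <- 0; grad <- rep(0, p); hess <- matrix(0, p, p)
    meat <- matrix(0, p, p)
    for (ix in strata) {
      Xi <- X[ix, , drop = FALSE]
      eta <- drop(Xi %*% b)
      eta <- eta - max(eta)
      pi <- exp(eta) / sum(exp(eta))
      ci <- which(y[ix] == 1)
      ws <- w[ix][1]
      ll <- ll + as.numeric(ws * (eta[ci] - log(sum(exp(eta)))))
      xbar <- drop(crossprod(pi, Xi))
      gs <- ws * (Xi[ci, ] - xbar)
      grad <- grad + gs
      meat <- meat + tcrossprod(gs)
      hess <- hess - ws * (crossprod(Xi * pi, Xi) - tcrossprod(xbar))
    }
    list(ll = ll, grad = grad, hess = hess, meat = meat)
  }
  ll0 <- objective(beta)$ll
  conv <- FALSE
  for (it in 1:50) {
    o <- objective(beta)
    step <- tryCatch(solve(o$hess, o$grad), error = function(e) NULL)
    if (is.null(step)) stop("singular Hessian in conditional logistic fit")
    newB <- beta - step
    ## step halving if likelihood decreases
    halve <- 0
    while (objective(newB)$ll < o$ll - 1e-12 && halve < 30) {
      newB <- (beta + newB) / 2; halve <- halve + 1
    }
    if (max(abs(newB - beta)) < 1e-10) { beta <- newB; conv <- TRUE; break }
    beta <- newB
    if (any(abs(beta * sdx) > 15))
      stop("separation: diverging coefficients in conditional logistic fit")
  }
  o <- objective(beta)
  ## sandwich variance: with stratum weights as likelihood powers the
  ## model-based inverse information is not consistent for the estimator's
  ## variance; the robust form reduces to near-model-based when weights are 1
  A <- solve(-o$hess)
  vcov <- A %*% o$meat %*% A
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  makeFittedModel(beta, vcov, o$ll, nS, "PR_kill", species,
                  paste(deparse(formula), collapse = " "), conv,
                  recipe = list(n_strata = nS, null_logLik = ll0))
}

#' Build the matched observation table for the kill-site model
#'
#' One stratum per kill: the case plus its matched random controls, with
#' 250-m buffer covariates and inverse-frequency stratum weights.
#'
#' @param kills kill data.frame (id, x, y, predator).
#' @param landscape Landscape.
#' @param stack kill-stage covariate stack.
#' @param specs covariate specs; default \code{defaultSpecs("PR_kill")}.
#' @param n controls per kill, default 20.
#' @param radius control disc radius (m), default 13200.
#' @param seed integer seed.
#' @return observation data.frame with stratum and weight columns.
#' @export
killStrataTable <- function(kills, landscape, stack, specs = NULL, n = 20,
                            radius = 13200, seed = 1) {
  if (is.null(specs)) specs <- defaultSpecs("PR_kill")
  wts <- assignInverseFrequencyWeights(kills)
  withSeed(seed, {
    rows <- vector("list", nrow(kills))
    for (i in seq_len(nrow(kills))) {
      st <- sampleKillControls(kills[i, ], landscape, n = n, radius = radius)
      pts <- rbind(c(kills$x[i], kills$y[i]), st$controls)
      rows[[i]] <- data.frame(x = pts[, 1], y = pts[, 2],
                              response = c(1, rep(0, n)),
                              stratum = kills$id[i], weight = wts[i])
    }
    allRows <- do.call(rbind, rows)
    buildDesignMatrix(cbind(allRows$x, allRows$y), specs, landscape,
                      stack = stack, response = allRows$response,
                      stratum = allRows$stratum, weight = allRows$weight)
  })
}

#' Predict the kill-site predation risk surface
#'
#' Per-cell \code{exp(x' beta)} with kill-stage (250-m buffer) covariates,
#' scaled to [0, 1].
#'
#' @param model FittedModel from \code{\link{fitConditionalLogistic}}.
#' @param landscape Landscape.
#' @param stack kill-stage covariate stack.
#' @return RiskSurface, component "PR_kill".
#' @export
predictPrKill <- function(model, landscape, stack) {
  r <- predictRsf(model, landscape, stack)
  asRiskSurface(scale01(r), "total", "PR_kill",
                list(formula = model@formula))
}
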