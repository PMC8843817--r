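## Matern (smoothness 1) correlation: rho(d) = (d/phi) K_1(d/phi).
maternCorrelation <- function(d, range) {
  u <- d / range
  out <- ifelse(u <= 0, 1, u * besselK(pmin(u, 700), 1))
  out[!is.finite(out)] <- 1
  out
}

#' Generalized least squares with Matern-correlated errors
#'
#' Profile-likelihood GLS for fixed correlation parameters: the error
#' covariance is \code{sigma^2 ((1 - nugget) R(range) + nugget I)} with
#' Matern smoothness 1. Exposed so the independence limit (range -> 0) can
#' be checked against ordinary least squares.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param D distance matrix between observations (m).
#' @param range Matern range parameter (m).
#' @param nugget nugget proportion in [0, 1).
#' @return list: beta, vcov, sigma2, logLik.
#' @export
maternGls <- function(y, X, D, range, nugget) {
  n <- length(y)
  R <- (1 - nugget) * maternCorrelation(D, range) + nugget * diag(n)
  ch <- chol(R + 1e-10 * diag(n))
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  XtX <- crossprod(Xi)
  beta <- solve(XtX, crossprod(Xi, yi))
  r <- yi - Xi %*% beta
  sigma2 <- sum(r^2) / n
  logLik <- -0.5 * n * log(sigma2) - sum(log(diag(ch))) -
    0.5 * n * (1 + log(2 * pi))
  list(beta = drop(beta), vcov = sigma2 * solve(XtX), sigma2 = sigma2,
       logLik = logLik)
}

#' Fit a population-level resource utilization function
#'
#' Estimates the utilization distribution of pooled relocations by kernel
#' density (reference bandwidth) on the analysis grid, then regresses UD
#' height on covariates by maximum-likelihood GLS with Matern-correlated
#' errors (smoothness fixed at 1; range and nugget estimated), falling back
#' to ordinary least squares with a warning if the ML search fails. The
#' prediction surface is the fitted linear predictor floored at zero and
#' min-max scaled.
#'
#' @param relocations data.frame with x, y (pooled fixes; >= 100).
#' @param landscape Landscape.
#' @param stack RUF-stage covariate stack.
#' @param specs covariate specs; default \code{defaultSpecs("RUF")}.
#' @param formula regression formula; default additive in spec names.
#' @param nSample cells used in the GLS stage (spatial subsample).
#' @param independence fit the independence (OLS) model instead of Matern.
#' @return list: \code{ud} (RasterGrid), \code{model} (FittedModel, stage
#'   "RUF"), \code{prediction} (RasterGrid in [0, 1]).
#' @export
fitRuf <- function(relocations, landscape, stack, specs = NULL,
                   formula = NULL, nSample = 400, independence = FALSE) {
  if (nrow(relocations) < 100) stop("need >= 100 pooled relocations")
  if (is.null(specs)) specs <- defaultSpecs("RUF")
  tmpl <- landscape@rasters[[1]]
  d <- dim(tmpl@values); h <- tmpl@cellSize
  ## evaluate the KDE exactly at cell centers
  ext <- c(tmpl@origin[1] + h / 2, tmpl@origin[1] + (d[2] - 0.5) * h,
           tmpl@origin[2] + h / 2, tmpl@origin[2] + (d[1] - 0.5) * h)
  bw <- c(MASS::bandwidth.nrd(relocations$x), MASS::bandwidth.nrd(relocations$y))
  if (any(!is.finite(bw))) stop("KDE bandwidth is undefined")
  bw[bw <= 0] <- h  # degenerate point cloud: fall back to one-cell bandwidth
  kd <- MASS::kde2d(relocations$x, relocations$y, h = bw, n = c(d[2], d[1]),
                    lims = ext)
  ud <- rasterGrid(t(kd$z), tmpl@origin, h, landscape@exclusionMask, "ud")
  ## regression response: UD height scaled to [0, 1] (raw kernel densities
  ## are O(1e-8) per m^2, which degrades the ML surface numerically)
  udS <- scale01(ud)

  covNames <- vapply(specs, `[[`, "", "name")
  if (is.null(formula))
    formula <- stats::reformulate(covNames, response = "udh")
  if (is.character(formula)) formula <- stats::as.formula(formula)

  ok <- which(!landscape@exclusionMask)
  take <- ok[seq(1, length(ok), length.out = min(nSample, length(ok)))]
  rr <- (take - 1L) %% d[1] + 1L; cc <- (take - 1L) %/% d[1] + 1L
  df <- data.frame(udh = udS@values[cbind(rr, cc)])
  for (nm in covNames) df[[nm]] <- stack[[nm]]@values[cbind(rr, cc)]
  X <- stats::model.matrix(stats::delete.response(stats::terms(formula)), df)
  y <- df$udh
  px <- tmpl@origin[1] + (cc - 0.5) * h
  py <- tmpl@origin[2] + (rr - 0.5) * h
  D <- as.matrix(stats::dist(cbind(px, py)))
  n <- length(y)

  fitOLS <- function() {
    lmf <- stats::lm.fit(X, y)
    s2 <- sum(lmf$residuals^2) / n
    list(beta = lmf$coefficients,
         vcov = s2 * solve(crossprod(X)),
         logLik = -0.5 * n * log(s2) - 0.5 * n * (1 + log(2 * pi)),
         kExtra = 1, recipe = list(correlation = "independence"))
  }
  res <- NULL
  if (!independence) {
    ## the KDE surface is itself smooth, so unconstrained ML drives the
    ## range to the domain scale and the GLS turns ill-conditioned; bound
    ## the range near the bandwidth scale and keep a small nugget floor
    rangeMax <- 3 * mean(bw)
    nugMin <- 0.01
    obj <- function(par) {
      if (exp(par[1]) > rangeMax || exp(par[1]) < h / 10) return(1e10)
      g <- try(maternGls(y, X, D, exp(par[1]),
                         nugMin + (1 - nugMin) * stats::plogis(par[2])),
               silent = TRUE)
      if (inherits(g, "try-error") || !is.finite(g$logLik)) 1e10 else -g$logLik
    }
    opt <- try(stats::optim(c(log(10 * h), stats::qlogis(0.3)), obj,
                            method = "Nelder-Mead",
                            control = list(maxit = 200)), silent = TRUE)
    if (!inherits(opt, "try-error") && opt$value < 1e9) {
      nug <- nugMin + (1 - nugMin) * stats::plogis(opt$par[2])
      g <- maternGls(y, X, D, exp(opt$par[1]), nug)
      res <- list(beta = g$beta, vcov = g$vcov, logLik = g$logLik, kExtra = 3,
                  recipe = list(correlation = "matern",
                                range = exp(opt$par[1]), nugget = nug))
    } else warning("Matern ML failed to converge; falling back to OLS")
  }
  if (is.null(res)) res <- fitOLS()

  beta <- res$beta
  names(beta) <- colnames(X)
  model <- makeFittedModel(beta, res$vcov, res$logLik, n, "RUF", "elk",
                           paste(deparse(formula), collapse = " "), TRUE, res$recipe)

  dfAll <- as.data.frame(lapply(stack[covNames],
                                function(r) as.numeric(r@values)))
  XA <- stats::model.matrix(stats::delete.response(stats::terms(formula)), dfAll)
  pred <- pmax(0, drop(XA %*% beta))
  predR <- scale01(rasterGrid(matrix(pred, d[1], d[2]), tmpl@origin, h,
                              landscape@exclusionMask, "ruf_pred"))
  list(ud = ud, model = model, prediction = predR)
}
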