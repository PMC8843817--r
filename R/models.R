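#' Available points in a linear corridor around a scat
#'
#' Samples n uniform points in a corridor of total length
#' \code{corridorLength} (half each side of the scat) and total width
#' \code{corridorWidth}, oriented along the scat's transect and truncated
#' (not reflected) at the transect ends.
#'
#' @param scat list/row with \code{x}, \code{y}, \code{transect_id}.
#' @param transect the transect list element (with \code{polyline}).
#' @param corridorWidth total width (m), default 50.
#' @param corridorLength total length (m), default 1300.
#' @param n number of points, default 10.
#' @param seed optional integer seed (NULL inherits the RNG stream).
#' @return n x 2 matrix of coordinates.
#' @export
sampleAvailableLinear <- function(scat, transect, corridorWidth = 50,
                                  corridorLength = 1300, n = 10, seed = NULL) {
  if (n < 0) stop("n must be nonnegative")
  if (n == 0) return(matrix(numeric(), 0, 2))
  p <- transect$polyline
  segLen <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  cum <- c(0, cumsum(segLen))
  L <- cum[length(cum)]
  ## arc position of the scat = position of its projection on the polyline
  best <- Inf; s0 <- 0
  for (i in seq_len(nrow(p) - 1)) {
    vx <- p[i + 1, 1] - p[i, 1]; vy <- p[i + 1, 2] - p[i, 2]
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else
      min(1, max(0, ((scat$x - p[i, 1]) * vx + (scat$y - p[i, 2]) * vy) / L2))
    dd <- (scat$x - p[i, 1] - t * vx)^2 + (scat$y - p[i, 2] - t * vy)^2
    if (dd < best) { best <- dd; s0 <- cum[i] + t * segLen[i] }
  }
  lo <- max(0, s0 - corridorLength / 2)
  hi <- min(L, s0 + corridorLength / 2)
  if (hi <= lo) stop("corridor truncation leaves zero length")
  draw <- function() {
    s <- stats::runif(n, lo, hi)
    off <- stats::runif(n, -corridorWidth / 2, corridorWidth / 2)
    seg <- findInterval(s, cum, rightmost.closed = TRUE)
    seg[seg >= nrow(p)] <- nrow(p) - 1L
    t <- (s - cum[seg]) / segLen[seg]
    ux <- (p[seg + 1, 1] - p[seg, 1]) / segLen[seg]
    uy <- (p[seg + 1, 2] - p[seg, 2]) / segLen[seg]
    cbind(p[seg, 1] + t * segLen[seg] * ux - off * uy,
          p[seg, 2] + t * segLen[seg] * uy + off * ux)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Use/available observation table for a scat RSF
#'
#' Non-old scats of one species are the used points (response 1); each
#' contributes \code{nAvailable} random points from its linear corridor
#' (response 0).
#'
#' @param scats scat data.frame (one species).
#' @param transects transect list.
#' @param landscape Landscape.
#' @param specs covariate specs (encounter stage).
#' @param stack precomputed covariate stack (strongly recommended).
#' @param nAvailable available points per scat, default 10.
#' @param seed integer seed for availability sampling.
#' @return observation data.frame (see \code{\link{buildDesignMatrix}}).
#' @export
rsfObservationTable <- function(scats, transects, landscape, specs,
                                stack = NULL, nAvailable = 10, seed = 1) {
  scats <- scats[scats$age_class != "old", , drop = FALSE]
  if (!nrow(scats)) stop("no usable scats")
  withSeed(seed, {
    avail <- vector("list", nrow(scats))
    for (i in seq_len(nrow(scats)))
      avail[[i]] <- sampleAvailableLinear(scats[i, ],
                                          transects[[scats$transect_id[i]]],
                                          n = nAvailable)
    av <- do.call(rbind, avail)
    pts <- rbind(cbind(scats$x, scats$y), av)
    resp <- c(rep(1, nrow(scats)), rep(0, nrow(av)))
    ## clamp availability points to the grid (corridors can graze the border)
    tmpl <- landscape@rasters[[1]]
    d <- dim(tmpl@values); h <- tmpl@cellSize
    pts[, 1] <- pmin(pmax(pts[, 1], tmpl@origin[1] + 1e-6),
                     tmpl@origin[1] + d[2] * h - 1e-6)
    pts[, 2] <- pmin(pmax(pts[, 2], tmpl@origin[2] + 1e-6),
                     tmpl@origin[2] + d[1] * h - 1e-6)
    out <- buildDesignMatrix(pts, specs, landscape, stack = stack,
                             response = resp)
    ## rows cluster by scat: the used point plus its matched availability set
    out$cluster <- c(seq_len(nrow(scats)),
                     rep(seq_len(nrow(scats)), each = nAvailable))
    out
  })
}

#' Construct a FittedModel from fit ingredients
#'
#' Computes AICc from the log-likelihood (the class validity enforces the
#' small-sample identity) and Wald 95\% limits from the covariance diagonal.
#'
#' @param coefs named coefficient vector.
#' @param vcov covariance matrix.
#' @param logLik maximized log-likelihood.
#' @param n rows (strata for matched designs).
#' @param stage,species,formula model tags.
#' @param converged logical.
#' @param recipe design metadata list.
#' @return a \linkS4class{FittedModel}.
#' @export
makeFittedModel <- function(coefs, vcov, logLik, n, stage, species, formula,
                            converged = TRUE, recipe = list()) {
  k <- length(coefs)
  aicc <- -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  se <- sqrt(diag(vcov))
  ci <- cbind(lower = coefs - 1.96 * se, upper = coefs + 1.96 * se)
  rownames(ci) <- names(coefs)
  new("FittedModel", coef = coefs, vcov = vcov, logLik = as.numeric(logLik),
      k = k, n = n, aicc = aicc, ci = ci, stage = stage, species = species,
      formula = formula, converged = converged, recipe = recipe)
}

#' Fit a logistic regression for a use/available design
#'
#' Maximum-likelihood logistic regression (optionally row-weighted) with the
#' convergence and degeneracy checks a selection analysis needs: both
#' response classes present, full column rank, no separation (|beta| > 15 on
#' standardized covariates raises an error).
#'
#' @param table observation data.frame with a 0/1 \code{response} column,
#'   optional \code{weight}, and covariate columns.
#' @param formula model formula, default all covariate columns additively.
#' @param stage,species tags stored in the model.
#' @param recipe design metadata list.
#' @param cluster optional grouping vector (length nrow(table)): confidence
#'   intervals then use the cluster-robust sandwich variance, the standard
#'   correction for use/available designs whose availability points are
#'   matched to a used point.
#' @return a \linkS4class{FittedModel}.
#' @export
fitLogistic <- function(table, formula = NULL, stage = "P_pred",
                        species = "all", recipe = list(), cluster = NULL) {
  if (is.null(formula)) {
    covs <- setdiff(names(table), c("point_id", "x", "y", "response",
                                    "stratum", "weight", "cluster"))
    formula <- stats::reformulate(covs, response = "response")
  }
  if (is.character(formula)) formula <- stats::as.formula(formula)
  y <- table$response
  if (length(unique(y[!is.na(y)])) < 2) stop("single-class input")
  X <- stats::model.matrix(formula, table)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design (constant or aliased column)")
  table$.wcol <- if (!is.null(table$weight)) table$weight else rep(1, nrow(table))
  fit <- suppressWarnings(
    stats::glm(formula, family = stats::binomial(), data = table,
               weights = .wcol,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- stats::coef(fit)
  sdx <- apply(X, 2, stats::sd)
  slopes <- sdx > 0  # separation is judged on standardized slopes only
  if (any(abs(beta[slopes] * sdx[slopes]) > 15) || !fit$converged)
    stop("separation: diverging coefficients in logistic fit")
  vc <- stats::summary.glm(fit)$cov.scaled
  if (!is.null(cluster)) {
    g <- X * (table$.wcol * (y - stats::fitted(fit)))
    gc <- rowsum(g, cluster)
    vc <- vc %*% crossprod(as.matrix(gc)) %*% vc
    recipe$vcov <- "cluster-robust"
  }
  makeFittedModel(beta, vc,
                  as.numeric(stats::logLik(fit)), nrow(table), stage, species,
                  paste(deparse(formula), collapse = " "), fit$converged, recipe)
}

#' Serialize a fitted model to JSON
#'
#' Stores names, coefficients, covariance, log-likelihood, k, n, AICc,
#' confidence limits and the design recipe; \code{\link{readFittedModel}}
#' restores an identical object.
#'
#' @param model FittedModel.
#' @param path output file.
#' @export
writeFittedModel <- function(model, path) {
  jsonlite::write_json(list(
    coef = as.list(model@coef), vcov = model@vcov, logLik = model@logLik,
    k = model@k, n = model@n, aicc = model@aicc,
    ci = list(lower = model@ci[, 1], upper = model@ci[, 2]),
    stage = model@stage, species = model@species, formula = model@formula,
    converged = model@converged, recipe = model@recipe),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted model from JSON
#' @param path file written by \code{\link{writeFittedModel}}.
#' @return FittedModel.
#' @export
readFittedModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- unlist(j$coef)
  vc <- matrix(unlist(j$vcov), length(cf), length(cf),
               dimnames = list(names(cf), names(cf)))
  ci <- cbind(lower = unlist(j$ci$lower), upper = unlist(j$ci$upper))
  rownames(ci) <- names(cf)
  new("FittedModel", coef = cf, vcov = vc, logLik = j$logLik, k = j$k,
      n = j$n, aicc = j$aicc, ci = ci, stage = j$stage, species = j$species,
      formula = j$formula, converged = j$converged,
      recipe = as.list(j$recipe))
}

#' AICc model selection with a parsimony rule
#'
#' Fits every candidate formula, forms the competing set within 4 AICc of
#' the minimum and, within it, prefers models in which every (non-intercept)
#' coefficient has a 95% CI excluding zero; remaining ties go to the fewest
#' parameters, then the lowest AICc.
#'
#' @param candidates list (or character vector) of model formulas.
#' @param table observation data.frame.
#' @param fitter fitting function with signature (table, formula, ...);
#'   default \code{\link{fitLogistic}}.
#' @param deltaAicc competing-set width, default 4.
#' @param ... passed to the fitter.
#' @return the selected \linkS4class{FittedModel}; the full AICc table is
#'   attached as attribute \code{"aiccTable"}, all fits as \code{"fits"}.
#' @export
aiccSelect <- function(candidates, table, fitter = fitLogistic,
                       deltaAicc = 4, ...) {
  if (!length(candidates)) stop("empty candidate set")
  fits <- lapply(candidates, function(f) fitter(table, f, ...))
  aiccs <- vapply(fits, aicc, numeric(1))
  delta <- aiccs - min(aiccs)
  competing <- which(delta <= deltaAicc)
  cleanCI <- vapply(fits[competing], function(m) {
    ci <- m@ci
    drop <- rownames(ci) %in% "(Intercept)"
    all(sign(ci[!drop, 1]) == sign(ci[!drop, 2]) & ci[!drop, 1] != 0)
  }, logical(1))
  pool <- if (any(cleanCI)) competing[cleanCI] else competing
  ks <- vapply(fits[pool], function(m) m@k, numeric(1))
  pool <- pool[ks == min(ks)]
  best <- pool[which.min(aiccs[pool])]
  out <- fits[[best]]
  attr(out, "aiccTable") <- data.frame(
    formula = vapply(fits, function(m) m@formula, ""),
    k = vapply(fits, function(m) m@k, numeric(1)),
    logLik = vapply(fits, function(m) m@logLik, numeric(1)),
    AICc = aiccs, dAICc = delta)
  attr(out, "fits") <- fits
  out
}

#' Two-step parsimony fit
#'
#' Fits the full model, forms the reduced model that keeps only terms whose
#' 95% CIs exclude zero (an interaction keeps its main effects), and lets
#' \code{\link{aiccSelect}} arbitrate among full, reduced and — when the fit
#' supports an intercept and no slope is cleanly identified — the
#' intercept-only model, under the 4-AICc / parsimony rule.
#'
#' @param table observation data.frame.
#' @param formula full model formula.
#' @param fitter fitting function (default \code{\link{fitLogistic}}).
#' @param ... passed to the fitter.
#' @return selected \linkS4class{FittedModel}.
#' @export
parsimonySelect <- function(table, formula, fitter = fitLogistic, ...) {
  if (is.character(formula)) formula <- stats::as.formula(formula)
  full <- fitter(table, formula, ...)
  ci <- full@ci
  clean <- rownames(ci)[sign(ci[, 1]) == sign(ci[, 2]) & ci[, 1] != 0]
  clean <- setdiff(clean, "(Intercept)")
  terms0 <- attr(stats::terms(formula), "term.labels")
  keep <- intersect(terms0, clean)
  ## hierarchy: an interaction keeps its main effects
  for (t in keep) if (grepl(":", t, fixed = TRUE))
    keep <- union(keep, strsplit(t, ":", fixed = TRUE)[[1]])
  keep <- terms0[terms0 %in% keep]
  if (length(keep) == length(terms0)) return(full)
  hasIntercept <- "(Intercept)" %in% rownames(ci)
  cand <- list(formula)
  if (length(keep))
    cand <- c(cand, stats::reformulate(keep, response = "response"))
  else if (hasIntercept)
    cand <- c(cand, stats::as.formula("response ~ 1"))
  else return(full)  # no-intercept fit with nothing identified: keep full
  aiccSelect(cand, table, fitter, ...)
}

#' Predict an exponential RSF surface
#'
#' Per-cell \code{w = exp(sum beta_j x_j)} with the intercept excluded
#' (Johnson-form relative selection), evaluated on precomputed covariate
#' surfaces. The result carries the landscape exclusion mask as nodata.
#'
#' @param model FittedModel.
#' @param landscape Landscape (provides the exclusion mask).
#' @param stack covariate stack covering the model terms.
#' @return RasterGrid of relative selection weights.
#' @export
predictRsf <- function(model, landscape, stack) {
  f <- stats::as.formula(model@formula)
  vars <- all.vars(stats::delete.response(stats::terms(f)))
  if (!length(vars)) {  # intercept-only model: flat relative selection
    tmpl <- landscape@rasters[[1]]
    return(rasterGrid(matrix(1, nrow(tmpl@values), ncol(tmpl@values)),
                      tmpl@origin, tmpl@cellSize, landscape@exclusionMask,
                      "rsf"))
  }
  miss <- setdiff(vars, names(stack))
  if (length(miss)) stop("stack lacks layers: ", paste(miss, collapse = ", "))
  tmpl <- stack[[vars[1]]]
  d <- dim(tmpl@values)
  df <- as.data.frame(lapply(stack[vars], function(r) as.numeric(r@values)))
  X <- stats::model.matrix(stats::delete.response(stats::terms(f)), df)
  beta <- model@coef
  keep <- setdiff(colnames(X), "(Intercept)")
  w <- exp(drop(X[, keep, drop = FALSE] %*% beta[keep]))
  rasterGrid(matrix(w, d[1], d[2]), tmpl@origin, tmpl@cellSize,
             landscape@exclusionMask, "rsf")
}

#' Observation table and fit for elk occurrence in scats
#'
#' Contrasts scats containing elk (response 1) with scats not analyzed for
#' contents (response 0) of the same species, with covariates buffered at
#' the species-specific radius. Old scats and (by default)
#' analyzed-but-elk-free scats are excluded.
#'
#' @param scats scat data.frame (all species; filtered internally).
#' @param species predator species.
#' @param landscape Landscape.
#' @param stack P_elk covariate stack for the species.
#' @param formula model formula; default additive in stack names.
#' @param includeAbsences also use analyzed scats without elk as available
#'   points (default FALSE).
#' @param specs covariate specs; default \code{defaultSpecs("P_elk", species)}.
#' @param parsimony apply the CI-screen / AICc parsimony step
#'   (\code{\link{parsimonySelect}}) to the fit.
#' @return a \linkS4class{FittedModel} tagged stage "P_elk".
#' @export
fitPelk <- function(scats, species, landscape, stack, formula = NULL,
                    includeAbsences = FALSE, specs = NULL,
                    parsimony = FALSE) {
  if (is.null(specs)) specs <- defaultSpecs("P_elk", species)
  s <- scats[scats$species == species & scats$age_class != "old", , drop = FALSE]
  used <- s[s$elk_content == "present", , drop = FALSE]
  keep0 <- if (includeAbsences) c("not_analyzed", "absent") else "not_analyzed"
  avail <- s[s$elk_content %in% keep0, , drop = FALSE]
  if (!nrow(used) || !nrow(avail)) stop("single-class input")
  pts <- rbind(cbind(used$x, used$y), cbind(avail$x, avail$y))
  resp <- c(rep(1, nrow(used)), rep(0, nrow(avail)))
  tab <- buildDesignMatrix(pts, specs, landscape, stack = stack,
                           response = resp)
  rec <- list(radius = specs[[1]]$radius,
              n_used = nrow(used), n_avail = nrow(avail))
  if (is.null(formula)) {
    covs <- vapply(specs, `[[`, "", "name")
    formula <- stats::reformulate(covs, response = "response")
  }
  if (parsimony)
    parsimonySelect(tab, formula, fitLogistic, stage = "P_elk",
                    species = species, recipe = rec)
  else fitLogistic(tab, formula, stage = "P_elk", species = species,
                   recipe = rec)
}
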