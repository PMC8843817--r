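#' @import methods
#' @importFrom stats coef
NULL

#' Single-band planar raster grid
#'
#' The carrier of every covariate and risk surface: a rectangular grid of
#' real values on a projected plane (metres), with a nodata mask. Indexing is
#' row-major with row 1 at the *bottom* of the grid; the origin is the
#' lower-left cell corner and a point maps to the cell containing it under
#' half-open intervals \code{[x0, x0 + cellSize)}.
#'
#' @slot values numeric matrix of cell values (row 1 = southernmost row).
#' @slot origin numeric length-2, x/y of the lower-left grid corner (m).
#' @slot cellSize cell edge length in metres (default 30).
#' @slot nodata logical matrix, TRUE where the cell carries no data.
#' @slot name band name.
#' @export
setClass("RasterGrid",
  representation(values = "matrix", origin = "numeric", cellSize = "numeric",
                 nodata = "matrix", name = "character"),
  prototype(origin = c(0, 0), cellSize = 30, name = "band"))

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0) msg <- c(msg, "cellSize must be a positive scalar")
  if (length(object@origin) != 2) msg <- c(msg, "origin must be length 2")
  if (!identical(dim(object@values), dim(object@nodata)))
    msg <- c(msg, "nodata mask must be congruent with values")
  if (!is.logical(object@nodata)) msg <- c(msg, "nodata must be logical")
  if (length(msg)) msg else TRUE
})

#' A set of polyline features of one class
#'
#' @slot features list of two-column coordinate matrices (metres), each with
#'   at least two vertices.
#' @slot classLabel one of "stream", "motorized", "nonmotorized", "transect".
#' @export
setClass("LinearFeatureSet",
  representation(features = "list", classLabel = "character"))

setValidity("LinearFeatureSet", function(object) {
  ok <- object@classLabel %in% c("stream", "motorized", "nonmotorized", "transect")
  if (!ok) return("classLabel must be stream/motorized/nonmotorized/transect")
  for (f in object@features) {
    if (!is.matrix(f) || ncol(f) != 2 || nrow(f) < 2)
      return("every polyline needs a 2-column matrix with >= 2 vertices")
    if (!all(is.finite(f))) return("polyline coordinates must be finite")
  }
  TRUE
})

#' The synthetic study region
#'
#' Named covariate rasters, linear features, the protected-area mask, the
#' analysis exclusion mask (high elevation / rock / ice) and the three summer
#' range polygons. All rasters share origin, shape and cell size.
#'
#' @slot rasters named list of \linkS4class{RasterGrid}.
#' @slot lines named list of \linkS4class{LinearFeatureSet}.
#' @slot parkMask logical matrix, TRUE inside the protected area.
#' @slot exclusionMask logical matrix, TRUE where cells are excluded from all
#'   analyses (elevation > 2000 m, rock or ice).
#' @slot rangePolygons named list of polygon vertex matrices (West, YHT, East).
#' @slot config the generator configuration that produced the landscape.
#' @export
setClass("Landscape",
  representation(rasters = "list", lines = "list", parkMask = "matrix",
                 exclusionMask = "matrix", rangePolygons = "list",
                 config = "list"))

setValidity("Landscape", function(object) {
  if (!length(object@rasters)) return("no rasters")
  d <- dim(object@rasters[[1]]@values)
  for (r in object@rasters) {
    if (!is(r, "RasterGrid")) return("rasters must be RasterGrid")
    if (!identical(dim(r@values), d)) return("rasters must share one shape")
  }
  if (!identical(dim(object@parkMask), d)) return("parkMask not congruent")
  if (!identical(dim(object@exclusionMask), d)) return("exclusionMask not congruent")
  TRUE
})

#' A spatial probability density for predator abundance
#'
#' Density per square metre on the analysis grid; integrates to one over
#' unmasked cells.
#'
#' @slot density \linkS4class{RasterGrid} of density values (1/m^2).
#' @slot species predator species the density describes.
#' @export
setClass("AbundancePDF",
  representation(density = "RasterGrid", species = "character"))

setValidity("AbundancePDF", function(object) {
  v <- object@density@values[!object@density@nodata]
  if (any(v < 0)) return("density must be nonnegative")
  tot <- sum(v) * object@density@cellSize^2
  if (abs(tot - 1) > 1e-9) return(sprintf("density integrates to %.12f, not 1", tot))
  TRUE
})

#' A fitted selection or kill-site model
#'
#' Coefficients, covariance, likelihood, AICc and the design recipe that
#' produced them. The AICc identity
#' \code{-2 lnL + 2k + 2k(k+1)/(n-k-1)} is enforced by validity.
#'
#' @slot coef named numeric coefficient vector.
#' @slot vcov coefficient covariance matrix.
#' @slot logLik maximized log-likelihood.
#' @slot k number of estimated parameters.
#' @slot n number of rows (strata for matched designs).
#' @slot aicc small-sample Akaike information criterion.
#' @slot ci two-column matrix of Wald 95\% limits.
#' @slot stage one of "P_pred", "P_elk", "RUF", "PR_kill".
#' @slot species species label or "all".
#' @slot formula model formula as text.
#' @slot converged logical.
#' @slot recipe list describing the design (radii, weights, sampling).
#' @export
setClass("FittedModel",
  representation(coef = "numeric", vcov = "matrix", logLik = "numeric",
                 k = "numeric", n = "numeric", aicc = "numeric", ci = "matrix",
                 stage = "character", species = "character",
                 formula = "character", converged = "logical",
                 recipe = "list"))

setValidity("FittedModel", function(object) {
  if (object@k < 1) return("k must be >= 1")
  if (object@n <= object@k + 1) return("n must exceed k + 1")
  want <- -2 * object@logLik + 2 * object@k +
    2 * object@k * (object@k + 1) / (object@n - object@k - 1)
  if (abs(want - object@aicc) > 1e-8) return("AICc identity violated")
  TRUE
})

#' A scaled risk or occurrence surface
#'
#' A raster restricted to [0, 1] on unmasked cells, tagged with the species
#' and pipeline component it represents, plus provenance (input model ids and
#' the pre-scaling bounds).
#'
#' @slot raster \linkS4class{RasterGrid}.
#' @slot species species label or "total".
#' @slot component one of "P_pred", "P_elk", "PR_scat", "PR_total", "PR_kill".
#' @slot provenance list; includes \code{scale_min}, \code{scale_max}.
#' @export
setClass("RiskSurface",
  representation(raster = "RasterGrid", species = "character",
                 component = "character", provenance = "list"))

setValidity("RiskSurface", function(object) {
  if (!object@component %in% c("P_pred", "P_elk", "PR_scat", "PR_total", "PR_kill"))
    return("unknown component")
  v <- object@raster@values[!object@raster@nodata]
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    return("risk surface values must lie in [0, 1]")
  TRUE
})

## ---- accessors ----

#' Cell values of a raster-backed object
#' @param x a RasterGrid, AbundancePDF or RiskSurface.
#' @return numeric matrix (row 1 = southernmost row); masked cells are NA.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
setMethod("gridValues", "RasterGrid", function(x) {
  v <- x@values
  v[x@nodata] <- NA_real_
  v
})

#' @rdname gridValues
setMethod("gridValues", "AbundancePDF", function(x) gridValues(x@density))

#' @rdname gridValues
setMethod("gridValues", "RiskSurface", function(x) gridValues(x@raster))

#' Nodata mask of a raster-backed object
#' @param x a RasterGrid, AbundancePDF or RiskSurface.
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

#' @rdname gridMask
setMethod("gridMask", "RasterGrid", function(x) x@nodata)
#' @rdname gridMask
setMethod("gridMask", "AbundancePDF", function(x) x@density@nodata)
#' @rdname gridMask
setMethod("gridMask", "RiskSurface", function(x) x@raster@nodata)

#' Cell edge length in metres
#' @param x a RasterGrid or Landscape.
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname cellSize
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)
#' @rdname cellSize
setMethod("cellSize", "Landscape", function(x) x@rasters[[1]]@cellSize)

#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

#' @describeIn FittedModel-class estimated coefficients.
#' @param object a FittedModel.
#' @export
setMethod("coef", "FittedModel", function(object, ...) object@coef)

#' AICc of a fitted model
#' @param x a FittedModel.
#' @export
aicc <- function(x) {
  stopifnot(is(x, "FittedModel"))
  x@aicc
}

#' Wald 95 percent confidence limits of a fitted model
#' @param x a FittedModel.
#' @export
waldCI <- function(x) {
  stopifnot(is(x, "FittedModel"))
  x@ci
}

## ---- show methods ----

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("RasterGrid '%s': %d x %d cells @ %g m, origin (%g, %g), %d masked\n",
              object@name, d[1], d[2], object@cellSize, object@origin[1],
              object@origin[2], sum(object@nodata)))
  v <- object@values[!object@nodata]
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "Landscape", function(object) {
  d <- dim(object@rasters[[1]]@values)
  cat(sprintf("Landscape: %d x %d cells @ %g m\n", d[1], d[2], cellSize(object)))
  cat("  rasters:", paste(names(object@rasters), collapse = ", "), "\n")
  cat("  lines:  ", paste(names(object@lines), collapse = ", "), "\n")
  cat(sprintf("  excluded cells: %d (%.1f%%)\n", sum(object@exclusionMask),
              100 * mean(object@exclusionMask)))
})

setMethod("show", "AbundancePDF", function(object) {
  cat(sprintf("AbundancePDF (%s): integrates to %.9f\n", object@species,
              sum(object@density@values[!object@density@nodata]) *
                object@density@cellSize^2))
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel [%s / %s]  n = %d, k = %d, lnL = %.3f, AICc = %.3f\n",
              object@stage, object@species, as.integer(object@n),
              as.integer(object@k), object@logLik, object@aicc))
  tab <- cbind(beta = object@coef, lower = object@ci[, 1], upper = object@ci[, 2])
  print(round(tab, 5))
})

setMethod("show", "RiskSurface", function(object) {
  v <- object@raster@values[!object@raster@nodata]
  cat(sprintf("RiskSurface %s [%s]: mean %.3f, range [%.3f, %.3f]\n",
              object@component, object@species, mean(v), min(v), max(v)))
})
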