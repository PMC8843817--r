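## Wrap a scaled raster as a RiskSurface, recording pre-scaling bounds.
asRiskSurface <- function(scaled, species, component, provenance = list()) {
  provenance$scale_min <- attr(scaled, "scale_min")
  provenance$scale_max <- attr(scaled, "scale_max")
  new("RiskSurface", raster = scaled, species = species,
      component = component, provenance = provenance)
}

#' Abundance-weighted encounter surface
#'
#' Multiplies a relative-selection raster by a spatial abundance density
#' (when available; cougar and coyote surfaces go unweighted) and rescales
#' to [0, 1], giving the encounter component P_pred.
#'
#' @param rsf RasterGrid of exponential-RSF weights.
#' @param pdf AbundancePDF or NULL for no weighting.
#' @param species species tag.
#' @return RiskSurface, component "P_pred".
#' @export
weightByAbundance <- function(rsf, pdf = NULL, species = "wolf") {
  if (!is.null(pdf)) {
    dv <- pdf@density
    if (!identical(dim(dv@values), dim(rsf@values)) ||
        dv@cellSize != rsf@cellSize)
      stop("grid mismatch between RSF and abundance density")
    w <- rasterGrid(rsf@values * dv@values, rsf@origin, rsf@cellSize,
                    rsf@nodata | dv@nodata, "wpred")
  } else w <- rsf
  asRiskSurface(scale01(w), species, "P_pred",
                list(weighted = !is.null(pdf)))
}

#' Scale a predicted occurrence raster as a P_elk surface
#'
#' @param raster RasterGrid of exponential model predictions.
#' @param species species tag.
#' @return RiskSurface, component "P_elk".
#' @export
asPelkSurface <- function(raster, species) {
  asRiskSurface(scale01(raster), species, "P_elk", list())
}

#' Species-level scat-based predation risk
#'
#' Cellwise product of the scaled encounter surface and the scaled
#' elk-in-scat surface; deliberately not rescaled (only the total across
#' species is), so the product stays bounded by both factors.
#'
#' @param pPred RiskSurface, component "P_pred".
#' @param pElk RiskSurface, component "P_elk", same species.
#' @return RiskSurface, component "PR_scat".
#' @export
prScat <- function(pPred, pElk) {
  if (pPred@component != "P_pred" || pElk@component != "P_elk")
    stop("inputs must be P_pred and P_elk surfaces")
  if (!identical(pPred@species, pElk@species)) stop("species mismatch")
  a <- pPred@raster; b <- pElk@raster
  if (!identical(dim(a@values), dim(b@values))) stop("grid mismatch")
  va <- a@values[!a@nodata]; vb <- b@values[!b@nodata]
  if (min(va) < -1e-9 || max(va) > 1 + 1e-9 ||
      min(vb) < -1e-9 || max(vb) > 1 + 1e-9) stop("unscaled input")
  out <- rasterGrid(a@values * b@values, a@origin, a@cellSize,
                    a@nodata | b@nodata, "pr_scat")
  new("RiskSurface", raster = out, species = pPred@species,
      component = "PR_scat",
      provenance = list(scale_min = 0, scale_max = 1))
}

#' Total predation risk across predators
#'
#' Sum of the four species-level PR_scat surfaces, rescaled to [0, 1].
#'
#' @param perSpecies list of PR_scat RiskSurfaces (bear, cougar, coyote,
#'   wolf, in any order).
#' @return RiskSurface, species "total", component "PR_total".
#' @export
prTotal <- function(perSpecies) {
  spcs <- vapply(perSpecies, function(s) s@species, "")
  need <- c("bear", "cougar", "coyote", "wolf")
  if (anyDuplicated(spcs)) stop("duplicate species")
  if (!setequal(spcs, need))
    stop("need exactly the four species: ", paste(need, collapse = ", "))
  ord <- match(need, spcs)
  acc <- perSpecies[[ord[1]]]@raster@values
  nod <- perSpecies[[ord[1]]]@raster@nodata
  for (i in ord[-1]) {
    acc <- acc + perSpecies[[i]]@raster@values
    nod <- nod | perSpecies[[i]]@raster@nodata
  }
  tmpl <- perSpecies[[1]]@raster
  asRiskSurface(scale01(rasterGrid(acc, tmpl@origin, tmpl@cellSize, nod,
                                   "pr_total")),
                "total", "PR_total",
                list(inputs = spcs))
}

#' Summarize a surface over range polygons
#'
#' Mean and SD of unmasked cell values per named polygon (summer range).
#'
#' @param surface RiskSurface or RasterGrid.
#' @param rangePolygons named list of polygon vertex matrices.
#' @return data.frame: range, n_cells, mean, sd.
#' @export
summarizeByRange <- function(surface, rangePolygons) {
  r <- if (is(surface, "RiskSurface")) surface@raster else surface
  ctr <- cellCenters(r)
  d <- dim(r@values)
  pts <- cbind(rep(ctr$x, each = d[1]), rep(ctr$y, times = d[2]))
  ok <- !as.logical(r@nodata)
  out <- data.frame(range = names(rangePolygons), n_cells = NA_integer_,
                    mean = NA_real_, sd = NA_real_)
  for (i in seq_along(rangePolygons)) {
    inside <- pointInPolygon(pts, rangePolygons[[i]]) & ok
    if (!any(inside)) stop("polygon '", names(rangePolygons)[i],
                           "' covers no unmasked cells")
    v <- as.numeric(r@values)[inside]
    out$n_cells[i] <- length(v)
    out$mean[i] <- mean(v)
    out$sd[i] <- stats::sd(v)
  }
  out
}
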