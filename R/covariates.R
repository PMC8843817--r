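#' Define one design-matrix covariate
#'
#' @param name column name (Table-style short code, e.g. "distwater").
#' @param layer source: a landscape raster name for buffer kinds, or a line
#'   class ("stream", "motorized", "nonmotorized") for distance/density/flag
#'   kinds; "edge" uses the derived forest-edge raster.
#' @param kind one of "cell" (value of the containing 30-m cell),
#'   "buffer_mean", "buffer_proportion", "distance", "linear_density",
#'   "flag".
#' @param radius buffer/density radius (m); required for buffer and density
#'   kinds.
#' @param scale multiplier applied to the extracted value (unit conversion;
#'   e.g. 1/1000 stores a distance in km).
#' @return a covariate spec (classed list).
#' @export
covariateSpec <- function(name, layer, kind, radius = NULL, scale = 1) {
  kind <- match.arg(kind, c("cell", "buffer_mean", "buffer_proportion",
                            "distance", "linear_density", "flag"))
  if (kind %in% c("buffer_mean", "buffer_proportion", "linear_density") &&
      (is.null(radius) || radius <= 0))
    stop("radius required for buffer and density covariates")
  structure(list(name = name, layer = layer, kind = kind,
                 radius = radius, scale = scale),
            class = "covariateSpec")
}

#' Buffer statistic at a point
#'
#' Mean (or proportion, identical arithmetic for 0/1 layers) over unmasked
#' cells whose centers fall within \code{radius} of the point.
#'
#' @param raster RasterGrid.
#' @param point length-2 numeric (x, y).
#' @param radius buffer radius (m).
#' @param stat "mean" or "proportion".
#' @return scalar statistic.
#' @export
bufferStat <- function(raster, point, radius, stat = c("mean", "proportion")) {
  stat <- match.arg(stat)
  if (radius <= 0) stop("radius must be positive")
  d <- dim(raster@values)
  h <- raster@cellSize
  ctr <- cellCenters(raster)
  cw <- which(abs(ctr$x - point[1]) <= radius)
  rw <- which(abs(ctr$y - point[2]) <= radius)
  if (!length(cw) || !length(rw)) stop("no cells within buffer")
  dx <- ctr$x[cw] - point[1]
  dy <- ctr$y[rw] - point[2]
  inside <- outer(dy^2, dx^2, "+") <= radius^2
  ok <- inside & !raster@nodata[rw, cw, drop = FALSE]
  if (!any(ok)) stop("no cells within buffer")
  mean(raster@values[rw, cw, drop = FALSE][ok])
}

#' Distance to the nearest linear feature
#'
#' Minimum point-to-segment Euclidean distance over all segments of the set.
#'
#' @param features LinearFeatureSet (or list of them).
#' @param point length-2 numeric, or a two-column matrix of points.
#' @return metres (vector for a point matrix).
#' @export
distanceTo <- function(features, point) {
  segs <- segmentTable(features)
  if (!nrow(segs)) stop("empty feature set: distance is undefined")
  pts <- matrix(as.numeric(point), ncol = 2)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(segs)))
    best <- pmin(best, segDistance(pts[, 1], pts[, 2], segs[i, 1], segs[i, 2],
                                   segs[i, 3], segs[i, 4]))
  if (length(best) == 1) best[[1]] else best
}

#' Linear-feature density around a point
#'
#' Total polyline length clipped to the disc of the given radius, divided by
#' the disc area; reported in km/km^2. Clipping is exact (circle-segment
#' intersection).
#'
#' @param features LinearFeatureSet (or list).
#' @param point length-2 numeric (x, y).
#' @param radius disc radius (m).
#' @return density in km/km^2.
#' @export
linearDensity <- function(features, point, radius) {
  if (radius <= 0) stop("radius must be positive")
  segs <- segmentTable(features)
  tot <- 0
  for (i in seq_len(nrow(segs))) {
    ax <- segs[i, 1] - point[1]; ay <- segs[i, 2] - point[2]
    bx <- segs[i, 3] - point[1]; by <- segs[i, 4] - point[2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    if (L2 == 0) next
    ## |a + t v|^2 = r^2
    A <- L2; B <- 2 * (ax * vx + ay * vy); C <- ax^2 + ay^2 - radius^2
    disc <- B^2 - 4 * A * C
    if (disc <= 0) next
    t1 <- (-B - sqrt(disc)) / (2 * A); t2 <- (-B + sqrt(disc)) / (2 * A)
    frac <- max(0, min(1, t2) - max(0, t1))
    tot <- tot + frac * sqrt(L2)
  }
  (tot / 1000) / (pi * radius^2 / 1e6)
}

#' On-trail indicator
#'
#' 1 when the point lies within 30 m (inclusive) of a nonmotorized trail.
#'
#' @param point length-2 numeric or two-column matrix.
#' @param trails LinearFeatureSet of trails.
#' @param threshold metres, default 30.
#' @return 0/1 (vectorized over rows).
#' @export
trailUseFlag <- function(point, trails, threshold = 30) {
  if (!length(trails@features)) return(rep(0, nrow(matrix(point, ncol = 2))))
  as.numeric(distanceTo(trails, point) <= threshold)
}

## ---- exact Euclidean distance transform (squared), 1-D lower envelope ----
dt1d <- function(f) {
  n <- length(f)
  dOut <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    dOut[q] <- (q - v[k])^2 + f[v[k]]
  }
  dOut
}

#' Exact distance transform of a binary raster
#'
#' Distance (m) from each cell center to the nearest TRUE cell center.
#'
#' @param binary logical or 0/1 matrix.
#' @param template RasterGrid providing geometry.
#' @return RasterGrid of distances.
#' @export
distanceTransform <- function(binary, template) {
  d <- dim(binary)
  ## large finite sentinel instead of Inf keeps parabola intersections finite
  f <- matrix(ifelse(binary, 0, 1e15), d[1], d[2])
  for (j in seq_len(d[2])) f[, j] <- dt1d(f[, j])
  for (i in seq_len(d[1])) f[i, ] <- dt1d(f[i, ])
  rasterGrid(sqrt(f) * template@cellSize, template@origin, template@cellSize,
             template@nodata, "disttrans")
}

#' Precompute covariate surfaces for a spec set
#'
#' Builds one raster per covariate spec: buffer statistics as masked focal
#' disc means, feature distances as exact per-cell-center distances, line
#' densities from rasterized lengths, and the on/off-trail flag. Extraction
#' from the stack is then a constant-time cell lookup, which is what the
#' simulators and surface predictions use; point-level operations
#' (\code{\link{bufferStat}} and friends) remain the exact reference.
#'
#' @param landscape Landscape.
#' @param specs list of \code{\link{covariateSpec}}.
#' @return named list of RasterGrid, one per spec.
#' @export
covariateStack <- function(landscape, specs) {
  out <- list()
  template <- landscape@rasters[[1]]
  for (sp in specs) {
    r <- switch(sp$kind,
      cell = {
        lay <- landscape@rasters[[sp$layer]]
        if (is.null(lay)) stop("unknown raster layer: ", sp$layer)
        lay
      },
      buffer_mean = ,
      buffer_proportion = {
        lay <- landscape@rasters[[sp$layer]]
        if (is.null(lay)) stop("unknown raster layer: ", sp$layer)
        focalDisc(lay, sp$radius, "mean")
      },
      distance = {
        if (sp$layer == "edge")
          distanceTransform(landscape@rasters$edge@values > 0.5, template)
        else {
          ln <- landscape@lines[[sp$layer]]
          if (is.null(ln)) stop("unknown line class: ", sp$layer)
          distanceRaster(ln, template)
        }
      },
      linear_density = {
        ln <- landscape@lines[[sp$layer]]
        if (is.null(ln)) stop("unknown line class: ", sp$layer)
        lenR <- rasterizeLineLength(ln, template)
        s <- focalDisc(lenR, sp$radius, "sum")
        s@values <- (s@values / 1000) / (pi * sp$radius^2 / 1e6)
        s
      },
      flag = {
        ln <- landscape@lines[[sp$layer]]
        if (is.null(ln)) stop("unknown line class: ", sp$layer)
        dr <- distanceRaster(ln, template)
        dr@values <- (dr@values <= 30) * 1
        dr
      })
    if (sp$scale != 1) r@values <- r@values * sp$scale
    r@name <- sp$name
    out[[sp$name]] <- r
  }
  out
}

#' Assemble an observation table of covariates at points
#'
#' One row per point, one column per covariate spec (in spec order).
#' Distances are in metres, proportions in [0, 1], densities in km/km^2,
#' unless a spec applies a unit scale. With \code{stack} supplied, values are
#' cell lookups from precomputed surfaces; otherwise exact point-level
#' operations are used.
#'
#' @param points two-column coordinate matrix.
#' @param specs list of \code{\link{covariateSpec}}.
#' @param landscape Landscape.
#' @param stack optional result of \code{\link{covariateStack}}.
#' @param response optional 0/1 vector.
#' @param stratum optional stratum ids.
#' @param weight optional positive weights (default 1).
#' @return data.frame: point_id, x, y, response, stratum, weight, covariates.
#' @export
buildDesignMatrix <- function(points, specs, landscape, stack = NULL,
                              response = NULL, stratum = NULL, weight = NULL) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  base <- data.frame(point_id = seq_len(n), x = points[, 1], y = points[, 2])
  base$response <- if (is.null(response)) rep(NA_real_, n) else response
  base$stratum <- if (is.null(stratum)) rep(NA_integer_, n) else stratum
  base$weight <- if (is.null(weight)) rep(1, n) else weight
  if (!is.null(weight) && any(weight <= 0)) stop("weights must be positive")
  if (n == 0) {
    for (sp in specs) base[[sp$name]] <- numeric(0)
    return(base)
  }
  rc <- pointToCell(landscape@rasters[[1]], points)
  if (any(is.na(rc[, 1]))) stop("point outside grid")
  for (sp in specs) {
    if (!is.null(stack)) {
      v <- extractAtPoints(stack[[sp$name]], points)
    } else {
      v <- vapply(seq_len(n), function(i) {
        p <- points[i, ]
        val <- switch(sp$kind,
          cell = extractAtPoints(landscape@rasters[[sp$layer]],
                                 matrix(p, ncol = 2)),
          buffer_mean = bufferStat(landscape@rasters[[sp$layer]], p, sp$radius),
          buffer_proportion = bufferStat(landscape@rasters[[sp$layer]], p,
                                         sp$radius, "proportion"),
          distance = {
            if (sp$layer == "edge") {
              ec <- which(landscape@rasters$edge@values > 0.5, arr.ind = TRUE)
              if (!nrow(ec)) stop("no edge cells")
              h <- cellSize(landscape)
              org <- landscape@rasters[[1]]@origin
              min(sqrt((org[1] + (ec[, 2] - 0.5) * h - p[1])^2 +
                         (org[2] + (ec[, 1] - 0.5) * h - p[2])^2))
            } else distanceTo(landscape@lines[[sp$layer]], p)
          },
          linear_density = linearDensity(landscape@lines[[sp$layer]], p,
                                         sp$radius),
          flag = trailUseFlag(p, landscape@lines[[sp$layer]]))
        val * sp$scale
      }, numeric(1))
    }
    base[[sp$name]] <- v
  }
  base
}

#' Default covariate spec sets by pipeline stage
#'
#' Encodes the analysis-unit conventions: encounter-stage buffers at 1.3 km
#' radius, elk-in-scat buffers at the species-specific gut-passage radius
#' (3 km wolf, 1.5 km bear, 2 km cougar and coyote), and kill-site buffers
#' at 250 m with distances in km (matching the magnitude of the kill-model
#' coefficients).
#'
#' @param stage "P_pred", "P_elk", "RUF" or "PR_kill".
#' @param species predator species (sets the P_elk radius).
#' @return named list of covariate specs.
#' @export
defaultSpecs <- function(stage = c("P_pred", "P_elk", "RUF", "PR_kill"),
                         species = "wolf") {
  stage <- match.arg(stage)
  pelkRadius <- c(wolf = 3000, bear = 1500, cougar = 2000, coyote = 2000)
  mk <- function(...) {
    sp <- list(...)
    names(sp) <- vapply(sp, `[[`, "", "name")
    sp
  }
  if (stage == "P_pred") {
    r <- 1300
    mk(covariateSpec("conifer", "conifer", "buffer_proportion", r),
       covariateSpec("decid", "decid", "buffer_proportion", r),
       covariateSpec("herb", "herb", "buffer_proportion", r),
       covariateSpec("shrub", "shrub", "buffer_proportion", r),
       covariateSpec("burn", "burn", "buffer_proportion", r),
       covariateSpec("cutblk", "cutblk", "buffer_proportion", r),
       covariateSpec("ndvi", "ndvi", "buffer_mean", r),
       ## topographic covariates enter at the 30-m cell
       covariateSpec("slope", "slope", "cell"),
       covariateSpec("rugg", "rugg", "cell"),
       covariateSpec("elev", "elev", "cell"),
       covariateSpec("edgedens", "edge", "buffer_mean", r),
       covariateSpec("distwater", "stream", "distance"),
       covariateSpec("distroad", "motorized", "distance"),
       covariateSpec("disttrail", "nonmotorized", "distance"),
       covariateSpec("distedge", "edge", "distance"),
       covariateSpec("trailuse", "nonmotorized", "flag"),
       covariateSpec("roaddens", "motorized", "linear_density", r),
       covariateSpec("traildens", "nonmotorized", "linear_density", r))
  } else if (stage == "P_elk") {
    r <- pelkRadius[[species]]
    mk(covariateSpec("herbfg", "herbfg", "buffer_mean", r),
       covariateSpec("rugg", "rugg", "buffer_mean", r),
       covariateSpec("decid", "decid", "buffer_proportion", r),
       covariateSpec("open", "open", "buffer_proportion", r),
       covariateSpec("burn", "burn", "buffer_proportion", r),
       covariateSpec("edgedens", "edge", "buffer_mean", r),
       covariateSpec("distwater", "stream", "distance"),
       covariateSpec("distroad", "motorized", "distance"),
       covariateSpec("roaddens", "motorized", "linear_density", r))
  } else if (stage == "RUF") {
    r <- 300
    mk(covariateSpec("herbfg", "herbfg", "buffer_mean", r),
       covariateSpec("herb", "herb", "buffer_proportion", r),
       covariateSpec("burn", "burn", "buffer_proportion", r),
       covariateSpec("distedge", "edge", "distance"))
  } else {
    r <- 250
    mk(covariateSpec("decid", "decid", "buffer_proportion", r),
       covariateSpec("distedge", "edge", "distance", scale = 1 / 1000),
       covariateSpec("distwater", "stream", "distance", scale = 1 / 1000),
       covariateSpec("herbfg", "herbfg", "buffer_mean", r),
       covariateSpec("open", "open", "buffer_proportion", r),
       covariateSpec("rugg", "rugg", "buffer_mean", r))
  }
}
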