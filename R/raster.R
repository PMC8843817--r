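#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = southernmost row).
#' @param origin x/y of the lower-left corner (m).
#' @param cellSize cell edge (m), default 30.
#' @param nodata logical mask congruent with \code{values}; default all FALSE.
#' @param name band name.
#' @return a \linkS4class{RasterGrid}.
#' @export
rasterGrid <- function(values, origin = c(0, 0), cellSize = 30,
                       nodata = NULL, name = "band") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(nodata)) nodata <- matrix(FALSE, nrow(values), ncol(values))
  new("RasterGrid", values = values, origin = as.numeric(origin),
      cellSize = as.numeric(cellSize), nodata = nodata, name = name)
}

## Evaluate code under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Map points to raster cells
#'
#' Half-open convention: a point with coordinate in \code{[x0 + (c-1)h,
#' x0 + ch)} falls in column c.
#'
#' @param raster a RasterGrid.
#' @param xy two-column matrix of point coordinates (m).
#' @return integer matrix with columns \code{row}, \code{col}; NA outside grid.
#' @export
pointToCell <- function(raster, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  h <- raster@cellSize
  cc <- floor((xy[, 1] - raster@origin[1]) / h) + 1L
  rr <- floor((xy[, 2] - raster@origin[2]) / h) + 1L
  d <- dim(raster@values)
  bad <- rr < 1L | rr > d[1] | cc < 1L | cc > d[2]
  rr[bad] <- NA_integer_
  cc[bad] <- NA_integer_
  cbind(row = rr, col = cc)
}

#' Cell-center coordinates
#' @param raster a RasterGrid.
#' @return list with vectors \code{x} (per column) and \code{y} (per row).
#' @export
cellCenters <- function(raster) {
  h <- raster@cellSize
  d <- dim(raster@values)
  list(x = raster@origin[1] + (seq_len(d[2]) - 0.5) * h,
       y = raster@origin[2] + (seq_len(d[1]) - 0.5) * h)
}

#' Extract raster values at points (containing cell)
#' @param raster a RasterGrid.
#' @param xy two-column coordinate matrix.
#' @return numeric vector; NA outside the grid or on masked cells.
#' @export
extractAtPoints <- function(raster, xy) {
  rc <- pointToCell(raster, xy)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  idx <- cbind(rc[ok, 1], rc[ok, 2])
  v <- raster@values[idx]
  v[raster@nodata[idx]] <- NA_real_
  out[ok] <- v
  out
}

## ---- FFT convolution machinery ----

## Convolve a matrix with a centered odd-sized kernel, zero boundary.
fftConvolve <- function(mat, kernel) {
  n1 <- nrow(mat); n2 <- ncol(mat)
  k1 <- nrow(kernel); k2 <- ncol(kernel)
  p1 <- n1 + k1 - 1L; p2 <- n2 + k2 - 1L
  A <- matrix(0, p1, p2); A[1:n1, 1:n2] <- mat
  K <- matrix(0, p1, p2); K[1:k1, 1:k2] <- kernel
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (p1 * p2)
  off1 <- (k1 - 1L) %/% 2L; off2 <- (k2 - 1L) %/% 2L
  conv[(off1 + 1L):(off1 + n1), (off2 + 1L):(off2 + n2)]
}

## Disc kernel of 0/1 weights over cell-center offsets within radius (m).
discKernel <- function(radius, cellSize) {
  rc <- floor(radius / cellSize)
  off <- (-rc):rc
  d2 <- outer(off^2, off^2, "+") * cellSize^2
  (d2 <= radius^2) * 1
}

#' Masked focal disc statistic over a raster
#'
#' Mean (or sum) of unmasked cell values whose centers lie within
#' \code{radius} of each cell center. Used to precompute buffer-statistic
#' surfaces for prediction and simulation.
#'
#' @param raster a RasterGrid.
#' @param radius buffer radius (m).
#' @param stat "mean" or "sum".
#' @return a RasterGrid (same mask).
#' @export
focalDisc <- function(raster, radius, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  if (radius <= 0) stop("radius must be positive")
  K <- discKernel(radius, raster@cellSize)
  ok <- 1 - raster@nodata
  v <- raster@values
  v[raster@nodata] <- 0
  num <- fftConvolve(v, K)
  if (stat == "sum") out <- num
  else {
    den <- fftConvolve(ok, K)
    out <- ifelse(den > 0.5, num / pmax(den, 0.5), NA_real_)
  }
  ## FFT roundoff can leave tiny negatives on zero fields
  out[abs(out) < 1e-10] <- 0
  rasterGrid(out, raster@origin, raster@cellSize, raster@nodata,
             paste0(raster@name, "_", stat, round(radius)))
}

## ---- Gaussian random fields ----

#' Smooth standardized Gaussian random field
#'
#' White noise filtered with a Gaussian kernel of the given correlation
#' length, standardized to mean 0 / sd 1. Deterministic for a fixed seed.
#'
#' @param nrow,ncol grid shape.
#' @param range correlation length in cells (kernel sd).
#' @param seed integer seed.
#' @return numeric matrix.
#' @export
gaussianField <- function(nrow, ncol, range, seed) {
  if (nrow <= 0 || ncol <= 0) stop("grid dimensions must be positive")
  withSeed(seed, {
    z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
    if (range > 0) {
      rc <- max(1L, ceiling(3 * range))
      off <- (-rc):rc
      k1 <- exp(-off^2 / (2 * range^2))
      K <- outer(k1, k1)
      K <- K / sum(K)
      z <- fftConvolve(z, K)
    }
    (z - mean(z)) / stats::sd(z)
  })
}

## ---- distances and line rasterization ----

## Vectorized point-to-segment distances: points (px,py), segment (a,b).
segDistance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * vx + (py - ay) * vy) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

## All segments of a list of LinearFeatureSet (or one set) as a matrix.
segmentTable <- function(lines) {
  if (is(lines, "LinearFeatureSet")) lines <- list(lines)
  segs <- list()
  for (fs in lines) for (f in fs@features) {
    n <- nrow(f)
    segs[[length(segs) + 1L]] <-
      cbind(f[-n, 1], f[-n, 2], f[-1, 1], f[-1, 2])
  }
  if (!length(segs)) matrix(numeric(), 0, 4) else do.call(rbind, segs)
}

#' Raster of distances to the nearest polyline feature
#'
#' @param lines a LinearFeatureSet or list of them.
#' @param template RasterGrid defining grid and mask.
#' @return RasterGrid of distances (m) from each cell center.
#' @export
distanceRaster <- function(lines, template) {
  segs <- segmentTable(lines)
  if (!nrow(segs)) stop("empty feature set: distance is undefined")
  ctr <- cellCenters(template)
  d <- dim(template@values)
  px <- rep(ctr$x, each = d[1])
  py <- rep(ctr$y, times = d[2])
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(segs)))
    best <- pmin(best, segDistance(px, py, segs[i, 1], segs[i, 2],
                                   segs[i, 3], segs[i, 4]))
  rasterGrid(matrix(best, d[1], d[2]), template@origin, template@cellSize,
             template@nodata, "distance")
}

#' Rasterize polyline length per cell
#'
#' Walks each segment in small steps and accumulates step lengths by the cell
#' the step midpoint falls in; used for line-density surfaces.
#'
#' @param lines a LinearFeatureSet or list of them.
#' @param template RasterGrid.
#' @param step walking step (m), default 5.
#' @return RasterGrid of metres of line per cell.
#' @export
rasterizeLineLength <- function(lines, template, step = 5) {
  d <- dim(template@values)
  acc <- matrix(0, d[1], d[2])
  segs <- segmentTable(lines)
  for (i in seq_len(nrow(segs))) {
    L <- sqrt((segs[i, 3] - segs[i, 1])^2 + (segs[i, 4] - segs[i, 2])^2)
    if (L == 0) next
    n <- max(1L, ceiling(L / step))
    t <- (seq_len(n) - 0.5) / n
    mx <- segs[i, 1] + t * (segs[i, 3] - segs[i, 1])
    my <- segs[i, 2] + t * (segs[i, 4] - segs[i, 2])
    rc <- pointToCell(template, cbind(mx, my))
    ok <- !is.na(rc[, 1])
    if (!any(ok)) next
    idx <- (rc[ok, 2] - 1L) * d[1] + rc[ok, 1]
    tab <- tabulate(idx, nbins = d[1] * d[2])
    acc <- acc + matrix(tab, d[1], d[2]) * (L / n)
  }
  rasterGrid(acc, template@origin, template@cellSize, template@nodata, "linelen")
}

## ---- scaling ----

#' Scale a raster to [0, 1]
#'
#' Subtracts the minimum and divides by the range over unmasked cells; a
#' constant raster maps to all zeros. The pre-scaling bounds are attached as
#' attributes \code{scale_min} / \code{scale_max} of the returned object's
#' values are recorded in the provenance of downstream RiskSurfaces.
#'
#' @param raster RasterGrid (or numeric matrix).
#' @param mask optional logical nodata mask overriding the raster's own.
#' @return RasterGrid in [0, 1] with attributes \code{scale_min}, \code{scale_max}.
#' @export
scale01 <- function(raster, mask = NULL) {
  if (!is(raster, "RasterGrid")) raster <- rasterGrid(raster)
  if (!is.null(mask)) raster@nodata <- mask | raster@nodata
  v <- raster@values[!raster@nodata]
  if (!length(v)) stop("no unmasked cells to scale")
  lo <- min(v); hi <- max(v)
  out <- raster
  if (hi == lo) out@values[] <- 0
  else out@values <- (raster@values - lo) / (hi - lo)
  out@values[out@nodata] <- 0
  attr(out, "scale_min") <- lo
  attr(out, "scale_max") <- hi
  out
}

## ---- polygon utilities ----

#' Point-in-polygon test (ray casting)
#' @param xy two-column point matrix.
#' @param poly polygon vertex matrix (closed implicitly).
#' @return logical vector.
#' @export
pointInPolygon <- function(xy, poly) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(xy))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > xy[, 2]) != (yj > xy[, 2])) &
      (xy[, 1] < (xj - xi) * (xy[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

## ---- plain-text raster and vector I/O ----

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band format readable by standard GIS tools. Masked cells
#' are written as the nodata value.
#'
#' @param raster RasterGrid.
#' @param path output file.
#' @param nodataValue sentinel, default -9999.
#' @export
writeAsciiGrid <- function(raster, path, nodataValue = -9999) {
  d <- dim(raster@values)
  v <- raster@values
  v[raster@nodata] <- nodataValue
  hdr <- c(paste("ncols", d[2]), paste("nrows", d[1]),
           paste("xllcorner", raster@origin[1]),
           paste("yllcorner", raster@origin[2]),
           paste("cellsize", raster@cellSize),
           paste("NODATA_value", nodataValue))
  rows <- apply(v[d[1]:1, , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 15),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file written by \code{\link{writeAsciiGrid}} (or any GIS).
#' @param name band name for the result.
#' @return RasterGrid.
#' @export
readAsciiGrid <- function(path, name = "band") {
  ln <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", ln[i])) {
    kv <- strsplit(trimws(ln[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- do.call(rbind, lapply(ln[i:length(ln)], function(r)
    as.numeric(strsplit(trimws(r), "[[:space:]]+")[[1]])))
  vals <- vals[nrow(vals):1, , drop = FALSE]
  nd <- if (!is.null(hdr$nodata_value)) vals == hdr$nodata_value
        else matrix(FALSE, nrow(vals), ncol(vals))
  vals[nd] <- 0
  rasterGrid(vals, c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize, nd, name)
}

#' Write linear features as GeoJSON
#' @param lines named list of LinearFeatureSet.
#' @param path output file.
#' @export
writeLinesGeoJSON <- function(lines, path) {
  feats <- list()
  for (nm in names(lines)) {
    fs <- lines[[nm]]
    for (f in fs@features)
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(class = fs@classLabel, set = nm),
        geometry = list(type = "LineString",
                        coordinates = unname(lapply(seq_len(nrow(f)),
                                                    function(i) as.numeric(f[i, ])))))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read linear features from GeoJSON
#' @param path GeoJSON file with LineString features carrying a "class" property.
#' @return named list of LinearFeatureSet, one per feature class present.
#' @export
readLinesGeoJSON <- function(path) {
  g <- jsonlite::read_json(path)
  cls <- vapply(g$features, function(f) f$properties$class, "")
  out <- list()
  for (cl in unique(cls)) {
    feats <- lapply(g$features[cls == cl], function(f)
      do.call(rbind, lapply(f$geometry$coordinates, as.numeric)))
    out[[cl]] <- new("LinearFeatureSet", features = feats, classLabel = cl)
  }
  out
}
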