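#' Default landscape synthesis configuration
#'
#' Parameters of the synthetic study region: grid shape and cell size,
#' correlation lengths of the Gaussian random fields behind each covariate,
#' linear-feature counts, the protected-area fraction and the high-elevation
#' exclusion threshold. Defaults give a 200 x 200 grid of 30-m cells (6 x 6
#' km) with a conifer-dominated mosaic, rare deciduous patches, cutblocks
#' concentrated on the unprotected eastern side, and contiguous high-country
#' above the 2000-m exclusion threshold.
#'
#' @param nrow,ncol grid shape (cells).
#' @param cellSize cell edge (m).
#' @param nStreams,nRoads,nTrails linear feature counts.
#' @param parkFraction fraction of the x-extent inside the protected area
#'   (western side).
#' @param exclusionElev exclusion threshold (m).
#' @return named list of parameters.
#' @export
landscapeConfig <- function(nrow = 200, ncol = 200, cellSize = 30,
                            nStreams = 6, nRoads = 3, nTrails = 6,
                            parkFraction = 0.45, exclusionElev = 2000) {
  if (nrow <= 0 || ncol <= 0) stop("grid dimensions must be positive")
  if (cellSize <= 0) stop("cell size must be positive")
  list(nrow = nrow, ncol = ncol, cellSize = cellSize,
       nStreams = nStreams, nRoads = nRoads, nTrails = nTrails,
       parkFraction = parkFraction, exclusionElev = exclusionElev)
}

## A polyline spanning the grid: straight base path with a mean-reverting
## (Ornstein-Uhlenbeck) lateral wiggle, so every feature crosses the region.
jitteredLine <- function(base, vertical, span, step, wiggleSd, lim, meanRev = 0.15) {
  n <- max(2L, ceiling(span / step) + 1L)
  along <- seq(0, span, length.out = n)
  off <- numeric(n)
  innov <- wiggleSd * sqrt(2 * meanRev)
  for (i in 2:n)
    off[i] <- off[i - 1] * (1 - meanRev) + stats::rnorm(1, 0, innov)
  lat <- pmin(pmax(base + off, 0), lim)
  if (vertical) cbind(lat, along) else cbind(along, lat)
}

#' Generate the synthetic study region
#'
#' Builds covariate rasters (landcover proportions, terrain, greenness,
#' herbaceous forage biomass), linear features (streams, motorized roads,
#' nonmotorized trails), the protected-area and exclusion masks, and the
#' three summer-range polygons. Bit-reproducible for a fixed seed.
#'
#' Landcover proportions come from exponentiated Gaussian random fields
#' normalized against a bare-ground class, so the six covariate classes sum
#' to at most 1 in every cell; "open" canopy is defined as 1 - conifer -
#' deciduous. The elevation field mixes a broad (3-km) component, which makes
#' the > 2000 m exclusion contiguous, with a short-range rough component that
#' carries slope and ruggedness variation.
#'
#' @param config list from \code{\link{landscapeConfig}}.
#' @param seed integer seed.
#' @return a \linkS4class{Landscape}.
#' @export
generateLandscape <- function(config = landscapeConfig(), seed = 1) {
  nr <- config$nrow; nc <- config$ncol; h <- config$cellSize
  if (nr <= 0 || nc <= 0) stop("grid dimensions must be positive")
  if (h <= 0) stop("cell size must be positive")
  xmax <- nc * h; ymax <- nr * h
  withSeed(seed, {
    sub <- sample.int(1e8, 24)

    ## terrain: broad structure carries the high-country exclusion; a
    ## stationary short-range roughness component carries slope/ruggedness
    broad <- gaussianField(nr, nc, 100, sub[1])
    rough <- gaussianField(nr, nc, 2, sub[2])
    ctr <- list(x = (seq_len(nc) - 0.5) * h, y = (seq_len(nr) - 0.5) * h)
    westUp <- matrix(rep(1 - ctr$x / xmax, each = nr), nr, nc)
    elev <- 1650 + 200 * broad + 280 * westUp + 50 * rough

    ## landcover class weights (softmax-normalized with a bare class)
    xfrac <- matrix(rep(ctr$x / xmax, each = nr), nr, nc)
    park <- xfrac < config$parkFraction
    wConifer <- exp(1.0 + 0.8 * gaussianField(nr, nc, 30, sub[3]))
    wDecid   <- exp(-3.2 + 1.2 * gaussianField(nr, nc, 18, sub[4]))
    wHerb    <- exp(-0.6 + 0.8 * gaussianField(nr, nc, 15, sub[5]))
    wShrub   <- exp(-1.1 + 0.8 * gaussianField(nr, nc, 10, sub[6]))
    wBurn    <- exp(-3.6 + 1.6 * gaussianField(nr, nc, 25, sub[7]))
    wCut     <- exp(-3.4 + 1.2 * gaussianField(nr, nc, 35, sub[8]) +
                      log(0.05 + 0.95 * xfrac)) * (!park)
    wBare    <- exp(-1.8 + 0.6 * gaussianField(nr, nc, 20, sub[9]) +
                      2.5 * pmax(0, elev - 1900) / 300)
    wSum <- wConifer + wDecid + wHerb + wShrub + wBurn + wCut + wBare
    conifer <- wConifer / wSum; decid <- wDecid / wSum
    herb <- wHerb / wSum; shrub <- wShrub / wSum
    burn <- wBurn / wSum; cutblk <- wCut / wSum
    open <- 1 - conifer - decid

    ## greenness on a 0-10000 integer-like scale: mostly fine-scale
    ## phenological texture with a mild herbaceous-cover signal
    g <- 1.2 * gaussianField(nr, nc, 6, sub[10]) + 1.0 * herb + 0.8 * shrub -
      0.5 * wBare / wSum
    ndvi <- 1000 + 8000 * (g - min(g)) / (max(g) - min(g))

    ## herbaceous forage biomass (g/m2): modest variation around ~3, with a
    ## broad productivity gradient so landscape-scale buffer means retain
    ## contrast
    herbfg <- pmax(2.8 + 2.2 * herb + 0.55 * gaussianField(nr, nc, 12, sub[11]) +
                     0.6 * gaussianField(nr, nc, 60, sub[16]), 0)

    ## linear features: semi-regular crossing networks (alternating
    ## orientations, evenly spaced with jitter) so transects meet them as
    ## short transverse encounters rather than long parallel stretches
    mkSet <- function(n, label, wiggleSd, step, eastOnly = FALSE,
                      placement = c("even", "random")) {
      placement <- match.arg(placement)
      feats <- list()
      if (n > 0) {
        nV <- ceiling(n / 2); nH <- n - nV
        lo <- if (eastOnly) 0.5 * xmax else 0
        k <- 0
        for (i in seq_len(nV)) {
          x0 <- if (placement == "even")
            lo + (i - 0.5) / nV * (xmax - lo) +
              stats::runif(1, -0.08, 0.08) * xmax
          else stats::runif(1, lo, xmax)
          k <- k + 1
          feats[[k]] <- jitteredLine(min(max(x0, 0), xmax), TRUE, ymax,
                                     step, wiggleSd, xmax)
        }
        for (i in seq_len(nH)) {
          y0 <- if (placement == "even")
            (i - 0.5) / max(nH, 1) * ymax +
              stats::runif(1, -0.08, 0.08) * ymax
          else stats::runif(1, 0, ymax)
          k <- k + 1
          feats[[k]] <- jitteredLine(min(max(y0, 0), ymax), FALSE,
                                     xmax - lo, step, wiggleSd, ymax)
          if (eastOnly) feats[[k]][, 1] <- feats[[k]][, 1] + lo
        }
      }
      new("LinearFeatureSet", features = feats, classLabel = label)
    }
    streams <- withSeed(sub[12], mkSet(config$nStreams, "stream", 250, 150))
    roads <- withSeed(sub[13], mkSet(config$nRoads, "motorized", 300, 200,
                                     eastOnly = TRUE, placement = "random"))
    trails <- withSeed(sub[14], mkSet(config$nTrails, "nonmotorized", 160, 90))

    template <- rasterGrid(elev, c(0, 0), h, name = "elev")
    terr <- deriveTerrain(template)
    edge <- deriveForestEdge(rasterGrid(conifer, c(0, 0), h, name = "conifer"),
                             rasterGrid(decid, c(0, 0), h, name = "decid"))

    mk <- function(v, nm) rasterGrid(v, c(0, 0), h, name = nm)
    rasters <- list(
      conifer = mk(conifer, "conifer"), decid = mk(decid, "decid"),
      herb = mk(herb, "herb"), shrub = mk(shrub, "shrub"),
      burn = mk(burn, "burn"), cutblk = mk(cutblk, "cutblk"),
      open = mk(open, "open"), elev = mk(elev, "elev"),
      slope = terr$slope, rugg = terr$rugg,
      ndvi = mk(ndvi, "ndvi"), herbfg = mk(herbfg, "herbfg"),
      edge = edge)

    exclusion <- elev > config$exclusionElev
    wX <- config$parkFraction * xmax
    yhtX <- 0.72 * xmax
    rect <- function(x1, x2) cbind(c(x1, x2, x2, x1), c(0, 0, ymax, ymax))
    new("Landscape", rasters = rasters,
        lines = list(stream = streams, motorized = roads, nonmotorized = trails),
        parkMask = park, exclusionMask = exclusion,
        rangePolygons = list(West = rect(0, wX), YHT = rect(wX, yhtX),
                             East = rect(yhtX, xmax)),
        config = c(config, seed = seed))
  })
}

#' Slope and ruggedness from an elevation raster
#'
#' Slope in degrees from central differences (one-sided at edges);
#' ruggedness as the standard deviation of the 3 x 3 elevation neighborhood
#' normalized by its grid-wide maximum, giving values in [0, 1].
#'
#' @param elev elevation RasterGrid (m).
#' @return list with RasterGrids \code{slope} and \code{rugg}.
#' @export
deriveTerrain <- function(elev) {
  z <- elev@values
  d <- dim(z)
  if (d[1] < 3 || d[2] < 3) stop("grid must be at least 3 x 3")
  h <- elev@cellSize

  colL <- z[, c(1, seq_len(d[2] - 1))]
  colR <- z[, c(seq_len(d[2] - 1) + 1, d[2])]
  den <- matrix(2 * h, d[1], d[2]); den[, c(1, d[2])] <- h
  dzdx <- (colR - colL) / den
  rowD <- z[c(1, seq_len(d[1] - 1)), ]
  rowU <- z[c(seq_len(d[1] - 1) + 1, d[1]), ]
  den <- matrix(2 * h, d[1], d[2]); den[c(1, d[1]), ] <- h
  dzdy <- (rowU - rowD) / den
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi

  ## neighborhood SD via moving sums of z and z^2 (edge cells use the
  ## neighbors that exist); sample SD with n-1 denominator
  K <- matrix(1, 3, 3)
  n <- fftConvolve(matrix(1, d[1], d[2]), K)
  s1 <- fftConvolve(z, K)
  s2 <- fftConvolve(z^2, K)
  varr <- pmax((s2 - s1^2 / n) / (n - 1), 0)
  ## FFT roundoff floor: a flat neighborhood must give exactly zero
  varr[varr < 1e-12 * mean(z^2)] <- 0
  sdv <- sqrt(varr)
  mx <- max(sdv)
  rugg <- if (mx > 0) sdv / mx else sdv

  list(slope = rasterGrid(slope, elev@origin, h, elev@nodata, "slope"),
       rugg = rasterGrid(rugg, elev@origin, h, elev@nodata, "rugg"))
}

#' Forest/non-forest edge cells
#'
#' A cell is edge when it is forest-majority (conifer + deciduous > 0.5) and
#' any of its 4-neighbors is not, or vice versa: a one-cell (30-m) buffer of
#' the forest boundary on both sides.
#'
#' @param conifer,decid proportion RasterGrids.
#' @return 0/1 RasterGrid named "edge".
#' @export
deriveForestEdge <- function(conifer, decid) {
  if (is.null(conifer) || is.null(decid)) stop("conifer and decid rasters required")
  f <- conifer@values + decid@values > 0.5
  d <- dim(f)
  differs <- matrix(FALSE, d[1], d[2])
  differs[-1, ] <- differs[-1, ] | (f[-1, ] != f[-d[1], ])
  differs[-d[1], ] <- differs[-d[1], ] | (f[-d[1], ] != f[-1, ])
  differs[, -1] <- differs[, -1] | (f[, -1] != f[, -d[2]])
  differs[, -d[2]] <- differs[, -d[2]] | (f[, -d[2]] != f[, -1])
  rasterGrid(differs * 1, conifer@origin, conifer@cellSize, conifer@nodata, "edge")
}

#' Protected-area step density, smoothed
#'
#' A spatial probability density that is \code{inOutRatio} times higher
#' inside the protected area than outside, smoothed along the border with a
#' circular moving-average window of the given diameter (a home-range-sized
#' footprint), then renormalized to integrate to one over unmasked cells.
#'
#' @param parkMask logical matrix, TRUE inside the protected area.
#' @param inOutRatio in-park : out-park density ratio (> 0).
#' @param windowDiameter smoothing window diameter (m); 0 skips smoothing.
#' @param species species tag.
#' @param template RasterGrid supplying grid geometry and nodata mask.
#' @return an \linkS4class{AbundancePDF}.
#' @export
buildAbundancePdf <- function(parkMask, inOutRatio, windowDiameter = 0,
                              species = "bear", template) {
  if (inOutRatio <= 0) stop("inOutRatio must be positive")
  if (windowDiameter < 0) stop("windowDiameter must be nonnegative")
  ok <- !template@nodata
  if (!any(ok)) stop("all cells are masked")
  dens <- matrix(1, nrow(parkMask), ncol(parkMask))
  dens[parkMask] <- inOutRatio
  if (windowDiameter > 0) {
    K <- discKernel(windowDiameter / 2, template@cellSize)
    num <- fftConvolve(dens * ok, K)
    den <- fftConvolve(ok * 1, K)
    dens <- ifelse(den > 0.5, num / pmax(den, 0.5), 0)
  }
  dens[!ok] <- 0
  dens <- dens / (sum(dens[ok]) * template@cellSize^2)
  new("AbundancePDF",
      density = rasterGrid(dens, template@origin, template@cellSize,
                           template@nodata, paste0(species, "_pdf")),
      species = species)
}

#' Territory-mixture abundance density
#'
#' Mixture of isotropic Gaussian kernels, one per pack, with mixture weights
#' proportional to pack size; renormalized to integrate to one over unmasked
#' cells.
#'
#' @param territoryCenters two-column matrix of pack centers (m).
#' @param packSizes integer vector of pack sizes (>= 1).
#' @param bandwidth kernel standard deviation (m).
#' @param template RasterGrid supplying geometry and mask.
#' @param species species tag.
#' @return an \linkS4class{AbundancePDF}.
#' @export
buildWolfPdf <- function(territoryCenters, packSizes, bandwidth, template,
                         species = "wolf") {
  territoryCenters <- matrix(as.numeric(territoryCenters), ncol = 2)
  if (nrow(territoryCenters) < 1) stop("need at least one territory")
  if (any(packSizes < 1)) stop("pack sizes must be >= 1")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  ctr <- cellCenters(template)
  d <- dim(template@values)
  px <- rep(ctr$x, each = d[1]); py <- rep(ctr$y, times = d[2])
  w <- packSizes / sum(packSizes)
  dens <- numeric(length(px))
  for (i in seq_len(nrow(territoryCenters))) {
    d2 <- (px - territoryCenters[i, 1])^2 + (py - territoryCenters[i, 2])^2
    dens <- dens + w[i] * exp(-d2 / (2 * bandwidth^2)) / (2 * pi * bandwidth^2)
  }
  dens <- matrix(dens, d[1], d[2])
  ok <- !template@nodata
  dens[!ok] <- 0
  dens <- dens / (sum(dens[ok]) * template@cellSize^2)
  new("AbundancePDF",
      density = rasterGrid(dens, template@origin, template@cellSize,
                           template@nodata, paste0(species, "_pdf")),
      species = species)
}
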