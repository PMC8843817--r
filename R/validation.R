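#' Random validation points over the unmasked study area
#'
#' Uniform points over cells outside the exclusion mask (high elevation,
#' rock, ice), jittered within cells.
#'
#' @param landscape Landscape.
#' @param n number of points, default 1000.
#' @param seed integer seed.
#' @return n x 2 coordinate matrix.
#' @export
sampleValidationPoints <- function(landscape, n = 1000, seed = 1) {
  if (n <= 0) stop("n must be positive")
  ok <- which(!landscape@exclusionMask)
  if (!length(ok)) stop("no unmasked area to sample")
  tmpl <- landscape@rasters[[1]]
  d <- dim(tmpl@values); h <- tmpl@cellSize
  withSeed(seed, {
    cells <- ok[sample.int(length(ok), n, replace = TRUE)]
    rr <- (cells - 1L) %% d[1] + 1L
    cc <- (cells - 1L) %/% d[1] + 1L
    cbind(x = tmpl@origin[1] + (cc - 1L) * h + stats::runif(n, 0, h),
          y = tmpl@origin[2] + (rr - 1L) * h + stats::runif(n, 0, h))
  })
}

#' Spearman rank correlation with a large-sample p-value
#'
#' Average (mid-) ranks for ties; p from the t approximation with n - 2
#' degrees of freedom. Pearson available behind a flag.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method "spearman" (default) or "pearson".
#' @return list: rho, p, n.
#' @export
spearmanCor <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  rho <- stats::cor(x, y)
  tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(rho = rho, p = p, n = n)
}

#' Equal-area value bins of a surface
#'
#' Sorts unmasked cells by value (stable order for ties) and splits them
#' into k contiguous groups whose sizes differ by at most one cell.
#'
#' @param surface RiskSurface or RasterGrid.
#' @param k number of bins, default 10.
#' @return data.frame: bin, n_cells, mean; plus attribute "assignment"
#'   (bin index per unmasked cell in cell order).
#' @export
equalAreaBins <- function(surface, k = 10) {
  r <- if (is(surface, "RiskSurface")) surface@raster else surface
  if (k < 2) stop("k must be >= 2")
  v <- as.numeric(r@values)[!as.logical(r@nodata)]
  n <- length(v)
  if (n < k) stop("more bins than unmasked cells")
  ord <- order(v)  # stable: ties keep cell order
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  binOf <- integer(n)
  binOf[ord] <- rep(seq_len(k), sizes)
  out <- data.frame(bin = seq_len(k), n_cells = sizes,
                    mean = vapply(seq_len(k),
                                  function(b) mean(v[binOf == b]), numeric(1)))
  attr(out, "assignment") <- binOf
  out
}

#' Compare two risk surfaces the survey-validation way
#'
#' Spearman correlation of the two surfaces at n random unmasked points, and
#' a bin-level Spearman of per-bin means: cells are binned into k equal-area
#' classes on surface a and the mean of both surfaces is taken per bin.
#'
#' @param a,b congruent RiskSurfaces (or RasterGrids).
#' @param landscape Landscape (for the point sampler's mask).
#' @param nPoints random points, default 1000.
#' @param kBins bins, default 10.
#' @param seed integer seed.
#' @param method "spearman" or "pearson" for the point-level correlation.
#' @return list: point (rho, p, n), bin (rho, p, n), binTable
#'   (bin, n_cells, mean_a, se_a, mean_b, se_b), seed.
#' @export
compareSurfaces <- function(a, b, landscape, nPoints = 1000, kBins = 10,
                            seed = 1, method = "spearman") {
  ra <- if (is(a, "RiskSurface")) a@raster else a
  rb <- if (is(b, "RiskSurface")) b@raster else b
  if (!identical(dim(ra@values), dim(rb@values))) stop("grid mismatch")
  pts <- sampleValidationPoints(landscape, nPoints, seed)
  va <- extractAtPoints(ra, pts)
  vb <- extractAtPoints(rb, pts)
  point <- spearmanCor(va, vb, method)

  okMask <- !as.logical(ra@nodata) & !as.logical(rb@nodata)
  ca <- as.numeric(ra@values)[okMask]
  cb <- as.numeric(rb@values)[okMask]
  bins <- equalAreaBins(rasterGrid(matrix(ca), nodata = matrix(FALSE, length(ca), 1)),
                        kBins)
  binOf <- attr(bins, "assignment")
  agg <- function(v) vapply(seq_len(kBins), function(bn) mean(v[binOf == bn]),
                            numeric(1))
  aggSE <- function(v) vapply(seq_len(kBins), function(bn) {
    vi <- v[binOf == bn]; stats::sd(vi) / sqrt(length(vi))
  }, numeric(1))
  binTable <- data.frame(bin = seq_len(kBins), n_cells = bins$n_cells,
                         mean_a = agg(ca), se_a = aggSE(ca),
                         mean_b = agg(cb), se_b = aggSE(cb))
  bin <- spearmanCor(binTable$mean_a, binTable$mean_b)
  list(point = point, bin = bin, binTable = binTable, seed = seed)
}
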