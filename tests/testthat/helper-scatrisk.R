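## The acceptance checks report every expectation; never quit early.
options(testthat.progress.max_fails = 1000)

## Shared fixtures, built once per test run and cached.
.cache <- new.env(parent = emptyenv())

## Small study region for unit tests (60 x 60 cells, 1.8 x 1.8 km).
smallLandscape <- function() {
  if (is.null(.cache$small))
    .cache$small <- generateLandscape(
      landscapeConfig(nrow = 60, ncol = 60, nStreams = 3, nRoads = 2,
                      nTrails = 3), seed = 7)
  .cache$small
}

smallStacks <- function() {
  if (is.null(.cache$smallStacks))
    .cache$smallStacks <- makeStacks(smallLandscape())
  .cache$smallStacks
}

## Full study conditions (200 x 200 grid) for the acceptance suite.
fullWorld <- function() {
  if (is.null(.cache$world)) {
    L <- generateLandscape(seed = 42)
    S <- makeStacks(L)
    tr <- truthSet()
    ST <- trueSurfaces(L, S, tr)
    .cache$world <- list(L = L, S = S, tr = tr, ST = ST)
  }
  .cache$world
}

## Uniform random raster with a given seed.
randomRaster <- function(nr, nc, seed, cellSize = 30) {
  set.seed(seed)
  rasterGrid(matrix(runif(nr * nc), nr, nc), cellSize = cellSize)
}

## Straight one-segment transect for corridor geometry tests.
straightTransect <- function(x0 = 0, y0 = 500, x1 = 3000) {
  list(polyline = cbind(c(x0, x1), c(y0, y0)), cell = 1L, year = 2014,
       lengthKm = (x1 - x0) / 1000)
}
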