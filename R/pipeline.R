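#' Precompute all covariate stacks for a landscape
#'
#' One stack per pipeline stage: encounter (1.3-km buffers), elk-in-scat at
#' the species radius (cougar and coyote share 2 km), kill-site (250-m
#' buffers, distances in km) and RUF covariates.
#'
#' @param landscape Landscape.
#' @return list: pred, pelk (named by species), kill, ruf.
#' @export
makeStacks <- function(landscape) {
  pelk <- list()
  pelk$wolf <- covariateStack(landscape, defaultSpecs("P_elk", "wolf"))
  pelk$bear <- covariateStack(landscape, defaultSpecs("P_elk", "bear"))
  pelk$cougar <- covariateStack(landscape, defaultSpecs("P_elk", "cougar"))
  pelk$coyote <- pelk$cougar  # same 2-km radius and layers
  list(pred = covariateStack(landscape, defaultSpecs("P_pred")),
       pelk = pelk,
       kill = covariateStack(landscape, defaultSpecs("PR_kill")),
       ruf = covariateStack(landscape, defaultSpecs("RUF")))
}

#' Abundance density surfaces from the truth parameters
#'
#' @param landscape Landscape.
#' @param truth truth set (\code{\link{truthSet}}).
#' @return list with AbundancePDFs for bear and wolf (cougar/coyote NULL).
#' @export
makeAbundancePdfs <- function(landscape, truth) {
  tmpl <- landscape@rasters[[1]]
  tmpl@nodata <- landscape@exclusionMask
  d <- dim(tmpl@values); h <- tmpl@cellSize
  wp <- truth$abundance$wolf
  centers <- cbind(unlist(wp$territory_frac_x) * d[2] * h,
                   unlist(wp$territory_frac_y) * d[1] * h)
  list(bear = buildAbundancePdf(landscape@parkMask,
                                truth$abundance$bear$ratio,
                                truth$abundance$bear$window, "bear", tmpl),
       wolf = buildWolfPdf(centers, unlist(wp$pack_sizes), wp$bandwidth_m,
                           tmpl, "wolf"),
       cougar = NULL, coyote = NULL)
}

#' True (generating) surfaces from a truth set
#'
#' Builds the per-species encounter, elk-in-scat and scat-risk surfaces, the
#' total risk surface, the kill-stage truth surface and the elk utilization
#' truth surface, all from the truth coefficient sets evaluated on the
#' covariate stacks.
#'
#' @param landscape Landscape.
#' @param stacks result of \code{\link{makeStacks}}.
#' @param truth truth set.
#' @return list: pdfs, pPred, pElk, prScat (per species), prTotal, kill, ruf.
#' @export
trueSurfaces <- function(landscape, stacks, truth) {
  pdfs <- makeAbundancePdfs(landscape, truth)
  species <- names(truth$rsf)
  excl <- landscape@exclusionMask
  expSurf <- function(beta, stack) {
    lp <- linearPredictorRaster(beta, stack)
    rasterGrid(exp(lp@values - max(lp@values[!excl])), lp@origin, lp@cellSize,
               excl, "w")
  }
  pPred <- pElk <- prS <- list()
  for (spc in species) {
    pPred[[spc]] <- weightByAbundance(expSurf(truth$rsf[[spc]], stacks$pred),
                                      pdfs[[spc]], spc)
    pElk[[spc]] <- asPelkSurface(expSurf(truth$pelk[[spc]],
                                         stacks$pelk[[spc]]), spc)
    prS[[spc]] <- prScat(pPred[[spc]], pElk[[spc]])
  }
  kill <- asRiskSurface(scale01(expSurf(truth$kill, stacks$kill)),
                        "total", "PR_kill", list(truth = TRUE))
  rufLp <- linearPredictorRaster(truth$ruf, stacks$ruf)
  ruf <- scale01(rasterGrid(pmax(rufLp@values, 0), rufLp@origin,
                            rufLp@cellSize, excl, "ruf_true"))
  list(pdfs = pdfs, pPred = pPred, pElk = pElk, prScat = prS,
       prTotal = prTotal(prS), kill = kill, ruf = ruf)
}

## response ~ <truth terms> formula for a coefficient vector.
truthFormula <- function(beta) {
  stats::reformulate(names(beta), response = "response")
}

## An intercept-only component carries no spatial information; entering the
## risk product through the degenerate-range scaling convention would zero
## the whole species, so it enters as a neutral factor of ones instead.
neutralIfFlat <- function(rs) {
  lo <- rs@provenance$scale_min; hi <- rs@provenance$scale_max
  if (!is.null(lo) && !is.null(hi) && identical(lo, hi)) {
    rs@raster@values[] <- 1
    rs@provenance$neutral <- TRUE
  }
  rs
}

#' Run the full scat-to-risk pipeline on synthetic data
#'
#' One truth generates a survey campaign (transects, scats, contents) and a
#' kill sample; every model stage is then estimated from those data and the
#' estimated total scat-based risk surface is compared with the estimated
#' kill-site surface at random points and over equal-area bins.
#'
#' @param seed integer seed driving all survey randomness.
#' @param landscape Landscape (default: generate with \code{landscapeSeed}).
#' @param landscapeSeed seed for the default landscape.
#' @param stacks,truth,surfTruth optional precomputed pieces (reused across
#'   seeds in replicate studies).
#' @param nTransects,kmPerCell survey design.
#' @param nTarget detected non-old scats per species.
#' @param composition kill counts per predator.
#' @param doRuf also fit the elk RUF stage (slower), default FALSE.
#' @param nPoints,kBins validation settings.
#' @return list with all data, fitted models, surfaces and the comparison.
#' @export
runRiskPipeline <- function(seed = 1, landscape = NULL, landscapeSeed = 42,
                            stacks = NULL, truth = truthSet(),
                            surfTruth = NULL,
                            nTransects = 16, kmPerCell = 4,
                            nTarget = c(bear = 373, cougar = 42,
                                        coyote = 223, wolf = 470),
                            composition = c(bear = 42, cougar = 16,
                                            wolf = 37, unknown = 9),
                            doRuf = FALSE, nPoints = 1000, kBins = 10) {
  if (is.null(landscape)) landscape <- generateLandscape(seed = landscapeSeed)
  if (is.null(stacks)) stacks <- makeStacks(landscape)
  if (is.null(surfTruth)) surfTruth <- trueSurfaces(landscape, stacks, truth)
  defaults <- studyDefaults()
  sub <- withSeed(seed, sample.int(1e8, 8))

  transects <- generateTransects(landscape, nTransects, kmPerCell, sub[1])
  scats <- simulateScats(landscape, transects, truth, nTarget,
                         detectP = defaults$constants$detect_p, seed = sub[2],
                         stack = stacks$pred)
  frac <- unlist(defaults$contents_analyzed$by_species) /
    unlist(defaults$scats_rsf[names(defaults$contents_analyzed$by_species)])
  scats <- simulateScatContents(scats, truth, frac, sub[3], landscape,
                                stacks$pelk)

  species <- names(truth$rsf)
  rsfFits <- pelkFits <- pPred <- pElk <- prS <- list()
  for (spc in species) {
    tab <- rsfObservationTable(scats[scats$species == spc, ], transects,
                               landscape, defaultSpecs("P_pred"),
                               stack = stacks$pred,
                               nAvailable = defaults$constants$n_available,
                               seed = sub[4])
    rsfFits[[spc]] <- parsimonySelect(tab, truthFormula(truth$rsf[[spc]]),
                                      fitLogistic, stage = "P_pred",
                                      species = spc)
    pPred[[spc]] <- neutralIfFlat(weightByAbundance(
      predictRsf(rsfFits[[spc]], landscape, stacks$pred),
      surfTruth$pdfs[[spc]], spc))
    pelkFits[[spc]] <- fitPelk(scats, spc, landscape, stacks$pelk[[spc]],
                               truthFormula(truth$pelk[[spc]]),
                               parsimony = TRUE)
    pElk[[spc]] <- neutralIfFlat(asPelkSurface(
      predictRsf(pelkFits[[spc]], landscape, stacks$pelk[[spc]]), spc))
    prS[[spc]] <- prScat(pPred[[spc]], pElk[[spc]])
  }
  prTotalHat <- prTotal(prS)

  kills <- simulateKills(surfTruth$prTotal, composition, sub[5])
  killTab <- killStrataTable(kills, landscape, stacks$kill,
                             n = defaults$constants$n_controls,
                             radius = defaults$constants$control_radius_m,
                             seed = sub[6])
  killFit <- parsimonySelect(killTab, truthFormula(truth$kill),
                             fitConditionalLogistic)
  prKillHat <- predictPrKill(killFit, landscape, stacks$kill)

  rufRes <- NULL
  if (doRuf) {
    reloc <- simulateRelocations(surfTruth$ruf, seed = sub[7])
    rufRes <- fitRuf(reloc, landscape, stacks$ruf)
  }

  comparison <- tryCatch(
    compareSurfaces(prTotalHat, prKillHat, landscape, nPoints, kBins, sub[8]),
    error = function(e) list(point = list(rho = NA_real_, p = NA_real_),
                             bin = list(rho = NA_real_, p = NA_real_),
                             error = conditionMessage(e)))
  list(landscape = landscape, stacks = stacks, truth = truth,
       surfTruth = surfTruth, transects = transects, scats = scats,
       kills = kills, rsfFits = rsfFits, pelkFits = pelkFits,
       killFit = killFit, pPred = pPred, pElk = pElk, prScat = prS,
       prTotal = prTotalHat, prKill = prKillHat, ruf = rufRes,
       comparison = comparison, seed = seed)
}
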