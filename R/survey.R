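#' Generate a transect campaign
#'
#' Lays a systematic grid of square survey cells over the study region,
#' selects \code{nCells} of them, and walks one random-walk transect of
#' total length about \code{kmPerCell} inside each. Emulates a
#' systematic-grid scat-survey design.
#'
#' @param landscape Landscape.
#' @param nCells number of surveyed cells.
#' @param kmPerCell transect length per cell (km).
#' @param seed integer seed.
#' @param year nominal survey year tag.
#' @return list of transects; each has \code{polyline} (matrix, m),
#'   \code{cell}, \code{year}, \code{lengthKm}.
#' @export
generateTransects <- function(landscape, nCells = 16, kmPerCell = 4, seed = 1,
                              year = 2014) {
  if (kmPerCell <= 0) stop("kmPerCell must be positive")
  d <- dim(landscape@rasters[[1]]@values)
  h <- cellSize(landscape)
  xmax <- d[2] * h; ymax <- d[1] * h
  side <- ceiling(sqrt(nCells))
  if (nCells > side * side) stop("too many cells")
  if (nCells == 0) return(list())
  cw <- xmax / side; chh <- ymax / side
  withSeed(seed, {
    chosen <- sample.int(side * side, nCells)
    out <- vector("list", nCells)
    step <- 100
    nStep <- max(2L, round(kmPerCell * 1000 / step))
    for (i in seq_len(nCells)) {
      cc <- chosen[i]
      cx0 <- ((cc - 1) %% side) * cw
      cy0 <- ((cc - 1) %/% side) * chh
      pts <- matrix(NA_real_, nStep + 1, 2)
      pts[1, ] <- c(stats::runif(1, cx0 + 0.2 * cw, cx0 + 0.8 * cw),
                    stats::runif(1, cy0 + 0.2 * chh, cy0 + 0.8 * chh))
      heading <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(nStep)) {
        repeat {
          cand <- pts[s, ] + step * c(cos(heading), sin(heading))
          if (cand[1] > cx0 && cand[1] < cx0 + cw &&
              cand[2] > cy0 && cand[2] < cy0 + chh) break
          heading <- stats::runif(1, 0, 2 * pi)
        }
        pts[s + 1, ] <- cand
        heading <- heading + stats::rnorm(1, 0, 0.45)
      }
      out[[i]] <- list(polyline = pts, cell = cc, year = year,
                       lengthKm = nStep * step / 1000)
    }
    out
  })
}

#' View transects as a LinearFeatureSet
#' @param transects result of \code{\link{generateTransects}}.
#' @export
transectLines <- function(transects) {
  new("LinearFeatureSet",
      features = lapply(transects, `[[`, "polyline"),
      classLabel = "transect")
}

## Global segment table for the transect set with transect ids and lengths.
transectSegments <- function(transects) {
  segs <- list()
  for (i in seq_along(transects)) {
    p <- transects[[i]]$polyline
    n <- nrow(p)
    segs[[i]] <- cbind(p[-n, 1], p[-n, 2], p[-1, 1], p[-1, 2], i)
  }
  tab <- do.call(rbind, segs)
  len <- sqrt((tab[, 3] - tab[, 1])^2 + (tab[, 4] - tab[, 2])^2)
  cbind(tab, len)
}

## Uniform points in the 50-m corridor around transects (vectorized).
corridorPoints <- function(segTab, n, halfWidth = 50) {
  i <- sample.int(nrow(segTab), n, replace = TRUE, prob = segTab[, 6])
  t <- stats::runif(n)
  off <- stats::runif(n, -halfWidth, halfWidth)
  dx <- segTab[i, 3] - segTab[i, 1]; dy <- segTab[i, 4] - segTab[i, 2]
  L <- segTab[i, 6]
  px <- segTab[i, 1] + t * dx - off * dy / L
  py <- segTab[i, 2] + t * dy + off * dx / L
  cbind(x = px, y = py, transect = segTab[i, 5])
}

## Cells touched by the transect corridor (for the rejection bound).
corridorCellMask <- function(transects, template, halfWidth = 50) {
  d <- dim(template@values)
  mask <- matrix(FALSE, d[1], d[2])
  segTab <- transectSegments(transects)
  for (i in seq_len(nrow(segTab))) {
    L <- segTab[i, 6]
    if (L == 0) next
    nstep <- max(1L, ceiling(L / 10))
    t <- (seq_len(nstep) - 0.5) / nstep
    bx <- segTab[i, 1] + t * (segTab[i, 3] - segTab[i, 1])
    by <- segTab[i, 2] + t * (segTab[i, 4] - segTab[i, 2])
    ux <- -(segTab[i, 4] - segTab[i, 2]) / L
    uy <- (segTab[i, 3] - segTab[i, 1]) / L
    for (off in seq(-halfWidth, halfWidth, by = 10)) {
      rc <- pointToCell(template, cbind(bx + off * ux, by + off * uy))
      okp <- !is.na(rc[, 1])
      mask[rc[okp, , drop = FALSE]] <- TRUE
    }
  }
  mask
}

## Linear predictor surface sum(beta_j * layer_j) from a stack; interaction
## terms ("a:b") are cellwise products of the component layers.
linearPredictorRaster <- function(beta, stack) {
  nm <- names(beta)
  parts <- strsplit(nm, ":", fixed = TRUE)
  miss <- setdiff(unique(unlist(parts)), names(stack))
  if (length(miss)) stop("stack lacks layers: ", paste(miss, collapse = ", "))
  layer <- function(p) {
    v <- stack[[p[1]]]@values
    for (q in p[-1]) v <- v * stack[[q]]@values
    v
  }
  lp <- layer(parts[[1]]) * beta[[1]]
  if (length(beta) > 1)
    for (j in 2:length(beta)) lp <- lp + layer(parts[[j]]) * beta[[j]]
  r <- stack[[parts[[1]][1]]]
  rasterGrid(lp, r@origin, r@cellSize, r@nodata, "lp")
}

## Arc-length machinery for one transect polyline.
transectArc <- function(transect) {
  p <- transect$polyline
  segLen <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  list(p = p, segLen = segLen, cum = c(0, cumsum(segLen)),
       L = sum(segLen))
}

## Points at arc positions s with perpendicular offsets off.
arcToXY <- function(arc, s, off) {
  seg <- findInterval(s, arc$cum, rightmost.closed = TRUE)
  seg[seg >= nrow(arc$p)] <- nrow(arc$p) - 1L
  t <- (s - arc$cum[seg]) / arc$segLen[seg]
  ux <- (arc$p[seg + 1, 1] - arc$p[seg, 1]) / arc$segLen[seg]
  uy <- (arc$p[seg + 1, 2] - arc$p[seg, 2]) / arc$segLen[seg]
  cbind(arc$p[seg, 1] + t * arc$segLen[seg] * ux - off * uy,
        arc$p[seg, 2] + t * arc$segLen[seg] * uy + off * ux)
}

#' Deposit predator scats along transect corridors
#'
#' Two deposition modes share the same exponential selection truth.
#' The default, \code{"global"}, draws candidate points uniformly over the
#' whole 50-m-each-side corridor and rejection-samples against the corridor
#' maximum, so scat density is globally proportional to the selection
#' surface \code{exp(x(s)' beta_true)}. \code{"local"} instead places a
#' deposition event uniformly along the transect arc and locates the scat
#' within the event's linear window with probability proportional to the
#' same selection weight. Scats are
#' thinned by the detection probability; a configurable fraction is old
#' (pre-season) and flagged for downstream exclusion; generation stops when
#' the target count of detected, non-old scats is reached per species.
#'
#' @param landscape Landscape.
#' @param transects transect list.
#' @param truth truth set (see \code{\link{truthSet}}); per-species RSF
#'   coefficients named by covariate.
#' @param nTarget named integer vector of detected non-old scats per species.
#' @param detectP detection probability per scat (0 < p <= 1).
#' @param oldFraction fraction of deposited scats that are old.
#' @param seed integer seed.
#' @param stack precomputed encounter-stage covariate stack (required; see
#'   \code{\link{covariateStack}}).
#' @param deposition "global" (corridor-wide rejection sampling, default) or
#'   "local" (event-window variant).
#' @param windowLength along-transect window length (m) for local mode.
#' @return data.frame of scat records: id, species, x, y, age_class,
#'   elk_content ("not_analyzed"), transect_id.
#' @export
simulateScats <- function(landscape, transects, truth,
                          nTarget = c(bear = 373, cougar = 42, coyote = 223,
                                      wolf = 470),
                          detectP = 0.9, oldFraction = 0.15, seed = 1,
                          stack = NULL, deposition = c("global", "local"),
                          windowLength = 1300) {
  deposition <- match.arg(deposition)
  if (detectP <= 0 || detectP > 1) stop("detectP must be in (0, 1]")
  if (is.null(stack)) stop("a covariate stack is required")
  miss <- setdiff(names(nTarget), names(truth$rsf))
  if (length(miss)) stop("truth lacks species: ", paste(miss, collapse = ", "))
  segTab <- transectSegments(transects)
  if (!nrow(segTab)) stop("empty corridor")
  template <- landscape@rasters[[1]]
  arcs <- lapply(transects, transectArc)
  arcLens <- vapply(arcs, `[[`, numeric(1), "L")

  withSeed(seed, {
    res <- list()
    for (spc in names(nTarget)) {
      beta <- truth$rsf[[spc]]
      lpR <- linearPredictorRaster(beta, stack)
      lpOf <- function(pts) {
        rc <- pointToCell(template, pts)
        ok <- !is.na(rc[, 1])
        ok[ok] <- !landscape@exclusionMask[rc[ok, , drop = FALSE]]
        lp <- rep(NA_real_, nrow(pts))
        lp[ok] <- lpR@values[rc[ok, , drop = FALSE]]
        lp
      }
      rows <- list(); nGood <- 0L
      if (deposition == "local") {
        while (nGood < nTarget[[spc]]) {
          tid <- sample.int(length(arcs), 1L, prob = arcLens)
          arc <- arcs[[tid]]
          sE <- stats::runif(1, 0, arc$L)
          lo <- max(0, sE - windowLength / 2)
          hi <- min(arc$L, sE + windowLength / 2)
          pt <- NULL
          for (round in 1:20) {
            s <- stats::runif(40, lo, hi)
            off <- stats::runif(40, -50, 50)
            cand <- arcToXY(arc, s, off)
            lp <- lpOf(cand)
            keep <- which(is.finite(lp))
            if (!length(keep)) break
            u <- stats::runif(length(keep)) < exp(lp[keep] - max(lp[keep]))
            if (any(u)) { pt <- cand[keep[which(u)[1]], ]; break }
          }
          if (is.null(pt)) next
          old <- stats::runif(1) < oldFraction
          if (stats::runif(1) >= detectP) { next }  # deposited, not detected
          rows[[length(rows) + 1L]] <- data.frame(
            species = spc, x = pt[1], y = pt[2],
            age_class = if (old) "old" else
              if (stats::runif(1) < 0.5) "fresh" else "recent",
            transect_id = tid)
          if (!old) nGood <- nGood + 1L
        }
        df <- do.call(rbind, rows)
      } else {
        corrMask <- corridorCellMask(transects, template)
        M <- max(lpR@values[corrMask & !landscape@exclusionMask])
        got <- list()
        while (nGood < nTarget[[spc]]) {
          batch <- max(2000L, 4L * (nTarget[[spc]] - nGood))
          pts <- corridorPoints(segTab, batch)
          lp <- lpOf(pts[, 1:2])
          ok <- is.finite(lp)
          pts <- pts[ok, , drop = FALSE]; lp <- lp[ok]
          acc <- stats::runif(nrow(pts)) < exp(lp - M)
          if (!any(acc)) next
          pts <- pts[acc, , drop = FALSE]
          nAcc <- nrow(pts)
          old <- stats::runif(nAcc) < oldFraction
          det <- stats::runif(nAcc) < detectP
          df <- data.frame(species = spc, x = pts[, 1], y = pts[, 2],
                           age_class = ifelse(old, "old",
                                              ifelse(stats::runif(nAcc) < 0.5,
                                                     "fresh", "recent")),
                           transect_id = pts[, 3])[det, , drop = FALSE]
          got[[length(got) + 1L]] <- df
          nGood <- nGood + sum(!old & det)
        }
        df <- do.call(rbind, got)
      }
      ## stop the campaign at the scat that completes the target count
      cut <- which(cumsum(df$age_class != "old") == nTarget[[spc]])[1]
      res[[spc]] <- df[seq_len(cut), , drop = FALSE]
    }
    out <- do.call(rbind, res)
    out$id <- seq_len(nrow(out))
    out$elk_content <- "not_analyzed"
    rownames(out) <- NULL
    out[, c("id", "species", "x", "y", "age_class", "elk_content",
            "transect_id")]
  })
}

#' Assign prey contents to a subset of scats
#'
#' A seeded random subset of the non-old scats of each species is marked as
#' analyzed and given elk presence/absence from a logistic model on
#' species-radius buffer covariates, with the intercept calibrated so that
#' the expected elk fraction among analyzed scats matches the target
#' marginal rate. Remaining scats stay "not_analyzed".
#'
#' @param scats scat data.frame from \code{\link{simulateScats}}.
#' @param truth truth set; \code{truth$pelk[[species]]} holds slope
#'   coefficients, \code{truth$elkRate[[species]]} the marginal rate.
#' @param analyzedFraction scalar or named per-species fraction in (0, 1].
#' @param seed integer seed.
#' @param landscape Landscape.
#' @param stacks named list (by species) of P_elk covariate stacks.
#' @return scat data.frame with elk_content filled in.
#' @export
simulateScatContents <- function(scats, truth, analyzedFraction = 0.43,
                                 seed = 1, landscape = NULL, stacks = NULL) {
  if (any(analyzedFraction <= 0) || any(analyzedFraction > 1))
    stop("analyzedFraction must be in (0, 1]")
  if (is.null(stacks)) stop("P_elk covariate stacks are required")
  withSeed(seed, {
    for (spc in unique(scats$species)) {
      gamma <- truth$pelk[[spc]]
      if (is.null(gamma)) stop("truth lacks content model for ", spc)
      rate <- truth$elkRate[[spc]]
      idx <- which(scats$species == spc & scats$age_class != "old")
      frac <- if (length(analyzedFraction) > 1) analyzedFraction[[spc]]
              else analyzedFraction
      nA <- max(1L, round(frac * length(idx)))
      an <- sample(idx, nA)
      z <- vapply(names(gamma), function(nm)
        extractAtPoints(stacks[[spc]][[nm]], cbind(scats$x[an], scats$y[an])),
        numeric(length(an)))
      z <- matrix(z, ncol = length(gamma))
      eta <- drop(z %*% gamma)
      alpha <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - rate,
                              c(-30, 30))$root
      p <- stats::plogis(alpha + eta)
      scats$elk_content[an] <- ifelse(stats::runif(nA) < p, "present", "absent")
    }
    scats
  })
}

#' Simulate elk GPS relocations from a utilization surface
#'
#' Fixes are sampled proportionally to the surface value with small
#' first-order autocorrelation: each fix is, with small probability, drawn
#' from a kernel-weighted window around the previous fix, otherwise
#' independently from the surface.
#'
#' @param trueRufSurface nonnegative RasterGrid.
#' @param nAnimals number of animals.
#' @param nFixes fixes per animal (nominal 6-h spacing).
#' @param seed integer seed.
#' @param serialP probability a fix is serially dependent on the previous.
#' @return data.frame: animal_id, fix, x, y.
#' @export
simulateRelocations <- function(trueRufSurface, nAnimals = 66, nFixes = 120,
                                seed = 1, serialP = 0.25) {
  v <- trueRufSurface@values
  v[trueRufSurface@nodata] <- 0
  if (all(v <= 0)) stop("all-zero utilization surface")
  if (any(v < 0)) stop("utilization surface must be nonnegative")
  d <- dim(v); h <- trueRufSurface@cellSize
  org <- trueRufSurface@origin
  withSeed(seed, {
    prob <- as.numeric(v)
    cellXY <- function(cells) {
      rr <- (cells - 1L) %% d[1] + 1L
      cc <- (cells - 1L) %/% d[1] + 1L
      cbind(org[1] + (cc - 1L) * h + stats::runif(length(cells), 0, h),
            org[2] + (rr - 1L) * h + stats::runif(length(cells), 0, h))
    }
    out <- vector("list", nAnimals)
    win <- 7L  # +/- 7 cells (~200 m kernel within a 420-m window)
    for (a in seq_len(nAnimals)) {
      cells <- integer(nFixes)
      serial <- stats::runif(nFixes) < serialP
      serial[1] <- FALSE
      indep <- sample.int(length(prob), nFixes, replace = TRUE, prob = prob)
      cells[1] <- indep[1]
      for (t in 2:nFixes) {
        if (!serial[t]) { cells[t] <- indep[t]; next }
        r0 <- (cells[t - 1] - 1L) %% d[1] + 1L
        c0 <- (cells[t - 1] - 1L) %/% d[1] + 1L
        rr <- max(1L, r0 - win):min(d[1], r0 + win)
        cc <- max(1L, c0 - win):min(d[2], c0 + win)
        d2 <- outer((rr - r0)^2, (cc - c0)^2, "+") * h^2
        w <- v[rr, cc, drop = FALSE] * exp(-d2 / (2 * 200^2))
        if (all(w <= 0)) { cells[t] <- indep[t]; next }
        pick <- sample.int(length(w), 1L, prob = as.numeric(w))
        cells[t] <- (cc[(pick - 1L) %/% length(rr) + 1L] - 1L) * d[1] +
          rr[(pick - 1L) %% length(rr) + 1L]
      }
      xy <- cellXY(cells)
      out[[a]] <- data.frame(animal_id = a, fix = seq_len(nFixes),
                             x = xy[, 1], y = xy[, 2])
    }
    do.call(rbind, out)
  })
}

#' Simulate kill sites from a risk surface
#'
#' Kill locations are sampled proportionally to the (nonnegative) risk
#' value; predator labels are assigned from the composition counts in
#' randomized order.
#'
#' @param trueTotalRisk RasterGrid (or RiskSurface).
#' @param composition named counts per predator; default the 104-kill
#'   composition 42 bear / 16 cougar / 37 wolf / 9 unknown.
#' @param seed integer seed.
#' @return data.frame: id, x, y, predator.
#' @export
simulateKills <- function(trueTotalRisk,
                          composition = c(bear = 42, cougar = 16, wolf = 37,
                                          unknown = 9),
                          seed = 1) {
  if (is(trueTotalRisk, "RiskSurface")) trueTotalRisk <- trueTotalRisk@raster
  v <- trueTotalRisk@values
  v[trueTotalRisk@nodata] <- 0
  if (all(v <= 0)) stop("all-zero risk surface")
  if (any(composition < 0)) stop("composition must be nonnegative")
  n <- sum(composition)
  d <- dim(v); h <- trueTotalRisk@cellSize; org <- trueTotalRisk@origin
  withSeed(seed, {
    cells <- sample.int(length(v), n, replace = TRUE, prob = as.numeric(v))
    rr <- (cells - 1L) %% d[1] + 1L
    cc <- (cells - 1L) %/% d[1] + 1L
    data.frame(id = seq_len(n),
               x = org[1] + (cc - 1L) * h + stats::runif(n, 0, h),
               y = org[2] + (rr - 1L) * h + stats::runif(n, 0, h),
               predator = sample(rep(names(composition), composition)))
  })
}
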