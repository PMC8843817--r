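#' Machine-readable study defaults
#'
#' Loads the versioned JSON resource holding the study's printed numbers:
#' survey effort by year, scat and kill sample sizes, per-species elk
#' occurrence rates, the published coefficient sets used as synthetic truth,
#' and the pipeline constants (detection probability, buffer radii, control
#' counts, smoothing window, exclusion threshold).
#'
#' @param path optional path to an alternative defaults file.
#' @return nested list of defaults.
#' @export
studyDefaults <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "study_defaults.json", package = "scatrisk")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Serialize a defaults list back to JSON
#'
#' @param defaults list as returned by \code{\link{studyDefaults}}.
#' @param path output file.
#' @export
writeDefaults <- function(defaults, path) {
  jsonlite::write_json(defaults, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Synthetic-truth coefficient sets
#'
#' Bundles the published coefficient tables as the generating truth for the
#' simulators: per-species scat-RSF coefficients, per-species elk-in-scat
#' coefficients with marginal occurrence rates, the kill-site model, a
#' synthetic elk-RUF coefficient set, and abundance-surface parameters.
#'
#' @param defaults defaults list, default \code{studyDefaults()}.
#' @return list: rsf, pelk, elkRate, kill, ruf, abundance.
#' @export
truthSet <- function(defaults = studyDefaults()) {
  asVec <- function(x) unlist(x)
  list(rsf = lapply(defaults$rsf_coefficients, asVec),
       pelk = lapply(defaults$pelk_coefficients, asVec),
       elkRate = defaults$elk_rate,
       kill = asVec(defaults$kill_coefficients),
       ruf = asVec(defaults$ruf_coefficients_synthetic),
       abundance = list(
         bear = list(ratio = defaults$constants$park_density_ratio,
                     window = defaults$constants$smoothing_window_m),
         wolf = defaults$wolf_pdf_synthetic))
}

#' Recompute printed totals from their components
#'
#' Every total in the defaults is recomputed from its printed components and
#' compared; failures are reported, not raised.
#'
#' @param defaults defaults list.
#' @return data.frame: name, computed, expected, pass.
#' @export
bookkeepingCheck <- function(defaults = studyDefaults()) {
  rows <- list(
    c("survey_km_total",
      defaults$survey_km$y2013 + defaults$survey_km$y2014 +
        defaults$survey_km$y2015 + defaults$survey_km$y2016,
      defaults$survey_km$total),
    c("rsf_scats_total",
      sum(unlist(defaults$scats_rsf[c("bear", "cougar", "coyote", "wolf")])),
      defaults$scats_rsf$total),
    c("contents_by_method",
      defaults$contents_analyzed$macroscopic + defaults$contents_analyzed$dna,
      defaults$contents_analyzed$total),
    c("contents_by_species",
      sum(unlist(defaults$contents_analyzed$by_species)),
      defaults$contents_analyzed$total),
    c("elk_containing_total",
      sum(unlist(defaults$elk_containing[c("bear", "wolf", "coyote", "cougar")])),
      defaults$elk_containing$total),
    c("available_total",
      sum(unlist(defaults$available_set[c("bear", "wolf", "coyote", "cougar")])),
      defaults$available_set$total),
    c("kills_total",
      sum(unlist(defaults$kills[c("bear", "cougar", "wolf", "unknown")])),
      defaults$kills$total))
  out <- data.frame(name = vapply(rows, `[[`, "", 1),
                    computed = as.numeric(vapply(rows, `[[`, "", 2)),
                    expected = as.numeric(vapply(rows, `[[`, "", 3)))
  out$pass <- out$computed == out$expected
  out
}
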