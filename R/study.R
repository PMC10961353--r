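#' Desk-scale decoding and quality studies
#'
#' Convenience harnesses reproducing the study designs the package targets
#' at reduced dimensionality:
#' \describe{
#'   \item{runDecodingStudy}{generates a single-session-per-subject cohort
#'     on the reduced motor-ROI montage ([reducedMontage()]), extracts
#'     causal decoder features, and scores the spatio-temporal decoder by
#'     leave-one-subject-out cross-validation. The `"mvq"` profile plants
#'     the default lateralized response in mild-hair subjects; the
#'     `"pq_noise"` profile combines the severe-hair coupling floor with
#'     zero response amplitude, i.e. recordings that contain no decodable
#'     neural signal.}
#'   \item{runQualityStudy}{generates a multi-session cohort with the
#'     planted hair-to-coupling dependence, scores every session's ROI
#'     quality, auto-partitions PQ/MVQ, and runs the factor battery.}
#' }
#'
#' @param profile study condition.
#' @param nSubjects number of subjects (one session each).
#' @param seed master seed.
#' @param montage montage to simulate.
#' @param alpha,beta,gamma decoder hyperparameters.
#' @param grid optional data.frame(alpha, beta) for nested selection.
#' @param max_iter solver iteration cap.
#' @return `runDecodingStudy`: the [losoCV()] result, with the cohort
#'   manifest in attribute `manifest` and the unscaled per-session features
#'   in attribute `features`.
#' @export
runDecodingStudy <- function(profile = c("mvq", "pq_noise"), nSubjects = 12,
                             seed = 1, montage = reducedMontage(),
                             alpha = 0.05, beta = 62.5, gamma = 5,
                             grid = NULL, max_iter = 150) {
  profile <- match.arg(profile)
  demo <- demographicsConfig()
  if (profile == "mvq") {
    demo$hair_length <- c(1, 1, 0, 0)
    demo$hair_color <- c(1, 1, 1, 1, 0, 0)
    demo$hair_density <- c(1, 1, 0)
    hemo <- hemodynamicSpec()
  } else {
    demo$hair_length <- c(0, 0, 0, 1)
    demo$hair_color <- c(0, 0, 0, 0, 0, 1)
    demo$hair_density <- c(0, 0, 1)
    hemo <- hemodynamicSpec(amp_hbo = 0, initial_dip = FALSE)
  }
  co <- generateCohort(
    nSubjects = nSubjects, sessionCounts = nSubjects, montage = montage,
    hemo = hemo, demographics = demo, seed = seed,
    sessionFun = function(s) extractTrialFeatures(s, scale = FALSE))
  cv <- losoCV(co$results, co$manifest$subject_id, alpha = alpha,
               beta = beta, gamma = gamma, grid = grid, max_iter = max_iter)
  attr(cv, "manifest") <- co$manifest
  attr(cv, "features") <- co$results
  cv
}

#' @rdname runDecodingStudy
#' @param sessionCounts subjects attending sessions 1..k (nested).
#' @return `runQualityStudy`: list(scores, partition, manifest, factors,
#'   battery, severity).
#' @export
runQualityStudy <- function(nSubjects = 32, sessionCounts = c(32, 15, 14),
                            seed = 1,
                            montage = buildDefaultMontage(
                              defaultGeometryConfig(tilesPerHemisphere = 2))) {
  co <- generateCohort(
    nSubjects = nSubjects, sessionCounts = sessionCounts, montage = montage,
    seed = seed,
    sessionFun = function(s) {
      cv <- coefficientOfVariation(s)
      roiQualityScore(cv, channels(s), montage@roiCenters)
    })
  scores <- unlist(co$results)
  part <- partitionSessions(scores)
  sev <- hairSeverity(co$factors)
  battery <- factorBattery(scores, co$factors)
  list(scores = scores, partition = part, manifest = co$manifest,
       factors = co$factors, battery = battery, severity = sev)
}
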