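#' Per-channel coefficient of variation
#'
#' CV_c = sigma_c / mu_c of the raw intensity, computed with sample SD
#' (ddof = 1) over the task segments of the session (baseline and break
#' periods discarded, with a 1-s guard band for filter transients).
#'
#' @param session a [NirsSession-class], or an intensity matrix (then all
#'   samples are used).
#' @param guard guard band (s) inside each block span.
#' @return numeric vector of CVs; channels with non-positive mean are NA and
#'   flagged via the `undefined` attribute.
#' @export
coefficientOfVariation <- function(session, guard = 1) {
  x <- segmentIntensity(session, guard)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  attr(cv, "undefined") <- which(mu <= 0)
  cv
}

segmentIntensity <- function(session, guard = 1) {
  if (!is(session, "NirsSession")) return(session)
  x <- intensity(session)
  idx <- taskSegmentIndex(markers(session), samplingRate(session), ncol(x), guard)
  if (!length(idx)) x else x[, idx, drop = FALSE]
}

#' Robust per-channel signal-to-noise ratio (dB)
#'
#' SNR_c = 10 log10( median(x_c) / median|x_c - median(x_c)| ) on the task
#' segments. A zero MAD (constant channel) returns the configured ceiling
#' and is flagged.
#'
#' @inheritParams coefficientOfVariation
#' @param ceiling_db cap for degenerate (zero-MAD) channels.
#' @return numeric vector (dB) with attribute `capped`.
#' @export
robustSNR <- function(session, guard = 1, ceiling_db = 60) {
  x <- segmentIntensity(session, guard)
  med <- apply(x, 1, median)
  madraw <- apply(abs(x - med), 1, median)
  out <- ifelse(madraw > 0 & med > 0, 10 * log10(med / madraw), ceiling_db)
  attr(out, "capped") <- which(madraw == 0 | med <= 0)
  out
}

#' Stimulus-dependent SNR (dB)
#'
#' Per channel: the signal power P_s is the mean square of the 0.01-0.1 Hz
#' Butterworth-bandpassed series in the [0, 2) s post-onset window after
#' subtracting its own [-2, 0) s baseline mean; the noise power P_n is the
#' mean square of the unfiltered series in [0, 2) s. Powers are averaged
#' over the covert motor-imagery trials before the ratio
#' 10 log10(P_s / P_n).
#'
#' @param x series matrix [channels x samples] (conventionally OD, or one
#'   chromophore's concentrations).
#' @param markerTable marker table with left/right trial markers at tapping
#'   onset.
#' @param fs sampling rate.
#' @return numeric vector (dB).
#' @export
stimulusSNR <- function(x, markerTable, fs) {
  onsets <- markerTable$time[markerTable$label %in% c("left", "right")]
  stopIfNot(length(onsets) > 0, "no motor-imagery trial markers present")
  xf <- butterBandpass(x, c(0.01, 0.1), fs, order = 2)
  ps <- matrix(NA_real_, nrow(x), 0); pn <- ps
  for (o in onsets) {
    iTask <- windowIndex(0, 2, fs, offset = -o)
    iBase <- windowIndex(-2, 0, fs, offset = -o)
    if (min(iBase) < 1 || max(iTask) > ncol(x)) next
    base <- rowMeans(xf[, iBase, drop = FALSE])
    sig <- xf[, iTask, drop = FALSE] - base
    ps <- cbind(ps, rowMeans(sig^2))
    pn <- cbind(pn, rowMeans(x[, iTask, drop = FALSE]^2))
  }
  10 * log10(rowMeans(ps) / rowMeans(pn))
}

#' ROI-weighted session quality score
#'
#' A 0-1 summary (1 = best) of montage quality that emphasizes channels over
#' the left/right motor cortices: score = sum_c w_c q(CV_c) / sum_c w_c with
#' w_c a Gaussian falloff (scale `sigma_mm`) of the channel midpoint's
#' distance to the nearest motor-ROI center and q(v) = exp(-v / v0) mapping
#' the coefficient of variation to quality. Channels with undefined CV count
#' as quality 0.
#'
#' @param cv per-channel CVs ([coefficientOfVariation()]).
#' @param channelTable matching channel table (mid_x/mid_y/mid_z columns).
#' @param roiCenters 2 x 3 matrix of ROI centers (e.g. `montage@roiCenters`).
#' @param sigma_mm Gaussian weight scale (mm).
#' @param v0 CV scale of the quality map.
#' @return scalar in [0, 1].
#' @export
roiQualityScore <- function(cv, channelTable, roiCenters, sigma_mm = 25,
                            v0 = 0.1) {
  d2 <- pmin(
    (channelTable$mid_x - roiCenters[1, 1])^2 +
      (channelTable$mid_y - roiCenters[1, 2])^2,
    (channelTable$mid_x - roiCenters[2, 1])^2 +
      (channelTable$mid_y - roiCenters[2, 2])^2
  )
  w <- exp(-d2 / (2 * sigma_mm^2))
  q <- ifelse(is.na(cv), 0, exp(-cv / v0))
  sum(w * q) / sum(w)
}

#' Convenience per-session quality summary
#'
#' @param session a [NirsSession-class].
#' @param roiCenters ROI centers; defaults to those recorded in the
#'   session's channel-table provenance via `montage`.
#' @param montage optional [Montage-class] supplying ROI centers.
#' @param ... passed to [roiQualityScore()].
#' @return list(cv, snr_db, score).
#' @export
sessionQuality <- function(session, montage = NULL, roiCenters = montage@roiCenters,
                           ...) {
  cv <- coefficientOfVariation(session)
  list(cv = cv, snr_db = robustSNR(session),
       score = roiQualityScore(cv, channels(session), roiCenters, ...))
}

#' Partition sessions into PQ / MVQ by ROI quality
#'
#' Manual mode labels a session MVQ iff its score exceeds `t_qual`. Auto
#' mode re-derives the threshold per cohort as the lowest upper bound of the
#' lowest-quality cluster: among sorted scores below the cohort median, the
#' largest gap separates the low cluster, and the threshold is that
#' cluster's maximum. If no meaningful gap exists (all scores equal, or <2
#' sessions) everything is labeled MVQ with a warning.
#'
#' @param scores per-session quality scores.
#' @param t_qual threshold, or NULL for auto mode.
#' @param min_gap smallest score gap regarded as a cluster separation.
#' @return data.frame(score, label) with attribute `t_qual`.
#' @export
partitionSessions <- function(scores, t_qual = NULL, min_gap = 1e-3) {
  if (is.null(t_qual)) {
    if (length(scores) < 2 || diff(range(scores)) <= min_gap) {
      warning("no quality gap found; all sessions labeled MVQ")
      t_qual <- -Inf
    } else {
      s <- sort(scores)
      # gap between consecutive sorted scores, restricted below the median
      gaps <- diff(s)
      gidx <- which(s[-length(s)] <= median(scores))
      gaps <- gaps[gidx]
      if (!length(gaps) || max(gaps) <= min_gap) {
        warning("no quality gap found; all sessions labeled MVQ")
        t_qual <- -Inf
      } else {
        t_qual <- s[gidx[which.max(gaps)]]
      }
    }
  }
  lab <- ifelse(scores > t_qual, "MVQ", "PQ")
  out <- data.frame(score = scores, label = lab)
  attr(out, "t_qual") <- t_qual
  out
}

#' Four-parameter logistic fit of CV vs channel length
#'
#' Fits cv(len) = a + (b - a) / (1 + exp(-(len - m) / s)) by nonlinear least
#' squares, describing the characteristic quality falloff with source-
#' detector separation.
#'
#' @param cv per-channel CVs.
#' @param lengths matching channel lengths (mm).
#' @return list(a, b, m, s, rmse, converged, degenerate); `degenerate` flags
#'   an essentially flat fit (|b - a| below 1% of the CV range scale).
#' @export
fitCvLengthSigmoid <- function(cv, lengths) {
  ok <- is.finite(cv) & is.finite(lengths)
  cv <- cv[ok]; lengths <- lengths[ok]
  stopIfNot(length(unique(round(lengths, 6))) >= 8,
            "need at least 8 distinct channel lengths")
  a0 <- quantile(cv, 0.05); b0 <- quantile(cv, 0.95)
  start <- list(a = as.numeric(a0), b = as.numeric(b0),
                m = as.numeric(median(lengths)), s = diff(range(lengths)) / 8)
  fit <- tryCatch(
    minpack.lm::nlsLM(cv ~ a + (b - a) / (1 + exp(-(lengths - m) / s)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(a = NA, b = NA, m = NA, s = NA, rmse = NA,
                converged = FALSE, degenerate = TRUE))
  }
  p <- as.list(coef(fit))
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  span <- abs(p$b - p$a)
  list(a = p$a, b = p$b, m = p$m, s = p$s, rmse = rmse,
       converged = TRUE,
       degenerate = span < 0.01 * max(abs(c(p$a, p$b, sd(cv), 1e-12))))
}
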