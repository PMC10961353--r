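#' Block-average hemodynamic responses of one session
#'
#' Offline neural-response chain: within-tile averaging of the raw
#' intensity, retention of 15-60 mm tile pairs, OD relative to the whole-
#' session mean, zero-phase 0.02-2 Hz Butterworth bandpass, TDDR motion
#' correction, GVTD outlier-trial rejection (3 SD, statistics over all
#' covert trials of the session), MBLL (DPF 6), epoching [-5, 17) s around
#' tapping onset, [-2, 0) s baseline subtraction, and averaging of the
#' retained covert trials per condition and chromophore.
#'
#' @param session a raw-intensity [NirsSession-class].
#' @param montage the matching [Montage-class].
#' @param band bandpass edges (Hz).
#' @param lengthRange retained tile-pair length band (mm).
#' @param gvtd_sd GVTD rejection threshold (SDs).
#' @param epoch,baseline epoch and baseline windows (s relative to onset).
#' @return list(hrf = array [pairs x 2 chromophores x time x 2 conditions]
#'   of mean waveforms, time, pairs = tile-pair table, n_kept per condition,
#'   keep = per-trial logical, trials = trial marker table).
#' @export
runBlockAverage <- function(session, montage, band = c(0.02, 2),
                            lengthRange = c(15, 60), gvtd_sd = 3,
                            epoch = c(-5, 17), baseline = c(-2, 0)) {
  fs <- samplingRate(session)
  ta <- tileAverage(session, montage)
  ta <- channelLengthFilter(ta, lengthRange[1], lengthRange[2])
  od <- intensityToOD(ta, "whole_session")
  od <- butterBandpass(od, band, fs)
  od <- tddr(od, fs)

  mk <- markers(ta)
  trials <- mk[mk$label %in% c("left", "right"), , drop = FALSE]
  stopIfNot(nrow(trials) > 0, "session has no covert trials")
  ep <- epochSeries(od, trials$time, epoch[1], epoch[2], fs)
  trials <- trials[attr(ep, "kept"), , drop = FALSE]
  rej <- gvtdReject(ep, gvtd_sd)
  keep <- rej$keep
  ep <- rej$kept
  if (!sum(keep)) {
    warning("all trials rejected by GVTD")
    return(list(hrf = NULL, time = NULL, pairs = channels(ta),
                n_kept = c(left = 0, right = 0), keep = keep, trials = trials))
  }
  kepttr <- trials[keep, , drop = FALSE]

  # concentrations per retained epoch
  tvec <- (windowIndex(epoch[1], epoch[2], fs) - 1) / fs
  conc <- NULL; pairs <- NULL
  nb <- length(windowIndex(baseline[1], baseline[2], fs, offset = -epoch[1] + baseline[1]))
  bIdx <- which(tvec >= baseline[1] & tvec < baseline[2])
  for (i in seq_len(dim(ep)[1])) {
    m <- ep[i, , , drop = FALSE]; dim(m) <- dim(m)[2:3]
    cc <- mbll(m, channels(ta))
    if (is.null(conc)) {
      pairs <- cc$pairs
      conc <- array(0, dim = c(dim(ep)[1], nrow(pairs), 2, length(tvec)))
    }
    conc[i, , 1, ] <- cc$hbo
    conc[i, , 2, ] <- cc$hbr
  }
  # baseline subtraction per trial/pair/chromophore
  for (i in seq_len(dim(conc)[1])) {
    base <- apply(conc[i, , , bIdx, drop = FALSE], c(2, 3), mean)
    conc[i, , , ] <- conc[i, , , , drop = FALSE] -
      array(rep(base, length(tvec)), dim = c(1, dim(base), length(tvec)))
  }
  conds <- c("left", "right")
  hrf <- array(NA_real_, dim = c(nrow(pairs), 2, length(tvec), 2),
               dimnames = list(NULL, c("hbo", "hbr"), NULL, conds))
  nk <- setNames(integer(2), conds)
  for (ci in seq_along(conds)) {
    sel <- kepttr$label == conds[ci]
    nk[ci] <- sum(sel)
    if (any(sel)) {
      hrf[, , , ci] <- apply(conc[sel, , , , drop = FALSE], c(2, 3, 4), mean)
    }
  }
  list(hrf = hrf, time = tvec, pairs = pairs, n_kept = nk, keep = keep,
       trials = trials)
}

#' Group statistics on block-average waveforms
#'
#' Per pair/chromophore/condition/timepoint: two-sided one-sample t-test of
#' the per-session mean waveforms against zero, Benjamini-Hochberg FDR
#' corrected over the time axis. Degenerate timepoints (zero variance across
#' sessions but nonzero mean) are flagged and treated as significant.
#'
#' @param hrfs list of `hrf` arrays from [runBlockAverage()] (equal shapes).
#' @param alpha significance level on FDR-adjusted p-values.
#' @return list(mean, ci_low, ci_high (95% CI), t, p, p_fdr, significant,
#'   degenerate) of arrays shaped like one `hrf`.
#' @export
groupTest <- function(hrfs, alpha = 0.05) {
  stopIfNot(length(hrfs) >= 3, "group test needs at least 3 sessions")
  d <- dim(hrfs[[1]])
  stack <- array(unlist(hrfs), dim = c(d, length(hrfs)))
  n <- length(hrfs)
  mu <- apply(stack, 1:4, mean)
  sdv <- apply(stack, 1:4, sd)
  se <- sdv / sqrt(n)
  tq <- qt(0.975, n - 1)
  tstat <- mu / se
  degenerate <- sdv == 0 & mu != 0
  tstat[sdv == 0] <- ifelse(mu[sdv == 0] == 0, 0, Inf)
  p <- 2 * pt(-abs(tstat), n - 1)
  p[degenerate] <- 0
  pfdr <- p
  # BH over the time axis (dim 3) per pair/chromophore/condition
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[4])) {
    pfdr[i, j, , k] <- p.adjust(p[i, j, , k], method = "BH")
  }
  list(mean = mu, ci_low = mu - tq * se, ci_high = mu + tq * se,
       t = tstat, p = p, p_fdr = pfdr,
       significant = pfdr < alpha, degenerate = degenerate)
}
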