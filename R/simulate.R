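#' Hemodynamic response specification
#'
#' Parameters of the planted neural response. The response kernel is a
#' canonical double-gamma HRF convolved with the 2-s task boxcar and peak-
#' normalized; with the default parameters the oxyhemoglobin (HbO) response
#' peaks about 8 s after tapping onset. Left-hand trials drive the right
#' motor patch at full amplitude and the left patch at `ipsi_ratio` (and vice
#' versa); deoxyhemoglobin (HbR) is a smaller, opposite-signed copy. An
#' optional "initial dip" subtracts a small early negative HbO lobe. A shared
#' superficial (scalp) compartment carries systemic physiology that projects
#' most strongly into short channels.
#'
#' @param amp_hbo contralateral HbO peak amplitude (uM).
#' @param hbr_ratio HbR amplitude as a (negative) fraction of HbO.
#' @param hbr_lag_s lag (s) of the HbR response behind HbO (deoxygenation
#'   washout follows the inflow response).
#' @param ipsi_ratio ipsilateral amplitude fraction.
#' @param overt_gain amplitude multiplier for executed (overt) trials.
#' @param hrf_peak_s peak latency (s) of the underlying double-gamma HRF.
#' @param undershoot_ratio relative amplitude of the post-stimulus undershoot.
#' @param initial_dip logical; plant an early negative HbO lobe.
#' @param dip_ratio dip amplitude relative to the main response peak.
#' @param dip_peak_s dip peak latency (s).
#' @param superficial_amp amplitude (uM HbO) of the shared superficial signal.
#' @param patch_sigma spatial Gaussian scale (mm) of the cortical patches,
#'   centered on the montage motor-ROI centers.
#' @return list; `response_peak_s` records the numerically computed peak
#'   latency of the planted HbO response at 10 Hz.
#' @export
hemodynamicSpec <- function(amp_hbo = 0.35, hbr_ratio = -0.3, hbr_lag_s = 1,
                            ipsi_ratio = 0.4,
                            overt_gain = 1.5, hrf_peak_s = 7,
                            undershoot_ratio = 1 / 6, initial_dip = TRUE,
                            dip_ratio = 0.12, dip_peak_s = 2.5,
                            superficial_amp = 0.3, patch_sigma = 20) {
  spec <- list(
    amp_hbo = amp_hbo, hbr_ratio = hbr_ratio, hbr_lag_s = hbr_lag_s,
    ipsi_ratio = ipsi_ratio,
    overt_gain = overt_gain, hrf_peak_s = hrf_peak_s,
    undershoot_ratio = undershoot_ratio, initial_dip = initial_dip,
    dip_ratio = dip_ratio, dip_peak_s = dip_peak_s,
    superficial_amp = superficial_amp, patch_sigma = patch_sigma
  )
  k <- responseKernel(spec, fs = 10, task_s = 2)
  spec$response_peak_s <- (which.max(k) - 1) / 10
  stopIfNot(spec$response_peak_s >= 6 && spec$response_peak_s <= 10,
            "default HbO response peak latency must lie in [6, 10] s")
  spec
}

#' Double-gamma HRF
#'
#' @param t time (s).
#' @param peak_s peak latency of the positive lobe.
#' @param undershoot_ratio relative undershoot amplitude.
#' @param undershoot_peak_s undershoot peak latency.
#' @return HRF values (unnormalized).
#' @export
doubleGammaHRF <- function(t, peak_s = 7, undershoot_ratio = 1 / 6,
                           undershoot_peak_s = 16) {
  h <- dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * dgamma(t, shape = undershoot_peak_s + 1, rate = 1)
  h[t < 0] <- 0
  h
}

# Peak-normalized HbO response kernel: HRF (minus optional dip lobe)
# convolved with the task boxcar.
responseKernel <- function(hemo, fs, task_s = 2, dur_s = 25) {
  t <- seq(0, dur_s, by = 1 / fs)
  h <- doubleGammaHRF(t, hemo$hrf_peak_s, hemo$undershoot_ratio)
  h <- h / max(h)
  if (isTRUE(hemo$initial_dip)) {
    d <- dgamma(t, shape = hemo$dip_peak_s * 2 + 1, rate = 2)
    h <- h - hemo$dip_ratio * d / max(d)
  }
  box <- rep(1, max(1L, round(task_s * fs)))
  k <- convolve(h, rev(box), type = "open")[seq_along(t)] / length(box)
  k / max(k)
}

#' Physiological and instrumental noise specification
#'
#' Noise families standard for continuous-wave fNIRS simulation. Slow drift
#' is a per-channel random walk in optical density (OD); cardiac (~1.2 Hz
#' with rate jitter), respiration (~0.25 Hz) and Mayer waves (~0.1 Hz) are
#' montage-wide oscillations with per-channel gains; white OD noise is
#' independent per sample; motion artifacts are montage-correlated transient
#' spikes and persistent baseline shifts; `additive_sd` is detector noise in
#' intensity counts (independent of light level, which is what makes weakly
#' coupled and long channels noise-dominated).
#'
#' @param drift_sd per-sample OD random-walk sd.
#' @param cardiac_freq,cardiac_amp,resp_freq,resp_amp,mayer_freq,mayer_amp
#'   oscillation frequencies (Hz) and OD amplitudes.
#' @param white_od_sd per-sample white OD noise sd.
#' @param additive_sd detector-noise sd (intensity counts).
#' @param dark_counts positive detector dark level (counts) added to every
#'   sample, so weakly coupled channels bottom out at a noisy dark floor
#'   rather than at zero.
#' @param spike_rate,spike_amp motion spikes per minute and OD magnitude.
#' @param shift_rate,shift_amp baseline shifts per minute and OD magnitude.
#' @param i0 nominal source intensity (counts) at zero length.
#' @param decay_mm_per_decade intensity falloff: one decade per this many mm
#'   of channel length.
#' @return list.
#' @export
noiseSpec <- function(drift_sd = 1e-4, cardiac_freq = 1.2, cardiac_amp = 0.003,
                      resp_freq = 0.25, resp_amp = 0.004,
                      mayer_freq = 0.1, mayer_amp = 0.005,
                      white_od_sd = 0.01, additive_sd = 50,
                      dark_counts = 100,
                      spike_rate = 0.5, spike_amp = 0.3,
                      shift_rate = 0.2, shift_amp = 0.02,
                      i0 = 1e6, decay_mm_per_decade = 15) {
  spec <- as.list(environment())
  sds <- c(spec$drift_sd, spec$white_od_sd, spec$additive_sd)
  stopIfNot(all(sds >= 0), "noise sigmas must be >= 0")
  spec
}

#' Zero-noise specification (for forward/inverse consistency checks)
#' @export
noiselessSpec <- function() {
  noiseSpec(drift_sd = 0, cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
            white_od_sd = 0, additive_sd = 0, dark_counts = 0,
            spike_rate = 0, shift_rate = 0)
}

#' Optode-coupling specification
#'
#' Per-optode coupling efficiencies in (0, 1] are drawn from a log-normal
#' distribution whose location decreases with the subject's hair-severity
#' index ([hairSeverity()]), emulating light occlusion by long/dark/dense
#' hair. Subjects whose severity reaches `pq_threshold` get a hard coupling
#' ceiling (`pq_floor`), the "poor quality" profile in which almost no light
#' couples through the hair.
#'
#' @param base_log_coupling log-coupling at severity 0.
#' @param severity_slope decrease of log-coupling per unit severity.
#' @param sigma per-optode log-normal sd.
#' @param pq_threshold severity at or above which the PQ profile applies.
#' @param pq_floor coupling ceiling for PQ-profile subjects (almost no scalp contact).
#' @return list.
#' @export
couplingSpec <- function(base_log_coupling = log(0.9), severity_slope = 1.5,
                         sigma = 0.3, pq_threshold = 0.65, pq_floor = 0.015) {
  as.list(environment())
}

#' Draw per-optode coupling efficiencies
#'
#' @param spec a [couplingSpec()].
#' @param severity hair-severity index in [0, 1] (NA treated as 0.5).
#' @param nOptodes number of optodes.
#' @param seed RNG seed.
#' @return list(coupling = numeric vector in (0, 1], pq = logical).
#' @export
drawCoupling <- function(spec, severity, nOptodes, seed = 1) {
  if (is.na(severity)) severity <- 0.5
  withSeed(subSeed(seed, "coupling"), {
    mu <- spec$base_log_coupling - spec$severity_slope * severity
    c0 <- pmin(1, exp(rnorm(nOptodes, mu, spec$sigma)))
    pq <- severity >= spec$pq_threshold
    if (pq) c0 <- pmin(c0, spec$pq_floor)
    list(coupling = c0, pq = pq)
  })
}

# Depth weighting of the two-compartment path model: superficial weight
# decays with channel length; cortical sensitivity rises with length, then
# collapses beyond ~50 mm where too little light returns.
superficialWeight <- function(len) exp(-len / 30)
corticalWeight <- function(len) {
  (len^2 / (len^2 + 25^2)) * exp(-(pmax(len - 50, 0) / 8)^2)
}

#' Simulate one session recording
#'
#' Forward model: left/right motor-patch and superficial-compartment
#' chromophore time courses are mixed into each channel with depth weights
#' that are smooth functions of channel length, converted to optical density
#' via the forward modified Beer-Lambert law (channel length, DPF 6, the
#' packaged extinction table), and exponentiated into intensity
#' `I0(L) * c_src * c_det * exp(-OD)` plus additive detector noise. Motion
#' artifacts are injected as montage-correlated spikes and baseline shifts in
#' OD. Channels beyond ~50-60 mm receive almost no cortical signal and little
#' light, so they are dominated by detector noise, as in real recordings.
#'
#' @param montage a [Montage-class].
#' @param schedule marker table from [generateSchedule()].
#' @param hemo a [hemodynamicSpec()].
#' @param noise a [noiseSpec()].
#' @param coupling either a [couplingSpec()] (coupling is then drawn from the
#'   subject's factors) or a numeric vector/scalar of per-optode couplings.
#' @param seed RNG seed (per-session substream).
#' @param fs sampling rate (Hz).
#' @param subjectId,sessionNumber,factors session metadata; `factors` is a
#'   single-row data.frame as from [readFactorsTable()].
#' @param dpf differential pathlength factor of the forward model.
#' @return a [NirsSession-class]; `meta(session)$truth` records the planted
#'   ground truth (coupling, PQ flag, severity, response peak, amplitudes).
#' @export
simulateSession <- function(montage, schedule, hemo = hemodynamicSpec(),
                            noise = noiseSpec(), coupling = couplingSpec(),
                            seed = 1, fs = 10, subjectId = "S01",
                            sessionNumber = 1L,
                            factors = data.frame(), dpf = 6) {
  ch <- channels(montage)
  nOpt <- nrow(optodes(montage))
  severity <- if (nrow(factors)) hairSeverity(factors) else NA_real_
  if (is.list(coupling) && !is.null(coupling$severity_slope)) {
    cp <- drawCoupling(coupling, severity, nOpt, seed)
  } else {
    cp <- list(coupling = rep_len(coupling, nOpt), pq = FALSE)
  }
  optIdx <- setNames(seq_len(nOpt), optodes(montage)$id)
  cSrc <- cp$coupling[optIdx[ch$source_id]]
  cDet <- cp$coupling[optIdx[ch$detector_id]]

  dur <- max(schedule$time)
  n <- ceiling(dur * fs)
  tvec <- (seq_len(n) - 1) / fs
  ext <- extinctionMatrix(montage@wavelengths)  # 2x2, rows wavelengths

  withSeed(subSeed(seed, "session"), {
    # --- cortical patch chromophore time courses (uM)
    kern <- responseKernel(hemo, fs)
    stimL <- numeric(n); stimR <- numeric(n)  # patch drive impulse trains
    tr <- schedule[!is.na(schedule$trial), ]
    for (i in seq_len(nrow(tr))) {
      idx <- round(tr$time[i] * fs) + 1L
      if (idx > n) next
      lab <- tr$label[i]
      overt <- grepl("^overt", lab)
      left <- grepl("left$", lab)
      a <- hemo$amp_hbo * if (overt) hemo$overt_gain else 1
      # contralateral full drive, ipsilateral reduced
      stimR[idx] <- stimR[idx] + a * if (left) 1 else hemo$ipsi_ratio
      stimL[idx] <- stimL[idx] + a * if (left) hemo$ipsi_ratio else 1
    }
    convStim <- function(s, k) {
      convolve(s, rev(k), type = "open")[seq_len(n)]
    }
    # HbR follows the HbO response with a short washout lag (no initial dip)
    lag <- round((hemo$hbr_lag_s %||% 0) * fs)
    hemoNoDip <- hemo; hemoNoDip$initial_dip <- FALSE
    kernR <- c(rep(0, lag), responseKernel(hemoNoDip, fs))[seq_along(kern)]
    cortL <- convStim(stimL, kern); cortR <- convStim(stimR, kern)
    cortLr <- convStim(stimL, kernR); cortRr <- convStim(stimR, kernR)

    # --- superficial systemic compartment (uM)
    supRaw <- cumsum(rnorm(n, 0, 0.02))
    supRaw <- supRaw - stats::filter(supRaw, rep(1 / (30 * fs), 30 * fs),
                                     sides = 2, circular = TRUE)
    sup <- hemo$superficial_amp *
      (0.6 * sin(2 * pi * 0.09 * tvec + runif(1, 0, 2 * pi)) +
         as.numeric(supRaw) / max(1e-9, 2 * sd(supRaw)))

    # --- mix into per-pair concentrations, forward MBLL per channel
    pid <- ch$pair_id
    upair <- !duplicated(pid)
    len <- ch$length[upair][order(pid[upair])]  # by pair id
    mx <- ch$mid_x[upair][order(pid[upair])]
    my <- ch$mid_y[upair][order(pid[upair])]
    roiC <- montage@roiCenters
    gL <- exp(-((mx - roiC[1, 1])^2 + (my - roiC[1, 2])^2) / (2 * hemo$patch_sigma^2))
    gR <- exp(-((mx - roiC[2, 1])^2 + (my - roiC[2, 2])^2) / (2 * hemo$patch_sigma^2))
    wS <- superficialWeight(len); wC <- corticalWeight(len)

    # HbO/HbR per pair: [npair x n]
    hbo <- outer(wC * gL, cortL) + outer(wC * gR, cortR) + outer(wS, sup)
    hbr <- hemo$hbr_ratio * (outer(wC * gL, cortLr) + outer(wC * gR, cortRr)) +
      (-0.3) * outer(wS, sup)

    # OD signal per wavelength-resolved channel
    wlIdx <- match(ch$wavelength, montage@wavelengths)
    odSig <- (ext[wlIdx, 1] * hbo[pid, , drop = FALSE] +
                ext[wlIdx, 2] * hbr[pid, , drop = FALSE]) *
      (ch$length * dpf)

    # --- OD-domain noise
    nc <- nrow(ch)
    odNoise <- matrix(0, nc, n)
    if (noise$white_od_sd > 0) {
      odNoise <- odNoise + matrix(rnorm(nc * n, 0, noise$white_od_sd), nc, n)
    }
    if (noise$drift_sd > 0) {
      odNoise <- odNoise + t(apply(matrix(rnorm(nc * n, 0, noise$drift_sd), nc, n),
                                   1, cumsum))
    }
    physio <- function(freq, amp, jitter = 0) {
      if (amp <= 0) return(NULL)
      ph <- cumsum(rep(freq / fs, n) * (1 + jitter * rnorm(n, 0, 0.05)))
      shared <- sin(2 * pi * ph + runif(1, 0, 2 * pi))
      gains <- amp * (0.7 + 0.6 * runif(nc))
      outer(gains, shared)
    }
    for (p in list(physio(noise$cardiac_freq, noise$cardiac_amp, jitter = 1),
                   physio(noise$resp_freq, noise$resp_amp),
                   physio(noise$mayer_freq, noise$mayer_amp))) {
      if (!is.null(p)) odNoise <- odNoise + p
    }
    addEvents <- function(rate, ampl, spike) {
      nev <- stats::rpois(1, rate * dur / 60)
      for (e in seq_len(nev)) {
        at <- sample.int(n, 1)
        gains <- ampl * rnorm(nc)
        if (spike) {
          w <- exp(-(0:round(0.5 * fs)) / (0.15 * fs))
          idx <- at:min(n, at + length(w) - 1)
          odNoise[, idx] <<- odNoise[, idx] + outer(gains, w[seq_along(idx)])
        } else {
          odNoise[, at:n] <<- odNoise[, at:n] + gains
        }
      }
    }
    if (noise$spike_rate > 0) addEvents(noise$spike_rate, noise$spike_amp, TRUE)
    if (noise$shift_rate > 0) addEvents(noise$shift_rate, noise$shift_amp, FALSE)

    # --- intensity
    i0c <- noise$i0 * 10^(-ch$length / noise$decay_mm_per_decade) * cSrc * cDet
    inten <- i0c * exp(-(odSig + odNoise)) + (noise$dark_counts %||% 0)
    if (noise$additive_sd > 0) {
      inten <- inten + matrix(rnorm(nc * n, 0, noise$additive_sd), nc, n)
    }
    inten <- pmax(inten, 0)

    new("NirsSession",
        intensity = inten, fs = fs, markers = schedule, channels = ch,
        subjectId = subjectId, sessionNumber = as.integer(sessionNumber),
        factors = factors,
        meta = list(truth = list(
          coupling = cp$coupling, mean_coupling = mean(cp$coupling),
          pq = cp$pq, severity = severity,
          response_peak_s = hemo$response_peak_s,
          amp_hbo = hemo$amp_hbo, seed = seed
        )))
  })
}

# Draw one subject's questionnaire factors from category frequencies.
sampleFactors <- function(config, subjectId) {
  lv <- factorLevels()
  pick <- function(nm) {
    p <- config[[nm]] %||% rep(1, length(lv[[nm]]))
    sample(lv[[nm]], 1, prob = p)
  }
  data.frame(
    subject_id = subjectId,
    age = sample(config$age_range[1]:config$age_range[2], 1),
    sex = pick("sex"), ethnicity = pick("ethnicity"),
    hair_length = pick("hair_length"), hair_color = pick("hair_color"),
    hair_density = pick("hair_density"),
    stringsAsFactors = FALSE
  )
}

#' Default demographics configuration
#'
#' Category frequencies used by [generateCohort()]; frequencies are in the
#' order of [factorLevels()]. The defaults emulate a general-population
#' convenience sample with diverse hair phenotypes.
#' @export
demographicsConfig <- function() {
  list(
    age_range = c(18, 68),
    sex = c(0.5, 0.5),
    ethnicity = c(0.38, 0.2, 0.12, 0.16, 0.14),
    hair_length = c(0.08, 0.34, 0.3, 0.28),
    hair_color = c(0.05, 0.15, 0.06, 0.22, 0.3, 0.22),
    hair_density = c(0.25, 0.5, 0.25)
  )
}

#' Generate a multi-subject synthetic cohort
#'
#' Draws per-subject demographics, derives hair-severity-dependent optode
#' coupling (consistent within subject across sessions), simulates every
#' session, and either keeps the sessions, writes them to `dir` (own
#' container + `factors.csv` + `manifest.csv`), or reduces each one through
#' `sessionFun` immediately (memory-friendly for large cohorts).
#'
#' @param nSubjects number of subjects.
#' @param sessionCounts number of subjects attending sessions 1..k (nested:
#'   returners are a seeded subset of the previous session's attendees).
#' @param montage a [Montage-class].
#' @param spec a [scheduleSpec()].
#' @param hemo,noise,coupling forwarded to [simulateSession()].
#' @param demographics a [demographicsConfig()].
#' @param seed master seed; all per-subject/per-session substreams derive
#'   from it.
#' @param dir output directory (NULL = in-memory).
#' @param sessionFun optional function applied to each simulated session; its
#'   results are returned in `$results` and the session is discarded.
#' @return list(manifest, factors, sessions or results).
#' @export
generateCohort <- function(nSubjects = 32, sessionCounts = c(32, 15, 14),
                           montage = buildDefaultMontage(),
                           spec = scheduleSpec(),
                           hemo = hemodynamicSpec(), noise = noiseSpec(),
                           coupling = couplingSpec(),
                           demographics = demographicsConfig(),
                           seed = 1, dir = NULL, sessionFun = NULL) {
  stopIfNot(sessionCounts[1] <= nSubjects, "sessionCounts[1] exceeds nSubjects")
  subjects <- sprintf("sub%03d", seq_len(nSubjects))
  base <- withSeed(subSeed(seed, "factors"), {
    do.call(rbind, lapply(subjects, function(s) sampleFactors(demographics, s)))
  })
  attendance <- withSeed(subSeed(seed, "attendance"), {
    att <- list(sample(subjects, sessionCounts[1]))
    for (k in seq_along(sessionCounts)[-1]) {
      att[[k]] <- sample(att[[k - 1]], sessionCounts[k])
    }
    att
  })
  facRows <- list(); manRows <- list(); out <- list()
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sn in seq_along(attendance)) {
    for (sub in sort(attendance[[sn]])) {
      fac <- base[base$subject_id == sub, , drop = FALSE]
      fac$session_number <- sn
      fac$alertness <- withSeed(subSeed(seed, sub, sn, "alert"),
                                sample(1:10, 1))
      lvz <- factorLevels()
      for (nm in c("hair_length", "hair_color", "hair_density")) {
        fac[[paste0(nm, "_ord")]] <- match(fac[[nm]], lvz[[nm]]) - 1L
      }
      sched <- generateSchedule(spec, sn, subSeed(seed, sub, sn, "sched"))
      ses <- simulateSession(montage, sched, hemo, noise, coupling,
                             seed = subSeed(seed, sub, sn, "sim"),
                             subjectId = sub, sessionNumber = sn,
                             factors = fac)
      truth <- ses@meta$truth
      file <- sprintf("%s_ses%d.nirs.rds", sub, sn)
      if (!is.null(dir)) writeSession(ses, file.path(dir, file))
      key <- sprintf("%s_%d", sub, sn)
      if (!is.null(sessionFun)) {
        out[[key]] <- sessionFun(ses)
      } else if (is.null(dir)) {
        out[[key]] <- ses
      }
      facRows[[key]] <- fac
      manRows[[key]] <- data.frame(
        subject_id = sub, session_number = sn, file = file,
        severity = truth$severity, pq_profile = truth$pq,
        mean_coupling = truth$mean_coupling
      )
    }
  }
  factors <- do.call(rbind, facRows); rownames(factors) <- NULL
  manifest <- do.call(rbind, manRows); rownames(manifest) <- NULL
  if (!is.null(dir)) {
    write.csv(factors, file.path(dir, "factors.csv"), row.names = FALSE)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  res <- list(manifest = manifest, factors = factors)
  if (!is.null(sessionFun)) res$results <- out
  else if (is.null(dir)) res$sessions <- out
  res
}
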