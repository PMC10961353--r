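#' Pinned hemoglobin extinction coefficients
#'
#' Reads the versioned extinction table shipped with the package and returns
#' the 2 x 2 extinction matrix for the requested wavelengths, in
#' (uM mm)^-1 units (rows = wavelengths, columns = HbO, HbR).
#'
#' @param wavelengths wavelengths (nm) present in the table.
#' @return 2 x 2 numeric matrix.
#' @export
extinctionMatrix <- function(wavelengths = c(735, 850)) {
  tab <- yaml::read_yaml(system.file("extdata", "extinction.yaml",
                                     package = "hdnirs", mustWork = TRUE))
  idx <- match(wavelengths, tab$wavelengths_nm)
  stopIfNot(!anyNA(idx), "wavelength not in pinned extinction table")
  # cm^-1/M -> (uM mm)^-1
  m <- cbind(hbo = tab$hbo[idx], hbr = tab$hbr[idx]) * 1e-7
  rownames(m) <- as.character(wavelengths)
  m
}

#' Convert intensity to change in optical density
#'
#' OD_c(t) = -log(I_c(t) / ref_c(t)). The reference is the whole-session
#' channel mean, the mean of the first 60 s, or a causal running exponential
#' moving average (EMA; yields delta-OD relative to a running baseline).
#' Intensities are clamped from below at `epsilon` times the channel median
#' before the log; channels whose clamp floor is non-positive raise an error.
#'
#' @param x intensity matrix [channels x samples] or a [NirsSession-class].
#' @param mode reference mode.
#' @param fs sampling rate (needed for `first_60s`/`running_ema` on
#'   matrices).
#' @param forget EMA forget factor for `running_ema`.
#' @param epsilon clamp floor as a fraction of the channel median.
#' @return OD matrix with attributes `reference` (mode) recorded.
#' @export
intensityToOD <- function(x, mode = c("whole_session", "first_60s", "running_ema"),
                          fs = NULL, forget = 0.01, epsilon = 1e-9) {
  mode <- match.arg(mode)
  if (is(x, "NirsSession")) {
    fs <- samplingRate(x)
    x <- intensity(x)
  }
  stopIfNot(!is.null(fs) || mode == "whole_session",
            "fs required for this reference mode")
  med <- apply(x, 1, median)
  floorv <- epsilon * med
  if (any(floorv <= 0)) {
    stop("nonpositive intensity after clamping in channel(s) ",
         paste(which(floorv <= 0), collapse = ", "), call. = FALSE)
  }
  xc <- pmax(x, floorv)
  ref <- switch(mode,
    whole_session = matrix(rowMeans(xc), nrow(xc), ncol(xc)),
    first_60s = {
      k <- max(1L, min(ncol(xc), round(60 * fs)))
      matrix(rowMeans(xc[, seq_len(k), drop = FALSE]), nrow(xc), ncol(xc))
    },
    running_ema = t(apply(xc, 1, function(r) {
      as.numeric(stats::filter(r * forget, 1 - forget, method = "recursive",
                               init = r[1]))
    }))
  )
  od <- -log(xc / ref)
  attr(od, "reference") <- mode
  od
}

#' Causal MACD-type bandpass filter
#'
#' Low-latency bandpass used before all causal decoding stages: the signal
#' minus its slow exponential moving average (high-pass, forget factor
#' `forget`), smoothed by a causal rectangular moving average of `window_s`
#' seconds (zero-padded at the start). Strictly causal with an effective
#' group delay of about half the moving-average window (~1 s at the
#' defaults).
#'
#' @param x matrix [channels x samples] or numeric vector.
#' @param fs sampling rate (Hz).
#' @param forget EMA forget factor.
#' @param window_s moving-average window (s).
#' @return filtered series, same shape as `x`.
#' @export
macdBandpass <- function(x, fs, forget = 0.01, window_s = 2) {
  one <- function(r) {
    ema <- as.numeric(stats::filter(r * forget, 1 - forget,
                                    method = "recursive"))
    hp <- r - ema
    w <- max(1L, round(window_s * fs))
    cs <- cumsum(hp)
    (cs - c(rep(0, w), head(cs, -w))) / w
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

#' Butterworth filtering
#'
#' Band edges are in Hz and must lie inside the Nyquist range. Bandpasses
#' are realized as a cascade of a high-pass (order `max(order/2, 2)`) and a
#' low-pass (order `order`), which is numerically stable for the very wide
#' relative bands used here (e.g. 0.02-2 Hz at 10 Hz sampling). Zero-phase
#' (forward-backward) filtering is used for offline stages; `causal = TRUE`
#' gives a single forward pass.
#'
#' @param x matrix [channels x samples] or vector.
#' @param band `c(low, high)` Hz; 0 or Inf disable the corresponding edge.
#' @param fs sampling rate (Hz).
#' @param order filter order (per section).
#' @param causal single forward pass instead of zero-phase.
#' @return filtered series.
#' @export
butterBandpass <- function(x, band, fs, order = 4, causal = FALSE) {
  nyq <- fs / 2
  stopIfNot(band[1] >= 0 && band[1] < nyq, "low band edge outside (0, Nyquist)")
  if (is.finite(band[2])) {
    stopIfNot(band[2] > band[1] && band[2] < nyq,
              "high band edge must lie below the Nyquist frequency")
  }
  filts <- list()
  if (band[1] > 0) {
    filts <- c(filts, list(signal::butter(max(2, order %/% 2), band[1] / nyq,
                                          type = "high")))
  }
  if (is.finite(band[2])) {
    filts <- c(filts, list(signal::butter(order, band[2] / nyq, type = "low")))
  }
  for (f in filts) {
    if (any(!is.finite(unlist(f))) || any(Mod(polyroot(rev(f$a))) > 1 + 1e-8)) {
      stop("unstable Butterworth design for the requested band", call. = FALSE)
    }
  }
  one <- function(r) {
    for (f in filts) {
      r <- if (causal) as.numeric(signal::filter(f, r)) else signal::filtfilt(f, r)
    }
    r
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

#' Temporal derivative distribution repair (TDDR)
#'
#' Robust motion-artifact correction: the signal is split at 0.5 Hz into a
#' low-frequency component and a high-frequency residual; the low-frequency
#' derivatives are iteratively reweighted with Tukey's biweight (c = 4.685,
#' robust sigma = 1.4826 * MAD) until the weighted-mean derivative
#' stabilizes, the weighted centered derivatives are integrated, and the
#' untouched high-frequency residual and signal mean are added back.
#'
#' @param x matrix [channels x samples] or vector.
#' @param fs sampling rate (Hz).
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning.
#' @return corrected series, same shape; attribute `converged` is FALSE if
#'   any channel hit `max_iter`.
#' @export
tddr <- function(x, fs, max_iter = 50) {
  flag <- FALSE
  one <- function(sig) {
    mu0sig <- mean(sig)
    sig <- sig - mu0sig
    fc <- 0.5 * 2 / fs
    if (fc < 1) {
      bw <- signal::butter(3, fc)
      low <- signal::filtfilt(bw, sig)
    } else low <- sig
    high <- sig - low
    drv <- diff(low)
    if (!length(drv)) return(sig + mu0sig)
    w <- rep(1, length(drv))
    tune <- 4.685
    eps <- sqrt(.Machine$double.eps)
    mu <- Inf
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      mu0 <- mu
      mu <- sum(w * drv) / sum(w)
      dev <- abs(drv - mu)
      sigma <- 1.4826 * median(dev)
      if (sigma == 0) { converged <- TRUE; break }
      r <- dev / (sigma * tune)
      w <- ((1 - r^2) * (r < 1))^2
      if (abs(mu - mu0) < eps * max(abs(mu), abs(mu0))) {
        converged <- TRUE; break
      }
    }
    if (!converged) flag <<- TRUE
    lowc <- cumsum(c(0, w * (drv - mu)))
    lowc <- lowc - mean(lowc)
    lowc + high + mu0sig
  }
  out <- if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
  if (flag) warning("TDDR did not converge within max_iter; returning last iterate")
  attr(out, "converged") <- !flag
  out
}

#' Global variance of temporal derivatives (GVTD)
#'
#' `gvtd()` returns the montage-wide motion time course
#' g(t) = sqrt(mean_c (x_c(t) - x_c(t-1))^2) (g(1) = 0). `gvtdReject()`
#' computes a per-epoch statistic (the maximum of g inside the epoch) over a
#' [trials x channels x time] array and rejects epochs whose statistic
#' exceeds the mean + `nsd` standard deviations of all epoch statistics of
#' the session.
#'
#' @param x multichannel matrix [channels x samples].
#' @return numeric vector g(t).
#' @export
gvtd <- function(x) {
  d <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  c(0, sqrt(colMeans(d^2)))
}

#' @rdname gvtd
#' @param epochs array [trials x channels x time].
#' @param nsd rejection threshold in standard deviations.
#' @return list(kept = retained epoch array, keep = logical mask,
#'   statistic = per-epoch GVTD maxima, threshold).
#' @export
gvtdReject <- function(epochs, nsd = 3) {
  nt <- dim(epochs)[1]
  stat <- vapply(seq_len(nt), function(i) {
    m <- epochs[i, , , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    max(gvtd(m))
  }, numeric(1))
  if (nt < 3) {
    warning("fewer than 3 epochs; GVTD rejection skipped")
    return(list(kept = epochs, keep = rep(TRUE, nt), statistic = stat,
                threshold = Inf))
  }
  thr <- mean(stat) + nsd * sd(stat)
  keep <- stat <= thr
  list(kept = epochs[keep, , , drop = FALSE], keep = keep,
       statistic = stat, threshold = thr)
}

#' Within-tile channel averaging
#'
#' Averages all channels that connect the same (source tile, detector tile)
#' pair at the same wavelength into one "virtual" channel, as if all sources
#' (detectors) of a tile acted as one multi-tip optode. The tile-pair length
#' is the tile center-to-center distance; midpoints, hemisphere and ROI
#' labels are recomputed from tile centers. Averaging is done on whatever
#' signal the session currently holds (conventionally raw intensity, before
#' OD conversion).
#'
#' @param session a [NirsSession-class].
#' @param montage the [Montage-class] the session was recorded with.
#' @param excludeIntraTile drop same-tile (zero-length) pairs.
#' @return a [NirsSession-class] with tile-pair channels.
#' @export
tileAverage <- function(session, montage, excludeIntraTile = FALSE) {
  ch <- channels(session)
  tl <- tiles(montage)
  key <- paste(ch$source_tile, ch$detector_tile, ch$wavelength, sep = "_")
  groups <- split(seq_len(nrow(ch)), key)
  ord <- order(vapply(groups, function(i) ch$source_tile[i[1]] * 1e6 +
                        ch$detector_tile[i[1]] * 1e2 +
                        match(ch$wavelength[i[1]], montage@wavelengths), numeric(1)))
  groups <- groups[ord]
  sig <- do.call(rbind, lapply(groups, function(i) {
    colMeans(session@intensity[i, , drop = FALSE])
  }))
  info <- do.call(rbind, lapply(groups, function(i) {
    st <- ch$source_tile[i[1]]; dt <- ch$detector_tile[i[1]]
    a <- tl[tl$id == st, ]; b <- tl[tl$id == dt, ]
    data.frame(
      source_tile = st, detector_tile = dt,
      wavelength = ch$wavelength[i[1]],
      length = sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2 + (a$cz - b$cz)^2),
      mid_x = (a$cx + b$cx) / 2, mid_y = (a$cy + b$cy) / 2,
      mid_z = (a$cz + b$cz) / 2,
      hemisphere = if (a$hemisphere == b$hemisphere) a$hemisphere else "cross"
    )
  }))
  rownames(info) <- NULL
  info$depth_proxy <- info$length / 4
  roiC <- montage@roiCenters
  dl <- sqrt((info$mid_x - roiC[1, 1])^2 + (info$mid_y - roiC[1, 2])^2)
  dr <- sqrt((info$mid_x - roiC[2, 1])^2 + (info$mid_y - roiC[2, 2])^2)
  rr <- montage@geometry$roiRadius
  info$roi <- ifelse(dl <= rr, "left_motor", ifelse(dr <= rr, "right_motor", "none"))
  info$source_id <- sprintf("T%02d", info$source_tile)
  info$detector_id <- sprintf("T%02d", info$detector_tile)
  pairKey <- paste(info$source_tile, info$detector_tile)
  info$pair_id <- as.integer(factor(pairKey, levels = unique(pairKey)))
  if (excludeIntraTile) {
    keep <- info$source_tile != info$detector_tile
    sig <- sig[keep, , drop = FALSE]
    info <- info[keep, , drop = FALSE]
    info$pair_id <- as.integer(factor(info$pair_id, levels = unique(info$pair_id)))
  }
  info <- cbind(id = seq_len(nrow(info)), info)
  rownames(info) <- rownames(sig) <- NULL
  out <- session
  out@intensity <- sig
  out@channels <- info
  out@meta <- c(session@meta, list(tile_averaged = TRUE))
  out
}

#' Modified Beer-Lambert law inversion
#'
#' Converts dual-wavelength delta-OD to chromophore concentration changes by
#' per-sample 2x2 inversion: solve E [dHbO; dHbR] = dOD / (L * DPF) for each
#' source-detector pair, with E the pinned extinction matrix.
#'
#' @param od OD matrix [wavelength-resolved channels x samples].
#' @param channelTable matching channel table with pair_id, wavelength,
#'   length columns.
#' @param dpf differential pathlength factor.
#' @param ext extinction matrix from [extinctionMatrix()].
#' @return list(hbo, hbr: matrices [pairs x samples] in uM, pairs: one-row-
#'   per-pair channel table).
#' @export
mbll <- function(od, channelTable, dpf = 6,
                 ext = extinctionMatrix(sort(unique(channelTable$wavelength)))) {
  wl <- sort(unique(channelTable$wavelength))
  stopIfNot(length(wl) == 2, "MBLL requires exactly two wavelengths")
  if (rcond(ext) < 1e-8) stop("degenerate wavelength pair: extinction matrix ill-conditioned")
  inv <- solve(ext)
  pid <- channelTable$pair_id
  upairs <- sort(unique(pid))
  i1 <- match(paste(upairs, wl[1]), paste(pid, channelTable$wavelength))
  i2 <- match(paste(upairs, wl[2]), paste(pid, channelTable$wavelength))
  stopIfNot(!anyNA(i1) && !anyNA(i2), "each pair needs both wavelengths")
  len <- channelTable$length[i1]
  pl <- pmax(len * dpf, .Machine$double.eps)  # intra-tile virtual pairs: L=0 guarded
  od1 <- od[i1, , drop = FALSE] / pl
  od2 <- od[i2, , drop = FALSE] / pl
  hbo <- inv[1, 1] * od1 + inv[1, 2] * od2
  hbr <- inv[2, 1] * od1 + inv[2, 2] * od2
  pairs <- channelTable[i1, , drop = FALSE]
  rownames(pairs) <- NULL
  list(hbo = hbo, hbr = hbr, pairs = pairs)
}

#' Recursive (causal) ZCA whitening
#'
#' Adaptive spatial decorrelation and standardization: a running channel
#' mean and covariance are updated once per `block_s`-second block with an
#' exponentially weighted scheme (half-life `half_life_s`), and each block is
#' transformed with the symmetric inverse square root of the previous
#' covariance estimate, shrunk by `shrinkage * tr(Sigma)/C` on the diagonal
#' so the shrinkage parameter is unit-free. The first block (no estimate
#' yet) passes through unchanged; state is per call, i.e. per session.
#'
#' @param x matrix [channels x samples].
#' @param fs sampling rate (Hz).
#' @param block_s update block length (s).
#' @param shrinkage diagonal shrinkage (relative to mean channel variance).
#' @param half_life_s forgetting half-life of the running estimates (s).
#' @return whitened matrix, same shape.
#' @export
recursiveZCA <- function(x, fs, block_s = 5, shrinkage = 1e-6,
                         half_life_s = 60) {
  C <- nrow(x); n <- ncol(x)
  bl <- max(2L, round(block_s * fs))
  if (n < bl) {
    warning("fewer samples than one ZCA block; returning input unchanged")
    return(x)
  }
  rho <- 0.5^(block_s / half_life_s)
  out <- x
  Sigma <- NULL; mu <- NULL
  starts <- seq(1L, n, by = bl)
  for (s0 in starts) {
    idx <- s0:min(n, s0 + bl - 1L)
    if (!is.null(Sigma)) {
      Sh <- Sigma + diag(shrinkage * sum(diag(Sigma)) / C, C)
      e <- eigen(Sh, symmetric = TRUE)
      Tm <- e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-300)))
      out[, idx] <- Tm %*% (x[, idx, drop = FALSE] - mu)
    }
    xb <- x[, idx, drop = FALSE]
    bmu <- rowMeans(xb)
    xc <- xb - bmu
    Sb <- tcrossprod(xc) / ncol(xb)
    if (is.null(Sigma)) { Sigma <- Sb; mu <- bmu }
    else { Sigma <- rho * Sigma + (1 - rho) * Sb; mu <- rho * mu + (1 - rho) * bmu }
  }
  out
}

# Task-segment sample indices: block spans minus a guard band, excluding
# baseline and breaks.
taskSegmentIndex <- function(markerTable, fs, nSamples, guard = 1) {
  bs <- markerTable[markerTable$label == "block_start", "time"]
  be <- markerTable[markerTable$label == "block_end", "time"]
  idx <- integer(0)
  for (i in seq_along(bs)) {
    idx <- c(idx, windowIndex(bs[i] + guard, be[i] - guard, fs))
  }
  idx[idx >= 1 & idx <= nSamples]
}

#' Epoch a continuous series around trial onsets
#'
#' Extracts half-open windows [t0, t1) seconds relative to each onset.
#'
#' @param x matrix [channels x samples].
#' @param onsets onset times (s).
#' @param t0,t1 window bounds (s, relative to onset).
#' @param fs sampling rate.
#' @return array [trials x channels x samples]; trials whose window falls
#'   outside the recording are dropped (attribute `kept` gives the indices).
#' @export
epochSeries <- function(x, onsets, t0, t1, fs) {
  nwin <- length(windowIndex(t0, t1, fs))
  keep <- integer(0)
  slices <- list()
  for (i in seq_along(onsets)) {
    idx <- windowIndex(t0, t1, fs, offset = -onsets[i])
    if (min(idx) < 1 || max(idx) > ncol(x)) next
    keep <- c(keep, i)
    slices[[length(slices) + 1]] <- x[, idx, drop = FALSE]
  }
  out <- array(0, dim = c(length(slices), nrow(x), nwin))
  for (i in seq_along(slices)) out[i, , ] <- slices[[i]]
  attr(out, "kept") <- keep
  out
}
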