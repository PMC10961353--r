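#' Extract causal decoder features from a session
#'
#' The subject-independent decoding chain: keep channels of length <=
#' `max_mm`; log-OD against a causal running EMA baseline (forget 0.01);
#' recursive ZCA decorrelation (5-s blocks, shrinkage 1e-6); MBLL (DPF 6);
#' epoch [0, 8.5] s from each covert trial onset; polyphase-resample each
#' epoch to 5 Hz (T = 43 samples: both endpoints of the 86-sample 10-Hz
#' segment map into the half-rate grid, floor(8.5*5)+1); stack HbO rows then
#' HbR rows. Robust z-scoring (per-feature median/MAD) uses the training-set
#' statistics: pass `scaler = NULL` to fit (training data) or a previously
#' fitted scaler to apply (test data); fitting on test data is impossible by
#' construction. Features with zero MAD get unit scale and are flagged in
#' the scaler.
#'
#' @param session a raw-intensity [NirsSession-class].
#' @param scaler NULL (fit here) or a scaler list from a previous call;
#'   `scale = FALSE` returns unscaled features.
#' @param max_mm channel length cut (mm).
#' @param epoch_s epoch window (s).
#' @param target_fs feature sampling rate (Hz).
#' @param scale logical; FALSE skips robust z-scoring (for harnesses that
#'   fit the scaler per cross-validation fold).
#' @return a [TrialFeatures-class].
#' @export
extractTrialFeatures <- function(session, scaler = NULL, max_mm = 50,
                                 epoch_s = c(0, 8.5), target_fs = 5,
                                 scale = TRUE) {
  fs <- samplingRate(session)
  ses <- channelLengthFilter(session, 0, max_mm)
  od <- intensityToOD(ses, "running_ema", fs = fs)
  od <- recursiveZCA(od, fs)
  cc <- mbll(od, channels(ses))
  mk <- markers(ses)
  trials <- mk[mk$label %in% c("left", "right"), , drop = FALSE]
  stopIfNot(nrow(trials) > 0, "session has no covert trials")
  npair <- nrow(cc$pairs)
  # half-open epoch [0, 8.5] with the onset sample included: 86 samples at
  # 10 Hz -> 43 at 5 Hz (pinned convention floor(8.5*5)+1)
  nIn <- round((epoch_s[2] - epoch_s[1]) * fs) + 1L
  Tn <- floor((epoch_s[2] - epoch_s[1]) * target_fs) + 1L
  stacked <- rbind(cc$hbo, cc$hbr)
  ep <- epochSeries(stacked, trials$time, epoch_s[1],
                    epoch_s[1] + nIn / fs, fs)
  kept <- attr(ep, "kept")
  trials <- trials[kept, , drop = FALSE]
  nt <- dim(ep)[1]
  q <- round(fs / target_fs)
  D <- decimationMatrix(nIn, q)
  x <- array(0, dim = c(nt, 2 * npair, Tn))
  for (i in seq_len(nt)) {
    m <- ep[i, , , drop = FALSE]; dim(m) <- dim(m)[2:3]
    x[i, , ] <- (m %*% t(D))[, seq_len(Tn), drop = FALSE]
  }
  pr <- cc$pairs
  rowInfo <- rbind(
    cbind(pr[, c("pair_id", "length", "mid_x", "mid_y", "mid_z",
                 "depth_proxy", "hemisphere")], chromophore = "hbo"),
    cbind(pr[, c("pair_id", "length", "mid_x", "mid_y", "mid_z",
                 "depth_proxy", "hemisphere")], chromophore = "hbr")
  )
  rownames(rowInfo) <- NULL
  tf <- new("TrialFeatures",
            x = x, labels = trials$label, blocks = as.integer(trials$block),
            rowInfo = rowInfo,
            time = epoch_s[1] + (seq_len(Tn) - 1) / target_fs,
            scaler = list())
  if (!scale) return(tf)
  applyScaler(tf, scaler %||% fitScaler(tf))
}

#' Robust feature scaler
#'
#' `fitScaler()` computes per-feature (row x time) median and MAD over the
#' trials of a [TrialFeatures-class]; `applyScaler()` standardizes features
#' with a fitted scaler. Zero-MAD features receive unit scale (flagged).
#'
#' @param tf a [TrialFeatures-class] (unscaled).
#' @return `fitScaler`: list(center, scale, flagged, n); `applyScaler`: a
#'   scaled [TrialFeatures-class].
#' @export
fitScaler <- function(tf) {
  x <- tf@x
  center <- apply(x, c(2, 3), median)
  scl <- apply(x, c(2, 3), function(v) mad(v))
  floorv <- 1e-12 * (abs(center) + 1)
  flagged <- scl <= floorv
  scl[flagged] <- 1
  list(center = center, scale = scl, flagged = flagged, n = dim(x)[1])
}

#' @rdname fitScaler
#' @param scaler a fitted scaler.
#' @export
applyScaler <- function(tf, scaler) {
  x <- tf@x
  for (i in seq_len(dim(x)[1])) {
    x[i, , ] <- (x[i, , ] - scaler$center) / scaler$scale
  }
  tf@x <- x
  tf@scaler <- scaler
  tf
}

#' Spatial and temporal Tikhonov operators
#'
#' The spatial operator Gs has one row per pair of feature rows of the same
#' chromophore whose anisotropic distance
#' d = sqrt(d_lateral^2 + (tau * d_depth)^2) is at most `r` mm, with lateral
#' distance between channel midpoints (x, y) and depth distance between
#' depth proxies (length/4); the row is w (e_i - e_j) with Gaussian weight
#' w = exp(-d^2 / (2 (r/2)^2)). The temporal operator Dt is the first-order
#' difference over the T feature columns. Both act on vec(W) with
#' column-major vectorization of the [rows x time] weight matrix (channel-
#' major with the HbO block before the HbR block, then time) — penalties are
#' evaluated as ||Gs W||_F^2 and ||W Dt'||_F^2, which is equivalent.
#'
#' @param rowInfo feature-row table of a [TrialFeatures-class].
#' @param T_len number of feature time points.
#' @param r smoothing radius (mm).
#' @param tau depth anisotropy factor.
#' @return list(Gs = sparse [n_pairs x n_rows], Dt = sparse
#'   [(T-1) x T]).
#' @export
buildTikhonovOperators <- function(rowInfo, T_len, r = 15, tau = 3 / 2) {
  n <- nrow(rowInfo)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (chrom in unique(rowInfo$chromophore)) {
    idx <- which(rowInfo$chromophore == chrom)
    px <- rowInfo$mid_x[idx]; py <- rowInfo$mid_y[idx]
    pz <- rowInfo$depth_proxy[idx]
    for (a in seq_along(idx)) {
      b <- seq_along(idx)
      b <- b[b > a]
      if (!length(b)) next
      d <- sqrt((px[a] - px[b])^2 + (py[a] - py[b])^2 +
                  (tau * (pz[a] - pz[b]))^2)
      sel <- which(d <= r)
      for (s in sel) {
        ii <- c(ii, idx[a]); jj <- c(jj, idx[b[s]])
        ww <- c(ww, exp(-d[s]^2 / (2 * (r / 2)^2)))
      }
    }
  }
  if (!length(ii)) {
    warning("no channel pairs within the smoothing radius; spatial operator empty")
    Gs <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(0, n))
  } else {
    m <- length(ii)
    Gs <- Matrix::sparseMatrix(
      i = c(seq_len(m), seq_len(m)), j = c(ii, jj), x = c(ww, -ww),
      dims = c(m, n))
  }
  Dt <- Matrix::sparseMatrix(
    i = c(seq_len(T_len - 1), seq_len(T_len - 1)),
    j = c(seq_len(T_len - 1), seq_len(T_len - 1) + 1L),
    x = c(rep(-1, T_len - 1), rep(1, T_len - 1)), dims = c(T_len - 1, T_len))
  list(Gs = Gs, Dt = Dt)
}

#' Singular-value soft-thresholding (proximal operator of the trace norm)
#'
#' @param M matrix.
#' @param threshold soft threshold on singular values.
#' @return U max(S - threshold, 0) V'.
#' @export
svtProx <- function(M, threshold) {
  if (threshold <= 0) return(M)
  s <- svd(M)
  d <- pmax(s$d - threshold, 0)
  s$u %*% (d * t(s$v))
}

#' Polyphase decimation matrix
#'
#' For integer decimation the polyphase resampler reduces to causal FIR
#' anti-alias filtering (fir1 of order 2d+1 at cutoff 1/q) followed by a
#' stride; this returns the [T_out x n] operator matrix so whole epochs can
#' be resampled with one matrix product. Matches `signal::resample(x, 1, q)`
#' exactly for integer `q`.
#'
#' @param n input length.
#' @param q integer decimation factor.
#' @param d half-order of the anti-alias FIR (as in `signal::resample`).
#' @return matrix [ceiling((n + 1 - q) / q) x n].
#' @export
decimationMatrix <- function(n, q, d = 5) {
  b <- signal::fir1(2 * d + 1, 1 / q)
  idx <- seq(1, n + 1 - q, by = q)
  D <- matrix(0, length(idx), n)
  for (j in seq_along(idx)) {
    ks <- seq_len(min(length(b), idx[j]))
    D[j, idx[j] - ks + 1] <- b[ks]
  }
  D
}

# Flatten a TrialFeatures (or 3D array) into the N x (rows*T) design matrix
# matching column-major vec(W).
designMatrix <- function(tf) {
  x <- if (is(tf, "TrialFeatures")) tf@x else tf
  d <- dim(x)
  matrix(x, nrow = d[1])  # trial-major flatten of [trials x rows x T]
}

# Smooth part of the decoder objective and its gradient.
decoderSmooth <- function(Xmat, yv, W, b, beta, gamma, AtA, BtB) {
  N <- nrow(Xmat)
  f <- as.numeric(Xmat %*% as.numeric(W)) + b
  z <- -yv * f
  loss <- mean(ifelse(z > 30, z, log1p(exp(z))))
  pen <- 0
  if (beta > 0) pen <- pen + beta * sum((AtA$Gs %*% W)^2)
  if (gamma > 0) pen <- pen + gamma * sum((W %*% BtB$DtT)^2)
  sigma <- 1 / (1 + exp(-z))
  gradv <- -as.numeric(crossprod(Xmat, yv * sigma)) / N
  gW <- matrix(gradv, nrow(W), ncol(W))
  if (beta > 0) gW <- gW + 2 * beta * as.matrix(AtA$GtG %*% W)
  if (gamma > 0) gW <- gW + 2 * gamma * W %*% BtB$DtD
  gb <- -sum(yv * sigma) / N
  list(value = loss + pen, gW = gW, gb = gb)
}

#' Fit the spatio-temporally regularized logistic decoder
#'
#' Minimizes
#' (1/N) sum_i log(1 + exp(-y_i (<W, X_i>_F + b))) + alpha ||W||_* +
#' beta ||Gs W||_F^2 + gamma ||W Dt'||_F^2
#' over the weight matrix W and unpenalized bias b, with labels mapped
#' left/right -> -1/+1. The smooth part (logistic loss + both Tikhonov
#' quadratics) is handled by gradient steps, the trace norm by singular-
#' value soft-thresholding, combined in a monotone FISTA with backtracking
#' line search. Iterations stop when the relative objective change falls
#' below `tol`.
#'
#' @param tf a scaled [TrialFeatures-class], or a 3D feature array.
#' @param labels trial labels ("left"/"right"); taken from `tf` if missing.
#' @param alpha,beta,gamma regularization strengths.
#' @param operators list(Gs, Dt) from [buildTikhonovOperators()]; built from
#'   `tf` when NULL (and set empty when beta = gamma = 0).
#' @param max_iter,tol solver controls.
#' @return a [DecoderModel-class]; its `trace` slot holds the objective per
#'   accepted iteration (non-increasing up to backtracking tolerance).
#' @export
fitDecoder <- function(tf, labels = NULL, alpha = 0.05, beta = 62.5,
                       gamma = 5, operators = NULL, max_iter = 200,
                       tol = 1e-6) {
  stopIfNot(all(c(alpha, beta, gamma) >= 0), "regularizers must be >= 0")
  isTF <- is(tf, "TrialFeatures")
  labels <- labels %||% (if (isTF) tf@labels else NULL)
  stopIfNot(!is.null(labels), "labels required")
  yv <- ifelse(labels == "right", 1, -1)
  stopIfNot(length(unique(yv)) == 2, "need both classes present")
  x <- if (isTF) tf@x else tf
  d <- dim(x)
  nr <- d[2]; Tn <- d[3]
  Xmat <- designMatrix(x)
  if (is.null(operators)) {
    operators <- if ((beta > 0 || gamma > 0) && isTF) {
      buildTikhonovOperators(tf@rowInfo, Tn)
    } else {
      list(Gs = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0), dims = c(0, nr)),
           Dt = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0), dims = c(0, Tn)))
    }
  }
  AtA <- list(Gs = operators$Gs, GtG = Matrix::crossprod(operators$Gs))
  BtB <- list(DtT = Matrix::t(operators$Dt),
              DtD = as.matrix(Matrix::crossprod(operators$Dt)))

  W <- matrix(0, nr, Tn); b <- 0
  Zw <- W; zb <- b
  tk <- 1
  L <- 1
  nuc <- function(M) sum(svd(M, nu = 0, nv = 0)$d)
  objective <- function(W, b) {
    decoderSmooth(Xmat, yv, W, b, beta, gamma, AtA, BtB)$value +
      alpha * nuc(W)
  }
  objBest <- objective(W, b)
  tracev <- objBest
  Wbest <- W; bbest <- b
  flat <- 0L
  restarted <- FALSE
  for (it in seq_len(max_iter)) {
    sm <- decoderSmooth(Xmat, yv, Zw, zb, beta, gamma, AtA, BtB)
    repeat {
      Wnew <- svtProx(Zw - sm$gW / L, alpha / L)
      bnew <- zb - sm$gb / L
      dW <- Wnew - Zw; db <- bnew - zb
      q <- sm$value + sum(sm$gW * dW) + sm$gb * db +
        (L / 2) * (sum(dW^2) + db^2)
      fnew <- decoderSmooth(Xmat, yv, Wnew, bnew, beta, gamma, AtA, BtB)$value
      if (fnew <= q + 1e-12 * abs(q) || L > 1e12) break
      L <- L * 2
    }
    objNew <- fnew + alpha * nuc(Wnew)
    if (!is.finite(objNew)) stop("decoder objective diverged; trace: ",
                                 paste(signif(tracev, 6), collapse = ", "))
    # monotone FISTA: the accepted iterate never increases the objective;
    # a rejected (momentum-overshot) step restarts the momentum sequence
    xPrev <- Wbest; bPrev <- bbest
    objCur <- objBest
    if (objNew < objBest) {
      Wbest <- Wnew; bbest <- bnew; objCur <- objNew
      tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
      Zw <- Wbest + (tk / tn) * (Wnew - Wbest) +
        ((tk - 1) / tn) * (Wbest - xPrev)
      zb <- bbest + (tk / tn) * (bnew - bbest) +
        ((tk - 1) / tn) * (bbest - bPrev)
      tk <- tn
      relchg <- (objBest - objCur) / max(abs(objBest), 1e-12)
      flat <- if (relchg < tol) flat + 1L else 0L
      restarted <- FALSE
    } else {
      if (restarted) { tracev <- c(tracev, objBest); break }
      tk <- 1
      Zw <- Wbest; zb <- bbest
      restarted <- TRUE
    }
    objBest <- objCur
    tracev <- c(tracev, objBest)
    if (it > 3 && flat >= 3L) break
  }
  new("DecoderModel",
      W = Wbest, b = bbest, alpha = alpha, beta = beta, gamma = gamma,
      operators = operators,
      scaler = if (isTF) tf@scaler else list(),
      rowInfo = if (isTF) tf@rowInfo else data.frame(),
      time = if (isTF) tf@time else numeric(0),
      trace = tracev, converged = it < max_iter)
}

#' Predict class probabilities with a fitted decoder
#'
#' p(right) = 1 / (1 + exp(-(<W, X>_F + b))) per trial.
#'
#' @param model a [DecoderModel-class].
#' @param tf a [TrialFeatures-class] (scaled with the model's training
#'   scaler) or 3D feature array with matching row/time dimensions.
#' @return numeric vector of probabilities of class "right".
#' @export
predictDecoder <- function(model, tf) {
  x <- if (is(tf, "TrialFeatures")) tf@x else tf
  d <- dim(x)
  stopIfNot(d[2] == nrow(model@W) && d[3] == ncol(model@W),
            "feature shape does not match model")
  f <- as.numeric(designMatrix(x) %*% as.numeric(model@W)) + model@b
  1 / (1 + exp(-f))
}

#' Export spatial weight maps and the hemispheric asymmetry curve
#'
#' The asymmetry curve is the mean signed weight over left-hemisphere
#' feature rows minus the right-hemisphere mean, per time point and
#' chromophore. Window maps average the per-channel weights within given
#' time windows, with midpoint/depth columns for plotting.
#'
#' @param model a fitted [DecoderModel-class].
#' @param windows optional data.frame(start, end) of time windows (s); the
#'   default splits the epoch into 5 equal windows.
#' @return list(asymmetry = data.frame(time, hbo, hbr),
#'   maps = data.frame(window, start, end, pair_id, chromophore, mid_x,
#'   mid_y, mid_z, depth_proxy, hemisphere, weight)).
#' @export
exportWeightMaps <- function(model, windows = NULL) {
  ri <- model@rowInfo
  stopIfNot(nrow(ri) > 0, "model carries no feature-row metadata")
  tvec <- model@time
  if (is.null(windows)) {
    br <- seq(min(tvec), max(tvec) + 1e-9, length.out = 6)
    windows <- data.frame(start = br[-6], end = br[-1])
  }
  asym <- data.frame(time = tvec)
  for (chrom in c("hbo", "hbr")) {
    li <- ri$chromophore == chrom & ri$hemisphere == "left"
    riRight <- ri$chromophore == chrom & ri$hemisphere == "right"
    asym[[chrom]] <- colMeans(model@W[li, , drop = FALSE]) -
      colMeans(model@W[riRight, , drop = FALSE])
  }
  maps <- do.call(rbind, lapply(seq_len(nrow(windows)), function(wi) {
    sel <- tvec >= windows$start[wi] & tvec < windows$end[wi] + 1e-9
    data.frame(
      window = wi, start = windows$start[wi], end = windows$end[wi],
      pair_id = ri$pair_id, chromophore = ri$chromophore,
      mid_x = ri$mid_x, mid_y = ri$mid_y, mid_z = ri$mid_z,
      depth_proxy = ri$depth_proxy, hemisphere = ri$hemisphere,
      weight = rowMeans(model@W[, sel, drop = FALSE])
    )
  }))
  list(asymmetry = asym, maps = maps)
}
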