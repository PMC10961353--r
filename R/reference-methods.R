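#' The five reference decoding pipelines
#'
#' Immutable presets for the adapted literature decoders, all sharing the
#' causal MACD bandpass and (where flagged) within-tile averaging, with the
#' shared handcrafted feature windows 2-4 s (initial dip), 4.25-6.25 s
#' (first imagined tap) and 6.5-7.5 s (second tap):
#' \describe{
#'   \item{cui}{tile-averaged 25-45 mm channels, mutual-information top-80
#'     features, linear C-SVM with nested grid search over C (subject-
#'     specific).}
#'   \item{shin}{unaveraged 10-20 mm and 25-35 mm channels, CoV >= 0.40
#'     channel rejection, shrinkage LDA (subject-specific).}
#'   \item{schudlo}{tile-averaged 25-35 mm channels, CoV rejection,
#'     sequential forward selection of the 4 best features, plain LDA
#'     (subject-specific).}
#'   \item{trambaiolli}{tile-averaged 25-34 mm channels, a single 4.5-8.5 s
#'     both-taps average plus the 2-4 s initial-dip feature, F-score
#'     selection with nested choice of the feature count (2..100),
#'     shrinkage LDA (subject-independent).}
#'   \item{shin_zca}{the shin chain pooled across sessions with causal
#'     recursive ZCA, shrinkage LDA (subject-independent).}
#' }
#'
#' @return named list of variant specifications.
#' @export
referenceVariants <- function() {
  shared <- rbind(c(2, 4), c(4.25, 6.25), c(6.5, 7.5))
  list(
    cui = list(name = "cui", tile_average = TRUE, bands = list(c(25, 45)),
               cov_reject = NULL, windows = shared, zca = FALSE,
               selector = list(kind = "mi_topk", k = 80),
               classifier = "svm_grid", scope = "subject_specific"),
    shin = list(name = "shin", tile_average = FALSE,
                bands = list(c(10, 20), c(25, 35)), cov_reject = 0.40,
                windows = shared, zca = FALSE,
                selector = list(kind = "none"),
                classifier = "slda", scope = "subject_specific"),
    schudlo = list(name = "schudlo", tile_average = TRUE,
                   bands = list(c(25, 35)), cov_reject = 0.40,
                   windows = shared, zca = FALSE,
                   selector = list(kind = "sfs", k = 4),
                   classifier = "lda", scope = "subject_specific"),
    trambaiolli = list(name = "trambaiolli", tile_average = TRUE,
                       bands = list(c(25, 34)), cov_reject = NULL,
                       windows = rbind(c(4.5, 8.5), c(2, 4)), zca = FALSE,
                       selector = list(kind = "fscore_nested",
                                       range = c(2, 100)),
                       classifier = "slda", scope = "subject_independent"),
    shin_zca = list(name = "shin_zca", tile_average = FALSE,
                    bands = list(c(10, 20), c(25, 35)), cov_reject = 0.40,
                    windows = shared, zca = TRUE,
                    selector = list(kind = "none"),
                    classifier = "slda", scope = "subject_independent")
  )
}

# Causal window-mean features of one session under a variant preset.
# Returns X [trials x features], y, blocks, and per-feature channel index
# plus per-block per-channel CoV (so rejection can be fit on training folds
# only).
variantFeatures <- function(session, montage, preset) {
  fs <- samplingRate(session)
  ses <- if (isTRUE(preset$tile_average)) tileAverage(session, montage) else session
  keep <- Reduce(`|`, lapply(preset$bands, function(b) {
    channels(ses)$length >= b[1] & channels(ses)$length <= b[2]
  }))
  if (!any(keep)) stop("variant length bands retain no channels")
  ses@intensity <- ses@intensity[keep, , drop = FALSE]
  ses@channels <- ses@channels[keep, , drop = FALSE]

  # per-block CoV of the 0.5 Hz low-passed intensity (channel rejection is
  # then decided from training blocks only)
  lp <- butterBandpass(ses@intensity, c(0, 0.5), fs, order = 4, causal = TRUE)
  mk <- markers(ses)
  bs <- mk[mk$label == "block_start", ]
  be <- mk[mk$label == "block_end", ]
  covBlock <- vapply(seq_len(nrow(bs)), function(b) {
    idx <- windowIndex(bs$time[b] + 1, be$time[b] - 1, fs)
    idx <- idx[idx <= ncol(lp)]
    seg <- lp[, idx, drop = FALSE]
    mu <- rowMeans(seg)
    ifelse(mu > 0, apply(seg, 1, sd) / mu, Inf)
  }, numeric(nrow(lp)))
  covBlock <- matrix(covBlock, nrow = nrow(lp))

  od <- intensityToOD(ses, "first_60s", fs = fs)
  od <- macdBandpass(od, fs)
  if (isTRUE(preset$zca)) od <- recursiveZCA(od, fs)
  cc <- mbll(od, channels(ses))
  # collapse channel-level CoV to pair level (mean over wavelengths)
  covBlock <- do.call(rbind, lapply(cc$pairs$pair_id, function(p) {
    colMeans(covBlock[channels(ses)$pair_id == p, , drop = FALSE])
  }))
  trials <- mk[mk$label %in% c("left", "right"), , drop = FALSE]
  npair <- nrow(cc$pairs)
  nw <- nrow(preset$windows)
  X <- matrix(NA_real_, nrow(trials), npair * 2 * nw)
  chanOfFeature <- integer(0)
  featNames <- character(0)
  for (w in seq_len(nw)) {
    for (chrom in 1:2) {
      cols <- (w - 1) * 2 * npair + (chrom - 1) * npair + seq_len(npair)
      sig <- if (chrom == 1) cc$hbo else cc$hbr
      for (i in seq_len(nrow(trials))) {
        idx <- windowIndex(preset$windows[w, 1], preset$windows[w, 2], fs,
                           offset = -trials$time[i])
        idx <- idx[idx >= 1 & idx <= ncol(sig)]
        X[i, cols] <- rowMeans(sig[, idx, drop = FALSE])
      }
      chanOfFeature <- c(chanOfFeature, seq_len(npair))
      featNames <- c(featNames, sprintf("w%d_%s_p%d", w,
                                        c("hbo", "hbr")[chrom], seq_len(npair)))
    }
  }
  colnames(X) <- featNames
  ok <- stats::complete.cases(X)
  list(X = X[ok, , drop = FALSE], y = trials$label[ok],
       blocks = as.integer(trials$block[ok]),
       chanOfFeature = chanOfFeature, covBlock = covBlock,
       pairs = cc$pairs)
}

#' Mutual-information feature score
#'
#' Histogram estimator: each feature is quantile-binned (fixed 8-bin rule,
#' seed-free) and the mutual information with the binary class label is
#' computed from the joint histogram.
#'
#' @param X feature matrix [n x p].
#' @param y labels.
#' @param bins number of quantile bins.
#' @return numeric vector of per-feature MI (nats).
#' @export
miScore <- function(X, y, bins = 8) {
  yf <- as.integer(factor(y))
  apply(X, 2, function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) return(0)
    b <- cut(v, br, include.lowest = TRUE, labels = FALSE)
    joint <- table(b, yf) / length(v)
    pb <- rowSums(joint); pc <- colSums(joint)
    s <- 0
    for (i in seq_along(pb)) for (j in seq_along(pc)) {
      if (joint[i, j] > 0) s <- s + joint[i, j] * log(joint[i, j] / (pb[i] * pc[j]))
    }
    s
  })
}

#' Fisher score of features
#' @inheritParams miScore
#' @return numeric vector of per-feature F-scores.
#' @export
fScore <- function(X, y) {
  cl <- sort(unique(y))
  stopIfNot(length(cl) == 2, "F-score needs two classes")
  i1 <- y == cl[1]; i2 <- y == cl[2]
  m <- colMeans(X); m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2, var)
  v2 <- apply(X[i2, , drop = FALSE], 2, var)
  ((m1 - m)^2 + (m2 - m)^2) / pmax(v1 + v2, 1e-300)
}

#' Sequential forward feature selection
#'
#' Greedy forward search maximizing cross-validated accuracy of the scorer
#' (default: plain LDA with 4-fold blockwise CV); ties are broken toward the
#' lowest feature index, making the selection deterministic.
#'
#' @param X feature matrix.
#' @param y labels.
#' @param k number of features to retain.
#' @param blocks fold grouping for the internal CV.
#' @param scorer function(X, y, blocks) -> accuracy used to score candidate
#'   sets.
#' @return integer vector of selected feature indices, in selection order.
#' @export
sfsSelect <- function(X, y, k = 4, blocks = NULL, scorer = NULL) {
  stopIfNot(k <= ncol(X), "k exceeds the number of features")
  blocks <- blocks %||% rep(seq_len(4), length.out = nrow(X))
  scorer <- scorer %||% function(Xs, ys, bl) {
    cvAccuracy(Xs, ys, bl, ldaFit, ldaPredict)
  }
  chosen <- integer(0)
  avail <- seq_len(ncol(X))
  for (step in seq_len(k)) {
    best <- -Inf; bestJ <- NA_integer_
    for (j in avail) {
      acc <- scorer(X[, c(chosen, j), drop = FALSE], y, blocks)
      if (acc > best + 1e-12) { best <- acc; bestJ <- j }
    }
    chosen <- c(chosen, bestJ)
    avail <- setdiff(avail, bestJ)
  }
  chosen
}

# Simple grouped CV accuracy used inside selectors.
cvAccuracy <- function(X, y, blocks, fit, pred) {
  folds <- unique(blocks)
  hits <- 0; tot <- 0
  for (f in folds) {
    tr <- blocks != f
    if (length(unique(y[tr])) < 2) next
    m <- fit(X[tr, , drop = FALSE], y[tr])
    p <- pred(m, X[!tr, , drop = FALSE])
    hits <- hits + sum(p == y[!tr]); tot <- tot + sum(!tr)
  }
  if (tot == 0) 0.5 else hits / tot
}

#' Ledoit-Wolf shrinkage linear discriminant analysis
#'
#' Two-class LDA with the pooled covariance analytically shrunk toward a
#' scaled identity (Ledoit-Wolf intensity), well-defined when the feature
#' dimension exceeds the sample count.
#'
#' @param X feature matrix [n x p].
#' @param y labels (exactly two classes).
#' @return classifier list (use [sldaPredict()]).
#' @export
sldaFit <- function(X, y) {
  cl <- sort(unique(y))
  stopIfNot(length(cl) == 2, "sLDA needs exactly two classes")
  mu <- rbind(colMeans(X[y == cl[1], , drop = FALSE]),
              colMeans(X[y == cl[2], , drop = FALSE]))
  Xc <- X
  Xc[y == cl[1], ] <- sweep(X[y == cl[1], , drop = FALSE], 2, mu[1, ])
  Xc[y == cl[2], ] <- sweep(X[y == cl[2], , drop = FALSE], 2, mu[2, ])
  n <- nrow(X); p <- ncol(X)
  S <- crossprod(Xc) / n
  muI <- sum(diag(S)) / p
  d2 <- sum((S - diag(muI, p))^2)
  rown2 <- rowSums(Xc^2)
  b2bar <- (sum(rown2^2) - n * sum(S^2)) / n^2
  b2 <- min(max(b2bar, 0), d2)
  shrink <- if (d2 > 0) b2 / d2 else 1
  Sstar <- shrink * diag(muI, p) + (1 - shrink) * S
  w <- solve(Sstar + diag(1e-10 * max(muI, 1e-300), p), mu[2, ] - mu[1, ])
  b <- -sum(w * (mu[1, ] + mu[2, ]) / 2)
  list(w = w, b = b, classes = cl, shrinkage = shrink)
}

#' @rdname sldaFit
#' @param model fitted classifier.
#' @param Xnew feature matrix to classify.
#' @export
sldaPredict <- function(model, Xnew) {
  s <- as.numeric(Xnew %*% model$w) + model$b
  model$classes[(s > 0) + 1]
}

# Plain LDA wrappers (MASS).
ldaFit <- function(X, y) {
  keep <- apply(X, 2, function(v) var(v) > 1e-300)
  m <- MASS::lda(X[, keep, drop = FALSE], grouping = factor(y))
  list(m = m, keep = keep)
}
ldaPredict <- function(model, Xnew) {
  as.character(predict(model$m, Xnew[, model$keep, drop = FALSE])$class)
}

# Linear C-SVM with nested blockwise grid search over the cost parameter.
svmGridFit <- function(X, y, blocks = NULL,
                       grid = 2^seq(-5, 15, by = 2)) {
  blocks <- blocks %||% rep(seq_len(4), length.out = nrow(X))
  fitC <- function(C) function(Xs, ys) {
    e1071::svm(Xs, factor(ys), kernel = "linear", cost = C, scale = TRUE)
  }
  predC <- function(m, Xs) as.character(predict(m, Xs))
  accs <- vapply(grid, function(C) {
    cvAccuracy(X, y, blocks, fitC(C), predC)
  }, numeric(1))
  bestC <- grid[which.max(accs)]
  list(m = e1071::svm(X, factor(y), kernel = "linear", cost = bestC,
                      scale = TRUE),
       C = bestC)
}
svmPredict <- function(model, Xnew) as.character(predict(model$m, Xnew))

# Train the preset's selector + classifier on training data; returns a
# prediction closure and a record of what was fit (for the leakage audit).
# `chCov` is the per-pair coefficient of variation computed by the caller
# from training data only.
variantTrain <- function(preset, X, y, blocks, chCov = NULL,
                         chanOfFeature = NULL) {
  cols <- seq_len(ncol(X))
  if (!is.null(preset$cov_reject) && !is.null(chCov)) {
    keepChan <- which(chCov < preset$cov_reject)
    if (!length(keepChan)) stop("CoV rejection removed all channels")
    cols <- which(chanOfFeature %in% keepChan)
  }
  Xt <- X[, cols, drop = FALSE]
  sel <- switch(preset$selector$kind,
    none = seq_len(ncol(Xt)),
    mi_topk = {
      k <- min(preset$selector$k, ncol(Xt))
      order(miScore(Xt, y), decreasing = TRUE)[seq_len(k)]
    },
    sfs = sfsSelect(Xt, y, min(preset$selector$k, ncol(Xt)), blocks),
    fscore_nested = {
      ord <- order(fScore(Xt, y), decreasing = TRUE)
      kmax <- min(preset$selector$range[2], ncol(Xt))
      kcand <- unique(pmin(kmax, pmax(preset$selector$range[1],
                                      round(exp(seq(log(preset$selector$range[1]),
                                                    log(kmax), length.out = 6))))))
      accs <- vapply(kcand, function(k) {
        cvAccuracy(Xt[, ord[seq_len(k)], drop = FALSE], y, blocks,
                   sldaFit, sldaPredict)
      }, numeric(1))
      ord[seq_len(kcand[which.max(accs)])]
    })
  Xs <- Xt[, sel, drop = FALSE]
  model <- switch(preset$classifier,
    svm_grid = svmGridFit(Xs, y, blocks),
    slda = sldaFit(Xs, y),
    lda = ldaFit(Xs, y))
  predictFn <- switch(preset$classifier,
    svm_grid = svmPredict, slda = sldaPredict, lda = ldaPredict)
  list(
    predict = function(Xnew) predictFn(model, Xnew[, cols, drop = FALSE][, sel, drop = FALSE]),
    n_features = ncol(Xs), cols = cols, sel = sel, model = model,
    fitRecord = list(n_train = nrow(X), blocks = sort(unique(blocks)))
  )
}

#' Run a reference decoding variant over a cohort
#'
#' Subject-specific presets are scored by 4-fold blockwise cross-validation
#' within each session (folds are the task blocks); subject-independent
#' presets by leave-one-subject-out cross-validation over pooled sessions.
#' All stages with fit semantics (CoV rejection, feature selection,
#' classifier) are fit on training folds only.
#'
#' @param preset one element of [referenceVariants()] (or its name).
#' @param sessions list of raw [NirsSession-class] objects.
#' @param montage the common [Montage-class].
#' @return data.frame(subject, session, accuracy, n_trials, n_features) with
#'   attributes `summary` (mean, sd, t, p vs chance) and `fitLog`.
#' @export
runVariant <- function(preset, sessions, montage) {
  if (is.character(preset)) preset <- referenceVariants()[[preset]]
  stopIfNot(!is.null(preset$name), "unknown variant preset")
  feats <- lapply(sessions, variantFeatures, montage = montage, preset = preset)
  subj <- vapply(sessions, subjectId, character(1))
  sesn <- vapply(sessions, sessionNumber, integer(1))
  fitLog <- list()
  rows <- list()
  if (preset$scope == "subject_specific") {
    for (i in seq_along(feats)) {
      f <- feats[[i]]
      folds <- sort(unique(f$blocks))
      stopIfNot(length(folds) >= 2, "blockwise CV needs >= 2 blocks")
      hits <- 0; tot <- 0; nf <- integer(0)
      for (b in folds) {
        tr <- f$blocks != b
        chCov <- rowMeans(f$covBlock[, sort(unique(f$blocks[tr])), drop = FALSE])
        tmod <- variantTrain(preset, f$X[tr, , drop = FALSE], f$y[tr],
                             f$blocks[tr], chCov, f$chanOfFeature)
        p <- tmod$predict(f$X[!tr, , drop = FALSE])
        hits <- hits + sum(p == f$y[!tr]); tot <- tot + sum(!tr)
        nf <- c(nf, tmod$n_features)
        fitLog[[length(fitLog) + 1]] <- list(
          variant = preset$name, session = i, test_block = b,
          train_blocks = sort(unique(f$blocks[tr])), n_train = sum(tr))
      }
      rows[[i]] <- data.frame(subject = subj[i], session = sesn[i],
                              accuracy = hits / tot, n_trials = tot,
                              n_features = max(nf))
    }
  } else {
    for (i in seq_along(feats)) {
      tr <- which(subj != subj[i])
      Xtr <- do.call(rbind, lapply(feats[tr], `[[`, "X"))
      ytr <- unlist(lapply(feats[tr], `[[`, "y"))
      btr <- unlist(lapply(seq_along(tr), function(j) {
        rep(j %% 4 + 1L, length(feats[[tr[j]]]$y))  # grouped pseudo-blocks
      }))
      chCov <- if (!is.null(preset$cov_reject)) {
        cb <- lapply(feats[tr], `[[`, "covBlock")
        Reduce(`+`, lapply(cb, rowMeans)) / length(cb)
      } else NULL
      tmod <- variantTrain(preset, Xtr, ytr,
                           if (length(unique(btr)) >= 2) btr else
                             rep(seq_len(4), length.out = length(ytr)),
                           chCov, feats[[i]]$chanOfFeature)
      p <- tmod$predict(feats[[i]]$X)
      rows[[i]] <- data.frame(subject = subj[i], session = sesn[i],
                              accuracy = mean(p == feats[[i]]$y),
                              n_trials = length(feats[[i]]$y),
                              n_features = tmod$n_features)
      fitLog[[length(fitLog) + 1]] <- list(
        variant = preset$name, test_session = i,
        train_sessions = tr, n_train = nrow(Xtr))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tt <- t.test(out$accuracy, mu = 0.5, alternative = "greater")
  attr(out, "summary") <- c(mean = mean(out$accuracy), sd = sd(out$accuracy),
                            t = unname(tt$statistic), p = tt$p.value)
  attr(out, "fitLog") <- fitLog
  out
}
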