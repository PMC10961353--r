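#' Leave-one-subject-out cross-validation of the high-density decoder
#'
#' For every session, a model is trained on all sessions of all *other*
#' subjects (every session of the test subject is excluded) and evaluated on
#' the held-out session. The robust feature scaler is fit on the pooled
#' training trials of each fold only and applied to the test session. An
#' optional nested grid over (alpha, beta) is resolved by an inner
#' leave-one-subject-out loop on each training set. Every fold's fit inputs
#' are fingerprinted for the no-leakage audit ([checkNoLeakage()]).
#'
#' @param features list of unscaled [TrialFeatures-class] objects (one per
#'   session, `scale = FALSE` in [extractTrialFeatures()]).
#' @param subjects character vector of subject ids per session.
#' @param alpha,beta,gamma decoder regularization (defaults used when no
#'   grid is given).
#' @param grid optional data.frame(alpha, beta) of hyperparameter candidates.
#' @param max_iter,tol solver controls passed to [fitDecoder()].
#' @return data.frame(subject, session_index, accuracy, n_trials) with
#'   attributes `summary` (mean, sd, one-sided t and p vs 50%), `fitLog`.
#' @export
losoCV <- function(features, subjects, alpha = 0.05, beta = 62.5, gamma = 5,
                   grid = NULL, max_iter = 150, tol = 1e-5) {
  stopIfNot(length(features) == length(subjects),
            "one subject id per session required")
  stopIfNot(length(unique(subjects)) >= 3, "LOSO needs at least 3 subjects")
  rows <- list(); fitLog <- list()
  for (i in seq_along(features)) {
    trIdx <- which(subjects != subjects[i])
    if (!length(trIdx)) next
    hp <- c(alpha = alpha, beta = beta)
    if (!is.null(grid) && nrow(grid) > 1) {
      hp <- innerGridSearch(features, subjects, trIdx, grid, gamma,
                            max_iter, tol)
    }
    fold <- fitFold(features, trIdx, hp["alpha"], hp["beta"], gamma,
                    max_iter, tol)
    testTF <- applyScaler(features[[i]], fold$scaler)
    p <- predictDecoder(fold$model, testTF)
    pred <- ifelse(p > 0.5, "right", "left")
    rows[[i]] <- data.frame(
      subject = subjects[i], session_index = i,
      accuracy = mean(pred == trialLabels(testTF)),
      n_trials = length(p), alpha = unname(hp["alpha"]),
      beta = unname(hp["beta"]))
    fitLog[[length(fitLog) + 1]] <- list(
      test_session = i, test_subject = subjects[i],
      train_sessions = trIdx, train_subjects = unique(subjects[trIdx]),
      scaler_n = fold$scaler$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tt <- t.test(out$accuracy, mu = 0.5, alternative = "greater")
  attr(out, "summary") <- c(mean = mean(out$accuracy), sd = sd(out$accuracy),
                            t = unname(tt$statistic), p = tt$p.value,
                            n = nrow(out))
  attr(out, "fitLog") <- fitLog
  out
}

# Pool training sessions, fit scaler + decoder.
fitFold <- function(features, trIdx, alpha, beta, gamma, max_iter, tol) {
  pooled <- poolFeatures(features[trIdx])
  scaler <- fitScaler(pooled)
  pooled <- applyScaler(pooled, scaler)
  model <- fitDecoder(pooled, alpha = alpha, beta = beta, gamma = gamma,
                      max_iter = max_iter, tol = tol)
  list(model = model, scaler = scaler)
}

#' Concatenate TrialFeatures along the trial axis
#'
#' @param fl list of [TrialFeatures-class] with identical row/time layouts.
#' @return one unscaled [TrialFeatures-class].
#' @export
poolFeatures <- function(fl) {
  d2 <- dim(fl[[1]]@x)[2]; d3 <- dim(fl[[1]]@x)[3]
  nt <- vapply(fl, function(f) dim(f@x)[1], integer(1))
  x <- array(0, dim = c(sum(nt), d2, d3))
  at <- 0L
  for (f in fl) {
    n <- dim(f@x)[1]
    x[at + seq_len(n), , ] <- f@x
    at <- at + n
  }
  new("TrialFeatures", x = x,
      labels = unlist(lapply(fl, trialLabels)),
      blocks = unlist(lapply(fl, function(f) f@blocks)),
      rowInfo = fl[[1]]@rowInfo, time = fl[[1]]@time, scaler = list())
}

# Inner LOSO over the training subjects to choose (alpha, beta).
innerGridSearch <- function(features, subjects, trIdx, grid, gamma,
                            max_iter, tol) {
  innerSub <- unique(subjects[trIdx])
  best <- -Inf; bestHp <- c(alpha = grid$alpha[1], beta = grid$beta[1])
  for (g in seq_len(nrow(grid))) {
    accs <- numeric(0)
    for (s in innerSub) {
      inTr <- trIdx[subjects[trIdx] != s]
      inTe <- trIdx[subjects[trIdx] == s]
      if (!length(inTr) || !length(inTe)) next
      fold <- fitFold(features, inTr, grid$alpha[g], grid$beta[g], gamma,
                      max_iter, tol)
      for (j in inTe) {
        tf <- applyScaler(features[[j]], fold$scaler)
        p <- predictDecoder(fold$model, tf)
        accs <- c(accs, mean(ifelse(p > 0.5, "right", "left") ==
                               trialLabels(tf)))
      }
    }
    if (mean(accs) > best) {
      best <- mean(accs)
      bestHp <- c(alpha = grid$alpha[g], beta = grid$beta[g])
    }
  }
  bestHp
}

#' Blockwise within-session cross-validation
#'
#' k folds follow the session's task-block structure (no trial ever crosses
#' between a training and test fold of the same block), the recommended
#' within-session protocol for blocked task designs.
#'
#' @param X feature matrix [trials x features].
#' @param y labels.
#' @param blocks task-block index per trial.
#' @param fitFn function(X, y) -> model.
#' @param predictFn function(model, X) -> predicted labels.
#' @param k number of folds (must not exceed the number of blocks).
#' @return data.frame(fold, accuracy, n_test) with attributes `summary` and
#'   `fitLog`.
#' @export
blockwiseCV <- function(X, y, blocks, fitFn, predictFn, k = 4) {
  ub <- sort(unique(blocks))
  stopIfNot(length(ub) >= k, "fewer blocks than folds")
  foldOf <- setNames(rep(seq_len(k), length.out = length(ub)), ub)
  rows <- list(); fitLog <- list()
  for (f in seq_len(k)) {
    te <- foldOf[as.character(blocks)] == f
    m <- fitFn(X[!te, , drop = FALSE], y[!te])
    p <- predictFn(m, X[te, , drop = FALSE])
    rows[[f]] <- data.frame(fold = f, accuracy = mean(p == y[te]),
                            n_test = sum(te))
    fitLog[[f]] <- list(fold = f, train_blocks = sort(unique(blocks[!te])),
                        test_blocks = sort(unique(blocks[te])),
                        n_train = sum(!te))
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(mean = mean(out$accuracy), sd = sd(out$accuracy))
  attr(out, "fitLog") <- fitLog
  out
}

#' No-leakage audit of a cross-validation result
#'
#' Inspects the fit log recorded by [losoCV()], [blockwiseCV()] or
#' [runVariant()] and asserts that (1) no test session/block appears among
#' its own fold's fit inputs, (2) for LOSO, no session of the test subject
#' was trained on, and (3) the scaler (when recorded) was fit on exactly
#' the training trials of the fold.
#'
#' @param cvResult a result carrying a `fitLog` attribute.
#' @param features optional feature list to cross-check scaler trial counts.
#' @return TRUE (invisibly) if the audit passes; otherwise an error
#'   describing the leak.
#' @export
checkNoLeakage <- function(cvResult, features = NULL) {
  log <- attr(cvResult, "fitLog")
  stopIfNot(!is.null(log), "result carries no fit log")
  for (entry in log) {
    if (!is.null(entry$test_session) && !is.null(entry$train_sessions)) {
      if (entry$test_session %in% entry$train_sessions) {
        stop("leakage: test session ", entry$test_session, " in training set")
      }
    }
    if (!is.null(entry$test_subject) && !is.null(entry$train_subjects)) {
      if (entry$test_subject %in% entry$train_subjects) {
        stop("leakage: sessions of test subject ", entry$test_subject,
             " in training set")
      }
    }
    if (!is.null(entry$test_block) && !is.null(entry$train_blocks)) {
      if (entry$test_block %in% entry$train_blocks) {
        stop("leakage: test block in training folds")
      }
    }
    if (!is.null(entry$test_blocks) && !is.null(entry$train_blocks)) {
      if (length(intersect(entry$test_blocks, entry$train_blocks))) {
        stop("leakage: overlapping train/test blocks")
      }
    }
    if (!is.null(entry$scaler_n) && !is.null(features)) {
      nTrain <- sum(vapply(entry$train_sessions, function(j) {
        dim(features[[j]]@x)[1]
      }, numeric(1)))
      if (entry$scaler_n != nTrain) {
        stop("leakage: scaler fit on ", entry$scaler_n,
             " trials but fold has ", nTrain, " training trials")
      }
    }
  }
  invisible(TRUE)
}
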