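# Synthetic per-session TrialFeatures with a controllable linear effect, so
# the CV harnesses can be exercised without simulating recordings.
synthCohort <- function(nSubjects, trialsPer = 24, effect = 0, seed = 1) {
  set.seed(seed)
  npair <- 4; Tn <- 6
  rowInfo <- data.frame(
    pair_id = rep(1:npair, 2), length = rep(c(20, 30, 20, 30), 2),
    mid_x = rep(c(-25, -15, 15, 25), 2), mid_y = 0, mid_z = 0,
    depth_proxy = rep(c(5, 7.5, 5, 7.5), 2),
    hemisphere = rep(c("left", "left", "right", "right"), 2),
    chromophore = rep(c("hbo", "hbr"), each = npair))
  pat <- outer(seq_len(2 * npair) %% 3 - 1, seq_len(Tn) %% 2)
  feats <- lapply(seq_len(nSubjects), function(s) {
    y <- sample(rep(c("left", "right"), trialsPer / 2))
    x <- array(rnorm(trialsPer * 2 * npair * Tn), c(trialsPer, 2 * npair, Tn))
    for (i in seq_len(trialsPer)) {
      x[i, , ] <- x[i, , ] + effect * (if (y[i] == "right") 1 else -1) * pat
    }
    new("TrialFeatures", x = x, labels = y,
        blocks = rep(1:4, each = trialsPer / 4), rowInfo = rowInfo,
        time = seq(0, by = 0.2, length.out = Tn), scaler = list())
  })
  list(features = feats, subjects = sprintf("s%02d", seq_len(nSubjects)))
}

test_that("LOSO recovers a planted effect and the audit passes", {
  co <- synthCohort(5, effect = 0.6, seed = 2)
  cv <- losoCV(co$features, co$subjects, max_iter = 80)
  expect_gt(attr(cv, "summary")["mean"], 0.7)
  expect_true(checkNoLeakage(cv, co$features))
  expect_equal(nrow(cv), 5)
})

test_that("LOSO on pure noise stays within 2 SE of chance", {
  co <- synthCohort(5, effect = 0, seed = 3)
  cv <- losoCV(co$features, co$subjects, max_iter = 60)
  n <- sum(cv$n_trials)
  expect_lt(abs(attr(cv, "summary")["mean"] - 0.5), 2 * sqrt(0.25 / n) + 0.05)
  expect_true(checkNoLeakage(cv, co$features))
})

test_that("a bias-only model scores the class base rate", {
  co <- synthCohort(3, trialsPer = 20, effect = 0, seed = 4)
  # unbalance the test session's labels
  co$features[[1]]@labels <- rep(c("left", "right"), c(15, 5))
  cv <- losoCV(co$features, co$subjects, alpha = 1e6, beta = 0, gamma = 0,
               max_iter = 10)
  # with W = 0 the prediction is the bias sign -> accuracy equals the rate
  # of whichever class the pooled training majority predicts
  expect_true(cv$accuracy[1] %in% c(15 / 20, 5 / 20, 0.5))
})

test_that("the nested grid search selects hyperparameters on inner folds only", {
  co <- synthCohort(4, trialsPer = 16, effect = 0.5, seed = 5)
  grid <- data.frame(alpha = c(0.01, 10), beta = c(0.1, 0.1))
  cv <- losoCV(co$features, co$subjects, grid = grid, gamma = 0.1,
               max_iter = 40)
  expect_true(all(cv$alpha %in% grid$alpha))
  # the informative effect should favor the weakly regularized model
  expect_true(mean(cv$alpha == 0.01) >= 0.75)
  expect_true(checkNoLeakage(cv, co$features))
})

test_that("blockwise CV respects block structure and counts", {
  set.seed(6)
  n <- 40
  X <- matrix(rnorm(n * 3), n)
  y <- rep(c("left", "right"), 20)
  blocks <- rep(1:4, each = 10)
  res <- blockwiseCV(X, y, blocks, sldaFit, sldaPredict, k = 4)
  expect_equal(sum(res$n_test), n)
  for (f in seq_len(4)) {
    lg <- attr(res, "fitLog")[[f]]
    expect_length(lg$test_blocks, 1)
    expect_false(lg$test_blocks %in% lg$train_blocks)
  }
  checkNoLeakage(res)
  expect_error(blockwiseCV(X, y, rep(1:2, each = 20), sldaFit, sldaPredict,
                           k = 4), "fewer blocks")
})

test_that("a trial-identity memorizer gains nothing across blocks", {
  # classifier that memorizes training rows exactly: on unseen blocks it
  # falls back to a coin flip decided by the nearest memorized row
  set.seed(7)
  n <- 48
  X <- matrix(rnorm(n * 4), n)
  y <- sample(rep(c("left", "right"), n / 2))
  blocks <- rep(1:4, each = n / 4)
  memFit <- function(Xs, ys) list(X = Xs, y = ys)
  memPred <- function(m, Xs) {
    apply(Xs, 1, function(r) {
      m$y[which.min(colSums((t(m$X) - r)^2))]
    })
  }
  res <- blockwiseCV(X, y, blocks, memFit, memPred, k = 4)
  expect_lt(abs(attr(res, "summary")["mean"] - 0.5), 0.25)
})

test_that("the leakage audit rejects a corrupted fit log", {
  co <- synthCohort(3, trialsPer = 8, effect = 0, seed = 8)
  cv <- losoCV(co$features, co$subjects, max_iter = 5)
  log <- attr(cv, "fitLog")
  log[[1]]$train_sessions <- c(log[[1]]$train_sessions, log[[1]]$test_session)
  attr(cv, "fitLog") <- log
  expect_error(checkNoLeakage(cv), "leakage")
})
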