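test_that("coefficient of variation follows the ddof=1 convention", {
  x <- matrix(c(1, 2, 3), 1)
  expect_equal(as.numeric(coefficientOfVariation(x)), 0.5)  # sd 1, mean 2
  const <- matrix(5, 1, 10)
  expect_equal(as.numeric(coefficientOfVariation(const)), 0)
  set.seed(1)
  y <- matrix(abs(rnorm(200, 10)), 1)
  expect_equal(coefficientOfVariation(2 * y), coefficientOfVariation(y),
               ignore_attr = TRUE)
  neg <- matrix(c(-1, 1), 1)
  expect_true(is.na(coefficientOfVariation(neg)))
})

test_that("robust SNR matches its formula and caps degenerate channels", {
  # median 100, median absolute deviation 1 -> 20 dB
  x <- matrix(c(99, 100, 101, 100, 102, 98, 100, 103, 97, 100, 101), 1)
  expect_equal(as.numeric(robustSNR(x)), 10 * log10(100 / 1))
  # MAD = 0 -> capped sentinel
  d <- matrix(c(9, 10, 11, 10, 10), 1)
  expect_equal(as.numeric(robustSNR(d)), 60)
  expect_equal(attr(robustSNR(d), "capped"), 1L)
  set.seed(2)
  ln <- matrix(exp(rnorm(500, 3, 0.3)), 1)
  med <- median(ln); madr <- median(abs(ln - med))
  expect_equal(as.numeric(robustSNR(ln)), 10 * log10(med / madr))
})

test_that("stimulus SNR separates band-limited signal from broadband noise", {
  fs <- 10
  sched <- generateSchedule(shortSchedule(1, 10), 2, seed = 1)
  mk <- sched
  n <- 3000
  t <- (0:(n - 1)) / fs
  set.seed(3)
  # planted 0.05 Hz component well above broadband noise: scores far higher
  # than broadband noise (the metric's purpose), though the mean-power ratio
  # is bounded near 0 dB by construction
  strong <- matrix(10 * sin(2 * pi * 0.05 * t) + rnorm(n, 0, 1), 1)
  white <- matrix(rnorm(n), 1)
  expect_gt(stimulusSNR(strong, mk, fs), stimulusSNR(white, mk, fs) + 5)
  # pure white noise: the narrow filter removes most power
  expect_lt(stimulusSNR(white, mk, fs), 0)
  expect_error(stimulusSNR(white, mk[mk$label == "block_start", ], fs),
               "no motor-imagery")
})

test_that("ROI quality score maps CoV to [0,1] with ROI emphasis", {
  m <- midMontage()
  ch <- channels(m)
  rc <- m@roiCenters
  cv0 <- rep(0, nrow(ch))
  expect_equal(roiQualityScore(cv0, ch, rc), 1)
  expect_lt(roiQualityScore(rep(1e6, nrow(ch)), ch, rc), 1e-6)
  # raising CoV on motor-ROI channels hurts more than on distal channels
  nRoi <- sum(ch$roi != "none")
  distal <- order(pmin(
    (ch$mid_x - rc[1, 1])^2 + (ch$mid_y - rc[1, 2])^2,
    (ch$mid_x - rc[2, 1])^2 + (ch$mid_y - rc[2, 2])^2),
    decreasing = TRUE)[seq_len(nRoi)]
  cvA <- cv0; cvA[ch$roi != "none"] <- 1
  cvB <- cv0; cvB[distal] <- 1
  expect_lt(roiQualityScore(cvA, ch, rc), roiQualityScore(cvB, ch, rc))
  # invariant to channel ordering
  perm <- sample(nrow(ch))
  expect_equal(roiQualityScore(cvA[perm], ch[perm, ], rc),
               roiQualityScore(cvA, ch, rc))
})

test_that("session partition finds the low-quality cluster", {
  p <- partitionSessions(c(0.01, 0.015, 0.4, 0.5))
  expect_equal(p$label, c("PQ", "PQ", "MVQ", "MVQ"))
  tq <- attr(p, "t_qual")
  expect_gt(tq, 0.014); expect_lt(tq, 0.4)
  expect_warning(pe <- partitionSessions(rep(0.3, 5)), "no quality gap")
  expect_true(all(pe$label == "MVQ"))
  # manual threshold: label is MVQ iff score > t_qual
  pm <- partitionSessions(c(0.01, 0.02, 0.03), t_qual = 0.02)
  expect_equal(pm$label, c("PQ", "PQ", "MVQ"))
  # monotonicity: raising a session's score never flips MVQ -> PQ
  sc <- c(0.01, 0.015, 0.4, 0.5)
  p1 <- partitionSessions(sc, t_qual = 0.1)
  sc2 <- sc; sc2[3] <- 0.6
  p2 <- partitionSessions(sc2, t_qual = 0.1)
  expect_false(any(p1$label == "MVQ" & p2$label == "PQ"))
})

test_that("CoV-length sigmoid fit recovers known parameters", {
  set.seed(4)
  len <- runif(300, 5, 80)
  truth <- c(a = 0.02, b = 0.6, m = 45, s = 6)
  cv <- truth["a"] + (truth["b"] - truth["a"]) /
    (1 + exp(-(len - truth["m"]) / truth["s"])) + rnorm(300, 0, 0.01)
  fit <- fitCvLengthSigmoid(cv, len)
  expect_true(fit$converged)
  for (nm in names(truth)) {
    expect_lt(abs(fit[[nm]] - truth[nm]) / truth[nm], 0.1)
  }
  # constant data: degenerate fit flagged
  fitc <- fitCvLengthSigmoid(rep(0.1, 50) + rnorm(50, 0, 1e-8),
                             seq(5, 80, length.out = 50))
  expect_true(fitc$degenerate || !fitc$converged)
})

test_that("MVQ sessions show the quality falloff with midpoint in 25-60 mm", {
  sched <- generateSchedule(shortSchedule(2, 10), 2, seed = 2)
  ses <- simulateSession(midMontage(), sched, seed = 31,
                         factors = mvqFactors())
  q <- sessionQuality(ses, midMontage())
  fit <- fitCvLengthSigmoid(q$cv, channels(ses)$length)
  expect_true(fit$converged)
  expect_gt(fit$m, 25); expect_lt(fit$m, 60)
})
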