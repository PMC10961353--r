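test_that("OD conversion matches its definition and handles references", {
  set.seed(1)
  x <- matrix(exp(rnorm(3 * 400, 5, 0.1)), 3)
  od <- intensityToOD(x, "whole_session")
  expect_equal(od, -log(x / rowMeans(x)), ignore_attr = TRUE)
  # I == ref -> OD == 0
  const <- matrix(7, 2, 100)
  expect_equal(max(abs(intensityToOD(const, "whole_session"))), 0)
  # I = ref * exp(-1) at one sample -> OD = 1 there
  y <- matrix(2, 1, 800)
  y[1, 700] <- 2 * exp(-1)
  odf <- intensityToOD(y, "first_60s", fs = 10)
  expect_equal(odf[1, 700], 1, tolerance = 1e-12)
  # running EMA reference is causal and starts at the first sample
  odr <- intensityToOD(y, "running_ema", fs = 10)
  expect_equal(odr[1, 1], 0)
  expect_error(intensityToOD(matrix(0, 1, 10), "whole_session"), "nonpositive")
})

test_that("MACD filter: constant input decays geometrically at 1 - forget", {
  x <- rep(3, 400)
  y <- macdBandpass(x, fs = 10)
  r <- y[300:399] / y[299:398]
  expect_equal(mean(r), 0.99, tolerance = 1e-3)
})

test_that("MACD impulse response equals the direct recursion oracle", {
  n <- 200
  x <- numeric(n); x[50] <- 1
  # independent oracle: explicit EMA recursion + boxcar average
  ema <- numeric(n)
  for (t in seq_len(n)) {
    prev <- if (t == 1) 0 else ema[t - 1]
    ema[t] <- prev + 0.01 * (x[t] - prev)
  }
  hp <- x - ema
  orc <- vapply(seq_len(n), function(t) {
    mean(c(rep(0, 19), hp)[t:(t + 19)])
  }, numeric(1))
  expect_equal(macdBandpass(x, fs = 10), orc, tolerance = 1e-12)
})

test_that("MACD sinusoid attenuation matches the analytic transfer function", {
  fs <- 10; f0 <- 0.05
  t <- (0:19999) / fs
  x <- sin(2 * pi * f0 * t)
  y <- macdBandpass(x, fs)
  # analytic |H|: (1 - EMA lowpass) cascaded with 20-tap boxcar
  z <- exp(-2i * pi * f0 / fs)
  hEma <- 0.01 / (1 - 0.99 * z)
  hBox <- (1 - z^20) / (20 * (1 - z))
  gain <- Mod((1 - hEma) * hBox)
  # steady-state amplitude over the last half
  amp <- sqrt(2 * mean(y[10000:20000]^2))
  expect_equal(amp, gain, tolerance = 0.01 * max(gain, 1e-6))
})

test_that("MACD is linear and causal", {
  set.seed(2)
  a <- rnorm(300); b <- rnorm(300)
  expect_equal(macdBandpass(a + b, 10),
               macdBandpass(a, 10) + macdBandpass(b, 10), tolerance = 1e-12)
  y <- macdBandpass(a, 10)
  yt <- macdBandpass(a[1:150], 10)
  expect_equal(y[1:150], yt, tolerance = 1e-12)
})

test_that("Butterworth bandpass kills DC, passes 1 Hz, rejects bad bands", {
  fs <- 10
  x <- rep(1, 2000)
  y <- butterBandpass(x, c(0.02, 2), fs)
  expect_lt(max(abs(y[500:1500])), 0.05)
  t <- (0:4999) / fs
  s <- sin(2 * pi * 1 * t)
  ys <- butterBandpass(s, c(0.02, 2), fs)
  amp <- sqrt(2 * mean(ys[2000:3000]^2))
  expect_equal(amp, 1, tolerance = 0.05)
  expect_error(butterBandpass(s, c(0.02, 6), fs), "Nyquist")
})

test_that("TDDR: exact on zeros, near-identity on clean data, idempotent", {
  expect_equal(tddr(rep(0, 500), 10), rep(0, 500), ignore_attr = TRUE)
  set.seed(3)
  t <- (0:1499) / 10
  x <- 0.5 * sin(2 * pi * 0.08 * t) + rnorm(1500, 0, 0.05)
  y <- tddr(x, 10)
  expect_lt(max(abs(y - x)), 0.2 * sd(x))
  y2 <- tddr(as.numeric(y), 10)
  expect_lt(max(abs(y2 - y)), 0.15 * sd(x))
})

test_that("TDDR suppresses a large low-frequency motion excursion >= 10x", {
  set.seed(4)
  n <- 3000
  x <- rnorm(n, 0, 0.01)
  # 1.5-s half-sine excursion of ~20 SD (a head-movement artifact)
  at <- 1500:1529
  x[at] <- x[at] + 0.3 * sin(pi * seq(0, 1, length.out = 30))
  y <- tddr(x, 10)
  epoch <- 1450:1580
  expect_gt(var(x[epoch]) / var(y[epoch]), 10)
})

test_that("GVTD statistic and rejection behave per definition", {
  # constant signal -> g identically zero, nothing rejected
  ep <- array(1, dim = c(5, 3, 40))
  r <- gvtdReject(ep)
  expect_true(all(r$keep))
  expect_equal(max(r$statistic), 0)
  # identical epochs -> zero SD -> none rejected
  set.seed(5)
  base <- matrix(rnorm(3 * 40), 3, 40)
  ep2 <- array(0, dim = c(6, 3, 40))
  for (i in 1:6) ep2[i, , ] <- base
  expect_true(all(gvtdReject(ep2)$keep))
  # 29 clean epochs + 1 with a planted spike -> exactly that one rejected
  ep3 <- array(rnorm(30 * 4 * 50, 0, 0.1), dim = c(30, 4, 50))
  ep3[17, , 25] <- ep3[17, , 25] + 5
  r3 <- gvtdReject(ep3)
  expect_equal(which(!r3$keep), 17L)
  expect_warning(gvtdReject(ep3[1:2, , , drop = FALSE]), "fewer than 3")
})

test_that("tile averaging reproduces member signals and the pair census", {
  m <- fullMontage()
  ch <- channels(m)
  # constant per-channel signal: averaging identical members is identity
  sched <- generateSchedule(shortSchedule(1, 2), 2, seed = 1)
  ses <- new("NirsSession",
             intensity = matrix(1, nrow(ch), 50), fs = 10,
             markers = sched[1, , drop = FALSE], channels = ch,
             subjectId = "t", sessionNumber = 1L,
             factors = data.frame(), meta = list())
  ta <- tileAverage(ses, m)
  expect_true(all(ta@intensity == 1))
  expect_equal(nrow(channels(ta)), 12 * 12 * 2)
  expect_equal(nrow(channels(tileAverage(ses, m, excludeIntraTile = TRUE))),
               12 * 12 * 2 - 12 * 2)
  # mirror symmetry of the retained in-hemisphere 15-60 mm set
  kept <- channelLengthFilter(channels(ta), 15, 60)
  kept <- kept[kept$hemisphere != "cross", ]
  expect_equal(sum(kept$hemisphere == "left"), sum(kept$hemisphere == "right"))
  expect_equal(length(unique(kept$pair_id)), 44)
  expect_equal(nrow(kept), 88)
})

test_that("MBLL inverts the forward model exactly", {
  m <- decodeMontage()
  ch <- channels(m)
  ext <- extinctionMatrix()
  n <- 80
  up <- !duplicated(ch$pair_id)
  npair <- sum(up)
  set.seed(6)
  hbo <- matrix(rnorm(npair * n, 0, 0.5), npair)
  hbr <- matrix(rnorm(npair * n, 0, 0.2), npair)
  wl <- match(ch$wavelength, c(735, 850))
  pid <- match(ch$pair_id, ch$pair_id[up])
  od <- (ext[wl, 1] * hbo[pid, ] + ext[wl, 2] * hbr[pid, ]) * (ch$length * 6)
  cc <- mbll(od, ch)
  expect_lt(max(abs(cc$hbo - hbo)) / max(abs(hbo)), 1e-10)
  expect_lt(max(abs(cc$hbr - hbr)) / max(abs(hbr)), 1e-10)
  # zero OD -> zero concentrations
  cc0 <- mbll(od * 0, ch)
  expect_equal(max(abs(cc0$hbo)), 0)
  # planted unit HbO step recovers exactly
  hboStep <- matrix(0, npair, n); hboStep[, 40:n] <- 1
  odS <- (ext[wl, 1] * hboStep[pid, ]) * (ch$length * 6)
  ccS <- mbll(odS, ch)
  expect_lt(max(abs(ccS$hbo - hboStep)), 1e-10)
  expect_lt(max(abs(ccS$hbr)), 1e-10)
  # degenerate wavelength pair errors out
  chBad <- ch
  expect_error(mbll(od, ch, ext = matrix(c(1, 1, 1, 1), 2)), "ill-conditioned")
})

test_that("recursive ZCA is near-identity on exactly white input", {
  # channels with exact identity sample covariance per 5-s block:
  # orthogonal sinusoids at bin frequencies, unit variance
  fs <- 10; n <- 1200
  t <- 0:(n - 1)
  x <- rbind(sqrt(2) * sin(2 * pi * 5 * t / 50),
             sqrt(2) * sin(2 * pi * 10 * t / 50),
             sqrt(2) * cos(2 * pi * 5 * t / 50))
  y <- recursiveZCA(x, fs)
  burn <- 500:n
  expect_lt(sqrt(sum((y[, burn] - x[, burn])^2) / sum(x[, burn]^2)), 1e-3)
})

test_that("recursive ZCA decorrelates and standardizes stationary input", {
  set.seed(7)
  fs <- 10; n <- 3000
  A <- matrix(rnorm(16), 4)
  x <- A %*% matrix(rnorm(4 * n), 4)
  y <- recursiveZCA(x, fs)
  burn <- y[, 1001:n]
  cr <- cor(t(burn))
  expect_lt(max(abs(cr[upper.tri(cr)])), 0.1)
  expect_true(all(abs(apply(burn, 1, var) - 1) < 0.35))
  # duplicated channels stay finite thanks to shrinkage
  xd <- rbind(x[1, ], x[1, ], x[2, ])
  expect_true(all(is.finite(recursiveZCA(xd, fs))))
  # fewer samples than a block: identity with a warning
  expect_warning(ident <- recursiveZCA(x[, 1:30], fs), "fewer samples")
  expect_equal(ident, x[, 1:30])
})

test_that("causal transforms pass the truncation test", {
  set.seed(8)
  x <- matrix(rnorm(2 * 800), 2)
  full <- recursiveZCA(x, 10)
  part <- recursiveZCA(x[, 1:400], 10)
  expect_equal(full[, 1:400], part, tolerance = 1e-12)
  odF <- intensityToOD(exp(x), "running_ema", fs = 10)
  odP <- intensityToOD(exp(x[, 1:400]), "running_ema", fs = 10)
  expect_equal(odF[, 1:400], odP, tolerance = 1e-10, ignore_attr = TRUE)
})
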