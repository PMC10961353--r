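test_that("zero noise, unit coupling, zero amplitude gives constant intensity", {
  hemo <- hemodynamicSpec(amp_hbo = 0, superficial_amp = 0, initial_dip = FALSE)
  ses <- midSession(seed = 1, n_blocks = 1, trials_per_block = 2,
                    hemo = hemo, noise = noiselessSpec(), coupling = 1)
  x <- intensity(ses)
  expect_true(all(abs(x - x[, 1]) < 1e-9 * x[, 1]))
})

test_that("inverse MBLL on noise-free simulation recovers planted concentrations", {
  hemo <- hemodynamicSpec(superficial_amp = 0)
  ses <- midSession(seed = 2, n_blocks = 1, trials_per_block = 4,
                    hemo = hemo, noise = noiselessSpec(), coupling = 1)
  od <- intensityToOD(ses, "whole_session")
  # undo the mean-reference so OD is absolute (constant shift per channel)
  cc <- mbll(od, channels(ses))
  # recompute the planted per-pair HbO from the generator's own model
  ch <- channels(ses)
  up <- !duplicated(ch$pair_id)
  len <- ch$length[up]
  sel <- which(len >= 20 & len <= 45 & ch$roi[up] == "right_motor")[1]
  expect_true(is.finite(sel))
  hbo <- cc$hbo[sel, ]
  # planted trace is the kernel train; correlation with recovered ~ 1
  tr <- markers(ses); on <- tr$time[tr$label %in% c("left", "right")]
  k <- hdnirs:::responseKernel(hemo, 10)
  n <- ncol(cc$hbo)
  stim <- numeric(n)
  lab <- tr$label[tr$label %in% c("left", "right")]
  amp <- ifelse(lab == "left", 1, hemo$ipsi_ratio)
  for (i in seq_along(on)) stim[round(on[i] * 10) + 1] <- amp[i]
  planted <- convolve(stim, rev(k), type = "open")[seq_len(n)]
  expect_gt(cor(hbo, planted), 0.999)
})

test_that("left-hand trials drive the contralateral motor ROI harder", {
  hemo <- hemodynamicSpec(superficial_amp = 0)
  ses <- midSession(seed = 3, n_blocks = 2, trials_per_block = 10,
                    hemo = hemo, noise = lowNoiseSpec(), coupling = 1)
  ba <- runBlockAverage(ses, midMontage())
  pr <- ba$pairs
  contra <- max(apply(ba$hrf[pr$roi == "right_motor", "hbo", , "left",
                             drop = FALSE], 3, mean))
  ipsi <- max(apply(ba$hrf[pr$roi == "left_motor", "hbo", , "left",
                           drop = FALSE], 3, mean))
  expect_gt(contra, ipsi)
})

test_that("PQ coupling floor makes every channel beyond 25 mm exceed 15% CoV", {
  sched <- generateSchedule(shortSchedule(2, 10), 2, seed = 1)
  ses <- simulateSession(midMontage(), sched, seed = 9, factors = pqFactors())
  expect_true(ses@meta$truth$pq)
  cv <- coefficientOfVariation(ses)
  lens <- channels(ses)$length
  expect_true(all(cv[lens > 25] > 0.15, na.rm = TRUE))
})

test_that("planted response peak latency is in range and recovered by epoching", {
  hemo <- hemodynamicSpec()
  expect_gte(hemo$response_peak_s, 6)
  expect_lte(hemo$response_peak_s, 10)
  # plain epoch means on a noiseless session (no causal chain) reproduce the
  # planted latency within +/-0.2 s
  ses <- midSession(seed = 4, n_blocks = 1, trials_per_block = 6,
                    hemo = hemodynamicSpec(superficial_amp = 0),
                    noise = noiselessSpec(), coupling = 1)
  cc <- mbll(intensityToOD(ses, "whole_session"), channels(ses))
  tr <- markers(ses)
  on <- tr$time[tr$label == "left"]
  on <- on[on * 10 + 171 <= ncol(cc$hbo)]
  sel <- cc$pairs$roi == "right_motor"
  v <- rowMeans(sapply(on, function(o) {
    idx <- round(o * 10) + 1 + 0:170
    colMeans(cc$hbo[sel, idx, drop = FALSE]) -
      mean(cc$hbo[sel, round(o * 10) + 1 - 20:1])
  }))
  expect_lt(abs((which.max(v) - 1) / 10 - hemo$response_peak_s), 0.2 + 1e-9)
})

test_that("cohort generation is deterministic and has the requested shape", {
  co1 <- generateCohort(nSubjects = 6, sessionCounts = c(6, 3, 2),
                        montage = decodeMontage(), spec = shortSchedule(1, 2),
                        seed = 8, sessionFun = function(s) NULL)
  co2 <- generateCohort(nSubjects = 6, sessionCounts = c(6, 3, 2),
                        montage = decodeMontage(), spec = shortSchedule(1, 2),
                        seed = 8, sessionFun = function(s) NULL)
  expect_identical(co1$factors, co2$factors)
  expect_identical(co1$manifest, co2$manifest)
  expect_equal(nrow(co1$manifest), 11)
  expect_equal(as.vector(table(co1$manifest$session_number)), c(6, 3, 2))
  # subject factors are consistent across a subject's sessions
  for (s in unique(co1$factors$subject_id)) {
    sub <- co1$factors[co1$factors$subject_id == s, ]
    expect_equal(length(unique(sub$hair_color)), 1)
    expect_equal(length(unique(sub$age)), 1)
  }
})

test_that("optode coupling decreases across hair-severity strata", {
  spec <- couplingSpec()
  meanCoupling <- function(sev) {
    mean(vapply(1:20, function(i) {
      mean(drawCoupling(spec, sev, 50, seed = i)$coupling)
    }, numeric(1)))
  }
  m <- c(meanCoupling(0.1), meanCoupling(0.4), meanCoupling(0.9))
  expect_true(all(diff(m) < 0))
})

test_that("severe-hair demographics produce PQ-flagged subjects downstream", {
  co <- generateCohort(nSubjects = 8, sessionCounts = c(8),
                       montage = decodeMontage(), spec = shortSchedule(1, 2),
                       seed = 5, demographics = pqDemographics(),
                       sessionFun = function(s) NULL)
  expect_gt(mean(co$manifest$pq_profile), 0.9)
})
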