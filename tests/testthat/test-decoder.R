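# Small synthetic TrialFeatures for solver tests: 6 channels (12 rows with
# both chromophores) x 5 time points, with a planted linear effect.
toyFeatures <- function(n = 40, effect = 1, seed = 1, Tn = 5, npair = 6) {
  set.seed(seed)
  rowInfo <- data.frame(
    pair_id = rep(seq_len(npair), 2),
    length = rep(seq(20, 45, length.out = npair), 2),
    mid_x = rep(c(-30, -20, -10, 10, 20, 30), 2),
    mid_y = 0, mid_z = 0,
    depth_proxy = rep(seq(5, 11, length.out = npair), 2),
    hemisphere = rep(c(rep("left", 3), rep("right", 3)), 2),
    chromophore = rep(c("hbo", "hbr"), each = npair)
  )
  y <- rep(c("left", "right"), length.out = n)
  x <- array(rnorm(n * 2 * npair * Tn), dim = c(n, 2 * npair, Tn))
  pat <- outer(sin(seq_len(2 * npair)), cos(seq_len(Tn)))
  for (i in seq_len(n)) {
    x[i, , ] <- x[i, , ] + effect * (if (y[i] == "right") 1 else -1) * pat
  }
  new("TrialFeatures", x = x, labels = y,
      blocks = rep(1:4, length.out = n), rowInfo = rowInfo,
      time = seq(0, by = 0.2, length.out = Tn), scaler = list())
}

test_that("feature extraction pins the 43-sample 5 Hz epoch convention", {
  expect_equal(floor(8.5 * 5) + 1, 43)
  set.seed(1)
  r <- rnorm(86)
  expect_equal(as.numeric(decimationMatrix(86, 2) %*% r),
               as.numeric(signal::resample(r, 1, 2)), tolerance = 1e-12)
  ses <- cached("decode_session", {
    sched <- generateSchedule(shortSchedule(1, 8), 2, seed = 2)
    simulateSession(decodeMontage(), sched, seed = 2,
                    factors = mvqFactors())
  })
  tf <- extractTrialFeatures(ses, scale = FALSE)
  d <- dim(featureArray(tf))
  expect_equal(d[3], 43)
  # row count = 2 * (number of pairs <= 50 mm), against brute force
  ch <- channels(ses)
  nPair <- length(unique(ch$pair_id[ch$length <= 50]))
  expect_equal(d[2], 2 * nPair)
  expect_equal(d[1], 8)
  expect_equal(tf@rowInfo$chromophore, rep(c("hbo", "hbr"), each = nPair))
})

test_that("constant intensity yields ~zero features via the MAD floor", {
  ses <- cached("decode_session", NULL)
  sesC <- ses
  sesC@intensity <- matrix(1000, nrow(intensity(ses)), ncol(intensity(ses)))
  tf <- extractTrialFeatures(sesC)
  expect_true(all(abs(featureArray(tf)) < 1e-8))
  expect_true(any(tf@scaler$flagged))
})

test_that("Tikhonov operators annihilate constants and match brute force", {
  tf <- toyFeatures()
  ops <- buildTikhonovOperators(tf@rowInfo, 5, r = 15, tau = 1.5)
  W0 <- matrix(1, 12, 5)
  expect_equal(max(abs(ops$Gs %*% W0)), 0)       # spatially constant
  expect_equal(max(abs(W0 %*% Matrix::t(ops$Dt)))[1], 0)  # temporally constant
  # brute-force pairwise penalty evaluation
  set.seed(2)
  W <- matrix(rnorm(60), 12, 5)
  ri <- tf@rowInfo
  pen <- 0
  for (a in 1:11) for (b in (a + 1):12) {
    if (ri$chromophore[a] != ri$chromophore[b]) next
    d <- sqrt((ri$mid_x[a] - ri$mid_x[b])^2 + (ri$mid_y[a] - ri$mid_y[b])^2 +
                (1.5 * (ri$depth_proxy[a] - ri$depth_proxy[b]))^2)
    if (d > 15) next
    w <- exp(-d^2 / (2 * 7.5^2))
    pen <- pen + sum((w * (W[a, ] - W[b, ]))^2)
  }
  expect_equal(sum((as.matrix(ops$Gs %*% W))^2), pen, tolerance = 1e-12)
  # temporal penalty is the first-difference roughness
  expect_equal(sum((W %*% Matrix::t(ops$Dt))^2),
               sum(diff(t(W))^2), tolerance = 1e-12)
})

test_that("singular-value soft thresholding matches definition and oracle", {
  expect_equal(svtProx(diag(c(3, 1)), 1), diag(c(2, 0)), tolerance = 1e-12)
  set.seed(3)
  M <- matrix(rnorm(35), 5, 7)
  expect_equal(svtProx(M, 0), M)
  # oracle: minimize 0.5||X - M||^2 + t ||X||_* with smoothed nuclear norm
  t0 <- 0.7
  obj <- function(v) {
    X <- matrix(v, 5, 7)
    e <- eigen(X %*% t(X) + diag(1e-14, 5), symmetric = TRUE)$values
    0.5 * sum((X - M)^2) + t0 * sum(sqrt(pmax(e, 0)))
  }
  o <- optim(as.numeric(M), obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(obj(as.numeric(svtProx(M, t0))), o$value, tolerance = 1e-4)
  expect_lte(obj(as.numeric(svtProx(M, t0))), o$value + 1e-4)
})

test_that("unregularized fit separates a separable toy problem", {
  tf <- toyFeatures(n = 2, effect = 5)
  m <- fitDecoder(tf, alpha = 0, beta = 0, gamma = 0, max_iter = 400)
  p <- predictDecoder(m, tf)
  expect_equal(ifelse(p > 0.5, "right", "left"), trialLabels(tf))
  expect_lt(tail(m@trace, 1), 0.05)  # objective driven toward 0
})

test_that("a huge trace-norm penalty collapses the weights", {
  tf <- toyFeatures(n = 30, effect = 0.5)
  m <- fitDecoder(tf, alpha = 1e4, beta = 0, gamma = 0, max_iter = 100)
  expect_lt(max(abs(m@W)), 1e-8)
  expect_true(all(abs(predictDecoder(m, tf) - predictDecoder(m, tf)[1]) < 1e-12))
})

test_that("FISTA matches an independent quasi-Newton oracle within 1e-4", {
  tf <- toyFeatures(n = 40, effect = 0.8)
  ops <- buildTikhonovOperators(tf@rowInfo, 5)
  alpha <- 0.05; beta <- 2; gamma <- 2
  m <- fitDecoder(tf, alpha = alpha, beta = beta, gamma = gamma,
                  operators = ops, max_iter = 500, tol = 1e-9)
  # independent objective implementation
  X <- matrix(tf@x, nrow = 40)
  yv <- ifelse(trialLabels(tf) == "right", 1, -1)
  Gs <- as.matrix(ops$Gs); Dt <- as.matrix(ops$Dt)
  objective <- function(v) {
    W <- matrix(v[-length(v)], 12, 5); b <- v[length(v)]
    f <- X %*% as.numeric(W) + b
    e <- eigen(W %*% t(W) + diag(1e-12, 12), symmetric = TRUE)$values
    mean(log1p(exp(-yv * f))) + alpha * sum(sqrt(pmax(e, 0))) +
      beta * sum((Gs %*% W)^2) + gamma * sum((W %*% t(Dt))^2)
  }
  o <- optim(rep(0, 61), objective, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-14))
  fista <- objective(c(as.numeric(m@W), m@b))
  expect_lt(abs(fista - o$value) / abs(o$value), 1e-4)
  # objective trace is monotone (within backtracking tolerance)
  expect_true(all(diff(m@trace) <= 1e-10))
})

test_that("predictions follow the logistic symmetry contracts", {
  tf <- toyFeatures(n = 10)
  m0 <- fitDecoder(tf, alpha = 1e6, beta = 0, gamma = 0, max_iter = 5)
  m0@W[] <- 0; m0@b <- 0
  expect_equal(predictDecoder(m0, tf), rep(0.5, 10))
  m <- fitDecoder(tf, alpha = 0.01, beta = 0.1, gamma = 0.1, max_iter = 50)
  tfn <- tf; tfn@x <- -tf@x
  if (abs(m@b) < 1e-8) {
    expect_equal(predictDecoder(m, tfn), 1 - predictDecoder(m, tf),
                 tolerance = 1e-8)
  } else {
    mb <- m; mb@b <- 0
    expect_equal(predictDecoder(mb, tfn), 1 - predictDecoder(mb, tf),
                 tolerance = 1e-8)
  }
  bad <- toyFeatures(Tn = 4)
  expect_error(predictDecoder(m, bad), "shape")
})

test_that("weight maps: symmetric weights cancel, windows tile the epoch", {
  tf <- toyFeatures()
  m <- fitDecoder(tf, alpha = 0.01, beta = 0.1, gamma = 0.1, max_iter = 30)
  # mirror-symmetric weights -> zero asymmetry curve
  ri <- m@rowInfo
  for (chrom in c("hbo", "hbr")) {
    li <- which(ri$chromophore == chrom & ri$hemisphere == "left")
    riR <- which(ri$chromophore == chrom & ri$hemisphere == "right")
    m@W[riR, ] <- m@W[li, ]
  }
  wm <- exportWeightMaps(m)
  expect_lt(max(abs(wm$asymmetry$hbo)), 1e-12)
  expect_lt(max(abs(wm$asymmetry$hbr)), 1e-12)
  # explicit windows partition [0, 8.5] without overlap
  wins <- data.frame(start = c(0, 1, 2.1, 4, 6),
                     end = c(1, 2.1, 4, 6, 8.5))
  m2 <- fitDecoder(toyFeatures(Tn = 43), alpha = 0.01, beta = 0, gamma = 0,
                   max_iter = 5)
  m2@time <- seq(0, 8.4, by = 0.2)
  maps <- exportWeightMaps(m2, wins)$maps
  counts <- table(maps$window)
  expect_equal(sum(counts), 5 * nrow(m2@rowInfo))
  # every time point lands in exactly one window
  tv <- m2@time
  hits <- sapply(tv, function(t) sum(t >= wins$start & t < wins$end + 1e-9))
  expect_true(all(hits >= 1))
})
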