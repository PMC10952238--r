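test_that("sharpness saturates on a step edge and matches the erf closed form", {
  # ideal 0 -> 1 step between adjacent pixels: |p80 - p20| = 0.6 px,
  # 1/0.6 > 1 clips to 100%
  step <- c(rep(0, 6), rep(1, 6))
  expect_equal(sharpness(step), 100)
  # error-function edge of width sigma: |p80 - p20| = 1.683 sigma
  for (sigma in c(1.2, 2, 3)) {
    x <- seq(-12, 12, by = 0.25)
    prof <- stats::pnorm(x / sigma)
    want <- 100 * min(1, 1 / (1.6832 * sigma))
    expect_equal(sharpness(prof, spacing = 0.25), want,
                 tolerance = 0.02 * want)
  }
  # monotone decreasing in edge width
  vals <- vapply(seq(0.5, 4, by = 0.5), function(s) {
    x <- seq(-12, 12, by = 0.25)
    sharpness(stats::pnorm(x / s), spacing = 0.25)
  }, numeric(1))
  expect_true(all(diff(vals) < 1e-9))
  expect_error(sharpness(rep(1, 12)), "constant")
  expect_error(sharpness(c(0, 1)), "samples")
})

test_that("temporal CoV measures flicker about the running-median curve", {
  expect_equal(temporal_cov(rep(3, 20)), 0)
  # isolated +/- delta spikes every 4th frame: the 5-frame median
  # recovers the level c exactly, the residual RMS is delta/2, so
  # CoV = 100 * delta / (2 c)
  c0 <- 2; delta <- 0.1
  curve <- rep(c0, 40)
  curve[seq(3, 40, by = 4)] <- c0 + delta * rep(c(1, -1), 5)
  expect_equal(temporal_cov(curve, window = 5), 100 * delta / (2 * c0),
               tolerance = 0.01 * 100 * delta / (2 * c0))
  # invariant to positive rescaling
  set.seed(70)
  r <- abs(stats::rnorm(40)) + 1
  expect_equal(temporal_cov(5 * r), temporal_cov(r), tolerance = 1e-12)
  expect_error(temporal_cov(rep(1, 10), window = 4), "odd")
  expect_error(temporal_cov(rep(1, 5), window = 7), "longer")
  expect_equal(formals(temporal_cov)$window, 7)
})

test_that("MAE normalizes to [0,1] and is affine invariant", {
  set.seed(71)
  a <- array(stats::runif(8 * 8 * 5), dim = c(8, 8, 5))
  expect_equal(mae(a, a), 0)
  # post-normalization inversion against direct summation
  b <- 1 - a
  an <- (a - min(a)) / diff(range(a))
  expect_equal(mae(b, a), mean(abs(1 - 2 * an)), tolerance = 1e-12)
  # invariant to (positive) affine rescaling of magnitude data
  expect_equal(mae(3 * a + 2, 0.5 * a + 0.1), mae(a, a), tolerance = 1e-12)
  expect_error(mae(a, array(1, dim = dim(a))), "constant")
  expect_error(mae(a, a[, , 1:2]), "shapes")
})

test_that("AHA segmentation partitions the myocardium into equiangular sectors", {
  # synthetic annulus on a 64x64 grid
  N <- 64
  rr <- matrix(1:N, N, N); cc <- t(rr)
  ctr <- c(33, 31)
  rad <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  myo <- rad >= 8 & rad <= 14
  rvp <- c(33, 10)
  labs <- aha_segments(myo, lv_center = ctr, rv_insertion = rvp)
  # partition: every myocardial pixel labeled exactly once, nothing outside
  expect_true(all(labs[myo] >= 1 & labs[myo] <= 6))
  expect_true(all(labs[!myo] == 0))
  # brute-force per-pixel angle oracle
  ang0 <- atan2(rvp[1] - ctr[1], rvp[2] - ctr[2])
  idx <- which(myo, arr.ind = TRUE)
  rel <- (atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2]) - ang0) %% (2 * pi)
  want <- pmin(floor(rel / (pi / 3)) + 1, 6)
  expect_equal(labs[idx], as.integer(want))
  # angular spans are equal (60 degrees each)
  spans <- vapply(1:6, function(s) {
    a <- sort(rel[want == s])
    diff(range(a))
  }, numeric(1))
  expect_true(all(abs(spans - pi / 3) < 0.1))
  # apical level uses 4 sectors
  labs4 <- aha_segments(myo, lv_center = ctr, rv_insertion = rvp,
                        slice_level = "apical")
  expect_equal(sort(unique(labs4[myo])), 1:4)
  # uniform intensity -> equal segment means
  ser <- array(2, dim = c(N, N, 9))
  cur <- segment_curves(ser, labs)
  expect_true(all(abs(cur$mean - 2) < 1e-12))
  expect_error(aha_segments(matrix(FALSE, 8, 8), lv_center = c(4, 4),
                            rv_insertion = c(4, 1)), "empty")
})

test_that("evaluation report selects peak-enhancement key frames and covers the schema", {
  ph <- tiny_phantom()
  recons <- list(truth = ph$truth_series, reference = ph$ref_series)
  rep <- evaluate_reconstructions(recons, ph, co_registered = "reference")
  peaks <- vapply(1:3, function(lab) {
    which.max(apply(ph$truth_series, 3, function(z) mean(z[ph$masks == lab])))
  }, integer(1))
  expect_equal(as.integer(rep$key_frames), peaks)
  # one sharpness value per (method, key frame); one CoV per (method, segment)
  expect_equal(nrow(rep$sharpness), 2 * 3)
  expect_equal(nrow(rep$cov), 2 * 6)
  # the ground truth itself scores (near) zero MAE
  expect_lt(rep$mae$value[rep$mae$method == "truth"], 1e-12)
  # the reference series compared in its own motion state also scores zero
  expect_lt(rep$mae$value[rep$mae$method == "reference"], 1e-12)
})
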