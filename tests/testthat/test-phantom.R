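test_that("gamma-variate curve has the analytic onset, peak and continuity", {
  t0 <- 4; alpha <- 3; beta <- 1.5; A <- 0.8; base <- 0.2
  expect_equal(gamma_variate(t0, t0, alpha, beta, A, base), base)
  # normalization forces the peak value baseline + amplitude at t0 + alpha*beta
  expect_equal(gamma_variate(t0 + alpha * beta, t0, alpha, beta, A, base),
               base + A, tolerance = 1e-12)
  # brute-force grid search: maximum within one grid step of the analytic peak
  tt <- seq(0, 30, by = 0.01)
  v <- gamma_variate(tt, t0, alpha, beta, A, base)
  expect_lt(abs(tt[which.max(v)] - (t0 + alpha * beta)), 0.011)
  # continuity at onset
  eps <- 1e-9
  expect_lt(abs(gamma_variate(t0 + eps, t0, alpha, beta, A, base) - base), 1e-6)
  expect_error(gamma_variate(1, 0, -1, 1), "alpha")
  expect_error(gamma_variate(1, 0, 1, 0), "alpha|beta")
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(matrix_size = 16), "matrix_size")
  expect_error(phantom_spec(n_frames = 4), "n_frames")
  expect_error(phantom_spec(noise_fraction = -1), "noise_fraction")
  expect_error(phantom_spec(resp_freq_hz = 0.7), "resp_freq_hz")
  tp <- default_tissue_params <- formals(phantom_spec)$tissue_params
  bad <- eval(tp)
  bad$lv$t0 <- 1  # LV before RV
  expect_error(phantom_spec(tissue_params = bad), "onsets")
})

test_that("phantom is deterministic and enhances RV, then LV, then myocardium", {
  ph <- tiny_phantom()
  ph2 <- make_phantom(ph$spec)
  expect_identical(ph$truth_series, ph2$truth_series)
  ph3 <- make_phantom(phantom_spec(matrix_size = 48, n_frames = 16, n_coils = 3,
                                   spokes_per_frame = 13, samples_per_spoke = 96,
                                   motion_amplitude_px = 4, noise_fraction = 0.02,
                                   seed = 8))
  expect_false(identical(ph$truth_series, ph3$truth_series))

  peaks <- vapply(1:3, function(lab) {
    which.max(apply(ph$truth_series, 3, function(z) mean(z[ph$masks == lab])))
  }, integer(1))
  expect_lt(peaks[1], peaks[2])  # RV before LV
  expect_lt(peaks[2], peaks[3])  # LV before myocardium

  expect_true(all(is.finite(ph$truth_series)))
  expect_true(all(ph$truth_series >= 0))
  expect_true(all(table(factor(ph$masks, levels = 0:5)) > 0))
})

test_that("motionless phantom frames differ only by contrast (Casorati rank = tissue curves)", {
  ph0 <- tiny_phantom_still()
  expect_true(all(ph0$motion$forward == 0))
  s <- svd(matrix(ph0$truth_series, 48 * 48, 16), nu = 0, nv = 0)$d
  # Casorati rank equals the rank of the tissue time-course matrix
  # (<= number of tissues; tissues whose enhancement has not started in
  # the simulated window collapse onto the constant course)
  curve_rank <- qr(ph0$tissue_curves)$rank
  expect_lte(curve_rank, 5)
  expect_equal(sum(s > 1e-8 * s[1]), curve_rank)
})

test_that("coil maps are smooth, positive in RSS, and reduce to identity for one coil", {
  one <- simulate_coils(1, 32)
  expect_equal(as.vector(one[, , 1]), rep(1 + 0i, 32 * 32))
  maps <- simulate_coils(6, 48)
  rss <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
  expect_true(all(rss > 0))
  expect_equal(max(rss), 1)
  # smoothness: largest finite-difference gradient well below the map scale
  for (cc in 1:6) {
    m <- abs(maps[, , cc])
    g <- max(abs(diff(m)), abs(t(diff(t(m)))))
    expect_lt(g, 0.05)
  }
})

test_that("k-space sampling matches an independent DFT oracle and the noise contract", {
  ph <- tiny_phantom()
  ks0 <- sample_kspace(ph, noise_fraction = 0)
  # frame 5, coil 2 against a double-loop DFT of the coil-weighted image
  A <- dense_dft_oracle(ks0$traj$coords[, , 5], 48)
  img <- (ph$truth_series[, , 5] + 0i) * ph$coil_maps[, , 2]
  expect_lt(max(Mod(ks0$data[, 2, 5] - A %*% as.vector(img))) / max(Mod(ks0$data)),
            1e-10)

  ks <- sample_kspace(ph, noise_fraction = 0.02, seed = 11)
  dif <- ks$data - ks0$data
  target <- 0.02 * max(Mod(ks0$data)) / sqrt(2)
  expect_lt(abs(stats::sd(Re(dif)) - target) / target, 0.05)
  expect_lt(abs(stats::sd(Im(dif)) - target) / target, 0.05)
  # determinism
  ks2 <- sample_kspace(ph, noise_fraction = 0.02, seed = 11)
  expect_identical(ks$data, ks2$data)
  # frame-count mismatch is a shape error
  bad <- golden_angle_traj(5, 13, 96)
  expect_error(sample_kspace(ph, traj = bad), "frame count")
})

test_that("golden-angle trajectory respects coordinate bounds and spoke angles", {
  tr <- golden_angle_traj(3, 8, 32)
  expect_lte(max(abs(tr$coords)), 0.5)
  ga <- 111.246117975 * pi / 180
  expect_equal(tr$angles[2, 1], ga %% pi, tolerance = 1e-12)
  # continuous indexing: first spoke of frame 2 is global spoke 8
  expect_equal(tr$angles[1, 2], (8 * ga) %% pi, tolerance = 1e-12)
  dcf <- radial_dcf(tr)
  expect_equal(mean(dcf[, 1]), 1)
  expect_true(all(dcf > 0))
})
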