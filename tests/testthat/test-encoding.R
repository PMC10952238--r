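test_that("nonuniform DFT matches the double-loop oracle and the impulse identity", {
  N <- 16
  img <- matrix(rand_cplx(N * N, seed = 2), N, N)
  set.seed(21)
  coords <- cbind(stats::runif(100, -0.5, 0.4999), stats::runif(100, -0.5, 0.4999))
  got <- nufft_forward(img, coords)
  want <- dense_dft_oracle(coords, N) %*% as.vector(img)
  expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-6)

  imp <- matrix(0i, N, N)
  imp[floor(N / 2) + 1, floor(N / 2) + 1] <- 1
  expect_equal(Mod(nufft_forward(imp, coords)), rep(1, 100), tolerance = 1e-12)

  expect_equal(nufft_forward(matrix(0i, N, N), coords), rep(0i, 100))
  expect_error(nufft_forward(img, coords * 2), "trajectory error")
})

test_that("forward and adjoint NUFFT form an exact adjoint pair", {
  N <- 16
  img <- matrix(rand_cplx(N * N, seed = 3), N, N)
  set.seed(31)
  coords <- cbind(stats::runif(80, -0.5, 0.4999), stats::runif(80, -0.5, 0.4999))
  y <- rand_cplx(80, seed = 4)
  lhs <- sum(Conj(nufft_forward(img, coords)) * y)
  rhs <- sum(Conj(img) * nufft_adjoint(y, coords, N))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
  expect_equal(nufft_adjoint(rep(0i, 80), coords, N), matrix(0i, N, N))
})

test_that("density-compensated gridding of a point object peaks at the object", {
  N <- 32
  # fully sampled radial set
  tr <- golden_angle_traj(1, 60, 2 * N)
  obj <- matrix(0i, N, N); obj[20, 11] <- 1
  k <- nufft_forward(obj, tr$coords[, , 1])
  img <- nufft_adjoint(k, tr$coords[, , 1], N, dcf = radial_dcf(tr)[, 1])
  expect_equal(as.vector(which(Mod(img) == max(Mod(img)), arr.ind = TRUE)),
               c(20, 11))
})

test_that("coil operator and its adjoint satisfy the diagonal-operator identities", {
  N <- 12
  maps <- simulate_coils(4, N)
  x <- matrix(rand_cplx(N * N, seed = 5), N, N)
  y <- array(rand_cplx(N * N * 4, seed = 6), dim = c(N, N, 4))
  lhs <- sum(Conj(apply_coils(x, maps)) * y)
  rhs <- sum(Conj(x) * combine_coils(y, maps))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-12)
  # C^H C is the diagonal sum of squared magnitudes
  chc <- combine_coils(apply_coils(x, maps), maps)
  expect_equal(chc, apply(abs(maps)^2, c(1, 2), sum) * x, tolerance = 1e-12)
  # single unit coil is the identity
  unit <- array(1 + 0i, dim = c(N, N, 1))
  expect_equal(apply_coils(x, unit)[, , 1], x)
  expect_equal(combine_coils(array(x, dim = c(N, N, 1)), unit), x)
  expect_error(apply_coils(matrix(0i, 5, 5), maps), "shape")
})

test_that("full encoding model equals the brute-force dense operator on a small instance", {
  # 8x8 image, 2 frames, 1 coil, rank-2 subspace, nonzero motion
  N <- 8
  tr <- golden_angle_traj(2, 4, 16)
  set.seed(40)
  maps <- array(exp(-((matrix(1:N, N, N) - 4)^2 + (t(matrix(1:N, N, N)) - 5)^2) / 40) *
                  exp(1i * 0.1 * matrix(1:N, N, N)), dim = c(N, N, 1))
  fields <- array(0, dim = c(N, N, 2, 2))
  fields[, , 1, 2] <- 0.8; fields[, , 2, 2] <- -0.5
  motion <- motion_field_series(fields)
  Ur <- qr.Q(qr(matrix(stats::rnorm(4), 2, 2)))
  plan <- encoding_plan(tr, N, motion)

  # dense oracle: per frame  A_f = DFT_f %*% diag(maps) %*% W_f
  E_dense <- matrix(0i, 2 * 4 * 16, 2 * N * N)
  for (f in 1:2) {
    Af <- dense_dft_oracle(tr$coords[, , f], N) %*%
      diag(as.vector(maps[, , 1])) %*% dense_warp_oracle(fields[, , , f])
    rows <- (f - 1) * 64 + 1:64
    for (j in 1:2) E_dense[rows, (j - 1) * 64 + 1:64] <- Ur[f, j] * Af
  }
  # assemble the model column by column through forward_model
  E_model <- matrix(0i, 2 * 64, 2 * 64)
  for (col in seq_len(2 * 64)) {
    y <- array(0i, dim = c(N, N, 2)); y[col] <- 1
    E_model[, col] <- as.vector(forward_model(y, Ur, maps, plan))
  }
  expect_lt(max(Mod(E_model - E_dense)), 1e-8)

  # adjoint equals the conjugate transpose of the dense operator
  Eh_model <- matrix(0i, 2 * 64, 2 * 64)
  for (col in seq_len(2 * 64)) {
    k <- array(0i, dim = c(64, 1, 2)); k[col] <- 1
    Eh_model[, col] <- as.vector(adjoint_model(k, Ur, maps, plan))
  }
  expect_lt(max(Mod(Eh_model - Conj(t(E_dense)))), 1e-8)
})

test_that("encoding model is linear and passes the adjoint dot-product test", {
  ph <- tiny_phantom()
  ks <- tiny_kspace()
  sub <- estimate_subspace(align_series(ph$truth_series, ph$motion),
                           roi = ph$roi, rank = 3)
  plan <- encoding_plan(ks$traj, 48, ph$motion)
  y1 <- array(rand_cplx(48 * 48 * 3, seed = 8), dim = c(48, 48, 3))
  y2 <- array(rand_cplx(48 * 48 * 3, seed = 9), dim = c(48, 48, 3))
  k1 <- forward_model(y1, sub, ph$coil_maps, plan)
  k2 <- forward_model(y2, sub, ph$coil_maps, plan)
  k12 <- forward_model(2 * y1 + (1 - 3i) * y2, sub, ph$coil_maps, plan)
  expect_lt(max(Mod(k12 - 2 * k1 - (1 - 3i) * k2)) / max(Mod(k12)), 1e-12)

  kr <- array(rand_cplx(length(k1), seed = 10), dim = dim(k1))
  lhs <- sum(Conj(k1) * kr)
  rhs <- sum(Conj(y1) * adjoint_model(kr, sub, ph$coil_maps, plan))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
  expect_equal(adjoint_model(array(0i, dim = dim(k1)), sub, ph$coil_maps, plan),
               array(0i, dim = c(48, 48, 3)))
})

test_that("the generative model is self-consistent on the noiseless phantom", {
  # motionless: forward model of the truth reproduces k-space exactly
  ph0 <- tiny_phantom_still()
  ks0 <- sample_kspace(ph0, noise_fraction = 0)
  plan0 <- encoding_plan(ks0$traj, 48, ph0$motion)
  k <- forward_model(ph0$truth_series + 0i, diag(16), ph0$coil_maps, plan0)
  expect_lt(sqrt(sum(Mod(k - ks0$data)^2) / sum(Mod(ks0$data)^2)), 1e-3)

  # moving: M is applied to the transpose-aligned truth; the mismatch is
  # bounded by the transpose-vs-inverse warp difference
  ph <- tiny_phantom()
  ks <- sample_kspace(ph, noise_fraction = 0)
  plan <- encoding_plan(ks$traj, 48, ph$motion)
  Xal <- align_series(ph$truth_series + 0i, ph$motion)
  km <- forward_model(Xal, diag(16), ph$coil_maps, plan)
  expect_lt(sqrt(sum(Mod(km - ks$data)^2) / sum(Mod(ks$data)^2)), 0.06)
})
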