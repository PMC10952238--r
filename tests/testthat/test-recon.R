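# Build a small single- or multi-frame k-space container directly.
toy_kspace <- function(object, traj, maps) {
  nf <- traj$n_frames
  kd <- array(0i, dim = c(dim(traj$coords)[1], dim(maps)[3], nf))
  for (f in seq_len(nf)) {
    pl <- lrmcperf:::nufft_plan(traj$coords[, , f], nrow(object))
    kd[, , f] <- lrmcperf:::frame_encode(object + 0i, maps, pl)
  }
  structure(list(data = kd, traj = traj, dcf = radial_dcf(traj),
                 noise_fraction = 0, matrix_size = nrow(object)),
            class = "lrmc_kspace")
}

block_object <- function(N = 32) {
  ph <- matrix(0, N, N)
  ph[round(N * 0.30):round(N * 0.70), round(N * 0.25):round(N * 0.78)] <- 1
  ph[round(N * 0.42):round(N * 0.58), round(N * 0.38):round(N * 0.62)] <- 2
  ph
}

test_that("conjugate gradient decreases the quadratic objective monotonically", {
  N <- 16
  tr <- golden_angle_traj(1, 20, 32)
  maps <- simulate_coils(2, N)
  obj <- block_object(16)
  ks <- toy_kspace(obj, tr, maps)
  pl <- lrmcperf:::nufft_plan(tr$coords[, , 1], N)
  A <- function(x) lrmcperf:::frame_encode_adjoint(
    lrmcperf:::frame_encode(x, maps, pl), maps, pl)
  kd <- ks$data[, , 1, drop = FALSE]; dim(kd) <- dim(ks$data)[1:2]
  b <- lrmcperf:::frame_encode_adjoint(kd, maps, pl)
  phi <- vapply(1:8, function(k) {
    x <- lrmcperf:::cg_normal(A, b, iters = k, tol = 0)
    0.5 * Re(sum(Conj(x) * A(x))) - Re(sum(Conj(b) * x))
  }, numeric(1))
  expect_true(all(diff(phi) <= 1e-8 * abs(phi[1])))
  # and the residual norm falls by orders of magnitude overall
  x <- lrmcperf:::cg_normal(A, b, iters = 25, tol = 0)
  res <- attr(x, "residuals")
  expect_lt(res[length(res)], 1e-3 * res[1])
})

test_that("iterative SENSE localizes a point object and recovers extended objects", {
  N <- 32
  tr <- golden_angle_traj(1, 51, 64)  # >= pi/2 * N spokes: dense radial
  maps <- array(1 + 0i, dim = c(N, N, 1))
  # point object: peak lands on the object pixel
  pt <- matrix(0, N, N); pt[20, 11] <- 1
  ksp <- toy_kspace(pt, tr, maps)
  xp <- itsense(ksp, maps, n_iters = 6)
  peak <- which(Mod(xp[, , 1]) == max(Mod(xp[, , 1])), arr.ind = TRUE)
  expect_equal(as.vector(peak), c(20, 11))
  # extended object at CG convergence: < 5% relative error
  obj <- block_object(N)
  ks <- toy_kspace(obj, tr, maps)
  x <- itsense(ks, maps, n_iters = 40, tol = 1e-12)
  expect_lt(sqrt(sum(Mod(x[, , 1] - obj)^2) / sum(obj^2)), 0.05)
  expect_equal(formals(itsense)$n_iters, 6)
})

test_that("L+S separates the series and beats zero-filling on the noisy moving phantom", {
  ph <- tiny_phantom()
  ks <- tiny_kspace()
  # zero k-space maps to zero components
  ks0 <- ks; ks0$data[] <- 0i
  z <- lps(ks0, ph$coil_maps, n_iters = 2)
  expect_true(all(Mod(z$L) == 0) && all(Mod(z$S) == 0))
  expect_equal(formals(lps)$lambda_L, 0.1)
  expect_equal(formals(lps)$lambda_S, 0.1)
  expect_equal(formals(lps)$n_iters, 6)

  fit <- lps(ks, ph$coil_maps)
  zf <- zerofill_recon(ks, ph$coil_maps)
  expect_lt(mae(fit$M, ph$truth_series), mae(zf, ph$truth_series))
})

test_that("patch-tensor denoising preserves exactly low-rank tensors and removes noise", {
  base <- matrix(7, 24, 24)
  y0 <- array(outer(as.vector(base), c(1, 0.6, -0.4)), dim = c(24, 24, 3)) + 0i
  cfg <- patch_config(search_window = 11, threshold_rule = "hard")
  thr <- 3 * 0.5 * sqrt(2) * sqrt(10 * 3)
  expect_lt(max(Mod(hd_prost_denoise(y0, cfg, threshold = thr) - y0)), 1e-8)

  # Monte-Carlo: with complex Gaussian noise the filtered MSE drops in
  # at least 95% of seeded trials
  set.seed(60)
  wins <- 0
  for (t in 1:50) {
    nz <- array(complex(real = stats::rnorm(24 * 24 * 3, sd = 0.5),
                        imaginary = stats::rnorm(24 * 24 * 3, sd = 0.5)),
                dim = c(24, 24, 3))
    y <- y0 + nz
    yd <- hd_prost_denoise(y, cfg, threshold = thr)
    wins <- wins + (mean(Mod(yd - y0)^2) < mean(Mod(y - y0)^2))
  }
  expect_gte(wins, 48)
  expect_error(hd_prost_denoise(y0, patch_config(search_window = 31), 1),
               "search window")
  expect_error(patch_config(patch_size = 4), "odd")
})

test_that("LRMC with degenerate operators reduces to CG-SENSE", {
  N <- 32
  tr <- golden_angle_traj(2, 40, 64)
  maps <- array(1 + 0i, dim = c(N, N, 1))
  obj <- block_object(N)
  ks <- toy_kspace(obj, tr, maps)
  its <- itsense(ks, maps, n_iters = 30, tol = 1e-10)
  rec <- lrmc(ks, maps, identity_motion(N, 2), diag(2),
              admm = admm_config(outer_iters = 10, inner_cg_iters = 3,
                                 lambda_reg = 0, cg_tolerance = 1e-10))
  expect_lt(sqrt(sum(Mod(rec$series - its)^2) / sum(Mod(its)^2)), 0.02)
  expect_lt(sqrt(sum(Mod(rec$series[, , 1] - obj)^2) / sum(obj^2)), 0.05)
  expect_equal(formals(admm_config)$outer_iters, 10)
  expect_equal(formals(admm_config)$inner_cg_iters, 3)
  expect_equal(formals(admm_config)$lambda_reg, 1e-3)
})

test_that("LRMC is co-registered, converges in ADMM, and beats zero-filling", {
  ph <- tiny_phantom()
  ks <- tiny_kspace()
  sub <- estimate_subspace(align_series(ph$truth_series, ph$motion),
                           roi = ph$roi)
  rec0 <- lrmc(ks, ph$coil_maps, ph$motion, sub,
               admm = admm_config(lambda_reg = 0))
  zf <- zerofill_recon(ks, ph$coil_maps)
  expect_lt(mae(rec0$series, ph$ref_series), mae(zf, ph$truth_series))

  rec <- lrmc(ks, ph$coil_maps, ph$motion, sub, admm = admm_config(),
              patch = patch_config(search_window = 15))
  pr <- rec$primal_residuals
  expect_gte(pr[1] / pr[10], 10)
  # co-registration: motion-induced centroid deviation (relative to the
  # contrast-matched motion-free reference) below half a pixel and
  # below the uncorrected itSENSE deviation
  roi_com <- function(X)
    center_of_mass(abs(X)[ph$roi$rows, ph$roi$cols, , drop = FALSE])
  ref_com <- roi_com(ph$ref_series)
  dev_lrmc <- sqrt(mean((roi_com(rec$series) - ref_com)^2))
  its <- itsense(ks, ph$coil_maps)
  dev_its <- sqrt(mean((roi_com(its) - ref_com)^2))
  expect_lt(dev_lrmc, 0.5)
  expect_lt(dev_lrmc, dev_its)
  # determinism
  rec2 <- lrmc(ks, ph$coil_maps, ph$motion, sub, admm = admm_config(),
               patch = patch_config(search_window = 15))
  expect_identical(rec$series, rec2$series)
})

test_that("motion scaling degrades the unregularized LRMC away from the true motion", {
  ph <- tiny_phantom()
  ks <- tiny_kspace()
  sub <- estimate_subspace(align_series(ph$truth_series, ph$motion),
                           roi = ph$roi, rank = 6)
  tab <- motion_error_sweep(ks, ph$coil_maps, ph$motion, sub, c(0, 1, 2), ph,
                            admm = admm_config(outer_iters = 4))
  expect_equal(tab$scale, c(0, 1, 2))
  expect_lt(tab$mae[2], tab$mae[1])
  expect_lt(tab$mae[2], tab$mae[3])
  expect_error(motion_error_sweep(ks, ph$coil_maps, ph$motion, sub, c(0, 2), ph),
               "scales")
})
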