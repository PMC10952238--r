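# MR encoding operators: nonuniform Fourier transform on the radial
# trajectory (F / F^H), coil sensitivities (C / C^H), and the full
# motion-corrected subspace model E = A F C M U_r with exact adjoint
# E^H = U_r^H M^H C^H F^H A^H.
#
# Conventions (fixed so that every oracle is reproducible):
#  * images are complex [N, N] matrices indexed (row, col); the image
#    origin (k-space phase reference) is at pixel (floor(N/2)+1,
#    floor(N/2)+1), i.e. 0-based index floor(N/2) on each axis;
#  * k-space coordinates are in cycles/FOV, each axis in [-0.5, 0.5);
#  * the transform is the plain (unscaled) nonuniform DFT
#      F(k) = sum_{r,c} I[r,c] exp(-2i pi (ky (r - r0) + kx (c - c0)))
#    and the adjoint is its conjugate transpose (no density weighting).

#' Exact nonuniform discrete Fourier transform (type 2)
#'
#' Evaluates the unscaled DFT of a 2D image at arbitrary k-space
#' positions.  The implementation factorizes the 2D phase into the
#' product of two per-axis phase matrices and evaluates the sum as BLAS
#' matrix products, so it is exact (no gridding/interpolation error)
#' while remaining fast for the matrix sizes used in 2D perfusion
#' imaging.
#'
#' @param image complex (or numeric) matrix `[N, N]`.
#' @param coords matrix `[n_samples, 2]` of (kx, ky) in cycles/FOV, each
#'   within \[-0.5, 0.5\].
#' @return complex vector of `n_samples` k-space values.
#' @seealso [nufft_adjoint()]
#' @export
nufft_forward <- function(image, coords) {
  p <- nufft_plan(coords, nrow(image))
  nufft_apply(p, image)
}

#' Adjoint nonuniform DFT (type 1)
#'
#' Exact Hermitian adjoint of [nufft_forward()]; with density
#' compensation weights `dcf` supplied it returns the weighted gridding
#' image `F^H diag(dcf) k` instead (used for zero-filled images only).
#'
#' @param samples complex vector of k-space values.
#' @param coords as in [nufft_forward()].
#' @param matrix_size image side length N.
#' @param dcf optional per-sample weights.
#' @return complex `[N, N]` image.
#' @export
nufft_adjoint <- function(samples, coords, matrix_size, dcf = NULL) {
  p <- nufft_plan(coords, matrix_size)
  if (!is.null(dcf)) samples <- samples * dcf
  nufft_apply_adjoint(p, samples)
}

# Precomputed per-trajectory phase matrices.  Ex[s, c] = exp(-2i pi
# kx_s (c - c0)), Ey[s, r] likewise along rows.  Reused across coils,
# frames and solver iterations.
nufft_plan <- function(coords, matrix_size) {
  coords <- as.matrix(coords)
  if (max(abs(coords)) > 0.5 + 1e-12)
    stop("trajectory error: coordinates must lie within [-0.5, 0.5] cycles/FOV")
  N <- as.integer(matrix_size)
  c0 <- floor(N / 2)
  pos <- (0:(N - 1)) - c0
  Ex <- exp(-2i * pi * outer(coords[, 1], pos))
  Ey <- exp(-2i * pi * outer(coords[, 2], pos))
  list(Ex = Ex, Ey = Ey, N = N, n_samples = nrow(coords))
}

nufft_apply <- function(plan, image) {
  if (!is.complex(image)) image <- image + 0i
  # F[s] = sum_r Ey[s, r] * (image %*% t(Ex))[r, s]
  V <- image %*% t(plan$Ex)            # [N, n_samples]
  colSums(t(plan$Ey) * V)
}

nufft_apply_adjoint <- function(plan, samples) {
  if (!is.complex(samples)) samples <- samples + 0i
  # I[r, c] = sum_s conj(Ey[s, r]) k_s conj(Ex[s, c])
  crossprod(Conj(plan$Ey), samples * Conj(plan$Ex))
}

#' Apply coil sensitivities and their adjoint
#'
#' `apply_coils` multiplies an image elementwise by each coil map,
#' returning per-coil images; `combine_coils` is the exact adjoint,
#' summing the conjugate-weighted coil images.
#'
#' @param image complex `[N, N]` matrix.
#' @param maps coil maps, complex array `[N, N, n_coils]`.
#' @param coil_images complex array `[N, N, n_coils]`.
#' @return `apply_coils`: array `[N, N, n_coils]`; `combine_coils`:
#'   `[N, N]` matrix.
#' @export
apply_coils <- function(image, maps) {
  d <- dim(maps)
  if (!all(dim(image) == d[1:2]))
    stop("shape mismatch between image and coil maps")
  out <- array(0i, dim = d)
  for (cc in seq_len(d[3])) out[, , cc] <- maps[, , cc] * image
  out
}

#' @rdname apply_coils
#' @export
combine_coils <- function(coil_images, maps) {
  d <- dim(maps)
  if (!all(dim(coil_images) == d))
    stop("shape mismatch between coil images and coil maps")
  out <- matrix(0i, d[1], d[2])
  for (cc in seq_len(d[3])) out <- out + Conj(maps[, , cc]) * coil_images[, , cc]
  out
}

#' Precompute an encoding plan for a trajectory
#'
#' Builds and caches the per-frame NUFFT phase matrices and (when a
#' motion-field series is given) the per-frame sparse warp matrices, so
#' repeated applications of the forward/adjoint model inside iterative
#' solvers do not rebuild them.
#'
#' @param traj [golden_angle_traj()] object.
#' @param matrix_size image side length N.
#' @param motion optional `lrmc_motion` object (see
#'   [motion_field_series()]); identity motion when `NULL`.
#' @return an `lrmc_encoding_plan` list.
#' @export
encoding_plan <- function(traj, matrix_size, motion = NULL) {
  stopifnot(inherits(traj, "lrmc_traj"))
  plans <- lapply(seq_len(traj$n_frames), function(f)
    nufft_plan(traj$coords[, , f, drop = TRUE], matrix_size))
  warps <- NULL
  if (!is.null(motion)) {
    if (dim(motion$forward)[4] != traj$n_frames)
      stop("shape error: motion frame count does not match trajectory")
    warps <- lapply(seq_len(traj$n_frames), function(f)
      warp_matrix(motion$forward[, , , f]))
  }
  structure(list(traj = traj, N = as.integer(matrix_size),
                 nufft = plans, warps = warps),
            class = "lrmc_encoding_plan")
}

# Frame-wise SENSE encoding (A F C) of one image: returns [n_samples,
# n_coils].  Internal building block for every reconstruction.
frame_encode <- function(image, maps, plan_f) {
  n_coils <- dim(maps)[3]
  out <- matrix(0i, plan_f$n_samples, n_coils)
  for (cc in seq_len(n_coils))
    out[, cc] <- nufft_apply(plan_f, maps[, , cc] * image)
  out
}

frame_encode_adjoint <- function(ksamp, maps, plan_f) {
  n_coils <- dim(maps)[3]
  out <- matrix(0i, dim(maps)[1], dim(maps)[2])
  for (cc in seq_len(n_coils))
    out <- out + Conj(maps[, , cc]) * nufft_apply_adjoint(plan_f, ksamp[, cc])
  out
}

#' Full LRMC forward model E = A F C M U_r and its adjoint
#'
#' `forward_model` maps the r motion-corrected singular images y to
#' multi-coil radial k-space: the temporal subspace U_r expands y to the
#' frame series, each frame is warped from the reference motion state to
#' its own state (M), multiplied by the coil maps (C) and evaluated on
#' that frame's spokes (A F).  `adjoint_model` is the exact Hermitian
#' adjoint U_r^H M^H C^H F^H A^H, with M^H the matrix transpose of the
#' bilinear warp.
#'
#' @param y complex array `[N, N, r]` of singular images.
#' @param Ur temporal basis matrix `[n_frames, r]` (a
#'   [estimate_subspace()] object or plain matrix).
#' @param maps coil maps `[N, N, n_coils]`.
#' @param plan [encoding_plan()] with warps precomputed (or `NULL`
#'   warps for identity motion).
#' @param kdata complex array `[n_samples, n_coils, n_frames]`.
#' @return `forward_model`: k-space array `[n_samples, n_coils,
#'   n_frames]`; `adjoint_model`: singular-image array `[N, N, r]`.
#' @export
forward_model <- function(y, Ur, maps, plan) {
  Ur <- subspace_basis(Ur)
  N <- plan$N
  r <- dim(y)[3]
  n_frames <- plan$traj$n_frames
  if (nrow(Ur) != n_frames || ncol(Ur) != r)
    stop("shape error: subspace basis does not match y / trajectory")
  n_coils <- dim(maps)[3]
  # expand: X[, t] = sum_j Ur[t, j] y_j (pixelwise)
  Y <- matrix(y, N * N, r)
  X <- Y %*% t(Ur)                               # [N^2, n_frames]
  kout <- array(0i, dim = c(plan$nufft[[1]]$n_samples, n_coils, n_frames))
  for (f in seq_len(n_frames)) {
    xf <- matrix(X[, f], N, N)
    if (!is.null(plan$warps)) xf <- warp_apply_sparse(plan$warps[[f]], xf)
    kout[, , f] <- frame_encode(xf, maps, plan$nufft[[f]])
  }
  kout
}

#' @rdname forward_model
#' @export
adjoint_model <- function(kdata, Ur, maps, plan) {
  Ur <- subspace_basis(Ur)
  N <- plan$N
  n_frames <- plan$traj$n_frames
  if (dim(kdata)[3] != n_frames)
    stop("shape error: k-space frame count does not match trajectory")
  X <- matrix(0i, N * N, n_frames)
  for (f in seq_len(n_frames)) {
    kd <- kdata[, , f, drop = FALSE]
    dim(kd) <- dim(kdata)[1:2]
    img <- frame_encode_adjoint(kd, maps, plan$nufft[[f]])
    if (!is.null(plan$warps))
      img <- warp_apply_sparse(plan$warps[[f]], img, transpose = TRUE)
    X[, f] <- img
  }
  Y <- X %*% Conj(Ur)                             # U_r^H pixelwise
  array(Y, dim = c(N, N, ncol(Ur)))
}

# Accept either a plain basis matrix or an lrmc_subspace object.
subspace_basis <- function(Ur) {
  if (inherits(Ur, "lrmc_subspace")) Ur$Ur else as.matrix(Ur)
}
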