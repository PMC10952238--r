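# Nonrigid warp operators M / M^H.
#
# A displacement field is an array [N, N, 2]: component 1 is the row
# displacement, component 2 the column displacement, both in pixels.
# warp(I, d)(r, c) = I(r + d1(r, c), c + d2(r, c)) by bilinear
# interpolation, with samples outside the FOV set to zero.  This "pull"
# convention means the field passed to the forward operator maps
# reference-grid coordinates into the coordinates of the target motion
# state.  warp_transpose is the exact matrix transpose of that linear
# map (not the inverse warp), which is what the Hermitian adjoint of
# the encoding model requires.

#' Build the sparse matrix of a bilinear warp
#'
#' Assembles the `[N^2, N^2]` sparse matrix W such that
#' `vec(warp(I, field)) = W vec(I)`.  Each row has at most four nonzero
#' bilinear weights.  Used internally to apply warps and their exact
#' transposes; exposed for operator-level testing.
#'
#' @param field displacement array `[N, N, 2]` (rows, cols, in pixels).
#' @return a `dgCMatrix`.
#' @export
warp_matrix <- function(field) {
  d <- dim(field)
  if (length(d) != 3 || d[3] != 2) stop("field must be [N, N, 2]")
  if (!all(is.finite(field))) stop("non-finite field values")
  N <- d[1]; Mc <- d[2]
  rr <- matrix(seq_len(N), N, Mc)
  cc <- matrix(seq_len(Mc), N, Mc, byrow = TRUE)
  sr <- as.vector(rr + field[, , 1])
  sc <- as.vector(cc + field[, , 2])
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0;   fc <- sc - c0
  out_idx <- seq_len(N * Mc)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (dr in 0:1) for (dc in 0:1) {
    rn <- r0 + dr; cn <- c0 + dc
    w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    ok <- rn >= 1 & rn <= N & cn >= 1 & cn <= Mc & w > 0
    ii <- c(ii, out_idx[ok])
    jj <- c(jj, (cn[ok] - 1L) * N + rn[ok])
    xx <- c(xx, w[ok])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N * Mc, N * Mc))
}

# Apply a prebuilt sparse warp (or its transpose) to a complex image.
warp_apply_sparse <- function(W, image, transpose = FALSE) {
  d <- dim(image)
  v <- cbind(Re(image), Im(image))
  dim(v) <- c(length(image), 2)
  out <- if (transpose) Matrix::crossprod(W, v) else W %*% v
  out <- as.matrix(out)
  matrix(complex(real = out[, 1], imaginary = out[, 2]), d[1], d[2])
}

#' Warp an image by a displacement field
#'
#' Bilinear resampling at displaced coordinates (`warp`), and the exact
#' matrix transpose of that linear map (`warp_transpose`), which serves
#' as the Hermitian adjoint M^H in the reconstruction model.  Both act
#' identically on the real and imaginary parts.
#'
#' @param image complex or numeric `[N, N]` matrix.
#' @param field displacement array `[N, N, 2]` in pixels (row
#'   displacement first).
#' @return matrix of the same shape and mode as `image`.
#' @export
warp <- function(image, field) {
  out <- warp_apply_sparse(warp_matrix(field), image)
  if (!is.complex(image)) Re(out) else out
}

#' @rdname warp
#' @export
warp_transpose <- function(image, field) {
  out <- warp_apply_sparse(warp_matrix(field), image, transpose = TRUE)
  if (!is.complex(image)) Re(out) else out
}

#' Container for a beat-to-beat motion-field series
#'
#' Holds per-frame forward fields (reference state -> frame state, the
#' operator M of the forward model) and backward fields (frame ->
#' reference), both as `[N, N, 2, n_frames]` arrays in pixels.
#'
#' @param forward,backward displacement arrays `[N, N, 2, n_frames]`.
#' @param reference_frame index of the reference motion state, or `NA`
#'   for a synthetic reference.
#' @return an object of class `lrmc_motion`.
#' @export
motion_field_series <- function(forward, backward = NULL, reference_frame = NA) {
  d <- dim(forward)
  if (length(d) != 4 || d[3] != 2) stop("forward fields must be [N, N, 2, n_frames]")
  if (is.null(backward)) {
    backward <- array(0, dim = d)
    for (f in seq_len(d[4]))
      backward[, , , f] <- invert_field(forward[, , , f])
  }
  if (!all(dim(backward) == d)) stop("forward/backward field shapes differ")
  structure(list(forward = forward, backward = backward,
                 reference_frame = reference_frame,
                 n_frames = d[4]),
            class = "lrmc_motion")
}

#' Identity motion for a given geometry
#' @param matrix_size image side length.
#' @param n_frames number of frames.
#' @return `lrmc_motion` with all-zero fields.
#' @export
identity_motion <- function(matrix_size, n_frames) {
  z <- array(0, dim = c(matrix_size, matrix_size, 2, n_frames))
  motion_field_series(z, z)
}

#' Scale a motion-field series
#'
#' Multiplies every displacement vector by `factor`; 0 gives identity
#' motion, 2 doubles the motion.  Used to inject controlled motion-model
#' errors into the reconstruction (motion-error sweep).
#'
#' @param fields an `lrmc_motion` object.
#' @param factor nonnegative scalar.
#' @return scaled `lrmc_motion`.
#' @export
scale_motion <- function(fields, factor) {
  stopifnot(inherits(fields, "lrmc_motion"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 0)
    stop("factor must be a nonnegative scalar")
  motion_field_series(fields$forward * factor, fields$backward * factor,
                      fields$reference_frame)
}

# Fixed-point inversion of a displacement field: find g with
# g(x) = -d(x + g(x)).  Adequate for the smooth, moderate-amplitude
# respiratory fields used here; the residual composition error is
# reported by compose_error().
invert_field <- function(field, iters = 20, tol = 1e-3) {
  g <- -field
  for (it in seq_len(iters)) {
    d1 <- warp(field[, , 1], g)
    d2 <- warp(field[, , 2], g)
    gn <- array(c(-d1, -d2), dim = dim(field))
    if (max(abs(gn - g)) < tol) { g <- gn; break }
    g <- gn
  }
  g
}

#' Composition endpoint error of forward/backward fields
#'
#' Median magnitude (in pixels) of the composition forward-then-backward
#' over the image grid; a diagnostic of how close the stored field pair
#' is to a true inverse pair.
#' @param motion `lrmc_motion` object.
#' @return numeric vector, one value per frame.
#' @export
compose_error <- function(motion) {
  stopifnot(inherits(motion, "lrmc_motion"))
  vapply(seq_len(motion$n_frames), function(f) {
    fw <- motion$forward[, , , f]; bw <- motion$backward[, , , f]
    e1 <- bw[, , 1] + warp(fw[, , 1], bw)
    e2 <- bw[, , 2] + warp(fw[, , 2], bw)
    stats::median(sqrt(e1^2 + e2^2))
  }, numeric(1))
}
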