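# Temporal low-rank subspace estimation from the motion-aligned
# auxiliary series.

#' Align an image series into the reference motion state
#'
#' Applies the operator-consistent alignment M^H: frame t is replaced
#' by `warp_transpose` of itself with that frame's forward field.  This
#' is exactly the per-frame action of the model adjoint, so the
#' subspace estimated from the aligned series matches the subspace the
#' reconstruction operates in.
#'
#' @param X image series `[N, N, n_frames]` (real or complex).
#' @param motion `lrmc_motion` object.
#' @return aligned series, same shape.
#' @export
align_series <- function(X, motion) {
  stopifnot(inherits(motion, "lrmc_motion"))
  d <- dim(X)
  if (motion$n_frames != d[3]) stop("shape mismatch: motion frames != series frames")
  out <- X
  for (f in seq_len(d[3]))
    out[, , f] <- warp_transpose(X[, , f], motion$forward[, , , f])
  out
}

#' Estimate the temporal contrast subspace
#'
#' Singular value decomposition of the Casorati matrix (pixels x
#' frames) of the motion-aligned series, restricted to a rectangular
#' region of interest around the heart.  The rank r is the smallest
#' integer whose cumulative squared singular values reach
#' `energy_threshold` of the total energy; the right singular vectors
#' truncated to r form the temporal basis U_r, which is applied
#' globally in reconstruction.
#'
#' @param X image series `[N, N, n_frames]` (aligned; see
#'   [align_series()]).
#' @param energy_threshold fraction of squared-singular-value energy to
#'   capture (default 0.96).
#' @param roi `NULL` for the whole image, or a list with integer
#'   vectors `rows` and `cols` (e.g. the phantom's heart bounding box).
#' @param rank optional fixed rank override; when supplied the energy
#'   threshold is ignored.
#' @return an `lrmc_subspace` object: `Ur` (`[n_frames, r]`,
#'   orthonormal columns), `singular_values` (full spectrum of the ROI
#'   Casorati matrix), `rank`, `energy_threshold`, `roi`.
#' @export
estimate_subspace <- function(X, energy_threshold = 0.96, roi = NULL,
                              rank = NULL) {
  if (!(energy_threshold > 0 && energy_threshold <= 1))
    stop("energy_threshold must be in (0, 1]")
  d <- dim(X)
  Xc <- matrix(X, d[1] * d[2], d[3])
  if (!is.null(roi)) {
    if (min(roi$rows) < 1 || max(roi$rows) > d[1] ||
        min(roi$cols) < 1 || max(roi$cols) > d[2])
      stop("roi outside image")
    sel <- as.vector(outer(roi$rows, (roi$cols - 1) * d[1], "+"))
    Xc <- Xc[sel, , drop = FALSE]
  }
  sv <- svd(Xc, nu = 0)
  s2 <- sv$d^2
  if (is.null(rank)) {
    cum <- cumsum(s2) / sum(s2)
    rank <- which(cum >= energy_threshold)[1]
  }
  rank <- min(as.integer(rank), d[3])
  structure(list(Ur = sv$v[, seq_len(rank), drop = FALSE],
                 singular_values = sv$d,
                 rank = rank, energy_threshold = energy_threshold,
                 roi = roi),
            class = "lrmc_subspace")
}

#' Project a frame series into the subspace / expand singular images
#'
#' `project_series` applies U_r^H pixelwise along the frame axis,
#' compressing an `[N, N, n_frames]` series to the `[N, N, r]` singular
#' images; `expand_series` applies U_r, reconstructing the frame
#' series.  `expand(project(x))` is the frame-wise best rank-r
#' approximation of x.
#'
#' @param X series `[N, N, n_frames]` (real or complex).
#' @param Y singular images `[N, N, r]`.
#' @param sub `lrmc_subspace` (or a plain `[n_frames, r]` basis).
#' @return array (complex if the input is complex).
#' @export
project_series <- function(X, sub) {
  Ur <- subspace_basis(sub)
  d <- dim(X)
  if (d[3] != nrow(Ur)) stop("rank mismatch: series frames != basis rows")
  Y <- matrix(X, d[1] * d[2], d[3]) %*% Conj(Ur)
  out <- array(Y, dim = c(d[1], d[2], ncol(Ur)))
  if (!is.complex(X)) out <- Re(out)
  out
}

#' @rdname project_series
#' @export
expand_series <- function(Y, sub) {
  Ur <- subspace_basis(sub)
  d <- dim(Y)
  if (d[3] != ncol(Ur)) stop("rank mismatch: singular images != basis columns")
  X <- matrix(Y, d[1] * d[2], d[3]) %*% t(Ur)
  out <- array(X, dim = c(d[1], d[2], nrow(Ur)))
  if (!is.complex(Y)) out <- Re(out)
  out
}
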