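#' Golden-angle radial trajectory
#'
#' Builds the k-space sampling pattern of a 2D golden-angle radial
#' acquisition: every spoke advances the azimuthal angle by the golden
#' angle (111.246117975 degrees modulo 180), and each frame (one image
#' per heartbeat) collects `spokes_per_frame` consecutive spokes.  With
#' `continuous_across_frames = TRUE` the spoke counter runs through the
#' whole scan, so frame f starts at global spoke index
#' `(f-1) * spokes_per_frame`; otherwise every frame reuses spokes
#' `0 .. spokes_per_frame - 1`.
#'
#' Coordinates are in cycles/FOV, each axis within \[-0.5, 0.5).  Sample
#' j (1-based) of a spoke sits at radius `(j - 1 - ns/2) / ns` along the
#' spoke direction, where `ns = samples_per_spoke`, so the readout spans
#' the full diameter of k-space with DC included.
#'
#' @param n_frames number of frames (heartbeats).
#' @param spokes_per_frame radial spokes acquired per frame.
#' @param samples_per_spoke readout samples per spoke (typically twice
#'   the matrix size).
#' @param golden_angle_deg angular increment in degrees.
#' @param continuous_across_frames logical; advance the spoke index
#'   continuously over the whole scan (default) or restart per frame.
#' @return An object of class `lrmc_traj`: a list with the arguments
#'   plus `coords`, an array `[n_samples, 2, n_frames]` holding (kx, ky)
#'   per within-frame sample (kx varies along image columns, ky along
#'   rows), and `angles`, the spoke angles per frame in radians.
#' @examples
#' tr <- golden_angle_traj(n_frames = 4, spokes_per_frame = 8,
#'                         samples_per_spoke = 32)
#' range(tr$coords)
#' @export
golden_angle_traj <- function(n_frames, spokes_per_frame, samples_per_spoke,
                              golden_angle_deg = 111.246117975,
                              continuous_across_frames = TRUE) {
  stopifnot(n_frames >= 1, spokes_per_frame >= 1, samples_per_spoke >= 2)
  ns <- samples_per_spoke
  radius <- ((seq_len(ns) - 1) - floor(ns / 2)) / ns   # in [-0.5, 0.5)
  n_samp <- ns * spokes_per_frame
  coords <- array(0, dim = c(n_samp, 2, n_frames))
  angles <- matrix(0, spokes_per_frame, n_frames)
  for (f in seq_len(n_frames)) {
    base <- if (continuous_across_frames) (f - 1L) * spokes_per_frame else 0L
    idx <- base + seq_len(spokes_per_frame) - 1L
    th <- (idx * golden_angle_deg * pi / 180) %% pi
    angles[, f] <- th
    kx <- as.vector(outer(radius, cos(th)))
    ky <- as.vector(outer(radius, sin(th)))
    coords[, 1, f] <- kx
    coords[, 2, f] <- ky
  }
  structure(list(n_frames = n_frames,
                 spokes_per_frame = spokes_per_frame,
                 samples_per_spoke = samples_per_spoke,
                 golden_angle_deg = golden_angle_deg,
                 continuous_across_frames = continuous_across_frames,
                 coords = coords, angles = angles),
            class = "lrmc_traj")
}

#' Ramp density-compensation weights for a radial trajectory
#'
#' Returns per-sample weights proportional to the k-space radius |k|
#' ("ramp" filter), with the DC sample capped at a quarter of the radial
#' sample spacing so it is neither zero nor dominant.  The weights are
#' normalized so their mean is 1.  They are intended only for
#' density-compensated zero-filled (gridding) images and for
#' initialization; the iterative solvers use exact, unweighted adjoints.
#'
#' @param traj an [golden_angle_traj()] object.
#' @return matrix `[n_samples, n_frames]` of weights.
#' @export
radial_dcf <- function(traj) {
  stopifnot(inherits(traj, "lrmc_traj"))
  ns <- traj$samples_per_spoke
  dcf <- matrix(0, dim(traj$coords)[1], traj$n_frames)
  floor_val <- 0.25 / ns
  for (f in seq_len(traj$n_frames)) {
    r <- sqrt(traj$coords[, 1, f]^2 + traj$coords[, 2, f]^2)
    w <- pmax(r, floor_val)
    dcf[, f] <- w / mean(w)
  }
  dcf
}
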