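# Motion-free reference synthesis by temporal independent component
# analysis.  The perfusion series (as a Casorati matrix, pixels x
# frames) is reduced to a small number of temporal components by PCA,
# unmixed by symmetric fixed-point FastICA (logcosh contrast), and the
# component whose temporal spectrum peaks inside the respiratory
# frequency band is identified and zeroed before resynthesis, yielding
# a series that keeps the contrast dynamics but suppresses respiratory
# motion.

# Symmetric FastICA on whitened data Z [n_comp, n_obs] (unit
# covariance rows).  Returns the orthogonal unmixing rotation.
# Deterministic given seed.
fastica_rotation <- function(Z, seed = 1L, max_iter = 200, tol = 1e-8) {
  nc <- nrow(Z); nobs <- ncol(Z)
  W <- with_seed_local(seed, matrix(stats::rnorm(nc * nc), nc, nc))
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / nobs - diag(rowMeans(Gp), nc) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Synthesize motion-free reference images by ICA filtering
#'
#' Decomposes the image series into `n_components` temporal components
#' (PCA dimensionality reduction followed by fixed-point ICA), computes
#' the discrete Fourier magnitude spectrum of every component's
#' temporal signal, and selects as respiratory the component whose
#' spectral peak frequency falls inside `resp_band_hz` with the largest
#' peak magnitude (`resp_index`).  With `remove = "in_band"` (default)
#' every in-band-peaking component is zeroed before resynthesis: a
#' periodic respiratory trace places harmonic energy at (aliased)
#' in-band frequencies across several components, and all of it is
#' respiration-locked, while contrast dynamics peak well below the
#' band.  With `remove = "dominant"` only `resp_index` is zeroed.  The
#' resynthesized series keeps the contrast dynamics but suppresses
#' respiratory motion.  If no component peaks inside the band, the
#' series is resynthesized from all components and `resp_index` is `NA`
#' (with a warning).
#'
#' @param X image series `[N, N, n_frames]` (real magnitudes).
#' @param n_components number of temporal components (default 5).
#' @param resp_band_hz numeric length-2: respiratory band, default
#'   `c(0.2, 0.5)` Hz.  The lower edge must lie below the frame Nyquist
#'   rate; the upper edge is clamped to it.
#' @param frame_rate_hz frames per second (1 / heartbeat interval).
#' @param seed seed for the deterministic ICA initialization.
#' @param remove removal rule; see Description.
#' @return list with `Xref` (filtered series, same shape) and `model`,
#'   an `lrmc_ica` object holding the spatial maps `A` (pixels x
#'   components), temporal `sources` (components x frames), per-source
#'   spectra, `resp_index`, `removed`, `n_components`, `frame_rate_hz`.
#' @export
ica_references <- function(X, n_components = 5, resp_band_hz = c(0.2, 0.5),
                           frame_rate_hz = 1, seed = 1L,
                           remove = c("in_band", "dominant")) {
  d <- dim(X)
  nf <- d[3]
  if (n_components < 2) stop("parameter error: need at least 2 components")
  if (n_components >= nf)
    stop("parameter error: n_components must be smaller than n_frames")
  nyquist <- frame_rate_hz / 2
  if (resp_band_hz[1] >= nyquist)
    stop("respiratory band lies entirely above the frame Nyquist rate")
  band <- c(resp_band_hz[1], min(resp_band_hz[2], nyquist))

  npx <- d[1] * d[2]
  Xc <- matrix(X, npx, nf)
  mu <- rowMeans(Xc)
  Xz <- Xc - mu
  # spatial ICA: sources are independent spatial maps (motion components
  # are sparse edge-derivative maps, which ICA isolates cleanly); each
  # map carries a temporal course used for the spectral identification
  sv <- svd(Xz, nu = n_components, nv = n_components)
  Z <- t(sv$u) * sqrt(npx)                    # whitened spatial data [nc, npx]
  R <- fastica_rotation(Z, seed = seed)
  Smap <- R %*% Z                             # spatial sources [nc, npx]
  # temporal mixing: columns are the time courses of each map
  Tc <- sv$v %*% diag(sv$d[seq_len(n_components)] / sqrt(npx),
                      n_components) %*% t(R)  # [nf, nc]
  S <- t(Tc)                                  # temporal courses [nc, nf]
  A <- t(Smap)                                # pixel maps as mixing [npx, nc]

  freqs <- (0:(nf - 1)) / nf * frame_rate_hz
  half <- freqs <= nyquist + 1e-12
  # scale each temporal course by its spatial-map norm so spectra rank
  # components by their actual energy in the series, not whitened units
  energy <- sqrt(colSums(abs(A)^2))
  spectra <- t(sapply(seq_len(n_components), function(i) {
    s <- S[i, ] - mean(S[i, ])
    tt <- seq_along(s)
    s <- stats::residuals(stats::lm(s ~ tt))   # detrend before the FFT
    abs(stats::fft(s)) * energy[i]
  }))
  peak_freq <- apply(spectra[, half, drop = FALSE], 1, function(m) {
    m[1] <- 0                                  # exclude DC
    freqs[half][which.max(m)]
  })
  peak_mag <- apply(spectra[, half, drop = FALSE], 1, function(m) {
    m[1] <- 0
    max(m)
  })
  in_band <- peak_freq > band[1] & peak_freq <= band[2]
  remove <- match.arg(remove)
  if (any(in_band)) {
    cand <- which(in_band)
    resp_index <- cand[which.max(peak_mag[cand])]
    removed <- if (remove == "in_band") cand else resp_index
    keep <- setdiff(seq_len(n_components), removed)
  } else {
    warning("no ICA component peaks inside the respiratory band; returning unfiltered reconstruction")
    resp_index <- NA_integer_
    removed <- integer(0)
    keep <- seq_len(n_components)
  }
  Xf <- mu + A[, keep, drop = FALSE] %*% S[keep, , drop = FALSE]
  Xref <- array(Xf, dim = d)
  model <- structure(list(A = A, sources = S, spectra = spectra,
                          freqs = freqs, resp_index = resp_index,
                          removed = removed,
                          peak_freq = peak_freq, peak_mag = peak_mag,
                          n_components = n_components,
                          frame_rate_hz = frame_rate_hz,
                          resp_band_hz = band),
                     class = "lrmc_ica")
  list(Xref = Xref, model = model)
}

#' Center-of-mass trace of an image series
#'
#' Intensity-weighted centroid per frame; its excursion (standard
#' deviation over frames) is the package's surrogate for bulk
#' respiratory displacement of a series.
#' @param X image series `[N, N, n_frames]`.
#' @return matrix `[n_frames, 2]` of (row, col) centroids.
#' @export
center_of_mass <- function(X) {
  d <- dim(X)
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  t(vapply(seq_len(d[3]), function(f) {
    w <- abs(X[, , f])
    s <- sum(w)
    c(sum(rr * w) / s, sum(cc * w) / s)
  }, numeric(2)))
}
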