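# Shared fixtures, computed once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small moving phantom used by most unit tests: 48x48, 16 heartbeats,
# 3 coils, 13 spokes/frame, 4 px respiratory motion, 2% noise.
tiny_phantom <- function() fixture("tiny_phantom", {
  make_phantom(phantom_spec(matrix_size = 48, n_frames = 16, n_coils = 3,
                            spokes_per_frame = 13, samples_per_spoke = 96,
                            motion_amplitude_px = 4, noise_fraction = 0.02,
                            seed = 7))
})

tiny_kspace <- function() fixture("tiny_kspace", sample_kspace(tiny_phantom()))

# Motionless, noiseless twin of the tiny phantom.
tiny_phantom_still <- function() fixture("tiny_phantom_still", {
  make_phantom(phantom_spec(matrix_size = 48, n_frames = 16, n_coils = 3,
                            spokes_per_frame = 13, samples_per_spoke = 96,
                            motion_amplitude_px = 0, noise_fraction = 0,
                            seed = 7))
})

# A single textured 64x64 magnitude image at myocardial enhancement
# (for registration tests; all tissues carry contrast at that frame).
texture_image <- function() fixture("texture_image", {
  ph <- make_phantom(phantom_spec(matrix_size = 64, n_frames = 24, n_coils = 1,
                                  spokes_per_frame = 8, samples_per_spoke = 64,
                                  motion_amplitude_px = 0, noise_fraction = 0,
                                  seed = 3))
  list(image = ph$ref_series[, , 20], body = ph$masks > 0)
})

# Band-limited subpixel translation via a Fourier phase ramp: the
# physically correct model of bulk motion of a band-limited image.
fourier_translate <- function(img, dr, dc) {
  N <- nrow(img)
  fr <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1)) / N
  ph <- exp(-2i * pi * (outer(fr * dr, rep(1, N)) + outer(rep(1, N), fr * dc)))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (N * N)
}

# Mild apodization so the test image has the spectral roll-off of a
# reconstructed MR image rather than razor edges.
apodize <- function(img, width = 0.18) {
  N <- nrow(img)
  fr <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1)) / N
  filt <- exp(-outer(fr^2, fr^2, "+") / (2 * width^2))
  Re(stats::fft(stats::fft(img) * filt, inverse = TRUE)) / (N * N)
}

# Independent dense bilinear-warp matrix, assembled by explicit loops
# (oracle for the package's sparse warp operators).
dense_warp_oracle <- function(field) {
  N <- dim(field)[1]; Mc <- dim(field)[2]
  W <- matrix(0, N * Mc, N * Mc)
  for (r in seq_len(N)) for (cc in seq_len(Mc)) {
    out <- (cc - 1) * N + r
    sr <- r + field[r, cc, 1]
    sc <- cc + field[r, cc, 2]
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    for (dr in 0:1) for (dc in 0:1) {
      rn <- r0 + dr; cn <- c0 + dc
      if (rn >= 1 && rn <= N && cn >= 1 && cn <= Mc) {
        w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
        W[out, (cn - 1) * N + rn] <- W[out, (cn - 1) * N + rn] + w
      }
    }
  }
  W
}

# Independent dense nonuniform-DFT matrix (double-loop construction).
dense_dft_oracle <- function(coords, N) {
  c0 <- floor(N / 2)
  A <- matrix(0i, nrow(coords), N * N)
  for (s in seq_len(nrow(coords))) {
    for (cc in seq_len(N)) for (r in seq_len(N)) {
      A[s, (cc - 1) * N + r] <-
        exp(-2i * pi * (coords[s, 2] * (r - 1 - c0) + coords[s, 1] * (cc - 1 - c0)))
    }
  }
  A
}

rand_cplx <- function(n, seed) {
  set.seed(seed)
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
}

com_excursion <- function(X) {
  cm <- center_of_mass(X)
  sqrt(sum(apply(cm, 2, stats::var)))
}
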