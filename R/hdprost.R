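# Patch-based high-order low-rank (tensor) denoising of the singular
# images: for each (strided) voxel, the K patches most similar to the
# local patch are collected across a search window, stacked with the
# contrast (singular-image) dimension into a 3-mode tensor, and the
# tensor's mode unfoldings are low-rank-filtered by singular-value
# thresholding.  Overlapping estimates are aggregated by averaging.

#' Patch-tensor regularization configuration
#'
#' @param patch_size odd patch side length in pixels (default 5).
#' @param search_window odd search-window side for block matching
#'   (default 21).
#' @param n_similar number K of similar patches per tensor (default 10).
#' @param stride patch-center stride in pixels (default 2).
#' @param matching_reference image used for block matching: `"rss"`
#'   (root-sum-of-squares of the singular images, default) or `"first"`
#'   (first singular image).
#' @param threshold_rule `"soft"` (singular-value soft thresholding,
#'   the nuclear-norm proximal map used inside the ADMM solver) or
#'   `"hard"` (truncation, which preserves exactly low-rank tensors).
#' @return list of class `lrmc_patch_config`.
#' @export
patch_config <- function(patch_size = 5, search_window = 21, n_similar = 10,
                         stride = 2, matching_reference = c("rss", "first"),
                         threshold_rule = c("soft", "hard")) {
  if (patch_size %% 2 != 1) stop("patch_size must be odd")
  if (n_similar < 2) stop("n_similar must be >= 2")
  if (search_window < patch_size) stop("search_window must cover the patch")
  structure(list(patch_size = as.integer(patch_size),
                 search_window = as.integer(search_window),
                 n_similar = as.integer(n_similar),
                 stride = as.integer(stride),
                 matching_reference = match.arg(matching_reference),
                 threshold_rule = match.arg(threshold_rule)),
            class = "lrmc_patch_config")
}

# Box sum of a matrix over patch_size x patch_size neighborhoods
# (centered), via separable cumulative sums; zero-padded edges.
box_sum <- function(M, half) {
  N <- nrow(M); Mc <- ncol(M)
  cs <- apply(rbind(0, M), 2, cumsum)
  up <- pmin(seq_len(N) + half, N) + 1
  lo <- pmax(seq_len(N) - half - 1, 0) + 1
  V <- cs[up, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- t(apply(cbind(0, V), 1, cumsum))
  upc <- pmin(seq_len(Mc) + half, Mc) + 1
  loc <- pmax(seq_len(Mc) - half - 1, 0) + 1
  cs2[, upc, drop = FALSE] - cs2[, loc, drop = FALSE]
}

# Mode-n unfold / fold for a 3-mode array.
unfold3 <- function(Tn, mode) {
  d <- dim(Tn)
  perm <- switch(mode, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  matrix(aperm(Tn, perm), d[mode])
}
fold3 <- function(M, mode, d) {
  perm <- switch(mode, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  back <- order(perm)
  aperm(array(M, d[perm]), back)
}

# Singular-value thresholding of a matrix (soft or hard).
svt_matrix <- function(M, thr, rule) {
  sv <- svd(M)
  d <- if (rule == "soft") pmax(sv$d - thr, 0) else sv$d * (sv$d > thr)
  sv$u %*% (d * t(Conj(sv$v)))
}

#' Patch-tensor (higher-order low-rank) denoising
#'
#' For every voxel on a stride grid, block matching on the reference
#' image collects the `n_similar` most similar patches (L2 patch
#' distance, ties in scan order) within the search window; the tensor
#' `[patch pixels x similar patches x singular images]` is filtered by
#' singular-value thresholding of each mode unfolding (sequentially,
#' modes 1..3), and the filtered patches are aggregated back by
#' uniform averaging.  Pixels never covered by a patch (a thin border)
#' are returned unchanged.
#'
#' @param y complex array `[N, N, r]` of singular images.
#' @param cfg [patch_config()].
#' @param threshold singular-value threshold, on the scale of the input
#'   values (inside the ADMM solver this is `lambda / mu`).
#' @return denoised array, same shape as `y`.
#' @export
hd_prost_denoise <- function(y, cfg = patch_config(), threshold) {
  d <- dim(y)
  N <- d[1]; Mc <- d[2]; r <- d[3]
  if (min(N, Mc) < cfg$search_window)
    stop("image smaller than the search window")
  p <- cfg$patch_size
  hp <- p %/% 2
  hw <- (cfg$search_window - p) %/% 2   # max offset of a candidate center
  K <- cfg$n_similar

  ref <- switch(cfg$matching_reference,
                rss = sqrt(apply(abs(y)^2, c(1, 2), sum)),
                first = abs(y[, , 1]))

  # candidate offsets, scan order; (0,0) first so the self patch wins ties
  offs <- as.matrix(expand.grid(dr = -hw:hw, dc = -hw:hw))
  offs <- offs[order(abs(offs[, "dr"]) + abs(offs[, "dc"]) > 0), , drop = FALSE]

  # patch centers: fully inside even for the extreme offset
  margin <- hp + hw
  cr <- seq(margin + 1, N - margin, by = cfg$stride)
  cc <- seq(margin + 1, Mc - margin, by = cfg$stride)
  centers <- as.matrix(expand.grid(r = cr, c = cc))
  n_cent <- nrow(centers)
  n_off <- nrow(offs)

  # SSD maps per offset, evaluated at all pixels via box filtering
  ssd <- matrix(0, n_cent, n_off)
  cidx <- (centers[, 2] - 1) * N + centers[, 1]
  for (o in seq_len(n_off)) {
    dr <- offs[o, 1]; dc <- offs[o, 2]
    sh <- matrix(0, N, Mc)
    rs <- (1 + max(0, -dr)):(N - max(0, dr))
    cs <- (1 + max(0, -dc)):(Mc - max(0, dc))
    sh[rs, cs] <- ref[rs + dr, cs + dc]
    Dmap <- box_sum((ref - sh)^2, hp)
    ssd[, o] <- Dmap[cidx]
  }

  # K best offsets per center (self always first: its SSD is 0)
  best <- t(apply(ssd, 1, function(v) order(v)[seq_len(K)]))

  # relative index pattern of one patch (within the image vec)
  pat <- as.vector(outer(-hp:hp, (-hp:hp) * N, "+"))
  yv <- matrix(y, N * Mc, r)

  acc <- matrix(0i, N * Mc, r)
  wt <- numeric(N * Mc)
  dtn <- c(p * p, K, r)
  for (ci in seq_len(n_cent)) {
    o_sel <- best[ci, ]
    cent_idx <- cidx[ci] + (offs[o_sel, 2] * N + offs[o_sel, 1])
    idx <- outer(pat, cent_idx, "+")          # [p^2, K]
    G <- array(yv[as.vector(idx), ], dim = dtn)
    for (m in 1:3) {
      d_m <- dim(G)
      G <- fold3(svt_matrix(unfold3(G, m), threshold, cfg$threshold_rule),
                 m, d_m)
    }
    Gm <- matrix(G, p * p * K, r)
    for (k in seq_len(K)) {
      ik <- idx[, k]
      acc[ik, ] <- acc[ik, ] + Gm[(k - 1) * p * p + seq_len(p * p), ]
      wt[ik] <- wt[ik] + 1
    }
  }
  covered <- wt > 0
  out <- yv
  out[covered, ] <- acc[covered, ] / wt[covered]
  array(out, dim = d)
}
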