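# Beat-to-beat nonrigid motion estimation: multi-resolution cubic
# B-spline free-form deformation (FFD) registration with a
# sum-of-squared-differences similarity and a bending-energy penalty
# on the control grid, optimized by gradient descent with backtracking
# line search.  Deterministic (no randomness).

# Bilinear sampling of img at (sr, sc) (matrices of row/col
# coordinates); out-of-bounds samples return 0 and are flagged.
bilinear_sample <- function(img, sr, sc) {
  N <- nrow(img); Mc <- ncol(img)
  no <- nrow(sr); mo <- ncol(sr)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- matrix(0, no, mo)
  inb <- matrix(TRUE, no, mo)
  for (dr in 0:1) for (dc in 0:1) {
    rn <- r0 + dr; cn <- c0 + dc
    ok <- rn >= 1 & rn <= N & cn >= 1 & cn <= Mc
    inb <- inb & ok
    w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    idx <- cbind(pmin(pmax(as.vector(rn), 1), N), pmin(pmax(as.vector(cn), 1), Mc))
    v <- matrix(img[idx], no, mo)
    val <- val + w * v * ok
  }
  list(value = val, inside = inb)
}

image_gradients <- function(img) {
  N <- nrow(img); Mc <- ncol(img)
  gr <- (img[c(2:N, N), ] - img[c(1, 1:(N - 1)), ]) / 2
  gc <- (img[, c(2:Mc, Mc)] - img[, c(1, 1:(Mc - 1))]) / 2
  list(gr = gr, gc = gc)
}

downsample2 <- function(img) {
  N <- nrow(img); Mc <- ncol(img)
  n2 <- N %/% 2; m2 <- Mc %/% 2
  i <- seq_len(2 * n2); j <- seq_len(2 * m2)
  a <- img[i, j, drop = FALSE]
  (a[seq(1, 2 * n2, 2), seq(1, 2 * m2, 2)] +
   a[seq(2, 2 * n2, 2), seq(1, 2 * m2, 2)] +
   a[seq(1, 2 * n2, 2), seq(2, 2 * m2, 2)] +
   a[seq(2, 2 * n2, 2), seq(2, 2 * m2, 2)]) / 4
}

# Upsample a displacement field defined on an n x m grid to N x M,
# scaling displacements by the grid ratio.
upsample_field <- function(field, N, Mc) {
  n <- dim(field)[1]; m <- dim(field)[2]
  sr <- matrix((seq_len(N) - 0.5) * n / N + 0.5, N, Mc)
  sc <- matrix((seq_len(Mc) - 0.5) * m / Mc + 0.5, N, Mc, byrow = TRUE)
  sr <- pmin(pmax(sr, 1), n); sc <- pmin(pmax(sc, 1), m)
  f1 <- bilinear_sample(field[, , 1], sr, sc)$value * (N / n)
  f2 <- bilinear_sample(field[, , 2], sr, sc)$value * (Mc / m)
  array(c(f1, f2), dim = c(N, Mc, 2))
}

# Single-level FFD optimization.  moving/fixed are intensity images on
# the same grid; P init comes from the caller.
ffd_level <- function(moving, fixed, h, bending_weight, P0r, P0c,
                      max_iter = 60, tol = 1e-6) {
  N <- nrow(fixed); Mc <- ncol(fixed)
  Br <- bspline_basis(N, h); Bc <- bspline_basis(Mc, h)
  grad_m <- image_gradients(moving)
  rr <- matrix(seq_len(N), N, Mc)
  cc <- matrix(seq_len(Mc), N, Mc, byrow = TRUE)
  npx <- N * Mc
  nctrl <- ncol(Br) * ncol(Bc)

  cost_grad <- function(Pr, Pc, want_grad = TRUE) {
    fr <- Br %*% Pr %*% t(Bc)
    fc <- Br %*% Pc %*% t(Bc)
    s <- bilinear_sample(moving, rr + fr, cc + fc)
    resid <- (s$value - fixed) * s$inside
    # bending term uses curvature units (second difference / h^2) so the
    # weight is comparable across pyramid levels and grid spacings
    bscale <- bending_weight / (nctrl * h^2)
    cost <- 0.5 * sum(resid^2) / npx +
      bscale * (bending_energy(Pr) + bending_energy(Pc))
    if (!want_grad) return(list(cost = cost))
    gr <- bilinear_sample(grad_m$gr, rr + fr, cc + fc)$value
    gc <- bilinear_sample(grad_m$gc, rr + fr, cc + fc)$value
    Gr <- crossprod(Br, (resid * gr)) %*% Bc / npx + bscale * bending_grad(Pr)
    Gc <- crossprod(Br, (resid * gc)) %*% Bc / npx + bscale * bending_grad(Pc)
    list(cost = cost, Gr = Gr, Gc = Gc)
  }

  Pr <- P0r; Pc <- P0c
  cg <- cost_grad(Pr, Pc)
  step <- h   # displacement-scale initial step
  for (it in seq_len(max_iter)) {
    gnorm2 <- sum(cg$Gr^2) + sum(cg$Gc^2)
    if (gnorm2 < 1e-20) break
    sc_step <- step / sqrt(gnorm2)
    accepted <- FALSE
    for (bt in 1:12) {
      Pr2 <- Pr - sc_step * cg$Gr
      Pc2 <- Pc - sc_step * cg$Gc
      c2 <- cost_grad(Pr2, Pc2, want_grad = FALSE)$cost
      if (c2 < cg$cost) { accepted <- TRUE; break }
      sc_step <- sc_step / 2
    }
    if (!accepted) break
    rel <- (cg$cost - c2) / max(cg$cost, 1e-12)
    Pr <- Pr2; Pc <- Pc2
    cg <- cost_grad(Pr, Pc)
    step <- min(sc_step * sqrt(gnorm2) * 1.5, 4 * h)
    if (rel < tol) break
  }
  list(Pr = Pr, Pc = Pc, Br = Br, Bc = Bc,
       field = bspline_field(Pr, Pc, Br, Bc), cost = cg$cost)
}

#' Nonrigid B-spline free-form deformation registration
#'
#' Estimates the dense displacement field aligning `moving` to `fixed`
#' by multi-resolution cubic B-spline FFD: sum-of-squared-differences
#' similarity (after 99th-percentile intensity normalization of each
#' image), a bending-energy penalty on the control grid, and gradient
#' descent with backtracking.  The returned field follows the package
#' warp convention: `warp(moving, field)` approximates `fixed`, i.e.
#' the field maps fixed-grid coordinates into the moving image.
#'
#' @param moving,fixed real magnitude images of equal size.
#' @param grid_spacing_px control-point spacing at full resolution.
#' @param levels number of pyramid levels (coarsest is
#'   `2^(levels-1)`-fold downsampled).
#' @param bending_weight bending-energy regularization weight.
#' @param max_iter gradient-descent iterations per level.
#' @return displacement field `[N, N, 2]` (row component first).
#' @export
register_ffd <- function(moving, fixed, grid_spacing_px = 16, levels = 3,
                         bending_weight = 1e-2, max_iter = 60) {
  if (!all(dim(moving) == dim(fixed))) stop("images must share a grid")
  norm99 <- function(x) {
    q <- stats::quantile(abs(x), 0.99, names = FALSE)
    if (q <= 0) q <- max(abs(x), 1)
    x / q
  }
  mv <- norm99(Re(moving)); fx <- norm99(Re(fixed))
  if (stats::sd(mv) < 1e-9 || stats::sd(fx) < 1e-9) {
    warning("degenerate (constant) image; returning zero field")
    return(array(0, dim = c(nrow(fixed), ncol(fixed), 2)))
  }
  pyr_m <- list(mv); pyr_f <- list(fx)
  for (l in seq_len(levels - 1)) {
    pyr_m[[l + 1]] <- downsample2(pyr_m[[l]])
    pyr_f[[l + 1]] <- downsample2(pyr_f[[l]])
  }
  field <- NULL
  for (l in rev(seq_len(levels))) {        # coarse -> fine
    m_l <- pyr_m[[l]]; f_l <- pyr_f[[l]]
    scale <- 2^(l - 1)
    h <- max(3, round(grid_spacing_px / scale))
    Br <- bspline_basis(nrow(f_l), h); Bc <- bspline_basis(ncol(f_l), h)
    if (is.null(field)) {
      P0r <- matrix(0, ncol(Br), ncol(Bc))
      P0c <- matrix(0, ncol(Br), ncol(Bc))
    } else {
      up <- upsample_field(field, nrow(f_l), ncol(f_l))
      P0r <- bspline_fit(up[, , 1], Br, Bc)
      P0c <- bspline_fit(up[, , 2], Br, Bc)
    }
    res <- ffd_level(m_l, f_l, h, bending_weight, P0r, P0c,
                     max_iter = max_iter)
    field <- res$field
  }
  field
}

#' Estimate beat-to-beat motion fields from a perfusion series
#'
#' For every frame t, registers the contrast-matched pair formed by the
#' observed frame `X[, , t]` and its motion-free reference
#' `Xref[, , t]` (from [ica_references()]).  The forward field (the M
#' operator: reference state towards frame t) is obtained with the
#' reference as moving image; the backward field with the observed
#' frame as moving image.
#'
#' @param X observed image series `[N, N, n_frames]` (magnitudes).
#' @param Xref motion-free reference series, same shape.
#' @param ... passed to [register_ffd()].
#' @param verbose print per-frame progress.
#' @return an `lrmc_motion` object.
#' @export
estimate_motion <- function(X, Xref, ..., verbose = FALSE) {
  if (!all(dim(X) == dim(Xref))) stop("series must share a grid")
  d <- dim(X)
  fwd <- array(0, dim = c(d[1], d[2], 2, d[3]))
  bwd <- array(0, dim = c(d[1], d[2], 2, d[3]))
  for (f in seq_len(d[3])) {
    fwd[, , , f] <- register_ffd(Xref[, , f], X[, , f], ...)
    bwd[, , , f] <- register_ffd(X[, , f], Xref[, , f], ...)
    if (verbose) message("registered frame ", f, "/", d[3])
  }
  motion_field_series(fwd, bwd)
}
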