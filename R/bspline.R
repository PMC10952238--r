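# Uniform cubic B-spline machinery shared by the free-form deformation
# registration and the phantom's smooth deformation basis.

# Cubic B-spline kernel beta3(u), support |u| < 2.
bspline3 <- function(u) {
  a <- abs(u)
  out <- numeric(length(u))
  i1 <- a < 1
  out[i1] <- (4 - 6 * a[i1]^2 + 3 * a[i1]^3) / 6
  i2 <- a >= 1 & a < 2
  out[i2] <- (2 - a[i2])^3 / 6
  out
}

# Basis matrix B [n_pix, n_ctrl] with control points spaced `h` pixels,
# padded so every pixel in 1..n has full cubic support.
bspline_basis <- function(n, h) {
  n_ctrl <- ceiling((n - 1) / h) + 3
  pos <- ((seq_len(n_ctrl)) - 2) * h + 1
  outer(seq_len(n), pos, function(x, p) bspline3((x - p) / h))
}

# Dense 2D field from control-point coefficient matrices (one per
# displacement component): field_k = Br %*% P_k %*% t(Bc).
bspline_field <- function(Pr, Pc, Br, Bc) {
  array(c(Br %*% Pr %*% t(Bc), Br %*% Pc %*% t(Bc)),
        dim = c(nrow(Br), nrow(Bc), 2))
}

# Least-squares fit of control coefficients to a dense scalar field
# (ridge-stabilized); used to carry a field across pyramid levels.
bspline_fit <- function(F, Br, Bc, ridge = 1e-6) {
  Ar <- crossprod(Br); Ac <- crossprod(Bc)
  diag(Ar) <- diag(Ar) + ridge * mean(diag(Ar))
  diag(Ac) <- diag(Ac) + ridge * mean(diag(Ac))
  solve(Ar, t(Br) %*% F %*% Bc) %*% solve(Ac)
}

# Interior second differences of a control grid along rows / columns,
# and their exact adjoints.  Together they define the discrete bending
# energy 0.5 * (||Dr P||^2 + ||Dc P||^2) with gradient
# Dr^T Dr P + Dc^T Dc P.
d2_rows <- function(P) {
  K <- nrow(P)
  if (K < 3) return(matrix(0, 0, ncol(P)))
  P[1:(K - 2), , drop = FALSE] - 2 * P[2:(K - 1), , drop = FALSE] + P[3:K, , drop = FALSE]
}
d2_rows_T <- function(Y, K) {
  out <- matrix(0, K, ncol(Y))
  if (nrow(Y) == 0) return(out)
  idx <- seq_len(nrow(Y))
  out[idx, ]     <- out[idx, ] + Y
  out[idx + 1, ] <- out[idx + 1, ] - 2 * Y
  out[idx + 2, ] <- out[idx + 2, ] + Y
  out
}
d2_cols <- function(P) t(d2_rows(t(P)))
d2_cols_T <- function(Y, K) t(d2_rows_T(t(Y), K))

bending_energy <- function(P) {
  0.5 * (sum(d2_rows(P)^2) + sum(d2_cols(P)^2))
}
bending_grad <- function(P) {
  d2_rows_T(d2_rows(P), nrow(P)) + d2_cols_T(d2_cols(P), ncol(P))
}
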