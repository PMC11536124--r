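# Real orthonormal spherical-harmonic machinery.
#
# Normalization: Ybar_l0 = Pbar_l0(cos theta); for m > 0,
#   Y_{l,+m} = sqrt(2) Pbar_lm cos(m phi),  Y_{l,-m} = sqrt(2) Pbar_lm sin(m phi),
# with Pbar_lm = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) P_lm (no Condon-Shortley
# phase), so that the basis is orthonormal under the solid-angle measure.
# Coefficient storage: column index col(l, m) = l^2 + l + m + 1.
#
# Recurrences are the standard fully-normalized geodesy forms (stable to
# degree several hundred); theta derivatives use
#   dPbar/dtheta = (l x Pbar_lm - c_lm Pbar_{l-1,m}) / sin(theta),
#   c_lm = sqrt((l^2 - m^2)(2l+1)/(2l-1)),
# and second derivatives the associated Legendre ODE
#   P'' = -cot(theta) P' - (l(l+1) - m^2/sin^2 theta) P.
# Quadrature nodes are interior (Gauss-Legendre in cos theta), so the
# sin(theta) divisions are well-conditioned everywhere they are used.

# triangular (l, m>=0) index
.tri_idx <- function(l, m) l * (l + 1) / 2 + m + 1

#' Number of real spherical-harmonic coefficients per coordinate
#'
#' A degree-`lmax` expansion carries `(lmax + 1)^2` real coefficients per
#' scalar function (one per (l, m) pair with |m| <= l <= lmax).
#'
#' @param lmax maximum spherical-harmonic degree.
#' @return integer coefficient count.
#' @export
#' @examples
#' spharm_n_coef(1)  # 4
#' spharm_n_coef(25) # 676
spharm_n_coef <- function(lmax) (as.integer(lmax) + 1L)^2

# column index of (l, m) in the full real basis, m in [-l, l]
sph_col <- function(l, m) l^2 + l + m + 1

# Normalized associated Legendre table Pbar_lm(cos theta) for all
# 0 <= m <= l <= lmax at the given theta values, with optional first and
# second theta-derivatives. Returns list(P, P1, P2); each npts x ntri.
alf_table <- function(theta, lmax, nderiv = 0) {
  x <- cos(theta); s <- sin(theta)
  n <- length(theta)
  ntri <- (lmax + 1) * (lmax + 2) / 2
  P <- matrix(0, n, ntri)
  P[, 1] <- sqrt(1 / (4 * pi))
  if (lmax >= 1) {
    # sectorals and the full table, m-major
    for (m in seq_len(lmax)) {
      P[, .tri_idx(m, m)] <-
        s * sqrt((2 * m + 1) / (2 * m)) * P[, .tri_idx(m - 1, m - 1)]
    }
    for (m in 0:(lmax - 1)) {
      P[, .tri_idx(m + 1, m)] <- sqrt(2 * m + 3) * x * P[, .tri_idx(m, m)]
      if (m + 2 <= lmax) for (l in (m + 2):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[, .tri_idx(l, m)] <-
          a * (x * P[, .tri_idx(l - 1, m)] - b * P[, .tri_idx(l - 2, m)])
      }
    }
  }
  out <- list(P = P)
  if (nderiv >= 1) {
    P1 <- matrix(0, n, ntri)
    for (l in seq_len(lmax)) for (m in 0:l) {
      low <- if (l - 1 >= m) P[, .tri_idx(l - 1, m)] else 0
      cl <- sqrt((l^2 - m^2) * (2 * l + 1) / (2 * l - 1))
      P1[, .tri_idx(l, m)] <- (l * x * P[, .tri_idx(l, m)] - cl * low) / s
    }
    out$P1 <- P1
    if (nderiv >= 2) {
      P2 <- matrix(0, n, ntri)
      cot <- x / s
      for (l in 0:lmax) for (m in 0:l) {
        k <- .tri_idx(l, m)
        P2[, k] <- -cot * P1[, k] - (l * (l + 1) - m^2 / s^2) * P[, k]
      }
      out$P2 <- P2
    }
  }
  out
}

# Dense real-harmonic design matrix at scattered points: npts x (lmax+1)^2.
sph_basis <- function(theta, phi, lmax) {
  tab <- alf_table(theta, lmax)$P
  n <- length(theta)
  B <- matrix(0, n, spharm_n_coef(lmax))
  for (l in 0:lmax) {
    B[, sph_col(l, 0)] <- tab[, .tri_idx(l, 0)]
    if (l >= 1) for (m in seq_len(l)) {
      pm <- sqrt(2) * tab[, .tri_idx(l, m)]
      B[, sph_col(l, m)] <- pm * cos(m * phi)
      B[, sph_col(l, -m)] <- pm * sin(m * phi)
    }
  }
  B
}

# Chunked normal-equation least squares of per-point values (npts x k)
# against the real harmonic basis. Returns list(coef, residual_rms).
sph_lsq_fit <- function(theta, phi, values, lmax, chunk = 4096L) {
  values <- as.matrix(values)
  n <- length(theta)
  nc <- spharm_n_coef(lmax)
  BtB <- matrix(0, nc, nc)
  BtY <- matrix(0, nc, ncol(values))
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ii in idx) {
    B <- sph_basis(theta[ii], phi[ii], lmax)
    BtB <- BtB + crossprod(B)
    BtY <- BtY + crossprod(B, values[ii, , drop = FALSE])
  }
  coef <- tryCatch(solve(BtB, BtY), error = function(e)
    solve(BtB + diag(1e-10 * mean(diag(BtB)), nc), BtY))
  ss <- 0
  for (ii in idx) {
    B <- sph_basis(theta[ii], phi[ii], lmax)
    ss <- ss + sum((values[ii, , drop = FALSE] - B %*% coef)^2)
  }
  list(coef = coef, residual_rms = sqrt(ss / (n * ncol(values))))
}

# Evaluate a truncated expansion (and, optionally, theta/phi derivatives up
# to second order) of k scalar functions on a separable (theta x phi) grid.
# coef: (lmax+1)^2 x k, truncated at degree L <= lmax.
# Returns list of arrays (ntheta x nphi x k): f, and if nderiv >= 1
# ft, fp; if nderiv >= 2 ftt, ftp, fpp.
sph_synth_grid <- function(coef, L, theta, phi, nderiv = 0) {
  k <- ncol(coef)
  nt <- length(theta); np <- length(phi)
  tab <- alf_table(theta, L, nderiv)
  zero <- function() array(0, c(nt, np, k))
  f <- zero()
  ft <- fp <- ftt <- ftp <- fpp <- NULL
  if (nderiv >= 1) { ft <- zero(); fp <- zero() }
  if (nderiv >= 2) { ftt <- zero(); ftp <- zero(); fpp <- zero() }
  for (m in 0:L) {
    ls <- m:L
    tri <- .tri_idx(ls, m)
    scl <- if (m == 0) 1 else sqrt(2)
    ca <- coef[sph_col(ls, m), , drop = FALSE]              # cos coefficients
    cb <- if (m > 0) coef[sph_col(ls, -m), , drop = FALSE] else NULL
    cm <- cos(m * phi); sm <- sin(m * phi)
    P0 <- tab$P[, tri, drop = FALSE] * scl
    A0 <- P0 %*% ca
    B0 <- if (m > 0) P0 %*% cb else NULL
    for (j in seq_len(k)) {
      f[, , j] <- f[, , j] + outer(A0[, j], cm) +
        (if (m > 0) outer(B0[, j], sm) else 0)
    }
    if (nderiv >= 1) {
      P1 <- tab$P1[, tri, drop = FALSE] * scl
      A1 <- P1 %*% ca; B1 <- if (m > 0) P1 %*% cb else NULL
      for (j in seq_len(k)) {
        ft[, , j] <- ft[, , j] + outer(A1[, j], cm) +
          (if (m > 0) outer(B1[, j], sm) else 0)
        if (m > 0)
          fp[, , j] <- fp[, , j] + m * (outer(B0[, j], cm) - outer(A0[, j], sm))
      }
      if (nderiv >= 2) {
        P2 <- tab$P2[, tri, drop = FALSE] * scl
        A2 <- P2 %*% ca; B2 <- if (m > 0) P2 %*% cb else NULL
        for (j in seq_len(k)) {
          ftt[, , j] <- ftt[, , j] + outer(A2[, j], cm) +
            (if (m > 0) outer(B2[, j], sm) else 0)
          if (m > 0) {
            ftp[, , j] <- ftp[, , j] +
              m * (outer(B1[, j], cm) - outer(A1[, j], sm))
            fpp[, , j] <- fpp[, , j] -
              m^2 * (outer(A0[, j], cm) + outer(B0[, j], sm))
          }
        }
      }
    }
  }
  list(f = f, ft = ft, fp = fp, ftt = ftt, ftp = ftp, fpp = fpp)
}

# Truncate a coefficient matrix to degree L (zero out l > L rows).
sph_truncate <- function(coef, lmax, L) {
  if (L >= lmax) return(coef)
  coef[(spharm_n_coef(L) + 1):nrow(coef), ] <- 0
  coef
}

# Gauss-Legendre nodes in cos(theta) plus uniform phi grid; weights are the
# GL weights (integrate d(cos theta) exactly for polynomials).
sph_quad_grid <- function(n_theta = 128L, n_phi = 256L) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  ord <- order(gl$x, decreasing = TRUE)       # theta increasing from pole
  list(theta = acos(gl$x[ord]), w_gl = gl$w[ord],
       phi = 2 * pi * (seq_len(n_phi) - 1) / n_phi,
       n_theta = n_theta, n_phi = n_phi)
}
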