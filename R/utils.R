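# Internal numerical helpers shared by the phantom generator and the
# inversion: FFT frequency axes, image rotation (for straight-ray path
# integrals), and separable Gaussian smoothing.

# Angular spatial frequencies (rad/m) for an n-point axis with spacing d (m),
# in FFT (wrap-around) order.
fft_k <- function(n, d) {
  idx <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  2 * pi * idx / (n * d)
}

# 1-D Gaussian smoothing matrix (n x n) with edge renormalisation, used for
# separable smoothing of phantom fields.
gauss_smooth_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  x <- seq_len(n)
  d <- outer(x, x, "-")
  w <- exp(-d^2 / (2 * sigma^2))
  w[abs(d) > ceiling(4 * sigma)] <- 0
  sweep(w, 1, rowSums(w), "/")
}

# Separable Gaussian smoothing of a 3-D array [row, col, slice] with
# per-dimension sigmas in voxels.
gauss_smooth_3d <- function(a, sigma) {
  d <- dim(a)
  Sr <- gauss_smooth_matrix(d[1], sigma[1])
  Sc <- gauss_smooth_matrix(d[2], sigma[2])
  for (s in seq_len(d[3])) a[, , s] <- Sr %*% a[, , s] %*% t(Sc)
  if (d[3] > 1 && sigma[3] > 0) {
    Ss <- gauss_smooth_matrix(d[3], sigma[3])
    a <- array(matrix(a, d[1] * d[2], d[3]) %*% t(Ss), d)
  }
  a
}

# Godunov upwind relaxation of the 2-D eikonal equation |grad T| = s(x) on
# an isotropic grid with spacing h, starting from an initial guess that
# bounds the solution from above (e.g. a straight-ray integral) and fixed
# values outside `free` (logical mask of cells allowed to update). Monotone
# decreasing Jacobi iteration; exact for plane-wave (linear) data.
eikonal_relax <- function(T0, slow, h, free, max_iter = 200, tol = 1e-7) {
  nr <- nrow(T0); nc <- ncol(T0)
  big <- max(T0) + 1
  sh <- slow * h
  T <- T0
  for (it in seq_len(max_iter)) {
    Tu <- rbind(big, T[-nr, ]); Td <- rbind(T[-1, ], big)
    Tl <- cbind(big, T[, -nc]); Tr <- cbind(T[, -1], big)
    Tx <- pmin(Tu, Td); Ty <- pmin(Tl, Tr)
    a <- pmin(Tx, Ty); b <- pmax(Tx, Ty)
    cand <- ifelse(b - a >= sh, a + sh,
                   (Tx + Ty + sqrt(pmax(2 * sh^2 - (Tx - Ty)^2, 0))) / 2)
    Tn <- ifelse(free, pmin(T, cand), T)
    dmax <- max(abs(Tn - T))
    T <- Tn
    if (dmax < tol) break
  }
  T
}

# Upwind transport of a path integral A along the characteristics of a
# travel-time field T: dA/dl = a with l the arc length along grad T.
# A is fixed outside `free`; A0 is the initial guess.
transport_relax <- function(A0, T, a, slow, h, free, max_iter = 200,
                            tol = 1e-9) {
  nr <- nrow(T); nc <- ncol(T)
  big <- max(T) + 1
  A <- A0
  Tu <- rbind(big, T[-nr, ]); Td <- rbind(T[-1, ], big)
  Tl <- cbind(big, T[, -nc]); Tr <- cbind(T[, -1], big)
  ux <- Td < Tu  # upwind x-neighbour below?
  uy <- Tr < Tl
  Txm <- pmin(Tu, Td); Tym <- pmin(Tl, Tr)
  px <- pmax(T - Txm, 0); py <- pmax(T - Tym, 0)
  den <- px + py
  src <- a * slow * h^2
  for (it in seq_len(max_iter)) {
    Axm <- ifelse(ux, rbind(A[-1, ], 0), rbind(0, A[-nr, ]))
    Aym <- ifelse(uy, cbind(A[, -1], 0), cbind(0, A[, -nc]))
    An <- ifelse(free & den > 0, (px * Axm + py * Aym + src) / den, A)
    dmax <- max(abs(An - A))
    A <- An
    if (dmax < tol) break
  }
  A
}

# In-plane ellipse mask for one slice.
ellipse_mask <- function(nr, nc, ctr, semi) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((rr - ctr[1]) / semi[1])^2 + ((cc - ctr[2]) / semi[2])^2 <= 1
}
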