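# Shared fixtures: small grids keep the unit tests fast; the acceptance
# tests use the full acquisition geometry.

small_spec <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(3L, 40L, 50L),
                                 vessel_count = 1L, noise_sigma = 0),
                            list(...))
  do.call(phantom_spec, args)
}

# uniform whole-grid medium wrapped as ground truth: closed-form oracle for
# the wave synthesis (no refraction at any interface)
uniform_gt <- function(c_mps, phi_rad, nr = 48, nc = 60, ns = 1,
                       vox = c(3, 3, 5)) {
  d <- c(nr, nc, ns)
  structure(list(
    sws_true_mps = array(c_mps, d),
    phi_true_rad = array(phi_rad, d),
    liver_mask = array(TRUE, d),
    vessel_mask = array(FALSE, d),
    body_mask = array(TRUE, d),
    voxel_size_mm = vox,
    spec = NULL), class = "ground_truth_maps")
}

# analytic damped plane wave on one slice, in the extracted-harmonic
# convention U = A0 * exp(-alpha * x) * exp(-i * k * x)
plane_wave <- function(nr, nc, h_m, k, alpha = 0, angle = 0) {
  x <- (matrix(seq_len(nr), nr, nc) * cos(angle) +
        matrix(seq_len(nc), nr, nc, byrow = TRUE) * sin(angle)) * h_m
  exp(-alpha * x) * exp(-1i * k * x)
}

# wrap a single-component single-frequency complex field as harmonic_field
as_harmonic <- function(U, freq_hz, vox = c(3, 3, 5)) {
  arr <- array(0 + 0i, c(dim(U), 1, 1, 1))
  arr[, , 1, 1, 1] <- U
  structure(list(u = arr, frequencies_hz = freq_hz, voxel_size_mm = vox),
            class = "harmonic_field")
}

# vectorised Welch permutation oracle: two-sided p of the observed Welch t
# under label shuffling
perm_t_pvalue <- function(a, b, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  n1 <- length(a); n <- n1 + length(b)
  dat <- c(a, b)
  t_of <- function(m) {
    g1 <- m[seq_len(n1), , drop = FALSE]
    g2 <- m[-seq_len(n1), , drop = FALSE]
    m1 <- colMeans(g1); m2 <- colMeans(g2)
    v1 <- (colSums(g1^2) - nrow(g1) * m1^2) / (nrow(g1) - 1)
    v2 <- (colSums(g2^2) - nrow(g2) * m2^2) / (nrow(g2) - 1)
    (m1 - m2) / sqrt(v1 / nrow(g1) + v2 / nrow(g2))
  }
  t_obs <- t_of(matrix(dat, ncol = 1))
  idx <- replicate(n_perm, sample.int(n))
  perm <- matrix(dat[idx], nrow = n)
  mean(abs(t_of(perm)) >= abs(t_obs))
}

# exhaustive pair-counting AUC oracle
auc_pairs <- function(pos, neg) {
  s <- 0
  for (x in pos) for (y in neg)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}
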