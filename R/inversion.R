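# Tomoelastography-style inversion: temporal harmonic extraction,
# directional k-space filtering, per-direction phase-gradient wave-number
# estimation, amplitude-weighted compounding, and Helmholtz-based fluidity.

#' Extract the complex harmonic at the drive frequency
#'
#' Collapses the time-offset dimension of a wave field by a discrete Fourier
#' transform, returning the complex amplitude of the fundamental at each
#' voxel, component, and frequency. With samples
#' `u(t_j) = A cos(2 pi f t_j + theta)` at `N` uniform offsets over one
#' period, the returned value is `A exp(i theta)` (positive-frequency bin,
#' scaled by `2/N`).
#'
#' @param wf a `wave_field` object.
#' @return an object of class `harmonic_field`: complex array `u` indexed
#'   (row, col, slice, component, frequency) plus `frequencies_hz` and
#'   `voxel_size_mm`.
#' @export
extract_harmonic <- function(wf) {
  stopifnot(inherits(wf, "wave_field"))
  nt <- wf$n_offsets
  if (nt < 3) stop("need at least 3 uniform offsets over one period")
  d <- dim(wf$displacement)
  ph <- exp(-2i * pi * (seq_len(nt) - 1) / nt)
  u <- array(0 + 0i, d[1:5])
  for (t in seq_len(nt)) {
    sl <- wf$displacement[, , , , , t, drop = FALSE]
    dim(sl) <- d[1:5]
    u <- u + sl * ph[t]
  }
  u <- u * (2 / nt)
  structure(list(u = u, frequencies_hz = wf$frequencies_hz,
                 voxel_size_mm = wf$voxel_size_mm),
            class = "harmonic_field")
}

# Angular raised-cosine windows over n_directions sectors multiplied by a
# radial band-pass, on the FFT grid of an nr x nc slice with in-plane
# spacing h (m). Windows form a partition of unity over directions inside
# the radial band. Returns a list of n_directions real matrices.
.direction_windows <- function(nr, nc, h, n_directions, k_lowcut, k_highcut) {
  kr_ax <- fft_k(nr, h); kc_ax <- fft_k(nc, h)
  KR <- matrix(kr_ax, nr, nc)
  KC <- matrix(kc_ax, nr, nc, byrow = TRUE)
  kmag <- sqrt(KR^2 + KC^2)
  band <- kmag >= k_lowcut & kmag <= k_highcut
  band[kmag == 0] <- k_lowcut == 0
  ang <- atan2(KC, KR)
  delta <- 2 * pi / n_directions
  lapply(seq_len(n_directions), function(j) {
    th <- -pi + (j - 1) * delta
    dd <- (ang - th + pi) %% (2 * pi) - pi
    w <- ifelse(abs(dd) < delta, cos(pi * dd / (2 * delta))^2, 0)
    w[kmag == 0] <- 1 / n_directions
    w * band
  })
}

#' Directional k-space filter bank
#'
#' Decomposes each slice's 2-D spatial spectrum into `n_directions` angular
#' sectors with raised-cosine windows that sum to unity over angle, combined
#' with a radial band-pass `[k_lowcut, k_highcut]` (rad/m). With the radial
#' band fully open the per-direction fields sum back to the input.
#'
#' @param field complex matrix (one slice) or 3-D complex array
#'   (row, col, slice).
#' @param voxel_size_mm voxel spacing (row, col, slice) in mm.
#' @param n_directions number of angular sectors, >= 4.
#' @param k_lowcut,k_highcut radial band edges in rad/m.
#' @return list of `n_directions` filtered complex fields, same shape as
#'   `field`.
#' @export
directional_filter_bank <- function(field, voxel_size_mm,
                                    n_directions = 12L,
                                    k_lowcut = 0, k_highcut = Inf) {
  stopifnot(n_directions >= 4, k_lowcut >= 0, k_lowcut < k_highcut)
  h <- voxel_size_mm[1] / 1000
  two_d <- is.matrix(field)
  if (two_d) field <- array(field, c(dim(field), 1L))
  d <- dim(field)
  if (d[1] < 8 || d[2] < 8) stop("grid too small for directional filtering")
  W <- .direction_windows(d[1], d[2], h, n_directions, k_lowcut, k_highcut)
  out <- lapply(seq_len(n_directions), function(j) array(0 + 0i, d))
  for (s in seq_len(d[3])) {
    G <- stats::fft(field[, , s])
    for (j in seq_len(n_directions))
      out[[j]][, , s] <- stats::fft(G * W[[j]], inverse = TRUE) / (d[1] * d[2])
  }
  if (two_d) out <- lapply(out, function(a) a[, , 1])
  out
}

# In-plane gradient of the phase of a complex matrix, from wrapped one-voxel
# phase differences averaged forward/backward (exact on discrete plane
# waves). Returns |grad| in rad/m.
.phase_gradient_mag <- function(U, h) {
  nr <- nrow(U); nc <- ncol(U)
  dr <- Arg(U[-1, , drop = FALSE] * Conj(U[-nr, , drop = FALSE])) / h
  dc <- Arg(U[, -1, drop = FALSE] * Conj(U[, -nc, drop = FALSE])) / h
  gr <- (rbind(dr[1, , drop = FALSE], dr) +
         rbind(dr, dr[nr - 1, , drop = FALSE])) / 2
  gc <- (cbind(dc[, 1, drop = FALSE], dc) +
         cbind(dc, dc[, nc - 1, drop = FALSE])) / 2
  sqrt(gr^2 + gc^2)
}

#' Phase-gradient shear-wave-speed estimate for one directional field
#'
#' Estimates the local wave number as the magnitude of the in-plane phase
#' gradient of a directionally filtered harmonic field and converts it to a
#' speed, `SWS = 2 pi f / |grad phase|`. The filtered-wave amplitude is
#' returned as the compounding weight; voxels with amplitude below
#' `amplitude_floor` times the field maximum, or with speeds above
#' `sws_max` (vanishing gradient), are flagged invalid.
#'
#' @param field complex matrix or (row, col, slice) array, one direction.
#' @param freq_hz drive frequency in Hz.
#' @param voxel_size_mm voxel spacing (row, col, slice) in mm.
#' @param amplitude_floor validity floor as a fraction of the per-field
#'   maximum amplitude.
#' @param sws_max speeds above this (m/s) are treated as unreliable.
#' @return list with `sws` (m/s), `amp`, and logical `valid`, same shape as
#'   the input.
#' @export
phase_gradient_sws <- function(field, freq_hz, voxel_size_mm,
                               amplitude_floor = 0.05, sws_max = 5) {
  two_d <- is.matrix(field)
  if (two_d) field <- array(field, c(dim(field), 1L))
  if (all(field == 0)) stop("all-zero directional field")
  h <- voxel_size_mm[1] / 1000
  d <- dim(field)
  sws <- array(0, d); amp <- array(0, d)
  for (s in seq_len(d[3])) {
    U <- field[, , s]
    g <- .phase_gradient_mag(U, h)
    sws[, , s] <- ifelse(g > 0, 2 * pi * freq_hz / g, Inf)
    amp[, , s] <- abs(U)
  }
  floor_val <- amplitude_floor * max(amp)
  valid <- amp >= floor_val & is.finite(sws) & sws <= sws_max & sws > 0
  if (two_d) {
    sws <- sws[, , 1]; amp <- amp[, , 1]; valid <- valid[, , 1]
  }
  list(sws = sws, amp = amp, valid = valid)
}

#' Amplitude-weighted compounding of per-direction SWS maps
#'
#' Weighted average of per-direction/component/frequency speed maps at each
#' voxel, using the filtered-wave amplitudes as weights and skipping invalid
#' contributions. Voxels with no valid contribution are set to 0 and
#' flagged.
#'
#' @param sws_maps,amp_maps,valid_maps lists of same-shaped arrays.
#' @return list with `sws`, integer `n_valid`, and logical `flagged`
#'   (no valid contribution).
#' @export
compound_sws <- function(sws_maps, amp_maps, valid_maps) {
  stopifnot(length(sws_maps) >= 1,
            length(sws_maps) == length(amp_maps),
            length(sws_maps) == length(valid_maps))
  d <- dim(sws_maps[[1]])
  num <- array(0, d); den <- array(0, d); nv <- array(0L, d)
  for (i in seq_along(sws_maps)) {
    if (!identical(dim(sws_maps[[i]]), d))
      stop("shape mismatch among compounded maps")
    w <- amp_maps[[i]] * valid_maps[[i]]
    num <- num + w * sws_maps[[i]]
    den <- den + w
    nv <- nv + valid_maps[[i]]
  }
  flagged <- den == 0
  sws <- ifelse(flagged, 0, num / pmax(den, .Machine$double.xmin))
  list(sws = sws, n_valid = nv, flagged = flagged)
}

#' Fluidity map from the harmonic field
#'
#' Algebraic Helmholtz estimate of the phase angle of the complex shear
#' modulus: per component and frequency,
#' `G* = -rho omega^2 u / laplacian(u)`, and the per-voxel fluidity is the
#' argument of the magnitude-weighted aggregate of numerator times
#' conjugate denominator over the 3 components and all frequencies, clipped
#' to `[0, pi/2)`. The harmonic field is low-pass smoothed (in-plane
#' Gaussian, `smooth_sigma` voxels) before the Laplacian, which suppresses
#' the strong noise amplification of the second derivative and leaves plane
#' waves (and hence the closed-form oracle) unchanged. The Laplacian is
#' taken in-plane with physical spacing; grid-edge voxels carry no
#' contribution.
#'
#' @param hf a `harmonic_field` object.
#' @param rho tissue density in kg/m^3.
#' @param smooth_sigma in-plane Gaussian smoothing of the harmonic field in
#'   voxels (0 disables).
#' @return list with `phi` (rad, clipped to `[0, pi/2)`) and logical
#'   `valid`, both (row, col, slice).
#' @export
estimate_fluidity <- function(hf, rho = 1000, smooth_sigma = 1) {
  stopifnot(inherits(hf, "harmonic_field"))
  h <- hf$voxel_size_mm[1] / 1000
  d <- dim(hf$u)
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  Z <- array(0 + 0i, c(nr, nc, ns))
  any_lap <- FALSE
  if (smooth_sigma > 0) {
    Sr <- gauss_smooth_matrix(nr, smooth_sigma)
    Sc <- t(gauss_smooth_matrix(nc, smooth_sigma))
  }
  for (comp in seq_len(d[4])) for (fi in seq_len(d[5])) {
    w2 <- (2 * pi * hf$frequencies_hz[fi])^2
    for (s in seq_len(ns)) {
      U <- hf$u[, , s, comp, fi]
      if (smooth_sigma > 0)
        U <- (Sr %*% Re(U) %*% Sc) + 1i * (Sr %*% Im(U) %*% Sc)
      L <- matrix(0 + 0i, nr, nc)
      L[2:(nr - 1), 2:(nc - 1)] <-
        (U[1:(nr - 2), 2:(nc - 1)] + U[3:nr, 2:(nc - 1)] +
         U[2:(nr - 1), 1:(nc - 2)] + U[2:(nr - 1), 3:nc] -
         4 * U[2:(nr - 1), 2:(nc - 1)]) / h^2
      # flat fields give a Laplacian at rounding level only
      if (max(Mod(L)) * h^2 > 1e-10 * max(Mod(U), 1e-300)) any_lap <- TRUE
      Z[, , s] <- Z[, , s] + (-rho * w2 * U) * Conj(L)
    }
  }
  if (!any_lap) stop("all-zero Laplacian: field is flat")
  phi <- Arg(Z)
  valid <- abs(Z) > 0
  phi[!valid] <- 0
  phi <- pmin(pmax(phi, 0), pi / 2 - 1e-9)
  list(phi = phi, valid = valid)
}

#' Invert a wave field into SWS and fluidity maps
#'
#' Full tomoelastography-style reconstruction: temporal harmonic extraction,
#' per-slice directional k-space filtering into `n_directions` sectors,
#' per-direction phase-gradient speed estimation, amplitude-weighted
#' compounding over directions x components x frequencies (216 maps per
#' slice at the defaults), and Helmholtz-based fluidity estimation.
#'
#' @param wf a `wave_field` object.
#' @param n_directions number of angular filter sectors.
#' @param c_max speeds above this (m/s) are treated as compression-wave
#'   leakage: the radial low cut is `2 pi f / c_max`, and per-direction
#'   estimates above `c_max` (out of band) are discarded.
#' @param k_highcut radial high cut in rad/m; default in-plane Nyquist.
#' @param amplitude_floor validity floor, as a fraction of the maximum
#'   filtered amplitude over all directions of a (component, frequency,
#'   slice); voxels below it mirror "insufficient wave excitation".
#' @param rho tissue density, kg/m^3.
#' @return an object of class `elastogram`: list with `sws_mps`, `phi_rad`,
#'   `n_valid`, `flagged`, `voxel_size_mm`, and `provenance` (counts of
#'   compounded maps per slice).
#' @export
invert_subject <- function(wf, n_directions = 12L, c_max = 4.0,
                           k_highcut = NULL, amplitude_floor = 0.05,
                           rho = 1000) {
  stopifnot(inherits(wf, "wave_field"))
  hf <- extract_harmonic(wf)
  d <- dim(hf$u)
  nr <- d[1]; nc <- d[2]; ns <- d[3]; ncomp <- d[4]; nf <- d[5]
  h <- wf$voxel_size_mm[1] / 1000
  if (is.null(k_highcut)) k_highcut <- pi / h
  num <- array(0, c(nr, nc, ns)); den <- array(0, c(nr, nc, ns))
  nv <- array(0L, c(nr, nc, ns))
  for (fi in seq_len(nf)) {
    f <- hf$frequencies_hz[fi]
    k_low <- 2 * pi * f / c_max
    W <- .direction_windows(nr, nc, h, n_directions, k_low, k_highcut)
    for (comp in seq_len(ncomp)) for (s in seq_len(ns)) {
      U <- hf$u[, , s, comp, fi]
      if (all(U == 0)) next
      G <- stats::fft(U)
      Uds <- lapply(W, function(w) stats::fft(G * w, inverse = TRUE) /
                                   (nr * nc))
      floor_val <- amplitude_floor *
        max(vapply(Uds, function(u) max(abs(u)), numeric(1)))
      for (j in seq_len(n_directions)) {
        Ud <- Uds[[j]]
        g <- .phase_gradient_mag(Ud, h)
        amp <- abs(Ud)
        sws <- ifelse(g > 0, 2 * pi * f / g, Inf)
        ok <- amp >= floor_val & is.finite(sws) & sws <= c_max & sws > 0
        w <- amp * ok
        num[, , s] <- num[, , s] + w * ifelse(ok, sws, 0)
        den[, , s] <- den[, , s] + w
        nv[, , s] <- nv[, , s] + ok
      }
    }
  }
  flagged <- den == 0
  sws <- ifelse(flagged, 0, num / pmax(den, .Machine$double.xmin))
  fl <- estimate_fluidity(hf, rho = rho)
  structure(list(sws_mps = sws, phi_rad = fl$phi, n_valid = nv,
                 flagged = flagged, phi_valid = fl$valid,
                 voxel_size_mm = wf$voxel_size_mm,
                 provenance = list(n_directions = as.integer(n_directions),
                                   n_components = ncomp,
                                   n_frequencies = nf,
                                   n_compounded = as.integer(n_directions) *
                                     ncomp * nf)),
            class = "elastogram")
}
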