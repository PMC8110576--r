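#' Phantom specification for synthetic liver MRE
#'
#' Describes the acquisition geometry and the ground-truth mechanical
#' properties of a synthetic liver phantom. The defaults mirror a typical
#' abdominal multifrequency MRE protocol: 9 axial slices on a 100 x 78
#' in-plane matrix with 3 x 3 x 5 mm voxels, six drive frequencies between
#' 35 and 60 Hz, and 8 time offsets sampling one vibration period.
#'
#' Two disease archetypes are available. `"heterogeneous_focal"` places
#' smooth-edged focal lesions of elevated shear-wave speed (SWS) inside the
#' liver, emulating the patchy fibrosis pattern of cholestatic disease such
#' as primary sclerosing cholangitis. `"homogeneous_diffuse"` modulates the
#' parenchyma with a fine-grained smooth random texture, emulating the
#' spatially uniform stiffening typical of viral hepatitis. In both cases
#' `target_cv_percent`, when set, standardises the spatial texture so that
#' over the parenchyma (liver minus vessels) the ground-truth SWS mean
#' equals `background_sws_mps` and the coefficient of variation
#' (CV = 100 * SD / mean) equals the requested value.
#'
#' @param grid_shape integer vector (slices, rows, cols).
#' @param voxel_size_mm numeric vector (row, col, slice) spacing in mm;
#'   the first two entries are the in-plane spacing and must be equal.
#' @param frequencies_hz vibration drive frequencies in Hz.
#' @param n_offsets number of time offsets over one vibration period.
#' @param archetype `"heterogeneous_focal"` or `"homogeneous_diffuse"`.
#' @param background_sws_mps parenchymal SWS level in m/s; with a CV target
#'   set this is the exact parenchymal mean, otherwise the background value
#'   outside lesions.
#' @param lesion_fraction fraction of the liver covered by focal stiffened
#'   regions (heterogeneous archetype only), in `[0, 1]`.
#' @param lesion_contrast relative SWS elevation in lesions (> -1); ignored
#'   when `target_cv_percent` is set.
#' @param target_cv_percent optional ground-truth parenchymal CV in percent;
#'   the spatial contrast is solved for exactly.
#' @param phi_background_rad fluidity (phase angle of the complex shear
#'   modulus) of the parenchyma, in `[0, pi/2)`; 0 is a pure solid.
#' @param vessel_count number of vessel-like low-SWS tubes inside the liver.
#' @param vessel_sws_mps SWS inside vessels (m/s); below the 1 m/s VOI
#'   threshold so vessels are excluded downstream.
#' @param noise_sigma SD of additive Gaussian displacement noise, as a
#'   fraction of the mean wave amplitude inside the body.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(9L, 78L, 100L),
                         voxel_size_mm = c(3, 3, 5),
                         frequencies_hz = c(35, 40, 45, 50, 55, 60),
                         n_offsets = 8L,
                         archetype = c("heterogeneous_focal",
                                       "homogeneous_diffuse"),
                         background_sws_mps = 1.84,
                         lesion_fraction = 0.4,
                         lesion_contrast = 0.5,
                         target_cv_percent = NULL,
                         phi_background_rad = 0.49,
                         vessel_count = 3L,
                         vessel_sws_mps = 0.5,
                         noise_sigma = 0.05,
                         seed = 1L) {
  archetype <- match.arg(archetype)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            length(frequencies_hz) >= 1, all(frequencies_hz > 0),
            n_offsets >= 3, background_sws_mps > 0,
            lesion_contrast > -1,
            phi_background_rad >= 0, phi_background_rad < pi / 2,
            vessel_count >= 0, vessel_sws_mps > 0, noise_sigma >= 0)
  if (abs(voxel_size_mm[1] - voxel_size_mm[2]) > 1e-9)
    stop("in-plane voxel spacing must be isotropic")
  if (lesion_fraction < 0 || lesion_fraction > 1)
    stop("lesion_fraction must lie in [0, 1]")
  if (!is.null(target_cv_percent) && target_cv_percent < 0)
    stop("target_cv_percent must be nonnegative")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 frequencies_hz = as.numeric(frequencies_hz),
                 n_offsets = as.integer(n_offsets),
                 archetype = archetype,
                 background_sws_mps = background_sws_mps,
                 lesion_fraction = lesion_fraction,
                 lesion_contrast = lesion_contrast,
                 target_cv_percent = target_cv_percent,
                 phi_background_rad = phi_background_rad,
                 vessel_count = as.integer(vessel_count),
                 vessel_sws_mps = vessel_sws_mps,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalised lesion/texture field B on [row, col, slice]; contrast enters as
# sws = background * (1 + c * B).
.phantom_texture <- function(spec, liver_mask) {
  d <- dim(liver_mask)
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  B <- array(0, d)
  if (spec$archetype == "heterogeneous_focal") {
    if (spec$lesion_fraction == 0) return(B)
    liv_idx <- which(liver_mask, arr.ind = TRUE)
    n_liver <- nrow(liv_idx)
    # confluent lobar/segmental regions of stiffening, large relative to
    # the drive wavelengths (~45-80 mm) so the inversion can resolve them
    vox <- spec$voxel_size_mm
    mean_r_mm <- 60
    mean_vol_vox <- (4 / 3) * pi * mean_r_mm^3 / prod(vox)
    n_lesions <- max(1L, round(spec$lesion_fraction * n_liver / mean_vol_vox))
    rr <- array(rep(seq_len(nr), nc * ns), d) * vox[1]
    cc <- array(rep(rep(seq_len(nc), each = nr), ns), d) * vox[2]
    ss <- array(rep(seq_len(ns), each = nr * nc), d) * vox[3]
    for (l in seq_len(n_lesions)) {
      ctr <- liv_idx[sample.int(n_liver, 1L), ]
      r_mm <- stats::runif(1, 0.8, 1.2) * mean_r_mm
      d2 <- (rr - ctr[1] * vox[1])^2 + (cc - ctr[2] * vox[2])^2 +
            (ss - ctr[3] * vox[3])^2
      B[d2 <= r_mm^2] <- 1
    }
    B <- gauss_smooth_3d(B, c(2, 2, 0.7))
  } else {
    # smooth Gaussian random field with multi-centimetre correlation length
    # (diffuse texture at a scale the drive wavelengths can resolve)
    g <- array(stats::rnorm(prod(d)), d)
    B <- gauss_smooth_3d(g, c(9, 9, 1.8))
  }
  B
}

#' Generate ground-truth viscoelastic liver maps
#'
#' Builds the ground truth a synthetic MRE experiment is scored against:
#' voxelwise true shear-wave speed and fluidity, a simply-connected
#' ellipsoidal liver mask inside a larger body ellipse, and vessel-like
#' low-SWS tubular structures. When `spec$target_cv_percent` is set, the
#' texture field `B` is standardised to zero mean and unit SD over the
#' parenchyma and the SWS field is `mu * (1 + cv * B_std)`, so the
#' parenchymal mean equals `background_sws_mps` and the parenchymal CV
#' equals the target exactly (up to a `+/- 3 SD` clip that protects
#' positivity).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `ground_truth_maps`: a list with 3-D arrays
#'   `sws_true_mps` and `phi_true_rad` (indexed row, col, slice), logical
#'   arrays `liver_mask`, `vessel_mask`, `body_mask`, plus `voxel_size_mm`
#'   and the originating `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  ns <- spec$grid_shape[1]; nr <- spec$grid_shape[2]; nc <- spec$grid_shape[3]
  d <- c(nr, nc, ns)

  body <- array(FALSE, d)
  liver <- array(FALSE, d)
  body2d <- ellipse_mask(nr, nc, c((nr + 1) / 2, (nc + 1) / 2),
                         c(0.47 * nr, 0.48 * nc))
  liv_ctr <- c((nr + 1) / 2, (nc + 1) / 2 - 0.03 * nc)
  mid <- (ns + 1) / 2
  for (s in seq_len(ns)) {
    body[, , s] <- body2d
    scale <- sqrt(max(0, 1 - ((s - mid) / (0.72 * ns))^2))
    if (scale > 0)
      liver[, , s] <- ellipse_mask(nr, nc, liv_ctr,
                                   scale * c(0.31 * nr, 0.33 * nc))
  }
  liver <- liver & body

  # vessels: tubes along random mostly-in-plane directions
  vessel <- array(FALSE, d)
  if (spec$vessel_count > 0) {
    liv_idx <- which(liver, arr.ind = TRUE)
    for (v in seq_len(spec$vessel_count)) {
      ctr <- liv_idx[sample.int(nrow(liv_idx), 1L), ]
      ang <- stats::runif(1, 0, pi)
      tilt <- stats::runif(1, -0.08, 0.08)
      tt <- seq(-max(nr, nc), max(nr, nc), by = 0.5)
      pr <- round(ctr[1] + tt * cos(ang))
      pc <- round(ctr[2] + tt * sin(ang))
      ps <- round(ctr[3] + tt * tilt)
      ok <- pr >= 2 & pr <= nr - 1 & pc >= 2 & pc <= nc - 1 &
            ps >= 1 & ps <= ns
      for (dr in -1:1) for (dc in -1:1) {
        if (abs(dr) + abs(dc) == 2) next  # rounded cross-section
        ii <- cbind(pr[ok] + dr, pc[ok] + dc, ps[ok])
        vessel[ii] <- TRUE
      }
    }
    vessel <- vessel & liver
  }

  paren <- liver & !vessel
  B <- .phantom_texture(spec, liver)
  mB <- mean(B[paren]); sB <- stats::sd(B[paren])
  if (!is.null(spec$target_cv_percent)) {
    # mean-anchored field: parenchymal mean is exactly background_sws_mps
    # and the parenchymal CV is exactly the target
    cv <- spec$target_cv_percent / 100
    if (cv == 0) {
      sws <- array(spec$background_sws_mps, d)
    } else {
      if (!is.finite(sB) || sB <= 1e-9)
        stop("infeasible heterogeneity target: requested CV of ",
             spec$target_cv_percent,
             "% is unreachable with the requested lesion layout")
      Bs <- pmin(pmax((B - mB) / sB, -3), 3)
      sws <- spec$background_sws_mps * (1 + cv * Bs)
    }
  } else {
    sws <- spec$background_sws_mps * (1 + spec$lesion_contrast * B)
  }
  if (min(sws[paren]) <= 0.05)
    stop("infeasible heterogeneity target: contrast drives SWS nonpositive")

  # surrounding soft tissue and vessels
  sws[!liver] <- 1.4
  sws[!body] <- 1.4
  sws[vessel] <- spec$vessel_sws_mps
  phi <- array(0.5, d)
  phi[liver] <- spec$phi_background_rad
  phi[vessel] <- min(1.2, pi / 2 - 0.05)

  structure(list(sws_true_mps = sws, phi_true_rad = phi,
                 liver_mask = liver, vessel_mask = vessel, body_mask = body,
                 voxel_size_mm = spec$voxel_size_mm, spec = spec),
            class = "ground_truth_maps")
}

#' Ground-truth parenchymal coefficient of variation
#'
#' CV (in percent) of true SWS over liver voxels outside vessels.
#' @param gt a `ground_truth_maps` object.
#' @return CV in percent.
#' @export
phantom_cv <- function(gt) {
  v <- gt$sws_true_mps[gt$liver_mask & !gt$vessel_mask]
  100 * stats::sd(v) / mean(v)
}

# Travel-time and attenuation path-integral fields for one plane wavefront
# entering along `angle`. Outside the body the medium is uniform, so the
# exact plane-wave ramp is imposed there as a Dirichlet condition; inside
# the body the travel time is relaxed to the eikonal solution from an
# upper bound, and the attenuation integral is transported along its rays.
.wavefront_fields <- function(slow2d, aslow2d, body2d, angle, h) {
  nr <- nrow(slow2d); nc <- ncol(slow2d)
  ramp <- (matrix(seq_len(nr), nr, nc) * cos(angle) +
           matrix(seq_len(nc), nr, nc, byrow = TRUE) * sin(angle)) * h
  ramp <- ramp - min(ramp)
  out_cells <- !body2d
  s_out <- stats::median(if (any(out_cells)) slow2d[out_cells] else slow2d)
  a_out <- stats::median(if (any(out_cells)) aslow2d[out_cells] else aslow2d)
  T0 <- max(slow2d) * ramp            # upper bound on the travel time
  T0[!body2d] <- s_out * ramp[!body2d]
  # the domain-edge ring keeps its analytic value: upwind updates there
  # would otherwise see no upstream neighbour
  free <- body2d
  free[c(1, nr), ] <- FALSE
  free[, c(1, nc)] <- FALSE
  T0[!free] <- (s_out * ramp)[!free]
  T <- eikonal_relax(T0, slow2d, h, free)
  A0 <- a_out * ramp
  A <- transport_relax(A0, T, aslow2d, slow2d, h, free)
  list(T = T, A = A)
}

#' Synthesize a multifrequency MRE wave field
#'
#' Superposes damped shear waves from `n_sources` boundary directions, per
#' slice, on the ground-truth maps. Each wave enters as a plane wavefront
#' and propagates in the geometric-optics limit: its phase is
#' `2 pi f T(x)` with `T` the travel-time field solving the eikonal
#' equation `|grad T| = 1 / sws_true` (so the local wave number magnitude
#' is exactly `k = 2 pi f / sws_true`), and its log-amplitude is the path
#' integral of the attenuation `alpha = k * tan(phi_true / 2)` along the
#' rays (the plane-wave consequence of the fluidity being the phase angle
#' of the complex shear modulus). Time offsets sample
#' `u(x, t) = Re[U(x) exp(-i 2 pi f t)]` at `n_offsets` uniform phases over
#' one period; seeded Gaussian noise with SD `noise_sigma` (fraction of the
#' mean amplitude) is added inside the body.
#'
#' @param gt a `ground_truth_maps` object.
#' @param spec the [phantom_spec()] used to generate `gt`.
#' @param n_sources number of wave sources (distinct propagation
#'   directions), >= 1.
#' @return an object of class `wave_field`: list with `displacement`, a real
#'   array indexed (row, col, slice, component, frequency, offset), plus
#'   `frequencies_hz`, `voxel_size_mm`, `n_offsets`, `body_mask`.
#' @export
synthesize_wavefield <- function(gt, spec, n_sources = 8L) {
  stopifnot(inherits(gt, "ground_truth_maps"), n_sources >= 1)
  if (!any(gt$liver_mask)) stop("empty liver mask")
  set.seed(spec$seed + 1L)
  d <- dim(gt$sws_true_mps)
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  h <- spec$voxel_size_mm[1] / 1000  # in-plane spacing in m
  freqs <- spec$frequencies_hz
  nf <- length(freqs); nt <- spec$n_offsets

  slow <- 1 / gt$sws_true_mps                 # s/m
  aslow <- slow * tan(gt$phi_true_rad / 2)    # attenuation per rad of phase

  angles <- 2 * pi * (seq_len(n_sources) - 1) / n_sources + 0.4
  # per-source, per-component polarisation amplitudes (z strongest)
  comp_amp <- matrix(stats::runif(3 * n_sources, 0.4, 1.0), 3, n_sources)
  comp_amp[3, ] <- 1

  U <- array(0 + 0i, c(nr, nc, ns, 3, nf))
  for (s in seq_len(ns)) {
    for (j in seq_len(n_sources)) {
      fld <- .wavefront_fields(slow[, , s], aslow[, , s], gt$body_mask[, , s],
                               angles[j], h)
      for (fi in seq_len(nf)) {
        w <- 2 * pi * freqs[fi]
        Wjf <- exp(-w * fld$A + 1i * w * fld$T)
        m <- max(abs(Wjf)[gt$body_mask[, , s]])
        if (m > 0) Wjf <- Wjf / m
        for (comp in 1:3)
          U[, , s, comp, fi] <- U[, , s, comp, fi] + comp_amp[comp, j] * Wjf
      }
    }
  }
  body <- array(gt$body_mask, c(d, 3, nf))
  U[!body] <- 0

  disp <- array(0, c(nr, nc, ns, 3, nf, nt))
  ph <- exp(-2i * pi * (seq_len(nt) - 1) / nt)
  for (t in seq_len(nt)) disp[, , , , , t] <- Re(U * ph[t])

  if (spec$noise_sigma > 0) {
    amp0 <- mean(abs(U)[body])
    noise <- array(0, dim(disp))
    nin <- array(gt$body_mask, dim(disp))
    noise[nin] <- stats::rnorm(sum(nin), sd = spec$noise_sigma * amp0)
    disp <- disp + noise
  }

  structure(list(displacement = disp, frequencies_hz = freqs,
                 voxel_size_mm = spec$voxel_size_mm, n_offsets = nt,
                 body_mask = gt$body_mask),
            class = "wave_field")
}
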