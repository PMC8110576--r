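# Inversion operators against closed-form oracles: harmonic extraction,
# directional filtering, phase-gradient speeds, compounding, fluidity.

test_that("harmonic extraction recovers amplitude and phase", {
  nt <- 8
  t_j <- (seq_len(nt) - 1) / nt
  mk_wf <- function(samples) {
    disp <- array(0, c(2, 2, 1, 3, 1, nt))
    for (j in seq_len(nt)) disp[, , , , , j] <- samples[j]
    structure(list(displacement = disp, frequencies_hz = 50,
                   voxel_size_mm = c(3, 3, 5), n_offsets = nt,
                   body_mask = array(TRUE, c(2, 2, 1))),
              class = "wave_field")
  }
  A <- 1.7; theta <- 0.8
  hf <- extract_harmonic(mk_wf(A * cos(2 * pi * t_j + theta)))
  expect_equal(Mod(hf$u[1, 1, 1, 1, 1]), A, tolerance = 1e-12)
  expect_equal(Arg(hf$u[1, 1, 1, 1, 1]), theta, tolerance = 1e-12)
  # DC input has no fundamental
  hf0 <- extract_harmonic(mk_wf(rep(3, nt)))
  expect_equal(Mod(hf0$u[1, 1, 1, 1, 1]), 0, tolerance = 1e-12)
  # a 2nd harmonic does not leak into the fundamental bin
  hf2 <- extract_harmonic(mk_wf(2 * cos(2 * pi * t_j) +
                                  cos(4 * pi * t_j + 0.3)))
  expect_equal(Mod(hf2$u[1, 1, 1, 1, 1]), 2, tolerance = 1e-12)
  expect_error(extract_harmonic(
    structure(list(displacement = array(0, c(2, 2, 1, 3, 1, 2)),
                   frequencies_hz = 50, voxel_size_mm = c(3, 3, 5),
                   n_offsets = 2), class = "wave_field")), "3 uniform")
})

test_that("angular windows partition unity and the bank reconstructs", {
  set.seed(1)
  U <- matrix(complex(real = rnorm(64 * 48), imaginary = rnorm(64 * 48)),
              64, 48)
  bank <- directional_filter_bank(U, c(3, 3, 5), n_directions = 12)
  expect_length(bank, 12)
  rec <- Reduce(`+`, bank)
  rms <- sqrt(mean(Mod(rec - U)^2)) / sqrt(mean(Mod(U)^2))
  expect_lt(rms, 0.01)
  expect_error(directional_filter_bank(U, c(3, 3, 5), n_directions = 3))
  expect_error(directional_filter_bank(U[1:4, 1:4], c(3, 3, 5)),
               "too small")
})

test_that("a plane wave lands in the sector containing its direction", {
  h <- 0.003
  k <- 2 * pi * 50 / 1.5
  U <- plane_wave(64, 64, h, k, angle = 0)   # propagates along +row
  bank <- directional_filter_bank(U, c(3, 3, 5), n_directions = 12)
  energy <- vapply(bank, function(b) sum(Mod(b)^2), numeric(1))
  # U = exp(-i k x): spectral peak at -k, i.e. the sector containing -row
  expect_gt(max(energy) / sum(energy), 0.9)
})

test_that("phase-gradient speed is exact on discrete plane waves", {
  h <- 0.003
  for (f in c(35, 40, 45, 50, 55, 60)) {
    for (c0 in c(1.5, 2.0)) {
      k <- 2 * pi * f / c0
      U <- plane_wave(60, 70, h, k, angle = 0.5)
      res <- phase_gradient_sws(U, f, c(3, 3, 5), sws_max = 5)
      expect_lt(max(abs(res$sws[3:58, 3:68] - c0)) / c0, 0.01)
    }
  }
  # |grad phase| worked value: c = 2.0 m/s at 40 Hz -> 40 pi rad/m
  U <- plane_wave(60, 70, h, 2 * pi * 40 / 2.0, angle = 0)
  res <- phase_gradient_sws(U, 40, c(3, 3, 5))
  expect_equal(2 * pi * 40 / res$sws[30, 35], 40 * pi, tolerance = 1e-6)
  expect_error(phase_gradient_sws(matrix(0 + 0i, 10, 10), 50, c(3, 3, 5)),
               "all-zero")
})

test_that("amplitude of a decaying wave is monotone along propagation", {
  h <- 0.003
  k <- 2 * pi * 50 / 1.5
  U <- plane_wave(40, 60, h, k, alpha = 0.2 * k, angle = 0)
  res <- phase_gradient_sws(U, 50, c(3, 3, 5))
  expect_true(all(diff(res$amp[, 10]) < 0))
})

test_that("compounding is an amplitude-weighted mean with flagging", {
  d <- c(4, 4, 1)
  one <- function(v) array(v, d)
  # identical maps stay identical
  res <- compound_sws(list(one(1.8), one(1.8)), list(one(1), one(2)),
                      list(one(TRUE), one(TRUE)))
  expect_equal(unique(as.vector(res$sws)), 1.8)
  # weighted arithmetic: values 1 and 2, weights 1 and 3 -> 1.75
  res <- compound_sws(list(one(1), one(2)), list(one(1), one(3)),
                      list(one(TRUE), one(TRUE)))
  expect_equal(unique(as.vector(res$sws)), 1.75)
  # invalid everywhere -> flagged zeros
  res <- compound_sws(list(one(1)), list(one(1)), list(one(FALSE)))
  expect_true(all(res$flagged))
  expect_true(all(res$sws == 0))
  expect_error(compound_sws(list(one(1), array(1, c(3, 3, 1))),
                            list(one(1), array(1, c(3, 3, 1))),
                            list(one(TRUE), array(TRUE, c(3, 3, 1)))),
               "shape mismatch")
})

test_that("fluidity estimator matches the damped plane-wave closed form", {
  h <- 0.003
  k <- 2 * pi * 50 / 1.5
  # lossless wave: phi = 0
  hf <- as_harmonic(plane_wave(60, 70, h, k, alpha = 0, angle = 0.4), 50)
  fl <- estimate_fluidity(hf)
  expect_lt(median(fl$phi[10:50, 10:60, 1]), 0.005)
  # attenuation chosen for phi_true = 0.25
  phi_t <- 0.25
  hf <- as_harmonic(plane_wave(60, 70, h, k, alpha = k * tan(phi_t / 2),
                               angle = 0.4), 50)
  fl <- estimate_fluidity(hf)
  expect_lt(abs(median(fl$phi[10:50, 10:60, 1]) - phi_t), 0.02)
  # clipping contract: never reaches pi/2
  expect_true(all(fl$phi < pi / 2))
  expect_error(estimate_fluidity(as_harmonic(matrix(1 + 0i, 20, 20), 50)),
               "flat")
})

test_that("invert_subject composes, is idempotent, and counts provenance", {
  spec <- phantom_spec(grid_shape = c(1L, 78L, 100L),
                       archetype = "homogeneous_diffuse",
                       lesion_contrast = 0, vessel_count = 0,
                       noise_sigma = 0, background_sws_mps = 1.84,
                       phi_background_rad = 0.5, seed = 5)
  gt <- make_phantom(spec)
  wf <- synthesize_wavefield(gt, spec, n_sources = 4)
  e1 <- invert_subject(wf)
  e2 <- invert_subject(wf)
  expect_identical(e1$sws_mps, e2$sws_mps)
  expect_identical(e1$phi_rad, e2$phi_rad)
  expect_equal(e1$provenance$n_compounded,
               12 * 3 * length(spec$frequencies_hz))
  voi <- gt$liver_mask & e1$sws_mps >= 1
  expect_lt(abs(mean(e1$sws_mps[voi]) - 1.84) / 1.84, 0.05)
  expect_lt(abs(mean(e1$phi_rad[voi]) - 0.5), 0.05)
})

test_that("reconstructed mean increases with true speed", {
  means <- vapply(c(1.5, 1.8, 2.1), function(c0) {
    spec <- small_spec(archetype = "homogeneous_diffuse",
                       lesion_contrast = 0, vessel_count = 0,
                       noise_sigma = 0, background_sws_mps = c0, seed = 6)
    gt <- make_phantom(spec)
    wf <- synthesize_wavefield(gt, spec, n_sources = 4)
    e <- invert_subject(wf)
    mean(e$sws_mps[gt$liver_mask & e$sws_mps > 0])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
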