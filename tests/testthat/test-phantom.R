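# Phantom generator: geometry invariants, CV targeting, determinism, and
# the closed-form structure of the synthesized wave fields.

test_that("phantom_spec validates its inputs", {
  expect_error(phantom_spec(lesion_fraction = 1.2), "lesion_fraction")
  expect_error(phantom_spec(lesion_fraction = -0.1), "lesion_fraction")
  expect_error(phantom_spec(target_cv_percent = -5), "target_cv_percent")
  expect_error(phantom_spec(phi_background_rad = pi / 2))
  expect_error(phantom_spec(voxel_size_mm = c(3, 4, 5)), "isotropic")
  expect_s3_class(phantom_spec(), "phantom_spec")
})

test_that("phantom defaults mirror the acquisition geometry", {
  spec <- phantom_spec()
  expect_identical(spec$grid_shape, c(9L, 78L, 100L))
  expect_equal(spec$voxel_size_mm, c(3, 3, 5))
  expect_equal(spec$frequencies_hz, c(35, 40, 45, 50, 55, 60))
  expect_identical(spec$n_offsets, 8L)
})

test_that("masks are nested and fields are in range", {
  gt <- make_phantom(small_spec(archetype = "heterogeneous_focal",
                                target_cv_percent = 21, seed = 4))
  expect_true(all(gt$liver_mask[gt$vessel_mask]))    # vessels inside liver
  expect_true(all(gt$body_mask[gt$liver_mask]))      # liver inside body
  expect_true(all(gt$sws_true_mps[gt$liver_mask] > 0))
  expect_true(all(gt$phi_true_rad >= 0 & gt$phi_true_rad < pi / 2))
  expect_true(all(gt$sws_true_mps[gt$vessel_mask] < 1))
})

test_that("homogeneous phantom without vessels has zero parenchymal CV", {
  gt <- make_phantom(small_spec(archetype = "homogeneous_diffuse",
                                vessel_count = 0, lesion_contrast = 0,
                                background_sws_mps = 1.84, seed = 1))
  expect_equal(phantom_cv(gt), 0)
  expect_equal(unique(gt$sws_true_mps[gt$liver_mask]), 1.84)
})

test_that("CV targeting is exact and mean-anchored for both archetypes", {
  for (cfg in list(list(a = "heterogeneous_focal", cv = 21, mu = 1.70),
                   list(a = "homogeneous_diffuse", cv = 18, mu = 1.84))) {
    gt <- make_phantom(small_spec(archetype = cfg$a,
                                  target_cv_percent = cfg$cv,
                                  background_sws_mps = cfg$mu, seed = 7))
    paren <- gt$liver_mask & !gt$vessel_mask
    v <- gt$sws_true_mps[paren]
    expect_lt(abs(100 * sd(v) / mean(v) - cfg$cv), 0.5)
    expect_lt(abs(mean(v) - cfg$mu), 0.02)
  }
})

test_that("unreachable heterogeneity targets are signalled", {
  # a flat texture cannot carry any CV: force it via zero lesion fraction
  expect_error(make_phantom(small_spec(archetype = "heterogeneous_focal",
                                       lesion_fraction = 0,
                                       target_cv_percent = 21, seed = 1)),
               "infeasible heterogeneity target")
})

test_that("identical spec and seed give bit-identical phantoms and waves", {
  spec <- small_spec(archetype = "heterogeneous_focal",
                     target_cv_percent = 15, noise_sigma = 0.05, seed = 9)
  a <- make_phantom(spec); b <- make_phantom(spec)
  expect_identical(a$sws_true_mps, b$sws_true_mps)
  expect_identical(a$vessel_mask, b$vessel_mask)
  wa <- synthesize_wavefield(a, spec, n_sources = 2)
  wb <- synthesize_wavefield(b, spec, n_sources = 2)
  expect_identical(wa$displacement, wb$displacement)
})

test_that("wave field is finite, zero outside the body, periodic in time", {
  spec <- small_spec(archetype = "homogeneous_diffuse", lesion_contrast = 0,
                     vessel_count = 0, noise_sigma = 0, seed = 2)
  gt <- make_phantom(spec)
  wf <- synthesize_wavefield(gt, spec, n_sources = 2)
  expect_true(all(is.finite(wf$displacement)))
  outside <- !array(gt$body_mask, dim(wf$displacement))
  expect_true(all(wf$displacement[outside] == 0))
  expect_identical(dim(wf$displacement)[4], 3L)  # exactly 3 components
  expect_error(synthesize_wavefield(
    structure(modifyList(gt, list(liver_mask = array(FALSE, dim(gt$liver_mask)))),
              class = "ground_truth_maps"), spec), "empty liver")
})

test_that("uniform-medium wave has the closed-form phase gradient", {
  # c = 1.5 m/s, phi = 0: |grad phase| = 2 pi f / c everywhere inside
  gt <- uniform_gt(1.5, 0)
  spec <- phantom_spec(grid_shape = c(1L, 48L, 60L), frequencies_hz = 50,
                       n_offsets = 8, noise_sigma = 0, seed = 1)
  wf <- synthesize_wavefield(gt, spec, n_sources = 1)
  hf <- extract_harmonic(wf)
  res <- phase_gradient_sws(hf$u[, , 1, 3, 1], 50, spec$voxel_size_mm)
  k_expect <- 2 * pi * 50 / 1.5
  interior <- res$sws[5:44, 5:56]
  expect_lt(max(abs(interior - 1.5)) / 1.5, 0.01)
  expect_equal(2 * pi * 50 / median(interior), k_expect, tolerance = 0.01)
})

test_that("amplitude decays as exp(-k tan(phi/2) d) along propagation", {
  phi0 <- 0.4; c0 <- 1.5; f0 <- 50
  gt <- uniform_gt(c0, phi0)
  spec <- phantom_spec(grid_shape = c(1L, 48L, 60L), frequencies_hz = f0,
                       n_offsets = 8, noise_sigma = 0, seed = 1)
  wf <- synthesize_wavefield(gt, spec, n_sources = 1)
  hf <- extract_harmonic(wf)
  amp <- abs(hf$u[, , 1, 3, 1])
  k <- 2 * pi * f0 / c0
  alpha <- k * tan(phi0 / 2)
  # |grad log amplitude| equals alpha, i.e. the ratio across any distance
  # d along the propagation direction is exp(-alpha d)
  la <- log(amp)
  h <- 3e-3
  gr <- (la[3:48, ] - la[1:46, ]) / (2 * h)
  gc <- (la[, 3:60] - la[, 1:58]) / (2 * h)
  gmag <- sqrt(gr[, 2:59]^2 + gc[2:47, ]^2)
  expect_equal(median(gmag), alpha, tolerance = 0.02)
})

test_that("wave synthesis is linear in the source amplitude", {
  spec <- small_spec(archetype = "homogeneous_diffuse", lesion_contrast = 0,
                     vessel_count = 0, noise_sigma = 0, seed = 3)
  gt <- make_phantom(spec)
  wf <- synthesize_wavefield(gt, spec, n_sources = 2)
  wf2 <- wf
  wf2$displacement <- 2 * wf$displacement
  h1 <- extract_harmonic(wf); h2 <- extract_harmonic(wf2)
  expect_equal(h2$u, 2 * h1$u)
})

test_that("cohort simulation is seeded, labelled and validates sizes", {
  expect_error(simulate_cohort(0, 5), "empty group")
  a <- simulate_cohort(4, 5, seed = 11)
  b <- simulate_cohort(4, 5, seed = 11)
  expect_identical(a$params, b$params)
  expect_equal(table(a$params$group)[["PSC"]], 4)
  expect_equal(table(a$params$group)[["viral"]], 5)
  expect_true(all(a$params$ast_u_per_l > 0))
  expect_true(all(a$params$platelets_1e9_per_l > 0))
  c2 <- simulate_cohort(4, 5, seed = 12)
  expect_false(identical(a$params$sws_true, c2$params$sws_true))
})

test_that("disjoint group CV distributions separate perfectly downstream", {
  cs <- cohort_spec(psc = list(cv_mean = 30, cv_sd = 0.5),
                    viral = list(cv_mean = 10, cv_sd = 0.5))
  sim <- simulate_cohort(5, 5, cs, seed = 3)
  st <- params_to_stats(sim$params)
  a <- auc_ci(st$sws_cv[st$group == "PSC"], st$sws_cv[st$group == "viral"])
  expect_equal(a$auc, 1.0)
})
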