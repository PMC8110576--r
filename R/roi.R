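# Volume-of-interest construction and per-subject heterogeneity statistics.

#' Build the analysis volume of interest
#'
#' The VOI is the liver mask with major blood vessels and regions of
#' insufficient wave excitation excluded by a lower SWS threshold: a voxel
#' is kept iff it lies inside the liver mask and its reconstructed SWS is
#' at least `threshold_mps` (inclusive at exactly the threshold).
#'
#' @param e an `elastogram`, or any object with an `sws_mps` array.
#' @param liver_mask logical array matching the map grid.
#' @param threshold_mps lower SWS threshold in m/s.
#' @return an object of class `voi_mask`: list with logical `mask`,
#'   `voxel_count`, and `volume_cm3`.
#' @export
build_voi <- function(e, liver_mask, threshold_mps = 1.0) {
  sws <- if (is.list(e)) e$sws_mps else e
  if (!identical(dim(sws), dim(liver_mask)))
    stop("liver mask does not match the map grid")
  vox <- if (is.list(e) && !is.null(e$voxel_size_mm)) e$voxel_size_mm
         else c(3, 3, 5)
  mask <- liver_mask & sws >= threshold_mps
  n <- sum(mask)
  if (n == 0) stop("empty VOI after SWS thresholding")
  structure(list(mask = mask, voxel_count = n,
                 volume_cm3 = n * prod(vox) / 1000),
            class = "voi_mask")
}

#' Mean, SD and coefficient of variation over a VOI
#'
#' SD uses the sample (N-1) denominator; the coefficient of variation is
#' `100 * SD / mean` (percent), the per-subject intrahepatic heterogeneity
#' measure.
#'
#' @param map numeric voxel array.
#' @param voi a `voi_mask` or logical array.
#' @return list with `mean`, `sd`, `cv_percent`, `n`.
#' @export
summarize_map <- function(map, voi) {
  mask <- if (inherits(voi, "voi_mask")) voi$mask else voi
  v <- map[mask]
  if (length(v) == 0) stop("empty VOI")
  m <- mean(v)
  if (m <= 0) stop("CV undefined: VOI mean is not positive")
  s <- stats::sd(v)
  list(mean = m, sd = s, cv_percent = 100 * s / m, n = length(v))
}

#' Stage fibrosis from mean shear-wave speed
#'
#' Applies published SWS staging cutoffs: F1 (any fibrosis) >= 1.52 m/s,
#' F2 (moderate) >= 1.55 m/s, F3 (severe) >= 1.67 m/s, F4 (cirrhosis)
#' >= 1.72 m/s; all cutoffs inclusive, values below 1.52 m/s are stage 0.
#' The result is the highest stage whose cutoff does not exceed the input.
#'
#' @param sws_mean_mps positive mean SWS value(s) in m/s; vectorised.
#' @param cutoffs named increasing numeric vector of stage cutoffs (m/s).
#' @return integer stage(s) 0-4.
#' @export
stage_fibrosis <- function(sws_mean_mps,
                           cutoffs = c(F1 = 1.52, F2 = 1.55,
                                       F3 = 1.67, F4 = 1.72)) {
  if (any(sws_mean_mps <= 0)) stop("mean SWS must be positive")
  stopifnot(length(cutoffs) == 4, !is.unsorted(cutoffs))
  vapply(sws_mean_mps,
         function(x) sum(x >= cutoffs), integer(1))
}

#' Format integer stages as F0-F4 labels
#' @param stage integer vector in 0-4.
#' @return character vector `"F0"`..`"F4"`.
#' @export
stage_label <- function(stage) {
  stopifnot(all(stage %in% 0:4))
  paste0("F", stage)
}

#' Mean fibrosis stage of a cohort
#' @param stages integer vector of stages in 0-4.
#' @return arithmetic mean stage.
#' @export
mean_stage <- function(stages) {
  if (length(stages) == 0) stop("empty stage list")
  if (!all(stages %in% 0:4)) stop("stages must be integers in 0-4")
  mean(stages)
}

#' Per-subject MRE statistics within the VOI
#'
#' Combines [build_voi()], [summarize_map()] and [stage_fibrosis()] into the
#' per-subject record: mean/SD/CV of SWS and of fluidity over the common
#' VOI, the SWS-based fibrosis stage, and the VOI volume.
#'
#' @param e an `elastogram`.
#' @param liver_mask logical liver mask.
#' @param threshold_mps lower SWS threshold for the VOI (m/s).
#' @param cutoffs staging cutoffs passed to [stage_fibrosis()].
#' @return one-row data.frame with columns `sws_mean`, `sws_sd`, `sws_cv`,
#'   `phi_mean`, `phi_sd`, `phi_cv`, `stage`, `voi_cm3`.
#' @export
subject_stats <- function(e, liver_mask, threshold_mps = 1.0,
                          cutoffs = c(F1 = 1.52, F2 = 1.55,
                                      F3 = 1.67, F4 = 1.72)) {
  voi <- build_voi(e, liver_mask, threshold_mps)
  sws <- summarize_map(e$sws_mps, voi)
  phi <- summarize_map(e$phi_rad, voi)
  data.frame(sws_mean = sws$mean, sws_sd = sws$sd, sws_cv = sws$cv_percent,
             phi_mean = phi$mean, phi_sd = phi$sd, phi_cv = phi$cv_percent,
             stage = stage_fibrosis(sws$mean, cutoffs),
             voi_cm3 = voi$volume_cm3)
}
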