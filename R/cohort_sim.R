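# Cohort-level simulation: per-subject draws of mechanical and clinical
# parameters for the two disease archetypes, with optional full imaging
# (phantom + wave field) per subject.

#' Cohort distribution parameters
#'
#' Group-level generating distributions for a synthetic two-group cohort:
#' a heterogeneous cholestatic-like group (focal archetype) and a
#' homogeneous viral-hepatitis-like group (diffuse archetype). Mechanical
#' parameters are the interindividual mean and SD of the subject-mean SWS
#' and of the subject CV; clinical covariates cover the inputs of the APRI
#' and Mayo risk scores. Lab values with heavy right tails (AST, bilirubin,
#' platelets) are drawn lognormally with moments matched to the requested
#' mean and SD.
#'
#' @param psc,viral per-group lists with elements `sws_mean`, `sws_sd`
#'   (m/s), `cv_mean`, `cv_sd` (percent), `phi_mean`, `phi_sd` (rad),
#'   `phi_cv_mean`, `phi_cv_sd` (percent), `age_mean`, `age_sd` (years),
#'   `ast_mean`, `ast_sd` (U/L), `bili_mean`, `bili_sd` (mg/dL),
#'   `albumin_mean`, `albumin_sd` (g/dL), `platelets_mean`, `platelets_sd`
#'   (1e9/L), `p_variceal` (probability), `archetype`.
#' @param ast_uln upper limit of normal for AST (U/L).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(psc = list(), viral = list(), ast_uln = 40) {
  def_psc <- list(sws_mean = 1.70, sws_sd = 0.28, cv_mean = 21, cv_sd = 5,
                  phi_mean = 0.48, phi_sd = 0.10,
                  phi_cv_mean = 42, phi_cv_sd = 5,
                  age_mean = 41, age_sd = 14, ast_mean = 64, ast_sd = 56,
                  bili_mean = 1.64, bili_sd = 3.11,
                  albumin_mean = 4.0, albumin_sd = 0.5,
                  platelets_mean = 220, platelets_sd = 90,
                  p_variceal = 0.10, archetype = "heterogeneous_focal")
  def_vir <- list(sws_mean = 1.84, sws_sd = 0.38, cv_mean = 18, cv_sd = 3,
                  phi_mean = 0.50, phi_sd = 0.13,
                  phi_cv_mean = 41, phi_cv_sd = 7,
                  age_mean = 50, age_sd = 14, ast_mean = 82, ast_sd = 99,
                  bili_mean = 1.03, bili_sd = 0.63,
                  albumin_mean = 4.0, albumin_sd = 0.5,
                  platelets_mean = 170, platelets_sd = 80,
                  p_variceal = 0.04, archetype = "homogeneous_diffuse")
  structure(list(psc = utils::modifyList(def_psc, psc),
                 viral = utils::modifyList(def_vir, viral),
                 ast_uln = ast_uln),
            class = "cohort_spec")
}

# lognormal draws matched to a target mean and SD
.rlnorm_ms <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# per-subject parameter draws for one group
.draw_group <- function(n, g, group_label, ast_uln) {
  data.frame(
    group = rep(group_label, n),
    archetype = rep(g$archetype, n),
    sws_true = pmin(pmax(stats::rnorm(n, g$sws_mean, g$sws_sd), 1.15), 3.2),
    cv_true = pmin(pmax(stats::rnorm(n, g$cv_mean, g$cv_sd), 2), 40),
    phi_true = pmin(pmax(stats::rnorm(n, g$phi_mean, g$phi_sd), 0.05), 1.2),
    phi_cv_true = pmin(pmax(stats::rnorm(n, g$phi_cv_mean, g$phi_cv_sd), 2),
                       80),
    age_years = pmin(pmax(stats::rnorm(n, g$age_mean, g$age_sd), 18), 88),
    ast_u_per_l = .rlnorm_ms(n, g$ast_mean, g$ast_sd),
    ast_uln_u_per_l = rep(ast_uln, n),
    bilirubin_mg_per_dl = .rlnorm_ms(n, g$bili_mean, g$bili_sd),
    albumin_g_per_dl = pmax(stats::rnorm(n, g$albumin_mean, g$albumin_sd),
                            2.0),
    platelets_1e9_per_l = .rlnorm_ms(n, g$platelets_mean, g$platelets_sd),
    variceal_bleeding = stats::runif(n) < g$p_variceal,
    stringsAsFactors = FALSE)
}

#' Simulate a two-group cohort
#'
#' Draws per-subject mechanical parameters (mean SWS, CV, fluidity) and
#' clinical covariates from the group distributions of a [cohort_spec()].
#' With `waves = TRUE` each subject additionally gets a full phantom and
#' synthetic multifrequency wave field (the inputs of [invert_subject()]);
#' with `waves = FALSE` only the parameter table is returned, which is the
#' cheap path for statistical null studies.
#'
#' @param n_psc,n_viral group sizes, >= 1.
#' @param cspec a [cohort_spec()].
#' @param seed integer seed; everything downstream is derived from it.
#' @param waves generate imaging data per subject?
#' @param base_spec template [phantom_spec()] providing grid, frequencies
#'   and noise level for the imaging path.
#' @param n_sources wave sources per subject (imaging path).
#' @return list with `params` (per-subject data.frame incl. `id`), and when
#'   `waves = TRUE` a list `subjects` of per-subject lists
#'   `(gt, wf, clinical)`.
#' @export
simulate_cohort <- function(n_psc, n_viral, cspec = cohort_spec(),
                            seed = 1L, waves = FALSE,
                            base_spec = phantom_spec(), n_sources = 8L) {
  if (n_psc < 1 || n_viral < 1) stop("empty group")
  stopifnot(inherits(cspec, "cohort_spec"))
  set.seed(seed)
  params <- rbind(.draw_group(n_psc, cspec$psc, "PSC", cspec$ast_uln),
                  .draw_group(n_viral, cspec$viral, "viral", cspec$ast_uln))
  params$id <- sprintf("S%03d", seq_len(nrow(params)))
  params <- params[, c("id", setdiff(names(params), "id"))]
  params$subject_seed <- sample.int(.Machine$integer.max - 1000L,
                                    nrow(params))
  out <- list(params = params)
  if (waves) {
    out$subjects <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      sp <- base_spec
      sp$archetype <- p$archetype
      sp$background_sws_mps <- p$sws_true
      sp$target_cv_percent <- p$cv_true
      sp$phi_background_rad <- min(p$phi_true, pi / 2 - 0.05)
      sp$seed <- p$subject_seed
      gt <- make_phantom(sp)
      wf <- synthesize_wavefield(gt, sp, n_sources)
      list(gt = gt, wf = wf, clinical = p)
    })
  }
  out
}

#' Subject statistics implied directly by drawn cohort parameters
#'
#' Converts the per-subject generating parameters into the `SubjectStats`
#' table without imaging: the subject's SWS mean and CV are taken as drawn,
#' SDs follow from `sd = cv/100 * mean`, and the stage is assigned from the
#' mean SWS. Used for statistical null/calibration studies where the
#' imaging chain is not under test.
#'
#' @param params the `params` table of [simulate_cohort()].
#' @return data.frame in the same layout as [subject_stats()] plus `id` and
#'   `group`.
#' @export
params_to_stats <- function(params) {
  data.frame(id = params$id, group = params$group,
             sws_mean = params$sws_true,
             sws_sd = params$cv_true / 100 * params$sws_true,
             sws_cv = params$cv_true,
             phi_mean = params$phi_true,
             phi_sd = params$phi_cv_true / 100 * params$phi_true,
             phi_cv = params$phi_cv_true,
             stage = stage_fibrosis(params$sws_true),
             voi_cm3 = NA_real_,
             stringsAsFactors = FALSE)
}
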