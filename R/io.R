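# Volume and table I/O, pipeline configuration, seeded end-to-end runs and
# report generation.

#' Write a voxel map as NIfTI
#'
#' @param map numeric or logical 3-D array (row, col, slice).
#' @param spacing_mm voxel spacing (row, col, slice) in mm.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, spacing_mm, path) {
  if (length(dim(map)) != 3) stop("expected a 3-D voxel map")
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing must be 3 positive values (mm)")
  img <- RNifti::asNifti(array(as.numeric(map), dim(map)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel map from NIfTI
#'
#' @param path NIfTI file.
#' @return list with `data` (3-D array) and `spacing_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop("expected a 3-D volume in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or non-positive voxel spacing in ", path)
  list(data = array(as.numeric(img), d), spacing_mm = unname(sp))
}

#' Write a wave field as NIfTI volumes plus a sidecar
#'
#' One volume per (component, frequency) pair holding the offset-resolved
#' displacement as a 4-D NIfTI, plus a plain-text `key = value` sidecar
#' with frequencies, offsets and voxel size.
#'
#' @param wf a `wave_field`.
#' @param dir output directory (created if needed).
#' @return the sidecar path, invisibly.
#' @export
write_wavefield <- function(wf, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comps <- c("x", "y", "z")
  for (ci in 1:3) for (fi in seq_along(wf$frequencies_hz)) {
    arr <- wf$displacement[, , , ci, fi, ]
    img <- RNifti::asNifti(arr, pixdim = c(wf$voxel_size_mm, 1))
    RNifti::writeNifti(img, file.path(dir, sprintf(
      "disp_%s_%02.0fHz.nii.gz", comps[ci], wf$frequencies_hz[fi])))
  }
  sidecar <- file.path(dir, "wavefield.txt")
  writeLines(c(
    paste0("frequencies_hz = ",
           paste(wf$frequencies_hz, collapse = ",")),
    paste0("n_offsets = ", wf$n_offsets),
    paste0("voxel_size_mm = ", paste(wf$voxel_size_mm, collapse = ",")),
    "components = x,y,z"), sidecar)
  invisible(sidecar)
}

#' Read a wave field written by [write_wavefield()]
#' @param dir directory containing the volumes and `wavefield.txt`.
#' @return a `wave_field` object (without a body mask).
#' @export
read_wavefield <- function(dir) {
  sidecar <- file.path(dir, "wavefield.txt")
  if (!file.exists(sidecar)) stop("missing sidecar ", sidecar)
  kv <- strsplit(readLines(sidecar), "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  freqs <- as.numeric(strsplit(vals[["frequencies_hz"]], ",")[[1]])
  vox <- as.numeric(strsplit(vals[["voxel_size_mm"]], ",")[[1]])
  nt <- as.integer(vals[["n_offsets"]])
  comps <- strsplit(vals[["components"]], ",")[[1]]
  first <- RNifti::readNifti(file.path(dir, sprintf(
    "disp_%s_%02.0fHz.nii.gz", comps[1], freqs[1])))
  d <- dim(first)
  disp <- array(0, c(d[1:3], length(comps), length(freqs), nt))
  for (ci in seq_along(comps)) for (fi in seq_along(freqs)) {
    img <- RNifti::readNifti(file.path(dir, sprintf(
      "disp_%s_%02.0fHz.nii.gz", comps[ci], freqs[fi])))
    disp[, , , ci, fi, ] <- array(as.numeric(img), dim(img))
  }
  structure(list(displacement = disp, frequencies_hz = freqs,
                 voxel_size_mm = vox, n_offsets = nt,
                 body_mask = NULL),
            class = "wave_field")
}

#' Pipeline configuration
#'
#' All numeric defaults of the pipeline in one serialisable list: phantom
#' geometry and archetypes, inversion parameters, the staging cutoff table
#' and VOI threshold, statistics options, cohort sizes and the master seed.
#'
#' @param ... overrides of the defaults (nested lists are merged).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_psc = 20L, n_viral = 26L,
    grid_shape = c(9L, 78L, 100L),
    voxel_size_mm = c(3, 3, 5),
    frequencies_hz = c(35, 40, 45, 50, 55, 60),
    n_offsets = 8L,
    noise_sigma = 0.05,
    n_sources = 8L,
    n_directions = 12L,
    c_max_mps = 4.0,
    amplitude_floor = 0.05,
    voi_threshold_mps = 1.0,
    stage_cutoffs_mps = c(F1 = 1.52, F2 = 1.55, F3 = 1.67, F4 = 1.72),
    ttest = "welch",
    ci_method = "delong",
    conf_level = 0.95,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- utils::modifyList(cfg, over)
  stopifnot(cfg$voi_threshold_mps > 0, length(cfg$stage_cutoffs_mps) == 4,
            cfg$ttest %in% c("welch", "student"))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (lossless YAML round trip)
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
config_write <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- unclass(cfg)
  lst$stage_cutoffs_mps <- as.list(cfg$stage_cutoffs_mps)  # keep names
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$stage_cutoffs_mps <- unlist(cfg$stage_cutoffs_mps)
  do.call(pipeline_config, cfg)
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the full pipeline: simulate, invert, analyze, compare
#'
#' Simulates a two-group cohort, reconstructs each subject's SWS and
#' fluidity maps, computes VOI statistics and fibrosis stages, and builds
#' the cohort comparison table. Everything is derived from the config and
#' its seed; two runs with identical config produce bit-identical CSV
#' outputs. Artifacts written to the run directory: `config.yaml`,
#' `manifest.txt`, `run.log`, `subject_stats.csv`, `clinical.csv`,
#' `cohort_summary.csv`, `test_results.csv`, `correlations.csv`,
#' `auc.csv`, and per-subject `maps/<id>_{sws,phi,mask}.nii.gz`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; must be writable).
#' @param write_maps write per-subject NIfTI maps?
#' @return `out_dir`, invisibly.
#' @export
run_end_to_end <- function(config = pipeline_config(), out_dir,
                           write_maps = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create run directory ", out_dir)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  config_write(config, file.path(out_dir, "config.yaml"))
  cfg_hash <- sum(utf8ToInt(paste(deparse(unclass(config)),
                                  collapse = ""))) %% 100000L
  writeLines(c(paste0("config_hash = ", cfg_hash),
               paste0("seed = ", config$seed),
               paste0("stages = simulate, invert, analyze, cohort")),
             file.path(out_dir, "manifest.txt"))

  stage <- "simulate"
  res <- tryCatch({
    base_spec <- phantom_spec(grid_shape = config$grid_shape,
                              voxel_size_mm = config$voxel_size_mm,
                              frequencies_hz = config$frequencies_hz,
                              n_offsets = config$n_offsets,
                              noise_sigma = config$noise_sigma,
                              seed = config$seed)
    sim <- simulate_cohort(config$n_psc, config$n_viral,
                           seed = config$seed, waves = TRUE,
                           base_spec = base_spec,
                           n_sources = config$n_sources)
    .log_line(log_con, "simulate: ", nrow(sim$params), " subjects on grid ",
              paste(config$grid_shape, collapse = "x"))

    stage <- "invert"
    n_comp <- config$n_directions * 3 * length(config$frequencies_hz)
    .log_line(log_con, "invert: compounding ", n_comp,
              " images per slice (", config$n_directions, " directions x 3",
              " components x ", length(config$frequencies_hz),
              " frequencies)")
    if (write_maps)
      dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
    stats_rows <- vector("list", length(sim$subjects))
    for (i in seq_along(sim$subjects)) {
      sub <- sim$subjects[[i]]
      e <- invert_subject(sub$wf, n_directions = config$n_directions,
                          c_max = config$c_max_mps,
                          amplitude_floor = config$amplitude_floor)
      stage <- "analyze"
      st <- subject_stats(e, sub$gt$liver_mask,
                          threshold_mps = config$voi_threshold_mps,
                          cutoffs = config$stage_cutoffs_mps)
      st <- cbind(data.frame(id = sub$clinical$id,
                             group = sub$clinical$group,
                             stringsAsFactors = FALSE), st)
      stats_rows[[i]] <- st
      if (write_maps) {
        pre <- file.path(out_dir, "maps", sub$clinical$id)
        write_volume(e$sws_mps, config$voxel_size_mm,
                     paste0(pre, "_sws.nii.gz"))
        write_volume(e$phi_rad, config$voxel_size_mm,
                     paste0(pre, "_phi.nii.gz"))
        write_volume(sub$gt$liver_mask, config$voxel_size_mm,
                     paste0(pre, "_mask.nii.gz"))
      }
      stage <- "invert"
    }
    stats <- do.call(rbind, stats_rows)
    .log_line(log_con, "analyze: VOI stats for ", nrow(stats), " subjects; ",
              "mean VOI volume ", round(mean(stats$voi_cm3), 1), " cm3")

    stage <- "cohort"
    clinical <- sim$params[, c("id", "group", "age_years", "ast_u_per_l",
                               "ast_uln_u_per_l", "platelets_1e9_per_l",
                               "bilirubin_mg_per_dl", "albumin_g_per_dl",
                               "variceal_bleeding")]
    cr <- build_cohort_table(stats, clinical,
                             var_equal = config$ttest == "student",
                             conf_level = config$conf_level)
    .log_line(log_con, "cohort: ", nrow(cr$summary), " summary metrics, ",
              nrow(cr$tests), " tests, ", nrow(cr$auc), " AUC classifiers")
    list(stats = stats, clinical = clinical, cohort = cr)
  }, error = function(err) {
    .log_line(log_con, "ERROR in stage ", stage, ": ", conditionMessage(err))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  })

  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(res$stats, "subject_stats.csv")
  wcsv(res$clinical, "clinical.csv")
  wcsv(res$cohort$summary, "cohort_summary.csv")
  wcsv(res$cohort$tests, "test_results.csv")
  wcsv(res$cohort$correlations, "correlations.csv")
  wcsv(res$cohort$auc, "auc.csv")
  invisible(out_dir)
}

#' Render a run report
#'
#' Produces a markdown summary of a completed run directory (cohort table
#' in the seven-metric layout, staging histogram, test results) plus
#' boxplot figures of SWS and CV by group as PNG files.
#'
#' @param run_dir directory written by [run_end_to_end()].
#' @param figures also write boxplot PNGs?
#' @return path of the report file, invisibly.
#' @export
render_report <- function(run_dir, figures = TRUE) {
  f_stats <- file.path(run_dir, "subject_stats.csv")
  report <- file.path(run_dir, "report.md")
  if (!file.exists(f_stats)) stop("incomplete run directory: missing ",
                                  f_stats)
  stats <- utils::read.csv(f_stats, stringsAsFactors = FALSE)
  if (nrow(stats) == 0) {
    writeLines(c("# Cohort report", "", "No subjects in this run."), report)
    return(invisible(report))
  }
  summary <- utils::read.csv(file.path(run_dir, "cohort_summary.csv"),
                             stringsAsFactors = FALSE)
  tests <- utils::read.csv(file.path(run_dir, "test_results.csv"),
                           stringsAsFactors = FALSE)
  auc <- utils::read.csv(file.path(run_dir, "auc.csv"),
                         stringsAsFactors = FALSE)
  fmt <- function(m, s, digits = 2)
    sprintf("%.*f (%.*f)", digits, m, digits, s)
  lines <- c("# Cohort report", "",
             sprintf("Subjects: %d (PSC-like %d, viral-like %d)",
                     nrow(stats), sum(stats$group == "PSC"),
                     sum(stats$group == "viral")), "",
             "## MRE results",
             "",
             "| Metric | All | PSC | Viral |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(summary))) {
    dg <- if (summary$key[i] %in% c("sws_cv", "phi_cv")) 0 else 2
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", summary$metric[i],
                              fmt(summary$all_mean[i], summary$all_sd[i], dg),
                              fmt(summary$psc_mean[i], summary$psc_sd[i], dg),
                              fmt(summary$viral_mean[i],
                                  summary$viral_sd[i], dg)))
  }
  tab <- table(factor(stage_label(stats$stage), levels = paste0("F", 0:4)),
               stats$group)
  lines <- c(lines, "", "## Fibrosis stage distribution", "",
             "| Stage | PSC | Viral |", "|---|---|---|",
             sprintf("| %s | %d | %d |", rownames(tab), tab[, "PSC"],
                     tab[, "viral"]),
             "",
             sprintf("Mean stage: PSC %.2f, viral %.2f, all %.2f",
                     mean_stage(stats$stage[stats$group == "PSC"]),
                     mean_stage(stats$stage[stats$group == "viral"]),
                     mean_stage(stats$stage)),
             "", "## Group comparisons", "",
             "| Comparison | t | P |", "|---|---|---|",
             sprintf("| %s | %.3f | %.4f |", tests$comparison,
                     tests$statistic, tests$p),
             "", "## Diagnostic performance", "",
             "| Classifier | AUC | 95% CI |", "|---|---|---|",
             sprintf("| %s | %.3f | %.3f-%.3f |", auc$classifier, auc$auc,
                     auc$ci_lo, auc$ci_hi))
  writeLines(lines, report)
  if (figures) {
    grDevices::png(file.path(run_dir, "boxplots.png"), width = 900,
                   height = 450)
    graphics::par(mfrow = c(1, 2))
    graphics::boxplot(sws_mean ~ group, data = stats,
                      ylab = "SWS (m/s)", xlab = "")
    graphics::boxplot(sws_cv ~ group, data = stats,
                      ylab = "CV of SWS (%)", xlab = "")
    grDevices::dev.off()
  }
  invisible(report)
}
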