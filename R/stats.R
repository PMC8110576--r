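# Statistical layer: group comparisons, correlations, AUC with DeLong
# confidence intervals, and the APRI / Mayo-risk-score calculators.

#' Two-sided t-test for two groups
#'
#' Welch's unequal-variance test by default (the group sizes and variances
#' of the two disease groups differ); the pooled-variance Student variant
#' is available for sensitivity checks. Degenerate input with zero variance
#' in both groups and equal means returns `t = 0, p = 1`.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @param var_equal use pooled variance (Student) instead of Welch.
#' @return list with `t`, `df`, `p`.
#' @export
two_sided_t_test <- function(group_a, group_b, var_equal = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ht <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ht$estimate), p = unname(ht$p.value), n = length(x))
}

#' AUC with 95\% DeLong confidence interval
#'
#' The area under the ROC curve is the Mann-Whitney probability that a
#' positive-group score exceeds a negative-group score, computed from
#' ranks with ties counted one half. The confidence interval uses DeLong's
#' placement-value variance estimate (Wald interval, clipped to `[0, 1]`);
#' degenerate inputs with zero variance give a point interval.
#'
#' @param scores_pos,scores_neg numeric scores of the positive (expected
#'   higher) and negative group.
#' @param conf_level confidence level.
#' @return list with `auc`, `lo`, `hi`.
#' @export
auc_ci <- function(scores_pos, scores_neg, conf_level = 0.95) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  rk <- rank(c(scores_pos, scores_neg), ties.method = "average")
  auc <- (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  # DeLong placement values
  v10 <- vapply(scores_pos, function(x)
    mean((x > scores_neg) + 0.5 * (x == scores_neg)), numeric(1))
  v01 <- vapply(scores_neg, function(y)
    mean((scores_pos > y) + 0.5 * (scores_pos == y)), numeric(1))
  s2 <- if (n1 > 1 && n2 > 1)
    stats::var(v10) / n1 + stats::var(v01) / n2 else 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(max(s2, 0))
  list(auc = auc, lo = max(0, auc - half), hi = min(1, auc + half))
}

#' APRI: aspartate-aminotransferase-to-platelet ratio index
#'
#' `APRI = 100 * (AST / AST_ULN) / platelets(1e9/L)`. Category bands:
#' below 0.5 no significant fibrosis; 0.5 to < 1.0 cirrhosis unlikely;
#' 1.0 to < 1.5 no reliable assessment; 1.5 to 2.0 significant fibrosis;
#' above 2.0 cirrhosis (edge values assigned to the band whose printed
#' range starts there; 2.0 closes the significant-fibrosis band).
#'
#' @param ast_u_per_l AST in U/L.
#' @param ast_uln_u_per_l upper limit of normal for AST in U/L.
#' @param platelets_1e9_per_l platelet count in 1e9/L.
#' @return data.frame with `score` and `category`; vectorised.
#' @export
apri <- function(ast_u_per_l, ast_uln_u_per_l, platelets_1e9_per_l) {
  if (any(ast_u_per_l <= 0) || any(ast_uln_u_per_l <= 0) ||
      any(platelets_1e9_per_l <= 0))
    stop("APRI inputs must be positive")
  score <- 100 * (ast_u_per_l / ast_uln_u_per_l) / platelets_1e9_per_l
  category <- cut(score, c(-Inf, 0.5, 1.0, 1.5, 2.0, Inf),
                  labels = c("no significant fibrosis", "cirrhosis unlikely",
                             "no reliable assessment", "significant fibrosis",
                             "cirrhosis"),
                  right = FALSE)
  # band 1.5-2.0 is closed at 2.0; only scores strictly above 2 are
  # "cirrhosis"
  category[score == 2.0] <- "significant fibrosis"
  data.frame(score = score, category = as.character(category),
             stringsAsFactors = FALSE)
}

#' Revised Mayo risk score for primary sclerosing cholangitis
#'
#' `R = 0.03 * age + 0.54 * ln(bilirubin) + 0.54 * ln(AST)
#'    + 1.24 * (variceal bleeding) - 0.84 * albumin`
#' with age in years, bilirubin in mg/dL, AST in U/L, albumin in g/dL.
#' Risk groups: `R <= 0` low, `0 < R <= 2` intermediate, `R > 2` high
#' (the printed bands leave 2 itself open; it is assigned to intermediate).
#'
#' @param age_years,bilirubin_mg_per_dl,ast_u_per_l,albumin_g_per_dl
#'   clinical inputs; bilirubin and AST must be positive.
#' @param variceal_bleeding logical history of variceal bleeding.
#' @return data.frame with `score` and `risk_group`; vectorised.
#' @export
mayo_risk_score <- function(age_years, bilirubin_mg_per_dl, ast_u_per_l,
                            albumin_g_per_dl, variceal_bleeding) {
  if (any(bilirubin_mg_per_dl <= 0) || any(ast_u_per_l <= 0))
    stop("bilirubin and AST must be positive")
  score <- 0.03 * age_years + 0.54 * log(bilirubin_mg_per_dl) +
    0.54 * log(ast_u_per_l) + 1.24 * as.numeric(variceal_bleeding) -
    0.84 * albumin_g_per_dl
  risk_group <- ifelse(score <= 0, "low",
                       ifelse(score <= 2, "intermediate", "high"))
  data.frame(score = score, risk_group = risk_group,
             stringsAsFactors = FALSE)
}

#' Cohort summary, comparisons, correlations and diagnostic AUC
#'
#' Builds the cohort-level result set from per-subject MRE statistics and
#' clinical records: per-group mean (interindividual SD) of the seven MRE
#' metrics (SWS, SD of SWS, CV of SWS, fluidity, SD of fluidity, CV of
#' fluidity, fibrosis stage), Welch t-tests between groups, correlations
#' (SWS vs SD of SWS, SWS vs CV of SWS, APRI vs SWS, APRI vs CV of SWS per
#' group; Mayo risk score vs each MRE metric within the PSC-like group),
#' and the AUC (DeLong 95\% CI) of CV of SWS and CV of fluidity as
#' classifiers of the heterogeneous group. Group CV entries are means of
#' per-subject CVs, never a ratio of group-level summaries.
#'
#' @param stats per-subject data.frame as from [subject_stats()] with `id`
#'   and `group` columns (`group` in `c("PSC", "viral")`).
#' @param records clinical data.frame aligned by `id` with the fields of
#'   the cohort table (AST, ULN, platelets, bilirubin, albumin, age,
#'   variceal flag).
#' @param var_equal pooled-variance t-tests instead of Welch.
#' @param conf_level confidence level for the AUC interval.
#' @return an object of class `cohort_result`: list of data.frames
#'   `summary`, `tests`, `correlations`, `auc`.
#' @export
build_cohort_table <- function(stats, records, var_equal = FALSE,
                               conf_level = 0.95) {
  stopifnot(all(c("id", "group") %in% names(stats)))
  if (!all(stats$group %in% c("PSC", "viral")))
    stop("group labels must be 'PSC' or 'viral'")
  if (!is.null(records)) {
    records <- records[match(stats$id, records$id), ]
    ap <- apri(records$ast_u_per_l, records$ast_uln_u_per_l,
               records$platelets_1e9_per_l)
    mrs <- mayo_risk_score(records$age_years, records$bilirubin_mg_per_dl,
                           records$ast_u_per_l, records$albumin_g_per_dl,
                           records$variceal_bleeding)
    stats$apri <- ap$score
    stats$mrs <- mrs$score
  }
  metrics <- c(sws_mean = "SWS (m/s)", sws_sd = "SD of SWS (m/s)",
               sws_cv = "CV of SWS (%)", phi_mean = "phi (rad)",
               phi_sd = "SD of phi (rad)", phi_cv = "CV of phi (%)",
               stage = "Fibrosis stage")
  grp <- function(g) stats[stats$group == g, ]
  psc <- grp("PSC"); vir <- grp("viral")
  if (nrow(psc) < 2 || nrow(vir) < 2)
    stop("each group needs at least 2 subjects")
  msd <- function(v) c(mean(v), stats::sd(v))
  summary <- do.call(rbind, lapply(names(metrics), function(m) {
    a <- msd(stats[[m]]); p <- msd(psc[[m]]); v <- msd(vir[[m]])
    data.frame(metric = metrics[[m]], key = m,
               all_mean = a[1], all_sd = a[2],
               psc_mean = p[1], psc_sd = p[2],
               viral_mean = v[1], viral_sd = v[2],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  tests <- do.call(rbind, lapply(names(metrics), function(m) {
    tt <- two_sided_t_test(psc[[m]], vir[[m]], var_equal = var_equal)
    data.frame(comparison = paste0(m, ": PSC vs viral"),
               statistic = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  cor_pairs <- list(c("sws_mean", "sws_sd"), c("sws_mean", "sws_cv"))
  if (!is.null(records))
    cor_pairs <- c(cor_pairs, list(c("apri", "sws_mean"),
                                   c("apri", "sws_cv")))
  empty_cor <- data.frame(group = character(0), x = character(0),
                          y = character(0), r = numeric(0), p = numeric(0),
                          n = integer(0), stringsAsFactors = FALSE)
  correlations <- if (nrow(psc) < 3 || nrow(vir) < 3) empty_cor else
    do.call(rbind, lapply(cor_pairs, function(pr) {
      do.call(rbind, lapply(list(psc, vir), function(g) {
        ct <- pearson_r(g[[pr[1]]], g[[pr[2]]])
        data.frame(group = g$group[1], x = pr[1], y = pr[2],
                   r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
      }))
    }))
  if (!is.null(records) && nrow(psc) >= 3) {
    mrs_rows <- do.call(rbind, lapply(
      c("sws_mean", "sws_cv", "phi_mean", "phi_cv"), function(m) {
        ct <- pearson_r(psc$mrs, psc[[m]])
        data.frame(group = "PSC", x = "mrs", y = m,
                   r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
      }))
    correlations <- rbind(correlations, mrs_rows)
  }
  rownames(correlations) <- NULL
  auc <- do.call(rbind, lapply(c("sws_cv", "phi_cv"), function(m) {
    a <- auc_ci(psc[[m]], vir[[m]], conf_level)
    data.frame(classifier = m, auc = a$auc, ci_lo = a$lo, ci_hi = a$hi,
               stringsAsFactors = FALSE)
  }))
  rownames(auc) <- NULL
  structure(list(summary = summary, tests = tests,
                 correlations = correlations, auc = auc),
            class = "cohort_result")
}
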