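# File-level pipeline: read volumes/masks, run paired_qct, write metrics
# JSON/CSV, label maps, overlays and a reproducibility manifest. The CLI
# in inst/cli/airtrap.R is a thin wrapper over this function and the
# other exported operations; no computation lives in the CLI layer.

#' Run the full per-subject pipeline on files
#'
#' Reads the inspiratory and expiratory volumes (NIfTI or DICOM series),
#' loads or computes lung masks, registers, quantifies and maps, then
#' writes `metrics.json`, `metrics.csv`, PRM/ATI label maps (NIfTI), an
#' axial overlay PNG per map, the transform as plain text, and
#' `manifest.json` recording the resolved configuration. Deterministic:
#' rerunning with identical inputs and configuration reproduces the same
#' metrics.
#'
#' @param insp_path,exp_path Paths to the scans.
#' @param insp_mask_path,exp_mask_path Optional NIfTI mask paths; when
#'   `NULL` the threshold segmenter is used.
#' @param out_dir Output directory (created if missing).
#' @param config A [registration_config()].
#' @param prm,ati Threshold configurations as in [paired_qct()].
#' @param air_threshold Segmentation threshold when masks are computed.
#' @return Invisibly, the `paired_qct` object.
#' @export
run_pipeline <- function(insp_path, exp_path, insp_mask_path = NULL,
                         exp_mask_path = NULL, out_dir = ".",
                         config = registration_config(),
                         prm = prm_thresholds(), ati = ati_config(),
                         air_threshold = -320) {
  for (p in c(insp_path, exp_path, insp_mask_path, exp_mask_path))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  insp <- read_volume(insp_path)
  exp <- read_volume(exp_path)
  insp_mask <- if (is.null(insp_mask_path))
    segment_lungs_threshold(insp, air_threshold)
  else load_mask(insp_mask_path, insp)
  exp_mask <- if (is.null(exp_mask_path))
    segment_lungs_threshold(exp, air_threshold)
  else load_mask(exp_mask_path, exp)

  fit <- paired_qct(insp, exp, insp_mask, exp_mask, config = config,
                    prm = prm, ati = ati)

  metrics <- fit$metrics
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(metrics),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write_volume(fit$prm$map, file.path(out_dir, "prm_map.nii.gz"))
  write_volume(fit$ati$map, file.path(out_dir, "ati_map.nii.gz"))
  write_transform(fit$study$transform,
                  file.path(out_dir, "transform.txt"))
  d <- dim(fit$prm$map$data)
  render_overlay(fit$study, fit$prm$map, 3, ceiling(d[3] / 2),
                 path = file.path(out_dir, "prm_overlay.png"))
  render_overlay(fit$study, fit$ati$map, 3, ceiling(d[3] / 2),
                 path = file.path(out_dir, "ati_overlay.png"))
  manifest <- list(
    inputs = list(insp = insp_path, exp = exp_path,
                  insp_mask = insp_mask_path, exp_mask = exp_mask_path),
    config = list(
      registration = unclass(config), prm = unclass(prm),
      ati = unclass(ati), air_threshold = air_threshold),
    registration = list(
      mi_initial = attr(fit$study$transform, "mi_initial"),
      mi_final = attr(fit$study$transform, "mi_final"),
      iterations = attr(fit$study$transform, "iterations")),
    package_version = as.character(utils::packageVersion("airtrap")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}

#' Cohort statistics report
#'
#' Applies the study's statistical battery to a cohort table: Pearson
#' correlations of every QCT metric with every spirometry column
#' (Bonferroni-adjusted), Welch group comparisons with 95% CIs, and for
#' each air-trapping measure an emphysema-adjusted logistic model plus ROC
#' analysis with the Youden-optimal cut-point.
#'
#' @param table Data frame with a `group` column (levels control/case),
#'   QCT metric columns, and spirometry columns.
#' @param qct_vars,spiro_vars Column names; defaults cover the standard
#'   metric set, intersected with what is present.
#' @param at_vars Air-trapping measures to model against the outcome.
#' @param adjust_for Confounder column for the logistic models, default
#'   `"prm_emph"`.
#' @param t_variant `"welch"` (default) or `"pooled"`.
#' @return List of class `cohort_report`: `correlations` (long data
#'   frame), `group_tests`, `models` (per AT measure: logistic fit + ROC).
#' @export
cohort_stats <- function(table,
                         qct_vars = c("ei_ratio", "nd_ei_ratio", "avi",
                                      "prm_emph", "laa_ins_950",
                                      "prm_fsad", "laa_exp_856", "ati"),
                         spiro_vars = c("fvc", "fev1", "fev1_fvc", "mmef"),
                         at_vars = c("prm_fsad", "laa_exp_856", "ati"),
                         adjust_for = "prm_emph",
                         t_variant = c("welch", "pooled")) {
  t_variant <- match.arg(t_variant)
  stopifnot(is.data.frame(table), "group" %in% names(table))
  grp <- table$group
  if (!is.factor(grp)) grp <- factor(grp, levels = c("control", "case"))
  qct_vars <- intersect(qct_vars, names(table))
  spiro_vars <- intersect(spiro_vars, names(table))
  at_vars <- intersect(at_vars, names(table))

  cors <- do.call(rbind, lapply(qct_vars, function(q)
    do.call(rbind, lapply(spiro_vars, function(s) {
      ct <- pearson(table[[q]], table[[s]])
      data.frame(qct = q, spirometry = s, r = ct$r, n = ct$n, p = ct$p,
                 ci_lower = ct$ci[1], ci_upper = ct$ci[2])
    }))))
  cors$p_bonferroni <- bonferroni(cors$p, m = nrow(cors))

  tests <- do.call(rbind, lapply(qct_vars, function(q) {
    tt <- two_sample_t(table[[q]][grp == "case"],
                       table[[q]][grp == "control"], variant = t_variant)
    data.frame(metric = q,
               mean_case = mean(table[[q]][grp == "case"], na.rm = TRUE),
               mean_control = mean(table[[q]][grp == "control"],
                                   na.rm = TRUE),
               mean_diff = tt$mean_diff, ci_lower = tt$ci[1],
               ci_upper = tt$ci[2], t = tt$t, df = tt$df, p = tt$p)
  }))

  outcome <- as.integer(grp == "case")
  models <- lapply(at_vars, function(v) {
    preds <- table[, c(v, intersect(adjust_for, names(table))),
                   drop = FALSE]
    list(variable = v,
         logistic = logistic_fit(outcome, preds),
         roc = roc_analysis(table[[v]], outcome))
  })
  names(models) <- at_vars
  structure(list(correlations = cors, group_tests = tests,
                 models = models, t_variant = t_variant),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report\n== QCT x spirometry correlations (Bonferroni-adjusted) ==\n")
  print(transform(x$correlations, r = round(r, 3), p = signif(p, 3),
                  p_bonferroni = signif(p_bonferroni, 3),
                  ci_lower = NULL, ci_upper = NULL), row.names = FALSE)
  cat(sprintf("\n== Group comparisons (%s t) ==\n", x$t_variant))
  gt <- x$group_tests
  gt[-1] <- lapply(gt[-1], function(z) signif(z, 3))
  print(gt, row.names = FALSE)
  cat("\n== Air-trapping predictors ==\n")
  for (m in x$models) {
    or <- m$logistic$odds_ratios[2, ]
    cat(sprintf("%s: adjusted OR %.2f (95%% CI %.2f-%.2f), AUC %.2f, cut-point %.3g (sens %.2f, spec %.2f)\n",
                m$variable, or["or"], or["lower"], or["upper"],
                m$roc$auc, m$roc$cutpoint, m$roc$sensitivity,
                m$roc$specificity))
  }
  invisible(x)
}
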