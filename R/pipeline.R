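#' Run the full validation analysis
#'
#' End-to-end study pipeline: validate and score both questionnaires, label
#' the four 6-month outcomes, build the per-outcome paired sub-samples,
#' run the preliminary ANOVA, fit the ROC coordinate tables, and assemble
#' the report: a sample-flow table (counts at every exclusion step), an AUC
#' table (counts at the Youden-optimal cut-off, prevalence, AUC, SE,
#' significance against 0.5, asymptotic 95% CI), and a cut-off table with
#' the Youden-optimal row plus the requested report cut-offs, each carrying
#' sample-prevalence metrics, predictive values re-adjusted to the
#' population prevalence, and the efficiency/quality classifications.
#'
#' @param baseline Baseline tibble (schema of [read_baseline()]).
#' @param followup Follow-up tibble (schema of [read_followup()]).
#' @param items OMPSQ item table.
#' @param hkf_items HKF-R 10 item manifest.
#' @param weights HKF-R 10 weight spec.
#' @param population_prevalence Epidemiological prevalence used to re-adjust
#'   PPV/NPV (default 0.10).
#' @param cutoffs Named list of report cut-offs per instrument,
#'   `list(ompsq = ..., hkf = ...)`.
#' @return Object of class `study_report`: list with `sample_flow`,
#'   `auc_table`, `cutoff_table`, `anova_table`, `subsamples`, `curves`,
#'   `population_prevalence`.
#' @export
run_study <- function(baseline, followup,
                      items = ompsq_item_spec(),
                      hkf_items = hkf_item_spec(),
                      weights = hkf_weight_spec(),
                      population_prevalence = 0.10,
                      cutoffs = list(ompsq = c(84, 76, 92, 72),
                                     hkf = c(46, 37, 20))) {
  if (population_prevalence <= 0 || population_prevalence >= 1) {
    stop("population_prevalence must lie strictly between 0 and 1",
         call. = FALSE)
  }
  omp_scores <- score_ompsq(baseline, items)
  hkf_scores <- score_hkf(baseline, weights, hkf_items)
  labels <- label_outcomes(followup)
  subsamples <- build_subsamples(omp_scores, hkf_scores, labels)

  flow <- sample_flow(baseline, followup, omp_scores, hkf_scores,
                      labels, subsamples)

  instr <- c(ompsq_pain = "ompsq", ompsq_sickleave = "ompsq",
             ompsq_function = "ompsq", hkf_pain = "hkf")
  auc_rows <- list(); cut_rows <- list(); anova_rows <- list()
  curves <- list()
  for (oc in names(subsamples)) {
    sub <- subsamples[[oc]]
    if (nrow(sub) == 0 || length(unique(sub$not_recovered)) < 2) {
      warning("outcome ", oc, " skipped: empty or single-class sub-sample",
              call. = FALSE)
      next
    }
    curve <- roc_curve(sub$score, sub$not_recovered)
    curves[[oc]] <- curve
    opt <- youden_optimal(curve)
    auc_rows[[oc]] <- tibble::tibble(
      outcome = oc, n = nrow(sub),
      tn = opt$tn, fp = opt$fp, tp = opt$tp, fn = opt$fn,
      prevalence = mean(sub$not_recovered),
      auc = curve$auc, se = curve$se, p_value = curve$p_value,
      ci_lower = curve$ci[1], ci_upper = curve$ci[2],
      auc_quality = classify_quality(100 * curve$auc)
    )
    rows <- rbind(cbind(role = "youden_optimal", opt),
                  do.call(rbind, lapply(cutoffs[[instr[[oc]]]], function(ct) {
                    cbind(role = "requested",
                          cm_metrics(confusion_at_cutoff(sub$score,
                                                         sub$not_recovered,
                                                         ct), cutoff = ct))
                  })))
    adj <- adjust_pv(rows$plr, rows$nlr,
                     rep(population_prevalence, nrow(rows)))
    rows$ppv_adjusted <- adj$ppv
    rows$npv_adjusted <- adj$npv
    rows$plr_band <- classify_plr(rows$plr)
    rows$nlr_band <- classify_nlr(rows$nlr)
    rows$sum_quality <- classify_quality_sum(
      100 * (rows$sensitivity + rows$specificity))
    cut_rows[[oc]] <- cbind(outcome = oc, rows)
    anova_rows[[oc]] <- cbind(outcome = oc,
                              oneway_anova(sub$score, sub$not_recovered))
  }
  structure(list(
    sample_flow = flow,
    auc_table = do.call(rbind, auc_rows),
    cutoff_table = tibble::as_tibble(do.call(rbind, cut_rows)),
    anova_table = tibble::as_tibble(do.call(rbind, anova_rows)),
    subsamples = subsamples,
    curves = curves,
    population_prevalence = population_prevalence
  ), class = "study_report")
}

# Structured step-by-step bookkeeping: counts in, counts out, reason codes.
sample_flow <- function(baseline, followup, omp_scores, hkf_scores,
                        labels, subsamples) {
  rows <- list(
    tibble::tibble(step = "baseline", instrument = "both",
                   n = nrow(baseline), reason = NA_character_),
    tibble::tibble(step = "valid_baseline", instrument = "ompsq",
                   n = sum(omp_scores$valid),
                   reason = sprintf("%d raw data validation negative",
                                    sum(!omp_scores$valid))),
    tibble::tibble(step = "valid_baseline", instrument = "hkf",
                   n = sum(hkf_scores$valid),
                   reason = sprintf("%d raw data validation negative",
                                    sum(!hkf_scores$valid))),
    tibble::tibble(step = "followup_returned", instrument = "both",
                   n = nrow(followup), reason = NA_character_)
  )
  for (oc in names(subsamples)) {
    n_lab <- sum(labels$outcome == oc)
    rows[[length(rows) + 1]] <- tibble::tibble(
      step = "labelled", instrument = oc, n = n_lab,
      reason = sprintf("%d missing outcome variables",
                       nrow(followup) - n_lab))
    rows[[length(rows) + 1]] <- tibble::tibble(
      step = "subsample", instrument = oc, n = nrow(subsamples[[oc]]),
      reason = sprintf("%d without valid baseline",
                       n_lab - nrow(subsamples[[oc]])))
  }
  do.call(rbind, rows)
}

#' Validity report from printed confusion matrices
#'
#' Matrix-injection entry point: computes the full cut-off-associated metric
#' bundle, population-prevalence-adjusted predictive values and
#' efficiency/quality classifications directly from confusion matrices, so
#' published count tables can be re-analysed without raw scores.
#'
#' @param matrices Named list of `confusion_matrix` objects.
#' @param population_prevalence Prevalence for the PV re-adjustment.
#' @return Tibble, one row per matrix, with all [cm_metrics()] columns plus
#'   `ppv_adjusted`, `npv_adjusted`, `plr_band`, `nlr_band`, `sum_quality`.
#' @export
#' @examples
#' report_from_matrices(list(
#'   ompsq_pain = confusion_matrix(tp = 44, fp = 15, tn = 46, fn = 17)))
report_from_matrices <- function(matrices, population_prevalence = 0.10) {
  stopifnot(length(matrices) > 0, !is.null(names(matrices)))
  rows <- do.call(rbind, lapply(names(matrices), function(nm) {
    cbind(outcome = nm, cm_metrics(matrices[[nm]]))
  }))
  adj <- adjust_pv(rows$plr, rows$nlr,
                   rep(population_prevalence, nrow(rows)))
  rows$ppv_adjusted <- adj$ppv
  rows$npv_adjusted <- adj$npv
  rows$plr_band <- classify_plr(rows$plr)
  rows$nlr_band <- classify_nlr(rows$nlr)
  rows$sum_quality <- classify_quality_sum(
    100 * (rows$sensitivity + rows$specificity))
  tibble::as_tibble(rows)
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  cat("Study validity report\n=====================\n\nSample flow:\n")
  print(as.data.frame(x$sample_flow), row.names = FALSE)
  cat("\nROC areas under the curve:\n")
  a <- x$auc_table
  a[] <- lapply(a, function(cl) if (is.numeric(cl)) round(cl, 3) else cl)
  print(as.data.frame(a), row.names = FALSE)
  cat(sprintf("\nCut-off-associated validity (PVs re-adjusted to %.0f%% prevalence):\n",
              100 * x$population_prevalence))
  ct <- x$cutoff_table
  num <- vapply(ct, is.numeric, TRUE)
  ct[num] <- lapply(ct[num], round, digits)
  print(as.data.frame(ct), row.names = FALSE)
  cat("\nPreliminary one-way ANOVA (baseline score by outcome state):\n")
  print(as.data.frame(x$anova_table), row.names = FALSE)
  invisible(x)
}

#' Export a ROC coordinate table as TSV
#'
#' @param curve A `roc_curve`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_coordinates <- function(curve, path) {
  stopifnot(inherits(curve, "roc_curve"))
  utils::write.table(curve$points, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
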