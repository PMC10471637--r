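#' Full study report for a cohort
#'
#' Runs the complete analysis pipeline on a cohort — graft-size prediction,
#' predicted-vs-actual agreement, intra-/inter-reader reproducibility, and
#' descriptive comparison — and assembles the results into a single report
#' object. All stages are pure functions of the cohort, so the report is
#' reproducible bit-for-bit apart from its timestamp.
#'
#' Records without an actual graft size are skipped by the agreement and
#' descriptive stages, with the exclusion count stated in the report; if no
#' record has an actual size, those stages are omitted entirely (and say
#' so) rather than failing.
#'
#' @param cohort A [graft_cohort()].
#' @param reader,session,reconcile Passed to [predict_cohort()]; the
#'   headline prediction uses reader `"R1"` at session `"t0"` by default.
#' @param inter_session Passed to [reproducibility_report()].
#' @return List of class `study_report` with elements `cohort_summary`,
#'   `predicted_summary`, `actual_summary`, `size_frequencies`,
#'   `agreement`, `reproducibility`, `wilcoxon`, `exclusions`,
#'   `provenance`.
#' @export
study_report <- function(cohort, reader = "R1", session = "t0",
                         reconcile = "single", inter_session = "t0") {
  data <- tibble::as_tibble(cohort)
  patients <- unique(data[c("patient_id", "age_years", "sex", "side",
                            "actual_graft_mm")])

  cohort_summary <- list(
    n = nrow(patients),
    n_male = sum(patients$sex == "M", na.rm = TRUE),
    n_female = sum(patients$sex == "F", na.rm = TRUE),
    n_left = sum(patients$side == "left", na.rm = TRUE),
    n_right = sum(patients$side == "right", na.rm = TRUE),
    age = median_iqr(patients$age_years)
  )

  preds <- predict_cohort(cohort, reader = reader, session = session,
                          reconcile = reconcile)
  excl_pred <- prediction_exclusions(preds)

  merged <- merge(preds, patients[c("patient_id", "actual_graft_mm")],
                  by = "patient_id")
  has_actual <- !is.na(merged$actual_graft_mm)
  n_missing_actual <- sum(!has_actual)
  paired <- merged[has_actual, ]

  predicted_summary <- median_iqr(preds$pgd_raw_mm)
  actual_summary <- if (nrow(paired) > 0) median_iqr(paired$actual_graft_mm) else NULL

  size_frequencies <- if (nrow(paired) > 0) {
    sizes <- sort(unique(c(paired$pgd_rounded_mm, paired$actual_graft_mm)))
    tibble::tibble(
      size_mm = sizes,
      n_predicted = vapply(sizes, function(s) sum(paired$pgd_rounded_mm == s), integer(1)),
      n_actual = vapply(sizes, function(s) sum(paired$actual_graft_mm == s), integer(1))
    )
  } else NULL

  agreement <- if (nrow(paired) >= 1) {
    agreement_summary(paired$pgd_rounded_mm, paired$actual_graft_mm)
  } else NULL

  # like-for-like comparison: the rounded (integer-mm) prediction against
  # the integer surgical size; comparing the raw PGD to an integer size
  # would detect the ceiling offset, not a prediction failure
  wilcoxon <- if (nrow(paired) >= 1) {
    wilcoxon_signed_rank(paired$pgd_rounded_mm, paired$actual_graft_mm)
  } else NULL

  reproducibility <- reproducibility_report(cohort, inter_session = inter_session)

  meta <- cohort_metadata(cohort)
  res <- list(
    cohort_summary = cohort_summary,
    predicted_summary = predicted_summary,
    actual_summary = actual_summary,
    size_frequencies = size_frequencies,
    agreement = agreement,
    wilcoxon = wilcoxon,
    reproducibility = reproducibility,
    exclusions = list(
      prediction = excl_pred,
      missing_actual = n_missing_actual,
      reproducibility = as.list(reproducibility$n_excluded)
    ),
    provenance = list(
      source = meta$source %||% "unknown",
      seed = meta$seed,
      reader = reader, session = session, reconcile = reconcile,
      package_version = as.character(utils::packageVersion("graftsize")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  class(res) <- "study_report"
  res
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_report_markdown(x))
  invisible(x)
}

# Flatten report components into plain lists for JSON serialisation.
report_to_list <- function(report, drop_timestamp = FALSE) {
  ba_list <- function(r) list(n = r$n, bias_mm = r$bias_mm,
                              sd_diff_mm = r$sd_diff_mm, cor_mm = r$cor_mm,
                              loa_lower_mm = unname(r$loa_mm[["lower"]]),
                              loa_upper_mm = unname(r$loa_mm[["upper"]]))
  ss_list <- function(s) if (is.null(s)) NULL else
    list(n = s$n, median = s$median, q1 = s$q1, q3 = s$q3)
  ag <- report$agreement
  agreement <- if (is.null(ag)) NULL else list(
    n = ag$n, n_concordant = ag$n_concordant, n_under = ag$n_under,
    n_over = ag$n_over,
    concordance_pct = ag$concordance_pct,
    concordance_ci = unname(ag$concordance_ci),
    under_pct = ag$under_pct, under_ci = unname(ag$under_ci),
    over_pct = ag$over_pct, over_ci = unname(ag$over_ci),
    kappa = ag$kappa, kappa_degenerate = ag$kappa_degenerate,
    kappa_band = ag$kappa_band, level = ag$level
  )
  wx <- report$wilcoxon
  prov <- report$provenance
  if (drop_timestamp) prov$timestamp <- NULL
  list(
    schema_version = "1.0",
    cohort_summary = c(report$cohort_summary[c("n", "n_male", "n_female",
                                               "n_left", "n_right")],
                       list(age = ss_list(report$cohort_summary$age))),
    predicted_summary = ss_list(report$predicted_summary),
    actual_summary = ss_list(report$actual_summary),
    size_frequencies = if (is.null(report$size_frequencies)) NULL else
      as.list(report$size_frequencies),
    agreement = agreement,
    wilcoxon = if (is.null(wx)) NULL else list(
      statistic = wx$statistic, p_value = wx$p_value,
      n_effective = wx$n_effective, method = wx$method,
      degenerate = wx$degenerate
    ),
    reproducibility = list(
      intra_st = ba_list(report$reproducibility$intra_st),
      intra_gt = ba_list(report$reproducibility$intra_gt),
      inter_st = ba_list(report$reproducibility$inter_st),
      inter_gt = ba_list(report$reproducibility$inter_gt)
    ),
    exclusions = list(
      prediction = as.list(report$exclusions$prediction),
      missing_actual = report$exclusions$missing_actual,
      reproducibility = report$exclusions$reproducibility
    ),
    provenance = prov
  )
}

#' Write a study report as JSON
#'
#' Numbers are written at full precision; display rounding belongs to the
#' markdown rendering only.
#'
#' @param report A [study_report()].
#' @param path Output path.
#' @param drop_timestamp Omit the timestamp (for byte-identical
#'   reproducibility checks).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, drop_timestamp = FALSE) {
  jsonlite::write_json(report_to_list(report, drop_timestamp), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Render a study report as markdown
#'
#' Human-readable summary with display rounding: integer percentages
#' (half away from zero), two-decimal millimetre values, three-decimal
#' kappa.
#'
#' @param report A [study_report()].
#' @return A single markdown string.
#' @export
render_report_markdown <- function(report) {
  lines <- character()
  push <- function(...) lines[[length(lines) + 1]] <<- paste0(...)
  cs <- report$cohort_summary
  push("# Graft size prediction study report\n")
  push(sprintf("Cohort: %d patients (%d M / %d F; %d left / %d right); median age %g years (IQR %g-%g).\n",
               cs$n, cs$n_male, cs$n_female, cs$n_left, cs$n_right,
               cs$age$median, cs$age$q1, cs$age$q3))
  ps <- report$predicted_summary
  push(sprintf("Predicted graft diameter (raw): median %.2f mm (IQR %.2f-%.2f mm).",
               ps$median, ps$q1, ps$q3))
  if (!is.null(report$actual_summary)) {
    as_ <- report$actual_summary
    push(sprintf("Actual graft diameter: median %.2f mm (IQR %.2f-%.2f mm).",
                 as_$median, as_$q1, as_$q3))
  }
  if (!is.null(report$wilcoxon)) {
    wx <- report$wilcoxon
    push(sprintf("Wilcoxon signed-rank (rounded predicted vs actual): p = %.3f%s.",
                 wx$p_value, if (wx$degenerate) " (degenerate: all differences zero)" else ""))
  }
  push("")
  if (!is.null(report$agreement)) {
    ag <- report$agreement
    fmt <- function(count, pct, ci) sprintf("%d/%d (%d%%, 95%% CI %d-%d%%)",
                                            count, ag$n, round_half_away(pct),
                                            round_half_away(ci[["lower"]]),
                                            round_half_away(ci[["upper"]]))
    push("## Agreement (rounded prediction vs surgical size)\n")
    push("- Concordant: ", fmt(ag$n_concordant, ag$concordance_pct, ag$concordance_ci))
    push("- Under-predicted: ", fmt(ag$n_under, ag$under_pct, ag$under_ci))
    push("- Over-predicted: ", fmt(ag$n_over, ag$over_pct, ag$over_ci))
    if (isTRUE(ag$kappa_degenerate)) {
      push("- Linearly weighted kappa: undefined (degenerate marginals)")
    } else {
      push(sprintf("- Linearly weighted kappa: %.3f (%s)", ag$kappa, ag$kappa_band))
    }
    push("")
    if (!is.null(report$size_frequencies)) {
      push("## Size frequencies\n")
      push("| size (mm) | predicted | actual |")
      push("|---|---|---|")
      sf <- report$size_frequencies
      for (i in seq_len(nrow(sf))) {
        push(sprintf("| %d | %d | %d |", sf$size_mm[i], sf$n_predicted[i], sf$n_actual[i]))
      }
      push("")
    }
  } else {
    push("## Agreement\n\nSkipped: no record carries an actual graft size.\n")
  }
  push("## Reproducibility (Bland-Altman, per-tendon mean diameter)\n")
  push("| comparison | tendon | bias (mm) | CoR (mm) | n |")
  push("|---|---|---|---|---|")
  for (nm in c("intra_st", "intra_gt", "inter_st", "inter_gt")) {
    r <- report$reproducibility[[nm]]
    push(sprintf("| %s | %s | %.2f | %.2f | %d |",
                 ifelse(grepl("intra", nm), "intra-reader", "inter-reader"),
                 toupper(sub(".*_", "", nm)), r$bias_mm, r$cor_mm, r$n))
  }
  push("")
  ex <- report$exclusions
  push(sprintf("Exclusions: %d prediction, %d missing actual size.",
               nrow(ex$prediction), ex$missing_actual))
  push(sprintf("\nSource: %s | reader %s, session %s | graftsize %s",
               report$provenance$source, report$provenance$reader,
               report$provenance$session, report$provenance$package_version))
  paste0(paste(lines, collapse = "\n"), "\n")
}
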