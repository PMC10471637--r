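#' Bland-Altman analysis of two paired measurement series
#'
#' Quantifies agreement between paired readings of the same quantity (two
#' sessions of one reader, or two readers at one session). With differences
#' `d_i = a_i - b_i`:
#' bias = mean(d); sd_diff = sample SD of d (n - 1 denominator);
#' coefficient of repeatability CoR = 1.96 x sd_diff; limits of agreement
#' = bias +/- CoR. 95% of absolute differences between repeated readings
#' are expected to fall below the CoR.
#'
#' The CoR here is the common Bland-Altman repeatability coefficient
#' 1.96 x SD of paired differences. An alternative definition found in the
#' literature, 2.77 x within-subject SD (equivalently 1.96 x sqrt(2) x Sw),
#' is not used; for two readings per subject the two coincide when the bias
#' is zero.
#'
#' @param series_a,series_b Equal-length (>= 2) numeric vectors in mm,
#'   position-paired.
#' @return List of class `bland_altman`: `n`, `bias_mm`, `sd_diff_mm`,
#'   `cor_mm`, `loa_mm` (named lower/upper).
#' @examples
#' bland_altman(c(4.1, 4.3, 3.9), c(4.1, 4.2, 4.0))
#' @export
bland_altman <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) {
    stop("series must be position-paired (equal length)", call. = FALSE)
  }
  if (length(series_a) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (any(is.na(series_a)) || any(is.na(series_b))) {
    stop("missing values in measurement series", call. = FALSE)
  }
  d <- series_a - series_b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  cor_mm <- 1.96 * sd_diff
  res <- list(
    n = length(d),
    bias_mm = bias,
    sd_diff_mm = sd_diff,
    cor_mm = cor_mm,
    loa_mm = c(lower = bias - cor_mm, upper = bias + cor_mm)
  )
  class(res) <- "bland_altman"
  res
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f mm, CoR %.2f mm, LoA [%.2f, %.2f] mm\n",
              x$n, x$bias_mm, x$cor_mm, x$loa_mm[["lower"]], x$loa_mm[["upper"]]))
  invisible(x)
}

#' Per-pair Bland-Altman plot data
#'
#' Mean and difference columns for external Bland-Altman plotting.
#'
#' @param series_a,series_b As in [bland_altman()].
#' @return Tibble with columns `mean`, `difference` (a - b).
#' @export
bland_altman_plot_data <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b))
  tibble::tibble(mean = (series_a + series_b) / 2,
                 difference = series_a - series_b)
}

# Per-patient per-tendon mean diameter for one (reader, session) slice,
# keyed by patient_id; NA when the slice is missing for a patient.
tendon_mean_slice <- function(data, tendon, reader, session, ids) {
  sl <- data[data$tendon == tendon & data$reader == reader &
               data$session == session, ]
  m <- mean_tendon_diameter(sl$major_mm, sl$minor_mm)
  m[match(ids, sl$patient_id)]
}

#' Intra- and inter-reader reproducibility report
#'
#' Bland-Altman reproducibility of the per-tendon mean diameter
#' `(D + d)/2` — the quantity that feeds the graft-size rule — for the
#' semitendinosus (ST) and gracilis (GT) tendons:
#'
#' * intra-reader: reader 1's baseline session vs their repeat session
#'   (difference orientation t0 - t1month);
#' * inter-reader: reader 1 vs reader 2, both at the same session
#'   (orientation reader1 - reader2; session `inter_session`, default
#'   `"t0"`; `"mean"` averages each reader over both sessions first).
#'
#' Patients missing any required measurement are excluded from the affected
#' comparison, with the exclusion count reported.
#'
#' @param cohort A [graft_cohort()] with both readers and both sessions.
#' @param readers Character vector of the two reader identifiers, in
#'   (reader 1, reader 2) order. Default `c("R1", "R2")`.
#' @param inter_session Session used for the inter-reader comparison:
#'   `"t0"` (default), `"t1month"`, or `"mean"`.
#' @param quantity `"mean"` (default) analyses the per-tendon mean
#'   diameter; `"major"` / `"minor"` analyse a single axis (diagnostic
#'   modes).
#' @return List of class `reproducibility_report` with elements
#'   `intra_st`, `intra_gt`, `inter_st`, `inter_gt` (each a
#'   [bland_altman()] result) and `n_excluded` (named integer vector per
#'   comparison).
#' @export
reproducibility_report <- function(cohort, readers = c("R1", "R2"),
                                   inter_session = c("t0", "t1month", "mean"),
                                   quantity = c("mean", "major", "minor")) {
  inter_session <- match.arg(inter_session)
  quantity <- match.arg(quantity)
  data <- tibble::as_tibble(cohort)
  if (!all(readers %in% unique(data$reader))) {
    stop("cohort does not contain both readers: ",
         paste(readers, collapse = ", "), call. = FALSE)
  }
  ids <- unique(data$patient_id)

  value_slice <- function(tendon, reader, session) {
    sl <- data[data$tendon == tendon & data$reader == reader &
                 data$session == session, ]
    v <- switch(quantity,
                mean = mean_tendon_diameter(sl$major_mm, sl$minor_mm),
                major = sl$major_mm,
                minor = sl$minor_mm)
    v[match(ids, sl$patient_id)]
  }

  compare <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    list(result = bland_altman(a[ok], b[ok]), n_excluded = sum(!ok))
  }

  res <- list()
  excl <- integer()
  for (tendon in TENDONS) {
    # intra-reader: reader 1, t0 vs t1month
    cmp <- compare(value_slice(tendon, readers[1], "t0"),
                   value_slice(tendon, readers[1], "t1month"))
    res[[paste0("intra_", tolower(tendon))]] <- cmp$result
    excl[paste0("intra_", tolower(tendon))] <- cmp$n_excluded
    # inter-reader: reader 1 vs reader 2
    if (inter_session == "mean") {
      a <- (value_slice(tendon, readers[1], "t0") +
              value_slice(tendon, readers[1], "t1month")) / 2
      b <- (value_slice(tendon, readers[2], "t0") +
              value_slice(tendon, readers[2], "t1month")) / 2
    } else {
      a <- value_slice(tendon, readers[1], inter_session)
      b <- value_slice(tendon, readers[2], inter_session)
    }
    cmp <- compare(a, b)
    res[[paste0("inter_", tolower(tendon))]] <- cmp$result
    excl[paste0("inter_", tolower(tendon))] <- cmp$n_excluded
  }
  res$n_excluded <- excl
  class(res) <- "reproducibility_report"
  res
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat("Reproducibility of per-tendon mean diameter (Bland-Altman)\n")
  for (nm in c("intra_st", "intra_gt", "inter_st", "inter_gt")) {
    label <- sprintf("%s %s", ifelse(grepl("intra", nm), "intra-reader", "inter-reader"),
                     toupper(sub(".*_", "", nm)))
    r <- x[[nm]]
    cat(sprintf("  %-16s bias %5.2f mm, CoR %.2f mm (n = %d)\n",
                label, r$bias_mm, r$cor_mm, r$n))
  }
  invisible(x)
}
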