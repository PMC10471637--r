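#' Mean tendon diameter
#'
#' The per-tendon summary used by the graft-size rule: the mean of the major
#' (D) and minor (d) cross-sectional diameters, (D + d)/2. Inputs sit on the
#' 0.1-mm measurement grid, so the half-sum is exact at two decimals — the
#' function asserts this rather than rounding (arithmetic is done on integer
#' tenths of a millimetre).
#'
#' @param major_mm Major diameter in mm (one decimal place).
#' @param minor_mm Minor diameter in mm (one decimal place); must satisfy
#'   `0 < minor_mm <= major_mm`.
#' @return Mean diameter in mm, exact at two decimals. Vectorised.
#' @examples
#' mean_tendon_diameter(4.3, 3.2) # 3.75
#' @export
mean_tendon_diameter <- function(major_mm, minor_mm) {
  if (length(major_mm) != length(minor_mm)) {
    stop("major_mm and minor_mm must have equal length", call. = FALSE)
  }
  if (any(!on_tenth_grid(major_mm)) || any(!on_tenth_grid(minor_mm))) {
    stop("diameters must be on the 0.1-mm grid (one decimal place)", call. = FALSE)
  }
  D <- as_tenths(major_mm)
  d <- as_tenths(minor_mm)
  if (any(d <= 0)) stop("minor diameter must be positive", call. = FALSE)
  if (any(d > D)) stop("minor diameter exceeds major diameter", call. = FALSE)
  (D + d) / 20
}

#' Round a length up to the next full millimetre
#'
#' "Excess" rounding of the predicted graft diameter: the smallest integer
#' number of millimetres not smaller than the input. Exact integers map to
#' themselves — a graft predicted at exactly 7.00 mm fits a 7-mm tunnel, so
#' no bump is applied. The rule exists because intraoperatively a graft can
#' pass through a larger tunnel but not a smaller one.
#'
#' @param x Positive length(s) in mm.
#' @return Integer mm, `ceiling(x)`. Vectorised.
#' @examples
#' round_up_mm(7.01) # 8
#' round_up_mm(7.00) # 7
#' @export
round_up_mm <- function(x) {
  if (any(is.na(x)) || any(x <= 0)) {
    stop("round_up_mm requires positive lengths", call. = FALSE)
  }
  # tolerate float representations of exact decimal values (e.g. 8.00
  # computed as 4.05 + 3.95) without bumping them to the next integer
  as.integer(ceiling(round(x * 1e9) / 1e9))
}

#' Predicted graft diameter (PGD) from four tendon diameters
#'
#' The prediction rule for a doubled semitendinosus + gracilis four-strand
#' graft: the sum of the two per-tendon mean diameters,
#' `PGD = (D_ST + d_ST)/2 + (D_GT + d_GT)/2`, rounded up to the next full
#' millimetre. The raw PGD is exact at two decimals because each input
#' carries one decimal.
#'
#' @param st_major_mm,st_minor_mm Semitendinosus major/minor diameters (mm).
#' @param gt_major_mm,gt_minor_mm Gracilis major/minor diameters (mm).
#' @return A tibble of class `graft_prediction` with columns `mean_st_mm`,
#'   `mean_gt_mm`, `pgd_raw_mm`, `pgd_rounded_mm`. Vectorised over inputs.
#' @examples
#' predicted_graft_diameter(4.6, 4.0, 3.4, 3.0) # raw 7.50, rounded 8
#' @export
predicted_graft_diameter <- function(st_major_mm, st_minor_mm,
                                     gt_major_mm, gt_minor_mm) {
  mean_st <- tryCatch(
    mean_tendon_diameter(st_major_mm, st_minor_mm),
    error = function(e) stop("ST: ", conditionMessage(e), call. = FALSE)
  )
  mean_gt <- tryCatch(
    mean_tendon_diameter(gt_major_mm, gt_minor_mm),
    error = function(e) stop("GT: ", conditionMessage(e), call. = FALSE)
  )
  # sum on the integer hundredths grid so raw PGD is exact at two decimals
  raw <- (as.integer(round(mean_st * 100)) + as.integer(round(mean_gt * 100))) / 100
  out <- tibble::tibble(
    mean_st_mm = mean_st,
    mean_gt_mm = mean_gt,
    pgd_raw_mm = raw,
    pgd_rounded_mm = round_up_mm(raw)
  )
  class(out) <- c("graft_prediction", class(out))
  out
}

#' Predict graft diameters for a whole cohort
#'
#' Applies the PGD rule to every patient using one reader's measurements at
#' one session (the default), or the average of both readers / both
#' sessions. Patients lacking the required ST or GT measurement are
#' reported in the `excluded` attribute, never silently dropped.
#'
#' @param cohort A [graft_cohort()].
#' @param reader Reader identifier (default `"R1"`). Ignored when
#'   `reconcile = "mean"`.
#' @param session Session, `"t0"` (default) or `"t1month"`. Ignored when
#'   `reconcile = "mean"`.
#' @param reconcile `"single"` (default): use the one reader/session named;
#'   `"mean"`: average each tendon's mean diameter over all readers and
#'   sessions before summing (an alternative reconciliation of the two
#'   readers, provided because study protocols differ on this point).
#' @return Tibble with one row per predicted patient: `patient_id`,
#'   `mean_st_mm`, `mean_gt_mm`, `pgd_raw_mm`, `pgd_rounded_mm`, plus an
#'   `excluded` attribute (tibble of `patient_id`, `reason`).
#' @export
predict_cohort <- function(cohort, reader = "R1", session = "t0",
                           reconcile = c("single", "mean")) {
  reconcile <- match.arg(reconcile)
  data <- tibble::as_tibble(cohort)

  if (reconcile == "single") {
    if (!reader %in% unique(data$reader)) {
      stop("unknown reader '", reader, "' (cohort has: ",
           paste(sort(unique(data$reader)), collapse = ", "), ")", call. = FALSE)
    }
    if (!session %in% SESSIONS) {
      stop("unknown session '", session, "' (expected ",
           paste(SESSIONS, collapse = "/"), ")", call. = FALSE)
    }
    data <- data[data$reader == reader & data$session == session, ]
  }

  data$mean_mm <- mean_tendon_diameter(data$major_mm, data$minor_mm)
  per_tendon <- dplyr::summarise(
    dplyr::group_by(data, .data$patient_id, .data$tendon),
    mean_mm = mean(.data$mean_mm),
    .groups = "drop"
  )
  wide <- dplyr::summarise(
    dplyr::group_by(per_tendon, .data$patient_id),
    mean_st_mm = .data$mean_mm[.data$tendon == "ST"][1],
    mean_gt_mm = .data$mean_mm[.data$tendon == "GT"][1],
    .groups = "drop"
  )

  all_ids <- unique(tibble::as_tibble(cohort)$patient_id)
  incomplete <- is.na(wide$mean_st_mm) | is.na(wide$mean_gt_mm)
  missing_ids <- setdiff(all_ids, wide$patient_id)
  excluded <- tibble::tibble(
    patient_id = c(wide$patient_id[incomplete], missing_ids),
    reason = "missing ST or GT measurement for the requested reader/session"
  )
  ok <- wide[!incomplete, ]

  raw <- round(ok$mean_st_mm + ok$mean_gt_mm, 10)
  out <- tibble::tibble(
    patient_id = ok$patient_id,
    mean_st_mm = ok$mean_st_mm,
    mean_gt_mm = ok$mean_gt_mm,
    pgd_raw_mm = raw,
    pgd_rounded_mm = round_up_mm(raw)
  )
  attr(out, "excluded") <- excluded
  out
}

#' Patients excluded from a cohort prediction
#'
#' @param predictions Result of [predict_cohort()].
#' @return Tibble of `patient_id`, `reason` for each excluded record.
#' @export
prediction_exclusions <- function(predictions) {
  attr(predictions, "excluded") %||%
    tibble::tibble(patient_id = character(), reason = character())
}
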