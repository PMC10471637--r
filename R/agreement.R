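#' Classify a predicted vs actual graft size pair
#'
#' @param predicted_mm,actual_mm Positive integer graft diameters in mm.
#' @return Character vector over `{"concordant", "under", "over"}`:
#'   `"under"` when the prediction is smaller than the actual size,
#'   `"over"` when larger. Vectorised.
#' @examples
#' classify_prediction(7, 8) # "under"
#' classify_prediction(9, 7) # "over"
#' @export
classify_prediction <- function(predicted_mm, actual_mm) {
  stopifnot(length(predicted_mm) == length(actual_mm))
  if (any(is.na(predicted_mm)) || any(is.na(actual_mm)) ||
      any(predicted_mm <= 0) || any(actual_mm <= 0)) {
    stop("predicted and actual sizes must be positive and non-missing", call. = FALSE)
  }
  ifelse(predicted_mm == actual_mm, "concordant",
         ifelse(predicted_mm < actual_mm, "under", "over"))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, the default CI for
#' the concordance / under- / over-prediction rates. The Wilson score
#' interval is offered as an alternative.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return Named numeric vector `c(lower = , upper = )` of proportions;
#'   `lower` is 0 when `successes = 0` and `upper` is 1 when
#'   `successes = n`.
#' @examples
#' exact_binomial_ci(78, 92) # approx (0.758, 0.914) -> prints as 76-91%
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95,
                              method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (length(successes) != 1 || length(n) != 1 ||
      is.na(successes) || is.na(n) ||
      successes < 0 || n < 1 || successes > n) {
    stop("require 0 <= successes <= n with n >= 1", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (method == "clopper-pearson") {
    ci <- stats::binom.test(successes, n, conf.level = level)$conf.int
    return(c(lower = ci[1], upper = ci[2]))
  }
  # Wilson score interval (no continuity correction)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Linearly weighted Cohen's kappa for ordered integer categories
#'
#' Chance-corrected agreement between two integer-valued ratings (here:
#' predicted and actual graft sizes in mm), penalising disagreements in
#' proportion to their distance in millimetres. With disagreement weights
#' `w_ij = |i - j| / (k - 1)` over a grid of k consecutive categories,
#'
#'   kappa_w = 1 - sum(w * O) / sum(w * E),
#'
#' where O is the observed joint frequency table and E the
#' product-of-marginals expected table. The grid defaults to all
#' consecutive integers from the minimum to the maximum observed value
#' (both vectors pooled), so unobserved interior sizes still contribute to
#' the distance metric.
#'
#' When the expected disagreement is zero (all mass in a single category
#' for both raters) kappa is undefined; the result is flagged `degenerate`
#' rather than forced to a number.
#'
#' @param predicted_mm,actual_mm Paired integer ratings (>= 2 pairs).
#' @param categories Optional ordered integer grid covering all values.
#' @return List of class `weighted_kappa`: `kappa`, `degenerate` (logical),
#'   `n`, `categories`, `observed` and `expected` tables.
#' @export
weighted_kappa_linear <- function(predicted_mm, actual_mm, categories = NULL) {
  stopifnot(length(predicted_mm) == length(actual_mm))
  if (length(predicted_mm) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (any(is.na(predicted_mm)) || any(is.na(actual_mm))) {
    stop("missing values in rating pairs", call. = FALSE)
  }
  if (is.null(categories)) {
    rng <- range(c(predicted_mm, actual_mm))
    categories <- seq.int(rng[1], rng[2])
  }
  if (!all(predicted_mm %in% categories) || !all(actual_mm %in% categories)) {
    stop("all ratings must lie on the category grid", call. = FALSE)
  }
  k <- length(categories)
  n <- length(predicted_mm)
  f1 <- factor(predicted_mm, levels = categories)
  f2 <- factor(actual_mm, levels = categories)
  O <- table(f1, f2)
  E <- outer(rowSums(O), colSums(O)) / n
  if (k == 1) {
    res <- list(kappa = NA_real_, degenerate = TRUE, n = n,
                categories = categories, observed = O, expected = E)
    class(res) <- "weighted_kappa"
    return(res)
  }
  W <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  exp_dis <- sum(W * E)
  if (exp_dis == 0) {
    kappa <- NA_real_
    degenerate <- TRUE
  } else {
    kappa <- 1 - sum(W * O) / exp_dis
    degenerate <- FALSE
  }
  res <- list(kappa = kappa, degenerate = degenerate, n = n,
              categories = categories, observed = O, expected = E)
  class(res) <- "weighted_kappa"
  res
}

#' @export
print.weighted_kappa <- function(x, ...) {
  if (x$degenerate) {
    cat("Linearly weighted kappa: undefined (degenerate marginals)\n")
  } else {
    cat(sprintf("Linearly weighted kappa: %.3f (%s), n = %d\n",
                x$kappa, kappa_band(x$kappa), x$n))
  }
  invisible(x)
}

#' Verbal agreement band for a kappa value
#'
#' McHugh's interpretation scale, applied to kappa rounded to two decimals
#' (so e.g. 0.797 rounds to 0.80 and is labelled "Strong"): <= .20 None,
#' .21-.39 Minimal, .40-.59 Weak, .60-.79 Moderate, .80-.90 Strong,
#' > .90 Almost Perfect.
#'
#' @param kappa Numeric in \[-1, 1\].
#' @return Character label.
#' @examples
#' kappa_band(0.797) # "Strong"
#' @export
kappa_band <- function(kappa) {
  if (length(kappa) != 1 || is.na(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must be a single value in [-1, 1]", call. = FALSE)
  }
  k <- round_half_away(kappa, 2)
  if (k <= 0.20) "None"
  else if (k <= 0.39) "Minimal"
  else if (k <= 0.59) "Weak"
  else if (k <= 0.79) "Moderate"
  else if (k <= 0.90) "Strong"
  else "Almost Perfect"
}

#' Predicted-vs-actual agreement summary
#'
#' The full agreement analysis for a set of (predicted, actual) integer
#' graft-size pairs: concordant / under- / over-prediction counts, their
#' percentages with exact binomial confidence intervals, and linearly
#' weighted Cohen's kappa with its verbal band.
#'
#' Percentages and CI bounds are stored at full precision; display
#' rounding (integer percent, half away from zero) happens only in the
#' print method and the markdown report, so downstream checks never suffer
#' double rounding.
#'
#' @param predicted_mm,actual_mm Paired integer graft sizes (>= 1 pair).
#' @param level Confidence level for the interval estimates (default 0.95).
#' @param ci_method Passed to [exact_binomial_ci()].
#' @return List of class `agreement_result`: `n`, `n_concordant`,
#'   `n_under`, `n_over`, `concordance_pct`, `concordance_ci`, `under_pct`,
#'   `under_ci`, `over_pct`, `over_ci` (percent scale), `kappa`,
#'   `kappa_degenerate`, `kappa_band`.
#' @export
agreement_summary <- function(predicted_mm, actual_mm, level = 0.95,
                              ci_method = "clopper-pearson") {
  if (length(predicted_mm) < 1) stop("need at least one pair", call. = FALSE)
  cls <- classify_prediction(predicted_mm, actual_mm)
  n <- length(cls)
  counts <- c(concordant = sum(cls == "concordant"),
              under = sum(cls == "under"),
              over = sum(cls == "over"))
  pct_ci <- function(x) 100 * exact_binomial_ci(x, n, level, ci_method)

  if (n >= 2) {
    kap <- weighted_kappa_linear(predicted_mm, actual_mm)
  } else {
    kap <- list(kappa = NA_real_, degenerate = TRUE)
  }

  res <- list(
    n = n,
    n_concordant = unname(counts["concordant"]),
    n_under = unname(counts["under"]),
    n_over = unname(counts["over"]),
    concordance_pct = 100 * counts[["concordant"]] / n,
    concordance_ci = pct_ci(counts[["concordant"]]),
    under_pct = 100 * counts[["under"]] / n,
    under_ci = pct_ci(counts[["under"]]),
    over_pct = 100 * counts[["over"]] / n,
    over_ci = pct_ci(counts[["over"]]),
    kappa = kap$kappa,
    kappa_degenerate = kap$degenerate,
    kappa_band = if (kap$degenerate) NA_character_ else kappa_band(kap$kappa),
    level = level
  )
  class(res) <- "agreement_result"
  res
}

#' @export
print.agreement_result <- function(x, ...) {
  fmt <- function(count, pct, ci) {
    sprintf("%d/%d (%d%%, %g%% CI %d-%d%%)", count, x$n,
            round_half_away(pct), 100 * x$level,
            round_half_away(ci[["lower"]]), round_half_away(ci[["upper"]]))
  }
  cat("Predicted vs actual graft size agreement\n")
  cat("  concordant:", fmt(x$n_concordant, x$concordance_pct, x$concordance_ci), "\n")
  cat("  under-predicted:", fmt(x$n_under, x$under_pct, x$under_ci), "\n")
  cat("  over-predicted:", fmt(x$n_over, x$over_pct, x$over_ci), "\n")
  if (isTRUE(x$kappa_degenerate)) {
    cat("  weighted kappa: undefined (degenerate)\n")
  } else {
    cat(sprintf("  weighted kappa: %.3f (%s)\n", x$kappa, x$kappa_band))
  }
  invisible(x)
}
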