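#' Median and interquartile range
#'
#' Summary used throughout the study report. Quartiles use linear
#' interpolation between order statistics (the default "type 7" convention
#' of [stats::quantile()]).
#'
#' @param values Numeric vector, length >= 1 (missing values rejected).
#' @return List of class `summary_stats`: `n`, `median`, `q1`, `q3`.
#' @examples
#' median_iqr(c(7, 7, 8, 8, 8)) # median 8, IQR 7-8
#' @export
median_iqr <- function(values) {
  if (length(values) < 1) stop("need at least one value", call. = FALSE)
  if (any(is.na(values))) stop("missing values not allowed", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  res <- list(n = length(values), median = q[2], q1 = q[1], q3 = q[3])
  class(res) <- "summary_stats"
  res
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d, median %.2f (IQR %.2f-%.2f)\n", x$n, x$median, x$q1, x$q3))
  invisible(x)
}

# Exact null distribution of W+ (sum of positive signed ranks) by dynamic
# programming over doubled midranks: each observation's rank is added with
# probability 1/2. Handles tied (mid) ranks, where the classical
# no-ties distribution (stats::psignrank) does not apply.
# Returns P(W+ <= w) and P(W+ >= w) for the observed statistic.
signed_rank_exact_tails <- function(ranks, w) {
  r2 <- as.integer(round(ranks * 2)) # midranks doubled -> integers
  total <- sum(r2)
  # probability vector over support 0..total of doubled W+
  p <- numeric(total + 1)
  p[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  w2 <- as.integer(round(w * 2))
  lower <- sum(p[seq_len(w2 + 1)])
  upper <- sum(p[seq.int(w2 + 1, total + 1)])
  c(lower = lower, upper = upper)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on paired differences, used to compare the
#' predicted and actual graft diameter distributions. Zero differences are
#' discarded before ranking (Wilcoxon's original procedure; Pratt's
#' zero-rank method is available as an option). Tied absolute differences
#' receive midranks.
#'
#' The null distribution of the statistic (W+, the sum of ranks of positive
#' differences) is computed exactly — by dynamic programming over the
#' midranks, which remains valid under ties — whenever the number of
#' non-zero differences is at most `exact_threshold`; beyond that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' When every difference is zero the data carry no evidence against the
#' null: the result is flagged `degenerate` with p = 1.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @param zero_method `"wilcox"` (default; discard zero differences) or
#'   `"pratt"` (rank zeros with the rest, then drop their ranks).
#' @param exact_threshold Largest effective n for the exact distribution
#'   (default 25).
#' @return List of class `wilcoxon_result`: `statistic` (W+), `p_value`,
#'   `n_effective`, `method` (`"exact"` / `"normal-approx"` /
#'   `"degenerate"`), `degenerate` (logical).
#' @examples
#' wilcoxon_signed_rank(1:6, 2:7) # all differences -1; exact p = 2/64
#' @export
wilcoxon_signed_rank <- function(a, b, zero_method = c("wilcox", "pratt"),
                                 exact_threshold = 25) {
  zero_method <- match.arg(zero_method)
  if (length(a) != length(b)) stop("paired vectors must have equal length", call. = FALSE)
  if (length(a) < 1) stop("need at least one pair", call. = FALSE)
  d <- a - b
  if (any(is.na(d))) stop("missing values in pairs", call. = FALSE)

  if (all(d == 0)) {
    res <- list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate", degenerate = TRUE)
    class(res) <- "wilcoxon_result"
    return(res)
  }

  if (zero_method == "wilcox") {
    d <- d[d != 0]
    ranks <- rank(abs(d))
  } else {
    # Pratt: rank |d| including zeros, then drop the zero differences
    ranks_all <- rank(abs(d))
    keep <- d != 0
    ranks <- ranks_all[keep]
    d <- d[keep]
  }
  n <- length(d)
  W <- sum(ranks[d > 0])

  if (zero_method == "wilcox" && n <= exact_threshold) {
    tails <- signed_rank_exact_tails(ranks, W)
    p <- min(1, 2 * min(tails))
    method <- "exact"
  } else {
    # normal approximation on the (possibly Pratt-adjusted) rank sum;
    # with midranks, mean = sum(r)/2 and var = sum(r^2)/4 — the latter
    # equals the classical n(n+1)(2n+1)/24 minus the tie correction
    mu <- sum(ranks) / 2
    sigma <- sqrt(sum(ranks^2) / 4)
    z <- (W - mu)
    z <- (z - sign(z) * 0.5) / sigma # continuity correction toward the mean
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, max(p, .Machine$double.xmin))
    method <- "normal-approx"
  }
  res <- list(statistic = W, p_value = p, n_effective = n,
              method = method, degenerate = FALSE)
  class(res) <- "wilcoxon_result"
  res
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Wilcoxon signed-rank: all differences zero (degenerate), p = 1\n")
  } else {
    cat(sprintf("Wilcoxon signed-rank: W+ = %g, n_eff = %d, p = %.4g (%s)\n",
                x$statistic, x$n_effective, x$p_value, x$method))
  }
  invisible(x)
}
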