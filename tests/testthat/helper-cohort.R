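# Build a small deterministic cohort in code: `specs` is a data frame with
# one row per patient giving st/gt major/minor axes; every reader/session
# gets the same measurements unless an offset is supplied per reader or
# session (named numeric vectors, added to every diameter).
make_cohort <- function(specs, reader_offset = c(R1 = 0, R2 = 0),
                        session_offset = c(t0 = 0, t1month = 0)) {
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    p <- specs[i, ]
    for (reader in c("R1", "R2")) {
      for (session in c("t0", "t1month")) {
        off <- reader_offset[[reader]] + session_offset[[session]]
        for (tendon in c("ST", "GT")) {
          maj <- if (tendon == "ST") p$st_major else p$gt_major
          mnr <- if (tendon == "ST") p$st_minor else p$gt_minor
          rows[[length(rows) + 1]] <- data.frame(
            patient_id = p$patient_id,
            age_years = p$age_years,
            sex = p$sex,
            side = p$side,
            actual_graft_mm = p$actual_graft_mm,
            reader = reader, session = session, tendon = tendon,
            major_mm = round(maj + off, 1),
            minor_mm = round(mnr + off, 1)
          )
        }
      }
    }
  }
  graft_cohort(do.call(rbind, rows))
}

default_specs <- function(n = 3) {
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    age_years = 25 + seq_len(n),
    sex = rep(c("M", "F"), length.out = n),
    side = rep(c("left", "right"), length.out = n),
    actual_graft_mm = rep(8L, n),
    st_major = 4.6, st_minor = 4.0,
    gt_major = 3.4, gt_minor = 3.0
  )
}

# Measurement values only, provenance stripped — for value-level
# round-trip comparisons.
cohort_values <- function(co) {
  t <- tibble::as_tibble(co)
  attr(t, "metadata") <- NULL
  t
}

# Independent brute-force linearly weighted kappa: explicit double loops
# over the observed and expected tables. Used as the oracle for
# weighted_kappa_linear.
brute_force_weighted_kappa <- function(pred, act, categories) {
  k <- length(categories)
  n <- length(pred)
  O <- matrix(0, k, k)
  for (idx in seq_len(n)) {
    i <- match(pred[idx], categories)
    j <- match(act[idx], categories)
    O[i, j] <- O[i, j] + 1
  }
  row_m <- rowSums(O)
  col_m <- colSums(O)
  num <- 0
  den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- abs(i - j) / (k - 1)
      num <- num + w * O[i, j]
      den <- den + w * row_m[i] * col_m[j] / n
    }
  }
  if (den == 0) return(NA_real_)
  1 - num / den
}
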