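#' Per-sequence motion scores for a session
#'
#' Computes one [motion_score()] per row of the sequence table; break
#' intervals between sequences are not scored. A sequence with too few
#' valid samples for resampling (or shorter than one second) is reported
#' as missing, not zero.
#'
#' @param trace A [motion_trace()] covering the session.
#' @param table A [sequence_table()].
#' @param ball A [ball_model()].
#' @param ... passed to [motion_score()] (`rate`, `window`, `slope`).
#' @return A `data.frame` with columns `sequence`, `score_mm_per_s`,
#'   `n_seconds`.
#' @export
score_session <- function(trace, table, ball = ball_model(), ...) {
  res <- lapply(seq_len(nrow(table)), function(r) {
    s <- tryCatch(
      motion_score(trace, interval = c(table$start_s[r], table$end_s[r]),
                   ball = ball, ...),
      error = function(e) NULL)
    if (is.null(s)) c(NA_real_, NA_real_) else c(s$value, s$n_seconds_used)
  })
  res <- do.call(rbind, res)
  data.frame(sequence = table$sequence, score_mm_per_s = res[, 1],
             n_seconds = res[, 2])
}

.lme_formula <- motion ~ time + bmi_c + age_c + sex +
  time:bmi_c + time:age_c + time:sex

#' Longitudinal mixed model of session motion
#'
#' Fits the random-intercept linear mixed model of motion versus session
#' time with BMI, age, sex and their time interactions as fixed effects:
#'
#'   `motion ~ time + bmi_c + age_c + sex + time:(bmi_c + age_c + sex)
#'    + (1 | subject_id)`
#'
#' BMI and age must be centered (`bmi_c`, `age_c`); sex is a factor with
#' female as the reference level. Estimation delegates to [lme4::lmer()]
#' (REML by default); this function owns the design construction, rank
#' checking and reporting.
#'
#' @param samples `data.frame` as produced by [make_cohort()]: columns
#'   `subject_id`, `time`, `motion`, `bmi_c`, `age_c`, `sex`.
#' @param reml fit by REML (default) or ML.
#' @return An object of class `lme_fit`: `coefficients` (data.frame with
#'   `estimate`, `se`, `z` for the 8 fixed effects), `var_intercept`,
#'   `var_residual`, `converged`, and the underlying `model`.
#' @export
fit_session_lme <- function(samples, reml = TRUE) {
  need <- c("subject_id", "time", "motion", "bmi_c", "age_c", "sex")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("fit_session_lme: missing columns: ",
                         paste(miss, collapse = ", "))
  if (length(unique(samples$subject_id)) < 2)
    stop("fit_session_lme: need at least 2 subjects")
  X <- stats::model.matrix(.lme_formula, data = samples)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("fit_session_lme: singular design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fml <- stats::update(.lme_formula, . ~ . + (1 | subject_id))
  fit <- lme4::lmer(fml, data = samples, REML = reml)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    coefficients = data.frame(term = names(est), estimate = as.numeric(est),
                              se = as.numeric(se),
                              z = as.numeric(est / se)),
    var_intercept = vc$vcov[vc$grp == "subject_id"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    converged = is.null(msgs) || length(msgs) == 0,
    model = fit), class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("<lme_fit> random-intercept model\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("var(intercept) = %.4g, var(residual) = %.4g, converged: %s\n",
              x$var_intercept, x$var_residual, x$converged))
  invisible(x)
}

#' Express a coefficient as percent of mean motion
#'
#' @param value coefficient in mm/s.
#' @param samples cohort samples with a `motion` column.
#' @return `value / mean(motion) * 100`.
#' @export
pct_of_mean_motion <- function(value, samples) {
  value / mean(samples$motion) * 100
}

#' Proxy correlation of a reference score with later time bins
#'
#' Pearson correlation, per time bin, between a per-subject reference
#' motion score (e.g. from an initial fMRI sequence) and later binned
#' scores. Bins with fewer than `min_frac` of subjects available are
#' discarded.
#'
#' @param reference_scores named or positional per-subject scalars.
#' @param later_scores matrix or data.frame, subjects x bins, `NA` allowed.
#' @param min_frac minimum fraction of non-missing subjects per bin.
#' @return `data.frame` with `bin`, `r`, `p`, `n`.
#' @export
proxy_correlation <- function(reference_scores, later_scores,
                              min_frac = 0.9) {
  later_scores <- as.matrix(later_scores)
  stopifnot(length(reference_scores) == nrow(later_scores))
  keep <- colMeans(!is.na(later_scores)) >= min_frac
  bins <- which(keep)
  res <- lapply(bins, function(b) {
    y <- later_scores[, b]
    ok <- !is.na(y) & !is.na(reference_scores)
    ct <- cor.test(reference_scores[ok], y[ok])
    data.frame(bin = b, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  if (length(res) == 0)
    return(data.frame(bin = integer(), r = numeric(), p = numeric(),
                      n = integer()))
  do.call(rbind, res)
}

#' Correlation of motion scores with image-quality metrics
#'
#' Pearson r (with two-sided p) between per-scan motion scores and each
#' column of a quality-metric table, dropping missing pairs listwise. A
#' constant metric has undefined correlation and is reported as `NA`.
#'
#' @param scores per-scan motion scores.
#' @param qc_table `data.frame` of per-scan metric columns, rows matched to
#'   `scores`.
#' @return `data.frame` with `metric`, `r`, `p`, `n`.
#' @export
quality_correlation <- function(scores, qc_table) {
  stopifnot(length(scores) == nrow(qc_table))
  res <- lapply(names(qc_table), function(m) {
    y <- qc_table[[m]]
    ok <- !is.na(y) & !is.na(scores)
    if (sum(ok) < 3 || sd(y[ok]) == 0 || sd(scores[ok]) == 0)
      return(data.frame(metric = m, r = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- cor.test(scores[ok], y[ok])
    data.frame(metric = m, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  do.call(rbind, res)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Non-parametric paired test used for method contrasts (e.g. two
#' registration variants measured on the same sessions). Exact p-values
#' for small samples without ties.
#'
#' @param x,y paired measurements.
#' @param ... passed to [stats::wilcox.test()].
#' @return The `htest` result.
#' @export
wilcoxon_paired <- function(x, y, ...) {
  wilcox.test(x, y, paired = TRUE, exact = TRUE, correct = FALSE, ...)
}
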