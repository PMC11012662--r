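# Two-way ANOVA reliability machinery: mean-square decomposition, the four
# two-way ICC forms with F tests and 95% confidence intervals, the standard
# error of measurement, and the interpretation bands.

#' Descriptive statistics with a documented quantile rule
#'
#' Mean, sample standard deviation (n-1 denominator), min, max, median and
#' interquartile range (Q3 - Q1) with quartiles by linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' @param values Numeric vector (no NAs); at least 2 values are needed for
#'   the standard deviation.
#' @return Named list `n`, `min`, `max`, `mean`, `sd`, `median`, `iqr`.
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) {
    stop("descriptive_stats: need a non-empty vector of finite values", call. = FALSE)
  }
  if (length(values) < 2L) {
    stop("descriptive_stats: at least 2 values are required for the standard deviation",
         call. = FALSE)
  }
  qs <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  list(
    n = length(values),
    min = min(values),
    max = max(values),
    mean = mean(values),
    sd = stats::sd(values),
    median = stats::median(values),
    iqr = qs[2L] - qs[1L]
  )
}

#' Two-way crossed ANOVA mean squares for a subject x rater grid
#'
#' Decomposes a complete subject-by-rater grid of single measurements into
#' between-subject (rows), between-rater (columns) and residual sums of
#' squares — the decomposition underlying every two-way ICC form. The three
#' components sum to the total sum of squares.
#'
#' @param grid Numeric matrix, rows = subjects (n >= 2), columns = raters
#'   (k >= 2), no missing cells.
#' @return Object of class `anova_mean_squares`: `ms_rows`, `ms_cols`,
#'   `ms_error`, the degrees of freedom `df_rows` = n-1, `df_cols` = k-1,
#'   `df_error` = (n-1)(k-1), and `n_subjects`, `k_raters`, `ss_total`.
#' @export
#' @examples
#' anova_mean_squares(rbind(c(1, 2), c(3, 4), c(5, 6)))
anova_mean_squares <- function(grid) {
  grid <- as.matrix(grid)
  n <- nrow(grid)
  k <- ncol(grid)
  if (n < 2L || k < 2L) {
    stop("anova_mean_squares: need at least 2 subjects and 2 raters", call. = FALSE)
  }
  if (anyNA(grid)) {
    idx <- which(is.na(grid), arr.ind = TRUE)[1L, ]
    subj <- if (!is.null(rownames(grid))) rownames(grid)[idx[1L]] else idx[1L]
    rat <- if (!is.null(colnames(grid))) colnames(grid)[idx[2L]] else idx[2L]
    stop(sprintf("anova_mean_squares: missing cell at subject '%s', rater '%s'",
                 subj, rat), call. = FALSE)
  }
  grand <- mean(grid)
  row_means <- rowMeans(grid)
  col_means <- colMeans(grid)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((grid - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  df_rows <- n - 1L
  df_cols <- k - 1L
  df_error <- (n - 1L) * (k - 1L)
  structure(
    list(
      ms_rows = ss_rows / df_rows,
      ms_cols = ss_cols / df_cols,
      ms_error = max(0, ss_error) / df_error,
      df_rows = df_rows, df_cols = df_cols, df_error = df_error,
      n_subjects = n, k_raters = k,
      ss_total = ss_total
    ),
    class = "anova_mean_squares"
  )
}

#' The four two-way ICC forms
#'
#' Names follow the single/average-measures by consistency/agreement
#' taxonomy: `single_consistency` = ICC(C,1), `single_agreement` = ICC(A,1),
#' `average_consistency` = ICC(C,k), `average_agreement` = ICC(A,k).
#'
#' @format Character vector of the four accepted `form` values.
#' @export
ICC_FORMS <- c("single_consistency", "single_agreement",
               "average_consistency", "average_agreement")

.icc_point <- function(ms, form) {
  msr <- ms$ms_rows; msc <- ms$ms_cols; mse <- ms$ms_error
  n <- ms$n_subjects; k <- ms$k_raters
  if (mse == 0) {
    # perfect residual fit: consistency ICCs are exactly 1
    return(switch(form,
      single_consistency = 1,
      average_consistency = 1,
      single_agreement = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
      average_agreement = (msr - mse) / (msr + (msc - mse) / n)
    ))
  }
  switch(form,
    single_consistency = (msr - mse) / (msr + (k - 1) * mse),
    single_agreement = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    average_consistency = (msr - mse) / msr,
    average_agreement = (msr - mse) / (msr + (msc - mse) / n)
  )
}

#' Intraclass correlation coefficient from two-way mean squares
#'
#' Computes one of the four two-way ICC forms from an
#' [anova_mean_squares()] decomposition (MSR between subjects, MSC between
#' raters, MSE residual):
#' \itemize{
#'   \item single/consistency: (MSR - MSE) / (MSR + (k-1) MSE)
#'   \item single/agreement: (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))
#'   \item average/consistency: (MSR - MSE) / MSR  (equals 1 - 1/F)
#'   \item average/agreement: (MSR - MSE) / (MSR + (MSC - MSE)/n)
#' }
#' The F test of subject discrimination is F = MSR/MSE on (n-1, (n-1)(k-1))
#' degrees of freedom; with MSE = 0 the consistency forms are exactly 1 and F
#' is reported as infinite.
#'
#' @param ms An `anova_mean_squares` object, or a complete subject x rater
#'   matrix (decomposed internally).
#' @param form One of [ICC_FORMS].
#' @param level Confidence level for the interval (default 0.95).
#' @return Object of class `icc_result`: `form`, `value`, `ci_low`,
#'   `ci_high`, `f_value`, `p_value`, `level`, `n_subjects`, `k_raters`.
#' @seealso [icc_confidence_interval()], [classify_icc()]
#' @export
icc <- function(ms, form = "single_consistency", level = 0.95) {
  if (is.matrix(ms) || is.data.frame(ms)) ms <- anova_mean_squares(ms)
  form <- match.arg(form, ICC_FORMS)
  value <- .icc_point(ms, form)
  f_value <- if (ms$ms_error == 0) Inf else ms$ms_rows / ms$ms_error
  p_value <- if (is.infinite(f_value)) 0 else
    stats::pf(f_value, ms$df_rows, ms$df_error, lower.tail = FALSE)
  ci <- icc_confidence_interval(ms, form, level = level)
  structure(
    list(
      form = form, value = value,
      ci_low = ci[[1L]], ci_high = ci[[2L]],
      f_value = f_value, p_value = p_value, level = level,
      n_subjects = ms$n_subjects, k_raters = ms$k_raters
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s): %.3f  %g%% CI [%.3f, %.3f]  F = %.3g, p = %.3g  (%s)\n",
              x$form, x$value, 100 * x$level, x$ci_low, x$ci_high,
              x$f_value, x$p_value, classify_icc(x$value)))
  invisible(x)
}

#' Confidence interval for a two-way ICC
#'
#' Consistency forms use the exact F-ratio construction: with
#' Fo = MSR/MSE, FL = Fo / F(1-alpha/2; n-1, (n-1)(k-1)) and
#' FU = Fo * F(1-alpha/2; (n-1)(k-1), n-1), the single-measures bounds are
#' (FL-1)/(FL+k-1) and (FU-1)/(FU+k-1) and the average-measures bounds are
#' 1 - 1/FL and 1 - 1/FU. Agreement forms use the Satterthwaite
#' degrees-of-freedom construction for the rater-plus-error denominator; the
#' average-measures agreement bounds are the single-measures bounds pushed
#' through the Spearman-Brown step-up. With MSE = 0 the interval degenerates
#' to [value, value].
#'
#' @inheritParams icc
#' @return Numeric `c(ci_low, ci_high)`; the interval always contains the
#'   point estimate.
#' @export
icc_confidence_interval <- function(ms, form = "single_consistency", level = 0.95) {
  if (is.matrix(ms) || is.data.frame(ms)) ms <- anova_mean_squares(ms)
  form <- match.arg(form, ICC_FORMS)
  value <- .icc_point(ms, form)
  if (ms$ms_error == 0) return(c(ci_low = value, ci_high = value))
  alpha <- 1 - level
  msr <- ms$ms_rows; msc <- ms$ms_cols; mse <- ms$ms_error
  n <- ms$n_subjects; k <- ms$k_raters
  df1 <- ms$df_rows; df2 <- ms$df_error

  if (form %in% c("single_consistency", "average_consistency")) {
    fo <- msr / mse
    fl <- fo / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fo * stats::qf(1 - alpha / 2, df2, df1)
    if (form == "single_consistency") {
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else {
      ci <- c(1 - 1 / fl, 1 - 1 / fu)
    }
  } else {
    # Satterthwaite df for the combined rater + residual mean square
    r1 <- .icc_point(ms, "single_agreement")
    a <- k * r1 / (n * (1 - r1))
    b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_star_l <- stats::qf(1 - alpha / 2, df1, v)
    f_star_u <- stats::qf(1 - alpha / 2, v, df1)
    low1 <- n * (msr - f_star_l * mse) /
      (f_star_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    up1 <- n * (f_star_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_star_u * msr)
    if (form == "single_agreement") {
      ci <- c(low1, up1)
    } else {
      step_up <- function(r) k * r / (1 + (k - 1) * r)
      ci <- c(step_up(low1), step_up(up1))
    }
  }
  # numerical guard: the interval must contain the point estimate
  c(ci_low = min(ci[1L], value), ci_high = max(ci[2L], value))
}

#' Standard error of measurement
#'
#' SEM = SD * sqrt(1 - ICC): the measurement-error scale of a parameter in
#' its own units, relating the reliability coefficient to the sample spread.
#' SEM is 0 exactly when ICC = 1 (for SD > 0), decreases monotonically in the
#' ICC at fixed SD and is linear in SD at fixed ICC.
#'
#' @param sd Sample standard deviation of the measure (>= 0).
#' @param icc_value Reliability coefficient (<= 1).
#' @return Object of class `sem_result`: `sem`, `sd_used`, `icc_used`.
#' @export
#' @examples
#' sem_measurement(9.5, 0.990) # 0.95
sem_measurement <- function(sd, icc_value) {
  if (!is.finite(sd) || sd < 0) stop("sem_measurement: sd must be >= 0", call. = FALSE)
  if (!is.finite(icc_value) || icc_value > 1) {
    stop("sem_measurement: icc_value must be <= 1", call. = FALSE)
  }
  structure(
    list(sem = sd * sqrt(1 - icc_value), sd_used = sd, icc_used = icc_value),
    class = "sem_result"
  )
}

#' @export
print.sem_result <- function(x, ...) {
  cat(sprintf("SEM = %.3g (SD %.3g x sqrt(1 - ICC %.3g))\n",
              x$sem, x$sd_used, x$icc_used))
  invisible(x)
}

#' Interpretation band of an ICC value
#'
#' Bands: below 0.5 poor, 0.5 to below 0.75 moderate, 0.75 to below 0.9 good,
#' 0.9 and above excellent. Bands are left-closed, so 0.75 classifies as
#' "good" and 0.9 as "excellent".
#'
#' @param value ICC value (<= 1).
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
classify_icc <- function(value) {
  if (any(value > 1, na.rm = TRUE)) stop("classify_icc: ICC cannot exceed 1", call. = FALSE)
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v < 0.5) "poor" else if (v < 0.75) "moderate" else if (v < 0.9) "good" else "excellent"
  }, character(1))
}
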