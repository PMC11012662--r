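# Observer-reliability study runners on long-format ratings tables:
# inter-observer (reproducibility), intra-observer (repeatability), the
# descriptives-with-SEM table, group comparison and the normality check.

#' Read a long-format ratings table
#'
#' Columns: `subject_id`, `rater_id`, `occasion` (1 or 2), `measure` (one of
#' [MEASURE_NAMES]), `value`. One row per single rating.
#'
#' @param path CSV path.
#' @return A `data.frame` with the five columns above.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "rater_id", "occasion", "measure", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("ratings CSV '%s' lacks column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$rater_id <- as.character(df$rater_id)
  df$occasion <- as.integer(df$occasion)
  df$value <- as.numeric(df$value)
  df
}

#' Write a long-format ratings table
#'
#' @param ratings Data frame as returned by [read_ratings()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

# Pivot one (measure, occasion) slice to a complete subject x rater grid.
# Errors name every missing (subject, rater) cell.
.ratings_grid <- function(ratings, measure, occasion) {
  slice <- ratings[ratings$measure == measure & ratings$occasion == occasion, ]
  if (nrow(slice) == 0L) {
    stop(sprintf("no ratings for measure '%s' at occasion %d", measure, occasion),
         call. = FALSE)
  }
  subjects <- sort(unique(slice$subject_id))
  raters <- sort(unique(slice$rater_id))
  grid <- matrix(NA_real_, length(subjects), length(raters),
                 dimnames = list(subjects, raters))
  grid[cbind(match(slice$subject_id, subjects), match(slice$rater_id, raters))] <-
    slice$value
  if (anyNA(grid)) {
    idx <- which(is.na(grid), arr.ind = TRUE)
    cells <- apply(idx, 1L, function(i) {
      sprintf("(%s, %s)", subjects[i[1L]], raters[i[2L]])
    })
    stop(sprintf(
      "incomplete subject x rater grid for measure '%s', occasion %d; missing cell(s): %s",
      measure, occasion, paste(cells, collapse = ", ")), call. = FALSE)
  }
  grid
}

#' Unweighted column means of a per-measure reliability table
#'
#' The "Total Mean" summary convention: the unweighted mean over the measures
#' of each numeric column (ICC values, CI bounds, per-rater minima/maxima,
#' ...).
#'
#' @param df Data frame with one row per measure; non-numeric columns are
#'   dropped.
#' @return One-row data frame of column means.
#' @export
reliability_summary_row <- function(df) {
  num <- df[vapply(df, is.numeric, logical(1))]
  as.data.frame(as.list(colMeans(num)))
}

#' Inter-observer (reproducibility) reliability study
#'
#' For each measure, pivots the ratings at the given occasion to a complete
#' subject x rater grid, runs the two-way ANOVA ICC, and appends the
#' unweighted "Total Mean" summary row over the measures (means of the ICC
#' values and of the CI bounds).
#'
#' @param ratings Long-format ratings data frame ([read_ratings()]).
#' @param occasion Which round to analyse (default 1, the convention for
#'   reproducibility).
#' @param form ICC form (default `"average_agreement"`: the reliability of
#'   the k-rater mean with raters treated as a source of absolute
#'   disagreement).
#' @param measures Measures to analyse (default: all present).
#' @param level Confidence level (default 0.95).
#' @return Object of class `interobserver_study`: `results` (one row per
#'   measure: `measure`, `icc`, `ci_low`, `ci_high`, `f_value`, `p_value`,
#'   `band`), `total_mean` (summary row), plus `form`, `occasion`, `level`
#'   and the per-measure `icc_objects`.
#' @export
interobserver_study <- function(ratings, occasion = 1, form = "average_agreement",
                                measures = NULL, level = 0.95) {
  form <- match.arg(form, ICC_FORMS)
  if (is.null(measures)) {
    measures <- intersect(MEASURE_NAMES, unique(ratings$measure))
    if (length(measures) == 0L) measures <- sort(unique(ratings$measure))
  }
  objs <- lapply(measures, function(m) {
    icc(.ratings_grid(ratings, m, occasion), form = form, level = level)
  })
  names(objs) <- measures
  results <- data.frame(
    measure = measures,
    icc = vapply(objs, `[[`, numeric(1), "value"),
    ci_low = vapply(objs, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(objs, `[[`, numeric(1), "ci_high"),
    f_value = vapply(objs, `[[`, numeric(1), "f_value"),
    p_value = vapply(objs, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  results$band <- classify_icc(pmin(results$icc, 1))
  rownames(results) <- NULL
  structure(
    list(results = results,
         total_mean = reliability_summary_row(
           results[c("icc", "ci_low", "ci_high")]),
         form = form, occasion = occasion, level = level,
         icc_objects = objs),
    class = "interobserver_study"
  )
}

#' @export
print.interobserver_study <- function(x, ...) {
  cat(sprintf("Inter-observer reliability (occasion %d, ICC form %s)\n",
              x$occasion, x$form))
  out <- x$results
  out$icc <- round(out$icc, 3)
  out$ci_low <- round(out$ci_low, 3)
  out$ci_high <- round(out$ci_high, 3)
  out$f_value <- signif(out$f_value, 4)
  out$p_value <- signif(out$p_value, 3)
  print(out, row.names = FALSE)
  cat(sprintf("Total mean ICC %.3f, CI [%.3f, %.3f]\n",
              x$total_mean$icc, x$total_mean$ci_low, x$total_mean$ci_high))
  invisible(x)
}

#' Aggregate a rater x measure ICC matrix (the repeatability convention)
#'
#' Per measure: mean, SD, minimum and maximum of the per-rater ICCs, plus a
#' "Total Mean" row of unweighted column-wise means over the measures
#' (including the mean of the per-measure minima and maxima).
#'
#' @param icc_matrix Numeric matrix, rows = raters, columns = measures.
#' @return List with `per_measure` (data frame: `measure`, `mean`, `sd`,
#'   `min`, `max`) and `total_mean` (one-row data frame).
#' @export
aggregate_intraobserver <- function(icc_matrix) {
  icc_matrix <- as.matrix(icc_matrix)
  per <- data.frame(
    measure = colnames(icc_matrix),
    mean = colMeans(icc_matrix),
    sd = apply(icc_matrix, 2L, stats::sd),
    min = apply(icc_matrix, 2L, min),
    max = apply(icc_matrix, 2L, max),
    stringsAsFactors = FALSE
  )
  rownames(per) <- NULL
  list(per_measure = per,
       total_mean = reliability_summary_row(per[c("mean", "sd", "min", "max")]))
}

#' Intra-observer (repeatability) reliability study
#'
#' For each rater and measure, the test-retest ICC is computed on that
#' rater's subject x occasion grid (k = 2 occasions). Results are aggregated
#' per measure over the raters (mean, SD, min, max) with the unweighted
#' "Total Mean" row over the measures.
#'
#' @param ratings Long-format ratings data frame with both occasions present
#'   for every rater, subject and measure.
#' @param form ICC form for the occasion grid (default
#'   `"single_consistency"`: repeatability of a single rating, indifferent to
#'   a systematic shift between rounds).
#' @param measures Measures to analyse (default: all present).
#' @param level Confidence level for the per-grid ICCs.
#' @return Object of class `intraobserver_study`: `icc_matrix` (raters x
#'   measures), `per_measure`, `total_mean`, `form`.
#' @export
intraobserver_study <- function(ratings, form = "single_consistency",
                                measures = NULL, level = 0.95) {
  form <- match.arg(form, ICC_FORMS)
  if (is.null(measures)) {
    measures <- intersect(MEASURE_NAMES, unique(ratings$measure))
    if (length(measures) == 0L) measures <- sort(unique(ratings$measure))
  }
  raters <- sort(unique(ratings$rater_id))
  occasions <- sort(unique(ratings$occasion))
  if (length(occasions) < 2L) {
    stop("intraobserver_study: both occasions are required", call. = FALSE)
  }
  mat <- matrix(NA_real_, length(raters), length(measures),
                dimnames = list(raters, measures))
  for (r in raters) {
    sub <- ratings[ratings$rater_id == r, ]
    for (m in measures) {
      slice <- sub[sub$measure == m, ]
      subjects <- sort(unique(ratings$subject_id))
      grid <- matrix(NA_real_, length(subjects), length(occasions),
                     dimnames = list(subjects, paste0("occ", occasions)))
      grid[cbind(match(slice$subject_id, subjects),
                 match(slice$occasion, occasions))] <- slice$value
      if (anyNA(grid)) {
        idx <- which(is.na(grid), arr.ind = TRUE)[1L, ]
        stop(sprintf(
          "intraobserver_study: rater '%s' is missing occasion %s for subject '%s' (measure '%s')",
          r, occasions[idx[2L]], subjects[idx[1L]], m), call. = FALSE)
      }
      mat[r, m] <- icc(grid, form = form, level = level)$value
    }
  }
  agg <- aggregate_intraobserver(mat)
  structure(
    list(icc_matrix = mat, per_measure = agg$per_measure,
         total_mean = agg$total_mean, form = form),
    class = "intraobserver_study"
  )
}

#' @export
print.intraobserver_study <- function(x, ...) {
  cat(sprintf("Intra-observer repeatability (ICC form %s, %d raters)\n",
              x$form, nrow(x$icc_matrix)))
  out <- x$per_measure
  out[-1L] <- lapply(out[-1L], round, 3)
  print(out, row.names = FALSE)
  cat(sprintf("Total mean %.3f (sd %.2f, range %.3f-%.3f)\n",
              x$total_mean$mean, x$total_mean$sd,
              x$total_mean$min, x$total_mean$max))
  invisible(x)
}

#' Descriptives-with-SEM table for a rater study
#'
#' For each measure: descriptive statistics of the n per-subject means over
#' raters at the given occasion, plus the standard error of measurement
#' pairing that SD with the inter-observer ICC of the same slice
#' (SEM = SD * sqrt(1 - ICC)).
#'
#' @inheritParams interobserver_study
#' @param form ICC form used for the SEM pairing (default
#'   `"average_agreement"`, the inter-observer default).
#' @return Data frame: `measure`, `n`, `min`, `max`, `mean`, `sd`, `median`,
#'   `iqr`, `icc`, `sem`.
#' @export
descriptives_table <- function(ratings, occasion = 1, form = "average_agreement",
                               measures = NULL) {
  form <- match.arg(form, ICC_FORMS)
  if (is.null(measures)) {
    measures <- intersect(MEASURE_NAMES, unique(ratings$measure))
    if (length(measures) == 0L) measures <- sort(unique(ratings$measure))
  }
  rows <- lapply(measures, function(m) {
    grid <- .ratings_grid(ratings, m, occasion)
    per_subject <- rowMeans(grid)
    d <- descriptive_stats(per_subject)
    ic <- icc(grid, form = form)$value
    data.frame(measure = m, n = d$n, min = d$min, max = d$max, mean = d$mean,
               sd = d$sd, median = d$median, iqr = d$iqr, icc = ic,
               sem = sem_measurement(d$sd, min(ic, 1))$sem,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample pooled-variance Student's t test
#'
#' Classical two-sided Student's t with the pooled variance estimate,
#' reported with the 0.05 significance convention. Degenerate inputs: zero
#' pooled variance with equal means gives t = 0, p = 1; zero pooled variance
#' with unequal means is an error.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return List `t`, `df`, `p_value`, `significant` (p < 0.05),
#'   `mean_a`, `mean_b`.
#' @export
#' @examples
#' group_compare(c(1, 2, 3), c(2, 3, 4))
group_compare <- function(group_a, group_b) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2L || nb < 2L) {
    stop("group_compare: each group needs at least 2 values", call. = FALSE)
  }
  df <- na + nb - 2L
  pooled <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / df
  dmean <- mean(group_a) - mean(group_b)
  if (pooled == 0) {
    if (dmean == 0) {
      return(list(t = 0, df = df, p_value = 1, significant = FALSE,
                  mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    stop("group_compare: zero pooled variance with unequal means", call. = FALSE)
  }
  t_stat <- dmean / sqrt(pooled * (1 / na + 1 / nb))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(t = t_stat, df = df, p_value = p, significant = p < 0.05,
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Normality check (Kolmogorov-Smirnov)
#'
#' One-sample KS statistic of the values against a normal with the sample
#' mean and SD. Because the parameters are estimated from the same sample,
#' the plain KS p-value is conservative; `method = "lilliefors"` applies the
#' Lilliefors correction (via \pkg{nortest}). The result is advisory only — a
#' `flag` of `"normal"`, `"non-normal"` (p below `alpha`) or
#' `"non-testable"` for degenerate (constant) input — and never blocks a
#' downstream analysis.
#'
#' @param values Numeric vector, n >= 5.
#' @param method `"ks"` (default) or `"lilliefors"`.
#' @param alpha Flagging threshold (default 0.05).
#' @return List `statistic`, `p_value`, `flag`, `method`.
#' @export
normality_check <- function(values, method = c("ks", "lilliefors"), alpha = 0.05) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) < 5L) {
    stop("normality_check: at least 5 values are required", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                flag = "non-testable", method = method))
  }
  res <- if (method == "ks") {
    suppressWarnings(stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  } else {
    nortest::lillie.test(values)
  }
  list(statistic = unname(res$statistic), p_value = res$p.value,
       flag = if (res$p.value < alpha) "non-normal" else "normal",
       method = method)
}
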