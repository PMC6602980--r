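#' Stage window specification
#'
#' The pre/during-anesthesia comparison uses two segments of each
#' recording: stage 1 is a 150-300 s window of heart-rate data ending at
#' anesthetic induction (baseline autonomic tone); stage 2 is a 300 s
#' window during maintenance, placed within minutes 15-30 of the recording
#' (default: minutes 15-20, matching the resting-control extraction).
#' Windows are `(start_s, end_s)` in seconds from recording start and must
#' not overlap.
#'
#' @param stage1_window Length-2 numeric `(start_s, end_s)`; length must be
#'   in `[150, 300]` s.
#' @param stage2_window Length-2 numeric `(start_s, end_s)`; length must be
#'   exactly 300 s.
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(stage1_window, stage2_window = c(900, 1200)) {
  check_window <- function(w, what) {
    if (!is.numeric(w) || length(w) != 2 || anyNA(w) || w[2] <= w[1]) {
      hrv_validation_error(sprintf("%s must be (start_s, end_s) with end > start", what))
    }
  }
  check_window(stage1_window, "stage1_window")
  check_window(stage2_window, "stage2_window")
  len1 <- diff(stage1_window)
  if (len1 < 150 - .time_eps || len1 > 300 + .time_eps) {
    hrv_validation_error("stage 1 window length must be within [150, 300] s")
  }
  if (abs(diff(stage2_window) - 300) > .time_eps) {
    hrv_validation_error("stage 2 window length must be exactly 300 s")
  }
  if (stage1_window[2] > stage2_window[1] + .time_eps &&
      stage2_window[2] > stage1_window[1] + .time_eps) {
    hrv_validation_error("stage windows must not overlap")
  }
  structure(list(stage1_window = as.numeric(stage1_window),
                 stage2_window = as.numeric(stage2_window)),
            class = "stage_spec")
}

#' Extract a stage segment from a recording
#'
#' Restricts a series to the grid samples inside `[start_s, end_s]`
#' (inclusive); the validity mask is carried over unchanged. With a `role`,
#' the stage-length rules of [stage_spec()] are enforced on the window.
#'
#' @param series An [hr_series()].
#' @param window Length-2 numeric `(start_s, end_s)`, seconds from
#'   recording start.
#' @param role `"none"` (default), `"stage1"` (length must be 150-300 s)
#'   or `"stage2"` (length must be 300 s).
#' @return An [hr_series()] on the same grid, restricted to the window.
#' @export
extract_stage <- function(series, window, role = c("none", "stage1", "stage2")) {
  stopifnot(inherits(series, "hr_series"))
  role <- match.arg(role)
  if (!is.numeric(window) || length(window) != 2 || anyNA(window) ||
      window[2] <= window[1]) {
    hrv_validation_error("`window` must be (start_s, end_s) with end > start")
  }
  len <- diff(window)
  if (role == "stage1" && (len < 150 - .time_eps || len > 300 + .time_eps)) {
    hrv_validation_error("stage 1 window length must be within [150, 300] s")
  }
  if (role == "stage2" && abs(len - 300) > .time_eps) {
    hrv_validation_error("stage 2 window length must be exactly 300 s")
  }
  if (window[1] < series$start_time - .time_eps ||
      window[2] > hr_end(series) + .time_eps) {
    hrv_range_error(sprintf(
      "window [%g, %g] s extends outside the recording [%g, %g] s",
      window[1], window[2], series$start_time, hr_end(series)))
  }
  t <- hr_times(series)
  sel <- t >= window[1] - .time_eps & t <= window[2] + .time_eps
  hr_series(series$values[sel], start_time = t[sel][1],
            sampling_interval = series$sampling_interval,
            valid = series$valid[sel])
}

#' Summary statistics for a set of descriptor values
#'
#' Mean, median (midpoint convention) and interquartile range with
#' linear-interpolation quartiles (R's default quantile type 7). The
#' quartile convention matters when reporting IQRs for small cohorts and is
#' therefore fixed and documented.
#'
#' @param values Numeric vector with at least one finite value.
#' @return A list with `mean`, `median`, `iqr`, `n`.
#' @export
#' @examples
#' summarize_values(c(1, 2, 3, 4))
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) hrv_insufficient("no values to summarize")
  list(mean = mean(values),
       median = stats::median(values),
       iqr = unname(stats::quantile(values, 0.75, type = 7) -
                    stats::quantile(values, 0.25, type = 7)),
       n = length(values))
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Unpaired two-sided rank-sum test between two groups. The exact null
#' distribution is used when both groups have at most 8 observations and
#' there are no ties; otherwise the normal approximation with midranks,
#' tie correction and continuity correction is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list with `U` (the Mann-Whitney statistic for `group_a`),
#'   `p_value`, and `exact` (logical, which branch was used).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    hrv_insufficient("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= 8 && length(group_b) <= 8 && !ties
  ht <- stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(U = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Compare pre-induction and maintenance stages across a cohort
#'
#' For each descriptor (SD1, SD2), summarizes the per-subject stage-1 and
#' stage-2 values and tests the stage difference with the unpaired
#' two-sided rank-sum test ([rank_sum_test()]). Subjects missing either
#' stage are excluded with a warning.
#'
#' @param per_subject A data frame with columns `subject`, `stage`
#'   (`"stage1"`/`"stage2"`), `sd1`, `sd2`: one row per subject and stage.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `stage_comparison_report`: per metric, the
#'   stage summaries ([summarize_values()]), the U statistic, p-value and
#'   significance flag.
#' @seealso [cohort_stage_descriptors()] to build `per_subject` from
#'   recordings.
#' @export
compare_stages <- function(per_subject, alpha = 0.05) {
  req <- c("subject", "stage", "sd1", "sd2")
  if (!is.data.frame(per_subject) || !all(req %in% names(per_subject))) {
    hrv_validation_error(
      "`per_subject` must be a data frame with columns subject, stage, sd1, sd2")
  }
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    hrv_config_error("`alpha` must be in (0, 1)")
  }
  if (!all(per_subject$stage %in% c("stage1", "stage2"))) {
    hrv_validation_error("`stage` must be 'stage1' or 'stage2'")
  }
  tab <- table(factor(per_subject$subject),
               factor(per_subject$stage, levels = c("stage1", "stage2")))
  complete <- rownames(tab)[tab[, "stage1", drop = TRUE] >= 1 &
                            tab[, "stage2", drop = TRUE] >= 1]
  excluded <- setdiff(unique(as.character(per_subject$subject)), complete)
  if (length(excluded) > 0) {
    warning(sprintf("excluding %d subject(s) missing a stage: %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
  }
  if (length(complete) < 2) {
    hrv_insufficient("need at least 2 subjects with both stages")
  }
  keep <- per_subject$subject %in% complete
  df <- per_subject[keep, , drop = FALSE]
  one_metric <- function(metric) {
    a <- df[[metric]][df$stage == "stage1"]
    b <- df[[metric]][df$stage == "stage2"]
    test <- rank_sum_test(a, b)
    list(stage1 = summarize_values(a), stage2 = summarize_values(b),
         U = test$U, p_value = test$p_value,
         significant = test$p_value < alpha)
  }
  structure(list(sd1 = one_metric("sd1"), sd2 = one_metric("sd2"),
                 alpha = alpha, n_subjects = length(complete),
                 excluded = excluded),
            class = "stage_comparison_report")
}

#' @export
print.stage_comparison_report <- function(x, ...) {
  cat(sprintf("Stage comparison (n = %d subjects, alpha = %g)\n",
              x$n_subjects, x$alpha))
  cat(sprintf("%-14s %8s %8s %8s %10s\n",
              "", "Mean", "Median", "IQR", "p"))
  for (metric in c("sd1", "sd2")) {
    m <- x[[metric]]
    lab <- toupper(metric)
    star <- if (m$significant) "*" else ""
    cat(sprintf("%-14s %8.2f %8.2f %8.2f %9.3g%s\n",
                paste0(lab, " stage 1"), m$stage1$mean, m$stage1$median,
                m$stage1$iqr, m$p_value, star))
    cat(sprintf("%-14s %8.2f %8.2f %8.2f\n",
                paste0(lab, " stage 2"), m$stage2$mean, m$stage2$median,
                m$stage2$iqr))
  }
  if (length(x$excluded) > 0) {
    cat(sprintf("Excluded (missing a stage): %s\n",
                paste(x$excluded, collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a stage-comparison report to JSON
#'
#' @param report A [compare_stages()] result.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "stage_comparison_report"))
  obj <- unclass(report)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    write_lines_checked(json, path)
    return(invisible(json))
  }
  json
}

#' Per-subject stage descriptors from a cohort of recordings
#'
#' Convenience pipeline for [compare_stages()]: for every subject, applies
#' the artifact filter, extracts both stage windows, and computes the
#' Poincare descriptors of each. Subjects whose stage segment yields too
#' few pairs are reported with `NA` and excluded downstream.
#'
#' @param recordings Named list of [hr_series()], one per subject.
#' @param spec A [stage_spec()], or a data frame manifest with columns
#'   `subject_id`, `induction_time_s`, `stage2_start_s` giving per-subject
#'   windows (stage 1 = the 300 s ending at induction, or `(0, 300)` when
#'   induction is `NA`; stage 2 = 300 s from `stage2_start_s`).
#' @param filter A [filter_config()] applied to each recording, or `NULL`.
#' @return A data frame with columns `subject`, `stage`, `sd1`, `sd2`.
#' @export
cohort_stage_descriptors <- function(recordings, spec,
                                     filter = filter_config()) {
  stopifnot(is.list(recordings), length(names(recordings)) == length(recordings))
  rows <- list()
  for (subj in names(recordings)) {
    series <- recordings[[subj]]
    if (!is.null(filter)) series <- filter_ectopic(series, filter)
    if (inherits(spec, "stage_spec")) {
      w1 <- spec$stage1_window
      w2 <- spec$stage2_window
    } else {
      m <- spec[spec$subject_id == subj, , drop = FALSE]
      if (nrow(m) != 1) {
        hrv_validation_error(sprintf("subject %s not found once in manifest", subj))
      }
      ind <- m$induction_time_s
      w1 <- if (is.na(ind)) c(0, 300) else c(max(series$start_time, ind - 300), ind)
      w2 <- c(m$stage2_start_s, m$stage2_start_s + 300)
    }
    for (stage in c("stage1", "stage2")) {
      w <- if (stage == "stage1") w1 else w2
      seg <- extract_stage(series, w, role = stage)
      desc <- tryCatch(sd_descriptors(make_pairs(seg)),
                       hrv_insufficient_data = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, stage = stage,
        sd1 = if (is.null(desc)) NA_real_ else desc$sd1,
        sd2 = if (is.null(desc)) NA_real_ else desc$sd2)
    }
  }
  out <- do.call(rbind, rows)
  keep <- !is.na(out$sd1) & !is.na(out$sd2)
  out[keep, , drop = FALSE]
}
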