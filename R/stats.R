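#' Preprocess reaction times
#'
#' Marks trials valid when a response was given and the reaction time lies
#' inside \[150, 1500\] ms (times below 150 ms or above 1.5 s are excluded
#' as extreme), and adds the natural-log reaction time for valid trials.
#'
#' @param data trial table with `rt_ms` and (optionally) `responded`.
#' @param lower,upper exclusion bounds in ms.
#' @return the table with columns `valid` and `log_rt` added/replaced.
#' @export
preprocess_rts <- function(data, lower = 150, upper = 1500) {
  if (!"rt_ms" %in% names(data)) abort("`data` needs an `rt_ms` column")
  if (any(data$rt_ms < 0, na.rm = TRUE)) {
    abort("negative reaction times are malformed input")
  }
  responded <- if ("responded" %in% names(data)) data$responded else
    !is.na(data$rt_ms)
  valid <- responded & !is.na(data$rt_ms) &
    data$rt_ms >= lower & data$rt_ms <= upper
  dplyr::mutate(data, valid = valid,
                log_rt = ifelse(valid, log(.data$rt_ms), NA_real_))
}

#' Mean log reaction time for expected versus unexpected events
#'
#' Events are classified from the relevant dimension only: expected when the
#' currently rewarded manifestation was followed by the coin or the
#' non-rewarded one by the circle; unexpected otherwise.
#'
#' @param data preprocessed trial table (one subject, or grouped by
#'   `subject_id` if present).
#' @return tibble with one row per subject: `mean_expected`,
#'   `mean_unexpected`, `n_expected`, `n_unexpected` (means of log RT over
#'   valid trials).
#' @export
expectedness_means <- function(data) {
  if (!"valid" %in% names(data)) data <- preprocess_rts(data)
  g <- if ("subject_id" %in% names(data)) "subject_id" else character()
  out <- data |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(g))) |>
    dplyr::summarise(
      mean_expected = mean(.data$log_rt[.data$expected == "expected"]),
      mean_unexpected = mean(.data$log_rt[.data$expected == "unexpected"]),
      n_expected = sum(.data$expected == "expected"),
      n_unexpected = sum(.data$expected == "unexpected"),
      .groups = "drop")
  if (any(out$n_expected == 0) || any(out$n_unexpected == 0)) {
    warn("a subject has zero valid trials in an expectedness cell")
  }
  out
}

#' Time-bin means of expected-event log reaction times
#'
#' Within every contingency block, the expected events (16 per block under
#' the exact-counts design) are split by outcome condition (coin versus
#' circle, 8 each), ordered by trial, and grouped into 4 bins of 2
#' consecutive events. Bin means of log RT are then averaged across blocks.
#'
#' @param data preprocessed trial table (optionally with `subject_id`).
#' @return tibble with columns (`subject_id`,) `condition` (`coin`/`circle`),
#'   `bin` (1..4), `mean_log_rt`, `n`. Bins with no valid trials are `NaN`
#'   and flagged with a warning.
#' @export
timebin_means <- function(data) {
  if (!"valid" %in% names(data)) data <- preprocess_rts(data)
  g <- if ("subject_id" %in% names(data)) "subject_id" else character()
  binned <- data |>
    dplyr::filter(.data$expected == "expected") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(g, "block", "outcome")))) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(bin = ceiling(dplyr::row_number() / 2)) |>
    dplyr::ungroup()
  out <- binned |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(g, "outcome", "bin")))) |>
    dplyr::summarise(mean_log_rt = mean(.data$log_rt), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::rename(condition = "outcome") |>
    tidyr::complete(!!!rlang::syms(g), condition = c("coin", "circle"),
                    bin = 1:4, fill = list(n = 0L))
  if (any(out$n == 0)) warn("empty time bins (no valid trials)")
  out
}

#' Ground-truth aberrant salience score
#'
#' The idiosyncratic reaction-time bias towards one of the two task-
#' irrelevant cue manifestations. Per relevance half, the ground-truth
#' irrelevant dimension is identified; the score for the half is the
#' absolute difference in mean raw reaction time (ms, valid trials) between
#' its two manifestations; halves are averaged.
#'
#' @param data preprocessed trial table (optionally with `subject_id`).
#' @return tibble with (`subject_id`,) `as_score_ms`.
#' @export
aberrant_salience_raw <- function(data) {
  if (!"valid" %in% names(data)) data <- preprocess_rts(data)
  g <- if ("subject_id" %in% names(data)) "subject_id" else character()
  half_scores <- data |>
    dplyr::filter(.data$valid) |>
    dplyr::mutate(
      irrelevant_dimension = ifelse(.data$relevant_dimension == "color",
                                    "shape", "color"),
      irr_manif = ifelse(.data$irrelevant_dimension == "color", .data$color,
                         .data$shape)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(g, "half")))) |>
    dplyr::summarise(
      n_manif = dplyr::n_distinct(.data$irr_manif),
      score = if (dplyr::n_distinct(.data$irr_manif) == 2)
        abs(diff(tapply(.data$rt_ms, .data$irr_manif, mean))) else NA_real_,
      .groups = "drop")
  if (any(half_scores$n_manif < 2)) {
    abort("an irrelevant manifestation has zero valid trials in a half")
  }
  half_scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(g))) |>
    dplyr::summarise(as_score_ms = mean(.data$score), .groups = "drop")
}

#' Per-subject summary of the raw analyses
#'
#' Convenience wrapper joining [expectedness_means()] and
#' [aberrant_salience_raw()] per subject.
#'
#' @param data preprocessed trial table with `subject_id`.
#' @return tibble, one row per subject.
#' @export
subject_summary <- function(data) {
  dplyr::left_join(expectedness_means(data), aberrant_salience_raw(data),
                   by = if ("subject_id" %in% names(data)) "subject_id" else
                     character())
}

#' Group comparisons used in the raw analyses
#'
#' Welch's unequal-variance two-sample test (reported as `F = t^2` on 1 and
#' Welch-Satterthwaite denominator degrees of freedom), a one-sample t test
#' against zero, or Spearman's rank correlation.
#'
#' @param a numeric vector (first group / values / first variable).
#' @param b numeric vector (second group or second variable); ignored for
#'   `kind = "one_sample_t"`.
#' @param kind `"welch"`, `"one_sample_t"` or `"spearman"`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (the tail
#'   refers to `t` / `rho`).
#' @return tibble with `statistic`, `df1`, `df2`, `estimate`, `p_value`.
#' @export
group_compare <- function(a, b = NULL,
                          kind = c("welch", "one_sample_t", "spearman"),
                          alternative = "two.sided") {
  kind <- match.arg(kind)
  if (kind == "welch") {
    if (length(a) < 2 || length(b) < 2) abort("need >= 2 values per group")
    if (sd(a) == 0 && sd(b) == 0) {
      abort("both groups have zero variance; Welch's test is undefined")
    }
    tt <- t.test(a, b, var.equal = FALSE, alternative = alternative)
    tibble::tibble(statistic = unname(tt$statistic^2), df1 = 1,
                   df2 = unname(tt$parameter),
                   estimate = mean(a) - mean(b),
                   p_value = tt$p.value)
  } else if (kind == "one_sample_t") {
    if (sd(a) == 0) abort("zero-variance sample; t test undefined")
    tt <- t.test(a, mu = 0, alternative = alternative)
    tibble::tibble(statistic = unname(tt$statistic), df1 = NA_real_,
                   df2 = unname(tt$parameter), estimate = mean(a),
                   p_value = tt$p.value)
  } else {
    if (length(a) != length(b) || length(a) < 3) {
      abort("spearman needs >= 3 paired values")
    }
    ct <- suppressWarnings(cor.test(a, b, method = "spearman",
                                    alternative = alternative))
    tibble::tibble(statistic = unname(ct$statistic), df1 = NA_real_,
                   df2 = NA_real_, estimate = unname(ct$estimate),
                   p_value = ct$p.value)
  }
}
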