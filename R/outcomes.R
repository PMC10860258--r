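RESPONSE_CLASSES <- c("CR", "PR", "SD", "PD", "NED")

MILESTONE_LEVELS <- c(
  "biopsy_to_sequencing", "biopsy_to_report", "biopsy_to_decision",
  "biopsy_to_treatment_start", "biopsy_to_end_of_therapy"
)

#' Percent change in tumor burden
#'
#' @param baseline_sum baseline sum of target-lesion longest diameters (mm),
#'   must be positive
#' @param timepoint_sum later sum (mm)
#' @return `100 * (timepoint - baseline) / baseline`
#' @export
percent_change <- function(baseline_sum, timepoint_sum) {
  if (any(baseline_sum <= 0)) abort("baseline_sum must be positive")
  100 * (timepoint_sum - baseline_sum) / baseline_sum
}

#' RECIST v1.1 best-response classification from target-lesion sums
#'
#' Works from a tidy lesion table: one row per subject and timepoint, with
#' `timepoint == 0` the pre-cycle-1 baseline. Per subject:
#' * `NED` when the no-measurable-disease flag is set (post-surgical);
#' * `CR` when the lesion sum reaches 0 at any timepoint before progression;
#' * `PR` when the change from baseline reaches -30% (boundary inclusive by
#'   default; see `pr_boundary`) before progression;
#' * `PD` when, before any CR/PR timepoint, some timepoint is at least +20%
#'   above the nadir so far **and** at least 5 mm above it in absolute terms
#'   (nadir-referenced, per the RECIST rulebook);
#' * `SD` otherwise.
#' `best_percent_change` is baseline-referenced — the convention used for
#' waterfall plots — and is undefined (`NA`) for NED subjects.
#'
#' @param lesions tibble with `subject_id`, `timepoint`, `sum_mm` and
#'   optionally `ned_flag`
#' @param pr_boundary `"inclusive"` classifies exactly -30% as PR;
#'   `"exclusive"` requires a strictly greater decrease (the stricter reading
#'   of a stable-disease band closed at 30%)
#' @return tibble with one row per subject: `subject_id`, `class`,
#'   `best_percent_change`
#' @export
classify_best_response <- function(lesions, pr_boundary = c("inclusive", "exclusive")) {
  pr_boundary <- match.arg(pr_boundary)
  check_columns(lesions, c("subject_id", "timepoint", "sum_mm"), "lesion table")
  if (!"ned_flag" %in% names(lesions)) lesions$ned_flag <- FALSE
  lesions |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ classify_one_series(.x, pr_boundary)) |>
    dplyr::ungroup()
}

classify_one_series <- function(series, pr_boundary) {
  if (any(series$ned_flag)) {
    return(tibble(class = "NED", best_percent_change = NA_real_))
  }
  series <- series[order(series$timepoint), ]
  baseline <- series$sum_mm[series$timepoint == 0]
  if (length(baseline) != 1L) abort("each measurable subject needs exactly one baseline (timepoint 0)")
  post <- series$sum_mm[series$timepoint > 0]
  if (length(post) == 0L) abort("no post-baseline timepoints")
  if (baseline <= 0) abort("baseline lesion sum must be positive for measurable disease")

  nadir <- baseline
  pd_at <- cr_at <- pr_at <- NA_integer_
  for (i in seq_along(post)) {
    s <- post[i]
    chg <- percent_change(baseline, s)
    if (is.na(pd_at) && s >= 1.2 * nadir && (s - nadir) >= 5) pd_at <- i
    if (is.na(cr_at) && s == 0) cr_at <- i
    pr_hit <- if (pr_boundary == "inclusive") chg <= -30 else chg < -30
    if (is.na(pr_at) && pr_hit) pr_at <- i
    nadir <- min(nadir, s)
  }
  resp_at <- suppressWarnings(min(cr_at, pr_at, na.rm = TRUE))
  cls <- if (!is.na(pd_at) && (is.infinite(resp_at) || pd_at < resp_at)) {
    "PD"
  } else if (!is.na(cr_at)) {
    "CR"
  } else if (!is.na(pr_at)) {
    "PR"
  } else {
    "SD"
  }
  tibble(class = cls, best_percent_change = percent_change(baseline, min(post)))
}

#' Clinical benefit rate
#'
#' The proportion of subjects with CR, PR, SD or NED among all
#' response-evaluable subjects (CR + PR + SD + NED + PD). The headline
#' percentage is rounded half-up to the nearest integer.
#'
#' @param responses character vector of response classes, or a tibble with a
#'   `class` column (e.g. the output of [classify_best_response()])
#' @return one-row tibble: `n_benefit`, `n_total`, `proportion`, `percent`
#' @export
clinical_benefit_rate <- function(responses) {
  if (is.data.frame(responses)) responses <- responses$class
  if (length(responses) == 0L) abort("no responses supplied")
  bad <- setdiff(unique(responses), RESPONSE_CLASSES)
  if (length(bad)) abort(sprintf("unknown response class: %s", paste(bad, collapse = ", ")))
  n_benefit <- sum(responses %in% c("CR", "PR", "SD", "NED"))
  n_total <- length(responses)
  prop <- n_benefit / n_total
  tibble(
    n_benefit = n_benefit, n_total = n_total,
    proportion = prop, percent = round_half_up(100 * prop, 0)
  )
}

#' Feasibility milestone summaries
#'
#' Mean, median and range of days from biopsy to each pipeline milestone
#' (sequencing complete, analysis/report, tumor-board decision, treatment
#' start, end of therapy). Missing milestones are excluded per statistic.
#'
#' @param milestones long tibble with `subject_id`, `milestone`, `days`
#' @param milestone_levels display order of milestones
#' @return tibble with `milestone`, `n`, `mean_days`, `median_days`,
#'   `min_days`, `max_days`
#' @export
feasibility_summary <- function(milestones, milestone_levels = MILESTONE_LEVELS) {
  check_columns(milestones, c("subject_id", "milestone", "days"), "milestone table")
  if (nrow(milestones) == 0L) abort("milestone table is empty")
  milestones |>
    dplyr::filter(!is.na(.data$days)) |>
    dplyr::mutate(milestone = factor(.data$milestone,
                                     levels = union(milestone_levels, unique(.data$milestone)))) |>
    dplyr::group_by(.data$milestone) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_days = mean(.data$days),
      median_days = median(.data$days),
      min_days = min(.data$days),
      max_days = max(.data$days),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$milestone)
}

#' Cycle-start feasibility table
#'
#' Summarises, per subject, the first cycle in which every recommended agent
#' had been started (`c1`, `c2`, `c3`, `c5`, or `never`). Percentages are per
#' category over `n`, rounded half-up to two decimals; the ever-started
#' percentage counts everything except `never`.
#'
#' @param first_cycle character vector of per-subject categories, or a named
#'   vector/list of category counts when `n` is given
#' @param n cohort size; defaults to `length(first_cycle)` for the vector form
#' @return list with `by_cycle` (tibble: `category`, `count`, `percent`) and
#'   `ever_started_percent`
#' @export
cycle_start_summary <- function(first_cycle, n = NULL) {
  cats <- c("c1", "c2", "c3", "c5", "never")
  if (!is.null(names(first_cycle)) && is.numeric(first_cycle)) {
    counts <- setNames(rep(0, length(cats)), cats)
    bad <- setdiff(names(first_cycle), cats)
    if (length(bad)) abort(sprintf("unknown cycle category: %s", paste(bad, collapse = ", ")))
    counts[names(first_cycle)] <- first_cycle
    if (is.null(n)) n <- sum(counts)
  } else {
    bad <- setdiff(unique(first_cycle), cats)
    if (length(bad)) abort(sprintf("unknown cycle category: %s", paste(bad, collapse = ", ")))
    counts <- vapply(cats, function(ct) sum(first_cycle == ct), numeric(1))
    if (is.null(n)) n <- length(first_cycle)
  }
  if (sum(counts) > n) abort("category counts exceed cohort size n")
  by_cycle <- tibble(
    category = cats,
    count = as.numeric(counts),
    percent = round_half_up(100 * as.numeric(counts) / n, 2)
  )
  list(
    by_cycle = by_cycle,
    ever_started_percent = round_half_up(100 * (n - counts[["never"]]) / n, 2)
  )
}

#' Waterfall table of best percent change
#'
#' Best (baseline-referenced) percent change in tumor burden per subject with
#' measurable disease, sorted descending for plotting, plus counts of
#' subjects with a decrease, no change (exactly 0) and an increase.
#'
#' @param responses tibble with `subject_id` and `best_percent_change`
#'   (measurable-disease subjects only; NED rows must be removed upstream)
#' @return object of class `waterfall`: the sorted tibble, with attributes
#'   `counts` (named: decrease/no_change/increase) and `percent_decrease`
#'   (half-up, two decimals)
#' @export
waterfall_table <- function(responses) {
  check_columns(responses, c("subject_id", "best_percent_change"), "response table")
  if (any(is.na(responses$best_percent_change))) {
    abort("best_percent_change is NA for some subjects; drop non-measurable (NED) subjects first")
  }
  out <- responses |>
    dplyr::arrange(dplyr::desc(.data$best_percent_change)) |>
    dplyr::mutate(change_sign = dplyr::case_when(
      .data$best_percent_change < 0 ~ "decrease",
      .data$best_percent_change == 0 ~ "no_change",
      TRUE ~ "increase"
    ))
  counts <- c(
    decrease = sum(out$change_sign == "decrease"),
    no_change = sum(out$change_sign == "no_change"),
    increase = sum(out$change_sign == "increase")
  )
  structure(out,
    class = c("waterfall", class(out)),
    counts = counts,
    percent_decrease = round_half_up(100 * counts[["decrease"]] / nrow(out), 2)
  )
}

#' @rdname waterfall_table
#' @param x `waterfall` object
#' @param ... unused
#' @export
#' @exportS3Method generics::glance
glance.waterfall <- function(x, ...) {
  counts <- attr(x, "counts")
  tibble(
    n = nrow(x),
    n_decrease = counts[["decrease"]],
    n_no_change = counts[["no_change"]],
    n_increase = counts[["increase"]],
    percent_decrease = attr(x, "percent_decrease")
  )
}

#' Waterfall plot of tumor-burden change
#' @param object `waterfall` object
#' @param ... unused
#' @return ggplot object
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.waterfall <- function(object, ...) {
  df <- as_tibble(object) |> dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$best_percent_change,
                                   fill = .data$change_sign)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-30, 20), linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(decrease = "#2980b9", no_change = "grey60",
                                          increase = "#c0392b")) +
    ggplot2::labs(x = "subjects (sorted)", y = "best % change from baseline", fill = NULL) +
    ggplot2::theme_minimal()
}
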