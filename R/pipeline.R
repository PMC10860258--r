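#' Run the full decision pipeline for one subject
#'
#' Executes the per-subject stages in fixed order: expression-outlier scoring
#' (NRZ), somatic landscape (TMB, arm-level events), optional signature
#' decomposition, three-tier drug matching, combination assembly, and report
#' generation. A stage whose input class is absent (e.g. no expression for
#' the subject) is skipped with an explicit note, and the tiers depending on
#' it are disabled. A subject for whom no eligible candidate survives veto
#' filtering yields `status = "no_plan"`, distinct from a hard error.
#'
#' @param bundle `cohort_bundle`
#' @param subject_id subject to run
#' @param tau NRZ actionability threshold (default 2)
#' @param max_drugs maximum combination size (default 4)
#' @param callable_mb TMB denominator in Mb (default 30)
#' @param min_genes,log2_thresh,arm_fraction arm-caller thresholds
#' @param signatures optional validated signature matrix enabling the
#'   signature stage
#' @param priority_regimens optional list of priority drug sets
#' @param seed provenance seed echoed into the report
#' @return list of class `subject_run` with elements `subject_id`, `status`,
#'   `nrz`, `tmb`, `arm_events`, `exposures`, `candidates`, `plan`, `report`,
#'   `notes`
#' @export
run_subject <- function(bundle, subject_id, tau = 2, max_drugs = 4,
                        callable_mb = 30, min_genes = 50, log2_thresh = 0.5,
                        arm_fraction = 0.5, signatures = NULL,
                        priority_regimens = NULL, seed = NA_integer_) {
  if (!subject_id %in% bundle$subjects$subject_id) {
    abort(sprintf("subject '%s' not in bundle", subject_id))
  }
  notes <- character()
  pick <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0L) return(NULL)
    out <- tab[tab$subject_id == subject_id, , drop = FALSE]
    if (nrow(out)) out else NULL
  }
  s_vars <- pick(bundle$variants)
  s_fus <- pick(bundle$fusions)
  s_cnv <- pick(bundle$cnv_genes)
  s_segs <- pick(bundle$segments)

  # expression stage
  nrz <- NULL
  if (!is.null(bundle$expression) && !is.null(bundle$normal_reference) &&
      subject_id %in% colnames(bundle$expression)) {
    vec <- setNames(bundle$expression[, subject_id], rownames(bundle$expression))
    nrz <- nrz_score(vec, bundle$normal_reference, tau = tau, subject_id = subject_id)
  } else {
    notes <- c(notes, "expression stage skipped: no expression or normal reference; tier-3 disabled")
  }

  # somatic landscape stage
  tmb <- if (!is.null(s_vars)) compute_tmb(s_vars, callable_mb = callable_mb) else NULL
  arm_events <- NULL
  if (!is.null(s_segs) && !is.null(bundle$arm_map)) {
    arm_events <- call_arm_events(s_segs, bundle$arm_map, min_genes = min_genes,
                                  log2_thresh = log2_thresh, arm_fraction = arm_fraction)
  } else if (is.null(s_segs)) {
    notes <- c(notes, "arm-event stage skipped: no copy-number segments")
  }

  # signature stage
  exposures <- NULL
  if (!is.null(signatures) && !is.null(s_vars)) {
    catalog <- catalog_from_variants(s_vars)
    if (sum(catalog) >= 1) {
      exposures <- decompose_lcd(catalog, signatures, subject_id = subject_id)
    } else {
      notes <- c(notes, "signature stage skipped: no context-bearing SNVs")
    }
  }

  # matching
  events <- somatic_events(s_vars, s_fus, s_cnv)
  candidates <- dplyr::bind_rows(
    if (!is.null(bundle$rules)) match_tier1(events, bundle$rules) else empty_candidates(),
    if (!is.null(bundle$rules)) match_tier2(events, bundle$rules, bundle$inference_map) else empty_candidates(),
    if (!is.null(bundle$rules) && !is.null(nrz)) match_tier3(nrz, bundle$rules, tau = tau) else empty_candidates()
  )
  params <- list(
    tau = tau, max_drugs = max_drugs, callable_mb = callable_mb,
    min_genes = min_genes, log2_thresh = log2_thresh, arm_fraction = arm_fraction
  )
  plan <- NULL
  report <- NULL
  status <- "ok"
  plan_try <- tryCatch(
    assemble_combination(candidates, blacklist = bundle$blacklist,
                         max_drugs = max_drugs, priority_regimens = priority_regimens),
    mtbkit_no_plan = function(e) NULL
  )
  if (is.null(plan_try)) {
    status <- "no_plan"
  } else {
    plan <- plan_try
    report <- generate_report(plan, subject_id, parameters = params, seed = seed)
  }
  structure(
    list(
      subject_id = subject_id, status = status, nrz = nrz, tmb = tmb,
      arm_events = arm_events, exposures = exposures, candidates = candidates,
      plan = plan, report = report, notes = notes
    ),
    class = "subject_run"
  )
}

#' @export
print.subject_run <- function(x, ...) {
  cat(sprintf("<subject_run> %s [%s]\n", x$subject_id, x$status))
  if (!is.null(x$plan)) print(x$plan)
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Cohort-level pipeline summaries
#'
#' Runs the cohort views: per-subject arm events pooled into the recurrence
#' filter and oncoprint, TMB per subject, signature exposures averaged per
#' tumor type (when a signature matrix is supplied), RECIST best responses
#' with overall and per-type clinical benefit, the waterfall table over
#' measurable-disease subjects, and milestone feasibility summaries.
#'
#' @param bundle `cohort_bundle` with at least one subject
#' @param signatures optional signature matrix for the exposure summary
#' @param gene_panel genes for the oncoprint (default: genes carrying rules)
#' @param min_subjects recurrence threshold for oncoprint arm rows
#' @param ... thresholds forwarded to [call_arm_events()]
#' @return list of class `cohort_run` with `arm_events`, `recurrent_arms`,
#'   `oncoprint`, `tmb`, `exposure_by_type`, `responses`, `benefit_overall`,
#'   `benefit_by_type`, `waterfall`, `feasibility`
#' @export
run_cohort <- function(bundle, signatures = NULL, gene_panel = NULL,
                       min_subjects = 15, ...) {
  if (nrow(bundle$subjects) < 1L) abort("cohort is empty")
  labels <- bundle$subjects

  arm_events <- NULL
  recurrent <- NULL
  if (!is.null(bundle$segments) && !is.null(bundle$arm_map)) {
    arm_events <- call_arm_events(bundle$segments, bundle$arm_map, ...)
    recurrent <- cohort_arm_recurrence(arm_events, min_subjects = min_subjects)
  }

  tmb <- NULL
  if (!is.null(bundle$variants) && nrow(bundle$variants)) {
    tmb <- bundle$variants |>
      dplyr::group_split(.data$subject_id) |>
      purrr::map(compute_tmb) |>
      dplyr::bind_rows()
  }

  exposure_by_type <- NULL
  if (!is.null(signatures) && !is.null(bundle$variants) && nrow(bundle$variants)) {
    exposures <- bundle$variants |>
      dplyr::group_split(.data$subject_id) |>
      purrr::map(function(v) {
        catalog <- catalog_from_variants(v)
        if (sum(catalog) < 1) return(NULL)
        decompose_lcd(catalog, signatures, subject_id = v$subject_id[1])
      }) |>
      purrr::compact() |>
      dplyr::bind_rows()
    if (nrow(exposures)) {
      exposure_by_type <- average_exposures_by_type(exposures, labels)
    }
  }

  if (is.null(gene_panel)) {
    gene_panel <- if (!is.null(bundle$rules)) sort(unique(bundle$rules$gene)) else character()
  }
  oncoprint <- if (length(gene_panel)) {
    build_oncoprint(bundle, gene_panel, recurrent_arms = recurrent, arm_events = arm_events)
  }

  responses <- NULL
  benefit_overall <- NULL
  benefit_by_type <- NULL
  waterfall <- NULL
  if (!is.null(bundle$lesions) && nrow(bundle$lesions)) {
    responses <- classify_best_response(bundle$lesions) |>
      dplyr::left_join(labels, by = "subject_id")
    benefit_overall <- clinical_benefit_rate(responses)
    benefit_by_type <- responses |>
      dplyr::group_by(.data$tumor_type) |>
      dplyr::group_modify(~ clinical_benefit_rate(.x$class)) |>
      dplyr::ungroup()
    measurable <- responses |> dplyr::filter(.data$class != "NED")
    if (nrow(measurable)) waterfall <- waterfall_table(measurable)
  }

  feasibility <- if (!is.null(bundle$milestones) && nrow(bundle$milestones)) {
    feasibility_summary(bundle$milestones)
  }

  structure(
    list(
      arm_events = arm_events, recurrent_arms = recurrent, oncoprint = oncoprint,
      tmb = tmb, exposure_by_type = exposure_by_type, responses = responses,
      benefit_overall = benefit_overall, benefit_by_type = benefit_by_type,
      waterfall = waterfall, feasibility = feasibility
    ),
    class = "cohort_run"
  )
}

#' @export
print.cohort_run <- function(x, ...) {
  cat("<cohort_run>\n")
  if (!is.null(x$benefit_overall)) {
    cat(sprintf("  clinical benefit: %d/%d (%g%%)\n",
                x$benefit_overall$n_benefit, x$benefit_overall$n_total,
                x$benefit_overall$percent))
  }
  if (!is.null(x$recurrent_arms)) {
    cat(sprintf("  recurrent arm events: %d\n", nrow(x$recurrent_arms)))
  }
  invisible(x)
}
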