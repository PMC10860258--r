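#' Default event-class ranking weights
#'
#' Deterministic surrogate for the tumor board's qualitative weighing of
#' evidence classes when ranking DNA-backed candidates within a tier:
#' fusions outrank protein-annotated (hotspot-like) SNVs, which outrank other
#' small variants, which outrank gene-level copy-number events.
#'
#' @return named numeric vector of weights
#' @export
default_event_weights <- function() {
  c(fusion = 4, hotspot_snv = 3, snv = 2, indel = 2, gain = 1, loss = 1)
}

#' Flatten a subject's somatic events to a gene-level table
#'
#' Builds the per-gene event list the tier-1/2 matchers consume. Fusions
#' contribute both partner genes; SNVs with an annotated protein change are
#' weighted as hotspot-like.
#'
#' @param variants,fusions,cnv_genes event tibbles for one subject (any may be
#'   `NULL` or empty)
#' @param weights event-class weights, see [default_event_weights()]
#' @return tibble with `subject_id`, `gene`, `event_class`, `description`,
#'   `weight`
#' @export
somatic_events <- function(variants = NULL, fusions = NULL, cnv_genes = NULL,
                           weights = default_event_weights()) {
  parts <- list()
  if (!is.null(variants) && nrow(variants)) {
    parts$var <- variants |>
      dplyr::mutate(
        event_class = dplyr::case_when(
          .data$variant_class == "SNV" & !is.na(.data$protein_change) ~ "hotspot_snv",
          .data$variant_class == "SNV" ~ "snv",
          TRUE ~ "indel"
        ),
        description = paste0(
          .data$gene, " ",
          ifelse(is.na(.data$protein_change),
                 paste0(.data$chrom, ":", .data$pos, " ", .data$ref, ">", .data$alt),
                 .data$protein_change),
          " (", .data$effect, ")"
        )
      ) |>
      dplyr::select("subject_id", "gene", "event_class", "description")
  }
  if (!is.null(fusions) && nrow(fusions)) {
    parts$fus <- dplyr::bind_rows(
      dplyr::transmute(fusions, .data$subject_id, gene = .data$gene_5p,
                       event_class = "fusion", description = .data$label),
      dplyr::transmute(fusions, .data$subject_id, gene = .data$gene_3p,
                       event_class = "fusion", description = .data$label)
    )
  }
  if (!is.null(cnv_genes) && nrow(cnv_genes)) {
    parts$cnv <- cnv_genes |>
      dplyr::transmute(
        .data$subject_id, .data$gene, event_class = .data$direction,
        description = paste0(.data$gene, " copy-number ", .data$direction)
      )
  }
  out <- dplyr::bind_rows(parts)
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(
      subject_id = character(), gene = character(), event_class = character(),
      description = character(), weight = double()
    ))
  }
  out$weight <- unname(weights[out$event_class])
  out
}

empty_candidates <- function() {
  tibble(
    drug = character(), tier = integer(), gene = character(),
    event = character(), mode = character(), score = double(),
    evidence = character()
  )
}

#' Tier-1: direct variant/drug matching
#'
#' A candidate is emitted for every (drug, gene) where a somatic event hits a
#' gene carrying a `direct` rule — literature evidence that the altered gene
#' is a target of, or changes response to, the drug. Both fusion partners are
#' eligible.
#'
#' @param events gene-level event table from [somatic_events()]
#' @param rules drug-rule tibble
#' @return candidate tibble (`drug`, `tier`, `gene`, `event`, `mode`,
#'   `score`, `evidence`)
#' @export
match_tier1 <- function(events, rules) {
  if (nrow(events) == 0L) return(empty_candidates())
  rules |>
    dplyr::filter(.data$tier == "direct") |>
    dplyr::inner_join(events, by = "gene", relationship = "many-to-many") |>
    dplyr::transmute(
      .data$drug, tier = 1L, .data$gene, event = .data$description,
      .data$mode, score = .data$weight, .data$evidence
    ) |>
    dplyr::distinct()
}

#' Tier-2: inferred variant/drug matching through a single-hop gene map
#'
#' A candidate is emitted when an event hits gene G, the inference map links
#' G to a target gene T (one hop only, no chaining), and T carries a `direct`
#' or `inferred` rule.
#'
#' @param events gene-level event table
#' @param rules drug-rule tibble
#' @param inference_map tibble with `gene`, `target_gene`, `evidence`
#' @return candidate tibble
#' @export
match_tier2 <- function(events, rules, inference_map) {
  if (nrow(events) == 0L || is.null(inference_map) || nrow(inference_map) == 0L) {
    return(empty_candidates())
  }
  hops <- events |>
    dplyr::inner_join(inference_map, by = "gene", relationship = "many-to-many")
  rules |>
    dplyr::filter(.data$tier %in% c("direct", "inferred")) |>
    dplyr::inner_join(hops, by = c(gene = "target_gene"),
                      suffix = c("", ".hop"), relationship = "many-to-many") |>
    dplyr::transmute(
      .data$drug, tier = 2L,
      gene = .data$gene.hop,  # the altered gene, not the drug target
      event = paste0(.data$description, " -> ", .data$gene),
      .data$mode, score = .data$weight, .data$evidence
    ) |>
    dplyr::distinct()
}

#' Tier-3: expression-based drug matching
#'
#' Matches expression rules to NRZ outlier flags: a rule with direction
#' `over` fires when the gene's Z-score is at least `tau`, `under` when at
#' most `-tau`. Sensitivity matches become candidates scored by `|z|`;
#' resistance matches are emitted too and act as vetoes downstream.
#'
#' @param nrz `nrz_scores` table for the subject
#' @param rules drug-rule tibble
#' @param tau actionability threshold (default 2, inclusive)
#' @return candidate tibble
#' @export
match_tier3 <- function(nrz, rules, tau = 2) {
  if (is.null(nrz) || nrow(nrz) == 0L) return(empty_candidates())
  rules |>
    dplyr::filter(.data$tier == "expression") |>
    dplyr::inner_join(as_tibble(nrz), by = "gene", relationship = "many-to-many") |>
    dplyr::filter(
      (.data$direction == "over" & .data$z >= tau) |
        (.data$direction == "under" & .data$z <= -tau)
    ) |>
    dplyr::transmute(
      .data$drug, tier = 3L, .data$gene,
      event = sprintf("%s %sexpressed (z = %.2f)", .data$gene,
                      ifelse(.data$direction == "over", "over", "under"), .data$z),
      .data$mode, score = abs(.data$z), .data$evidence
    ) |>
    dplyr::distinct()
}

pair_conflicts <- function(drug_a, drug_b, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) return(FALSE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  any(key(drug_a, drug_b) %in% key(blacklist$drug_a, blacklist$drug_b))
}

#' Assemble a combination treatment plan
#'
#' Greedy cycling over ranked candidates, the software surrogate of the
#' tumor board's repeat-until-combination loop. Resistance candidates are
#' hard vetoes for their drug. Remaining sensitivity candidates are deduped
#' to their best row per drug and ranked by tier (ascending), then score
#' (descending), then drug name. If a priority regimen is fully contained in
#' the candidate drugs and internally conflict-free it seeds the plan. Each
#' cycle then adds the top-ranked drug that neither duplicates nor conflicts
#' (interaction blacklist) with the plan so far, stopping at `max_drugs` or
#' exhaustion.
#'
#' @param candidates candidate tibble pooled across tiers
#' @param blacklist tibble of unordered conflicting pairs (`drug_a`, `drug_b`)
#' @param max_drugs maximum combination size (default 4)
#' @param priority_regimens optional list of character drug sets tried, in
#'   order, as plan seeds
#' @param excluded_drugs optional drugs ruled out on non-molecular grounds
#'   (tolerability, access); recorded with reason `"excluded_by_config"`
#' @return object of class `treatment_plan`: list with `drugs` (tibble of
#'   chosen drugs with tier, gene, event, score, evidence), `excluded`
#'   (drug + reason), `priority_regimen_used`
#' @export
assemble_combination <- function(candidates, blacklist = NULL, max_drugs = 4,
                                 priority_regimens = NULL, excluded_drugs = NULL) {
  excluded <- tibble(drug = character(), reason = character())

  veto_drugs <- sort(unique(candidates$drug[candidates$mode == "resistance"]))
  if (length(veto_drugs)) {
    excluded <- dplyr::bind_rows(excluded, tibble(drug = veto_drugs, reason = "resistance_veto"))
  }
  if (length(excluded_drugs)) {
    excluded <- dplyr::bind_rows(excluded, tibble(drug = excluded_drugs, reason = "excluded_by_config"))
  }
  pool <- candidates |>
    dplyr::filter(.data$mode == "sensitivity",
                  !.data$drug %in% veto_drugs,
                  !.data$drug %in% (excluded_drugs %||% character())) |>
    dplyr::arrange(.data$tier, dplyr::desc(.data$score), .data$drug) |>
    dplyr::distinct(.data$drug, .keep_all = TRUE)
  if (nrow(pool) == 0L) {
    abort("no eligible candidates after veto filtering: no plan", class = "mtbkit_no_plan")
  }

  plan_drugs <- character()
  regimen_used <- NA_character_
  for (i in seq_along(priority_regimens %||% list())) {
    reg <- priority_regimens[[i]]
    if (!all(reg %in% pool$drug) || length(reg) > max_drugs) next
    pairs_ok <- TRUE
    if (length(reg) > 1) {
      cmb <- utils::combn(reg, 2)
      pairs_ok <- !any(apply(cmb, 2, function(p) pair_conflicts(p[1], p[2], blacklist)))
    }
    if (pairs_ok) {
      plan_drugs <- reg
      regimen_used <- paste(reg, collapse = "+")
      break
    }
  }

  for (drug in pool$drug) {
    if (length(plan_drugs) >= max_drugs) break
    if (drug %in% plan_drugs) next
    if (length(plan_drugs) &&
        any(vapply(plan_drugs, function(d) pair_conflicts(d, drug, blacklist), logical(1)))) {
      excluded <- dplyr::bind_rows(excluded, tibble(drug = drug, reason = "interaction_conflict"))
      next
    }
    plan_drugs <- c(plan_drugs, drug)
  }

  drugs <- pool[match(plan_drugs, pool$drug), ] |>
    dplyr::select("drug", "tier", "gene", "event", "score", "evidence")
  structure(
    list(drugs = drugs, excluded = excluded, priority_regimen_used = regimen_used,
         max_drugs = max_drugs),
    class = "treatment_plan"
  )
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("<treatment_plan> %d drug(s): %s\n",
              nrow(x$drugs), paste(x$drugs$drug, collapse = " + ")))
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%s (%s)", x$excluded$drug, x$excluded$reason), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname assemble_combination
#' @param x `treatment_plan`
#' @param ... unused
#' @export
#' @exportS3Method generics::tidy
tidy.treatment_plan <- function(x, ...) as_tibble(x$drugs)

#' @rdname assemble_combination
#' @export
#' @exportS3Method generics::glance
glance.treatment_plan <- function(x, ...) {
  tibble(
    n_drugs = nrow(x$drugs),
    n_excluded = nrow(x$excluded),
    n_vetoed = sum(x$excluded$reason == "resistance_veto"),
    priority_regimen_used = x$priority_regimen_used
  )
}

#' Generate a deterministic drug-prediction report
#'
#' Serialises a treatment plan, its per-drug molecular rationale, vetoed and
#' conflicted drugs, and run provenance (package version, parameters, seed)
#' into canonical JSON plus a human-readable markdown summary. Identical
#' inputs produce byte-identical JSON: no timestamps are embedded.
#'
#' @param plan `treatment_plan`
#' @param subject_id subject identifier
#' @param parameters named list of pipeline parameters to echo
#' @param seed the run seed, echoed for provenance
#' @return list with elements `json` (single string) and `markdown`
#' @export
generate_report <- function(plan, subject_id, parameters = list(), seed = NA_integer_) {
  payload <- list(
    subject_id = subject_id,
    plan = lapply(seq_len(nrow(plan$drugs)), function(i) {
      r <- plan$drugs[i, ]
      list(drug = r$drug, tier = r$tier, gene = r$gene, event = r$event,
           score = r$score, evidence = r$evidence)
    }),
    excluded = lapply(seq_len(nrow(plan$excluded)), function(i) {
      as.list(plan$excluded[i, ])
    }),
    priority_regimen_used = plan$priority_regimen_used,
    provenance = list(
      tool = "mtbkit",
      version = as.character(utils::packageVersion("mtbkit")),
      parameters = parameters,
      seed = seed
    )
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
  md <- c(
    sprintf("# Drug prediction report: %s", subject_id),
    "",
    "## Recommended combination",
    sprintf("%d. **%s** (tier %d) - %s [%s]",
            seq_len(nrow(plan$drugs)), plan$drugs$drug, plan$drugs$tier,
            plan$drugs$event, plan$drugs$evidence),
    "",
    "## Excluded drugs",
    if (nrow(plan$excluded)) {
      sprintf("- %s: %s", plan$excluded$drug, plan$excluded$reason)
    } else "- none"
  )
  list(json = as.character(json), markdown = paste(md, collapse = "\n"))
}

#' Structural validation of a report JSON
#'
#' Checks the report against the shipped schema
#' (`inst/extdata/report-schema.json`): required top-level fields, required
#' per-drug fields, and type sanity.
#'
#' @param json report JSON string
#' @return `TRUE` invisibly; errors describing the first violation otherwise
#' @export
validate_report <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  for (field in c("subject_id", "plan", "excluded", "provenance")) {
    if (is.null(obj[[field]])) abort(sprintf("report missing field '%s'", field))
  }
  if (length(obj$plan) < 1L || length(obj$plan) > 4L) {
    abort("report plan must contain 1-4 drugs")
  }
  for (d in obj$plan) {
    for (field in c("drug", "tier", "gene", "event")) {
      if (is.null(d[[field]])) abort(sprintf("plan entry missing '%s'", field))
    }
    if (!d$tier %in% 1:3) abort("plan entry tier must be 1, 2 or 3")
  }
  if (is.null(obj$provenance$version)) abort("report missing provenance version")
  invisible(TRUE)
}
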