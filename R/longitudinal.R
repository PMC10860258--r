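#' Canonical event keys for longitudinal comparison
#'
#' Serial biopsies are compared on canonicalised event keys: a mutation is
#' `gene:protein_change` when a protein change is annotated (named protein
#' changes are how recurrent hits are tracked across biopsies), else
#' `chrom:pos:ref:alt`; an arm-level CNV is `arm+` / `arm-`; a fusion is its
#' partner-pair label.
#'
#' @param variants,arm_events,fusions event tibbles for one biopsy (any may
#'   be `NULL`)
#' @return character vector of distinct event keys
#' @export
event_keys <- function(variants = NULL, arm_events = NULL, fusions = NULL) {
  keys <- character()
  if (!is.null(variants) && nrow(variants)) {
    keys <- c(keys, ifelse(
      is.na(variants$protein_change),
      paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":"),
      paste(variants$gene, variants$protein_change, sep = ":")
    ))
  }
  if (!is.null(arm_events) && nrow(arm_events)) {
    keys <- c(keys, paste0(arm_events$arm_id, ifelse(arm_events$direction == "gain", "+", "-")))
  }
  if (!is.null(fusions) && nrow(fusions)) {
    keys <- c(keys, fusions$label)
  }
  unique(keys)
}

#' Shared/unique partition of events across serial biopsies
#'
#' Exact set algebra over 2 or 3 labeled biopsies: every non-empty
#' combination of biopsies gets a region holding the events present in
#' exactly those biopsies (the Venn-diagram regions). Percentages are of the
#' union of all events.
#'
#' @param event_sets named list of 2 or 3 character vectors of event keys
#'   (see [event_keys()])
#' @return tibble with `region` (biopsy labels joined by `&`), `n_biopsies`
#'   (how many biopsies share the region), `count`, `percent`, `keys`
#'   (list-column); attribute `union_size`
#' @export
partition_events <- function(event_sets) {
  if (length(event_sets) < 2L || length(event_sets) > 3L) {
    abort("partition_events() needs 2 or 3 labeled event sets")
  }
  if (is.null(names(event_sets)) || any(names(event_sets) == "")) {
    names(event_sets) <- paste0("biopsy", seq_along(event_sets))
  }
  event_sets <- lapply(event_sets, unique)
  all_keys <- unique(unlist(event_sets))
  membership <- vapply(event_sets, function(s) all_keys %in% s, logical(length(all_keys)))
  if (length(all_keys) == 1L) membership <- matrix(membership, nrow = 1)

  k <- length(event_sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]  # drop all-FALSE
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    pattern <- as.logical(combos[i, ])
    in_region <- if (length(all_keys)) {
      apply(membership, 1, function(m) all(m == pattern))
    } else {
      logical(0)
    }
    tibble(
      region = paste(names(event_sets)[pattern], collapse = "&"),
      n_biopsies = sum(pattern),
      count = sum(in_region),
      keys = list(sort(all_keys[in_region]))
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(percent = if (length(all_keys)) 100 * .data$count / length(all_keys) else 0) |>
    dplyr::arrange(dplyr::desc(.data$n_biopsies), .data$region) |>
    dplyr::select("region", "n_biopsies", "count", "percent", "keys")
  structure(out, class = c("event_partition", class(out)), union_size = length(all_keys))
}

#' Targetable-gene Z-score matrix across serial biopsies
#'
#' Restricts per-biopsy NRZ tables to a gene panel and lays them out as a
#' genes-by-biopsies long table. Cells whose gene backed a drug chosen for
#' that biopsy's treatment plan are flagged (`is_target`); a panel gene
#' absent from a biopsy's score table is marked missing, never imputed to
#' zero.
#'
#' @param nrz_tables named list (one per biopsy, in series order) of
#'   `nrz_scores` tables
#' @param gene_panel character vector of targetable genes to display
#' @param plan_genes optional named list, parallel to `nrz_tables`, of the
#'   genes supporting the drugs chosen for each biopsy (e.g.
#'   `tidy(plan)$gene`)
#' @return tibble with `gene`, `biopsy`, `z`, `missing`, `is_target`
#' @export
targetable_nrz_matrix <- function(nrz_tables, gene_panel, plan_genes = NULL) {
  if (is.null(names(nrz_tables)) || any(names(nrz_tables) == "")) {
    names(nrz_tables) <- paste0("biopsy", seq_along(nrz_tables))
  }
  if (length(gene_panel) == 0L) abort("gene_panel must be non-empty")
  purrr::imap(nrz_tables, function(tab, biopsy) {
    tab <- as_tibble(tab)
    idx <- match(gene_panel, tab$gene)
    targets <- plan_genes[[biopsy]] %||% character()
    tibble(
      gene = gene_panel,
      biopsy = biopsy,
      z = tab$z[idx],
      missing = is.na(idx),
      is_target = gene_panel %in% targets
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(biopsy = factor(.data$biopsy, levels = names(nrz_tables)))
}

#' Heatmap of targetable-gene Z-scores across biopsies
#' @param object output of [targetable_nrz_matrix()]
#' @param ... unused
#' @return ggplot object
#' @export
plot_targetable_nrz <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$biopsy, y = .data$gene, fill = .data$z)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_tile(
      data = dplyr::filter(object, .data$is_target),
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white", high = "#c0392b", na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "NRZ z",
                  title = "Outlined cells: molecular target of a chosen drug") +
    ggplot2::theme_minimal()
}
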