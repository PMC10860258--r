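#' Call chromosome arm-level copy-number events
#'
#' Segments first pass a gene-count filter (`n_genes >= min_genes`) and a
#' direction-specific log2-ratio filter (`>= log2_thresh` for gains,
#' `<= -log2_thresh` for losses; all thresholds inclusive). Surviving
#' segments are intersected with each arm; per arm and direction their
#' overlaps are unioned (so overlapping calls cannot inflate coverage) and an
#' event is emitted when the union covers at least `arm_fraction` of the arm.
#'
#' @param segments segment tibble (see [read_segments()])
#' @param arms arm tibble (see [read_arm_map()])
#' @param min_genes minimum genes per qualifying segment (default 50)
#' @param log2_thresh absolute log2-ratio threshold (default 0.5)
#' @param arm_fraction minimum covered fraction of the arm (default 0.5)
#' @return tibble with `subject_id`, `arm_id`, `direction`, `covered_fraction`
#' @export
call_arm_events <- function(segments, arms, min_genes = 50, log2_thresh = 0.5,
                            arm_fraction = 0.5) {
  if (nrow(segments) == 0L) {
    return(tibble(
      subject_id = character(), arm_id = character(),
      direction = character(), covered_fraction = double()
    ))
  }
  off_map <- setdiff(unique(segments$chrom), arms$chrom)
  if (length(off_map)) {
    warn(sprintf(
      "skipping segments on chromosome(s) absent from the arm map: %s",
      paste(off_map, collapse = ", ")
    ))
  }
  kept <- segments |>
    dplyr::filter(
      .data$n_genes >= min_genes,
      abs(.data$log2_ratio) >= log2_thresh,
      .data$chrom %in% arms$chrom
    ) |>
    dplyr::mutate(direction = ifelse(.data$log2_ratio > 0, "gain", "loss"))
  if (nrow(kept) == 0L) {
    return(tibble(
      subject_id = character(), arm_id = character(),
      direction = character(), covered_fraction = double()
    ))
  }
  hits <- dplyr::inner_join(kept, arms, by = "chrom", suffix = c("", ".arm"),
                            relationship = "many-to-many") |>
    dplyr::mutate(
      ov_start = pmax(.data$start, .data$start.arm),
      ov_end = pmin(.data$end, .data$end.arm)
    ) |>
    dplyr::filter(.data$ov_start <= .data$ov_end)
  if (nrow(hits) == 0L) {
    return(tibble(
      subject_id = character(), arm_id = character(),
      direction = character(), covered_fraction = double()
    ))
  }
  hits |>
    dplyr::group_by(.data$subject_id, .data$arm_id, .data$direction) |>
    dplyr::summarise(
      covered_fraction = interval_union_length(.data$ov_start, .data$ov_end) /
        (.data$end.arm[1] - .data$start.arm[1] + 1),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$covered_fraction >= arm_fraction) |>
    dplyr::arrange(.data$subject_id, .data$arm_id, .data$direction)
}

#' Cohort recurrence filter for arm events
#'
#' An (arm, direction) pair is recurrent when it is seen in at least
#' `min_subjects` distinct subjects; repeated biopsies of one subject count
#' once.
#'
#' @param events arm-event tibble across the cohort
#' @param min_subjects recurrence threshold (default 15, inclusive)
#' @return tibble with `arm_id`, `direction`, `n_subjects`, sorted by count
#'   descending then arm
#' @export
cohort_arm_recurrence <- function(events, min_subjects = 15) {
  events |>
    dplyr::distinct(.data$subject_id, .data$arm_id, .data$direction) |>
    dplyr::count(.data$arm_id, .data$direction, name = "n_subjects") |>
    dplyr::filter(.data$n_subjects >= min_subjects) |>
    dplyr::arrange(dplyr::desc(.data$n_subjects), .data$arm_id, .data$direction)
}

#' Tumor mutational burden
#'
#' Somatic point mutations (SNVs only; indels excluded) per megabase of
#' callable territory. The callable footprint is a required parameter; no
#' standard exome size is silently assumed beyond the documented default of
#' 30 Mb, and the denominator is echoed in the result so reports can flag it.
#'
#' @param variants variant tibble for one subject
#' @param callable_mb callable megabases (> 0; default 30, a typical exome)
#' @return one-row tibble: `subject_id`, `n_point_mutations`, `callable_mb`,
#'   `tmb`
#' @export
compute_tmb <- function(variants, callable_mb = 30) {
  if (callable_mb <= 0) abort("callable_mb must be positive")
  n <- sum(variants$variant_class == "SNV")
  tibble(
    subject_id = if (nrow(variants)) variants$subject_id[1] else NA_character_,
    n_point_mutations = n,
    callable_mb = callable_mb,
    tmb = n / callable_mb
  )
}

#' Assemble an oncoprint matrix
#'
#' Long-format gene/arm-by-subject alteration table. Rows are recurrent arm
#' events first, then panel genes ordered by overall alteration frequency
#' (descending, ties alphabetical); columns (subjects) are grouped by tumor
#' type. Each cell unions every alteration label hitting that gene in that
#' subject (`SNV`, `indel`, `fusion`, `gain`, `loss`).
#'
#' @param bundle `cohort_bundle`
#' @param gene_panel character vector of genes to display
#' @param recurrent_arms output of [cohort_arm_recurrence()] (optional)
#' @param arm_events per-subject arm events feeding the arm rows (optional)
#' @return tibble with `row_id`, `row_type` (`"arm"`/`"gene"`), `subject_id`,
#'   `tumor_type`, `labels` (comma-joined), plus attributes `row_order` and
#'   `subject_order`
#' @export
build_oncoprint <- function(bundle, gene_panel, recurrent_arms = NULL, arm_events = NULL) {
  if (length(gene_panel) == 0L) abort("gene_panel must be non-empty")
  subjects <- bundle$subjects |> dplyr::arrange(.data$tumor_type, .data$subject_id)

  gene_hits <- list()
  if (!is.null(bundle$variants) && nrow(bundle$variants)) {
    gene_hits$var <- bundle$variants |>
      dplyr::filter(.data$gene %in% gene_panel) |>
      dplyr::transmute(
        .data$subject_id, row_id = .data$gene,
        label = ifelse(.data$variant_class == "SNV", "SNV", "indel")
      )
  }
  if (!is.null(bundle$fusions) && nrow(bundle$fusions)) {
    fus <- bundle$fusions
    gene_hits$fus <- dplyr::bind_rows(
      dplyr::transmute(fus, .data$subject_id, row_id = .data$gene_5p, label = "fusion"),
      dplyr::transmute(fus, .data$subject_id, row_id = .data$gene_3p, label = "fusion")
    ) |> dplyr::filter(.data$row_id %in% gene_panel)
  }
  if (!is.null(bundle$cnv_genes) && nrow(bundle$cnv_genes)) {
    gene_hits$cnv <- bundle$cnv_genes |>
      dplyr::filter(.data$gene %in% gene_panel) |>
      dplyr::transmute(.data$subject_id, row_id = .data$gene, label = .data$direction)
  }
  gene_long <- dplyr::bind_rows(gene_hits)
  if (nrow(gene_long) == 0L) {
    gene_long <- tibble(subject_id = character(), row_id = character(), label = character())
  }
  gene_long$row_type <- "gene"

  arm_long <- tibble(subject_id = character(), row_id = character(),
                     label = character(), row_type = character())
  if (!is.null(arm_events) && nrow(arm_events) && !is.null(recurrent_arms) && nrow(recurrent_arms)) {
    arm_long <- arm_events |>
      dplyr::semi_join(recurrent_arms, by = c("arm_id", "direction")) |>
      dplyr::transmute(
        .data$subject_id,
        row_id = paste0(.data$arm_id, ifelse(.data$direction == "gain", "+", "-")),
        label = .data$direction, row_type = "arm"
      )
  }

  # gene rows ordered by distinct-subject alteration frequency, ties alphabetical
  freq <- gene_long |>
    dplyr::distinct(.data$row_id, .data$subject_id) |>
    dplyr::count(.data$row_id, name = "n")
  freq <- dplyr::left_join(tibble(row_id = gene_panel), freq, by = "row_id") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$row_id)
  row_order <- c(sort(unique(arm_long$row_id)), freq$row_id)

  cells <- dplyr::bind_rows(arm_long, gene_long) |>
    dplyr::group_by(.data$row_id, .data$row_type, .data$subject_id) |>
    dplyr::summarise(labels = paste(sort(unique(.data$label)), collapse = ","), .groups = "drop")

  grid <- tidyr::expand_grid(
    row_id = row_order,
    subject_id = subjects$subject_id
  ) |>
    dplyr::left_join(dplyr::distinct(cells, .data$row_id, .data$row_type), by = "row_id") |>
    dplyr::mutate(row_type = tidyr::replace_na(.data$row_type, "gene")) |>
    dplyr::left_join(cells, by = c("row_id", "row_type", "subject_id")) |>
    dplyr::mutate(labels = tidyr::replace_na(.data$labels, "")) |>
    dplyr::left_join(subjects, by = "subject_id") |>
    dplyr::select("row_id", "row_type", "subject_id", "tumor_type", "labels")

  structure(grid,
    class = c("oncoprint_matrix", class(grid)),
    row_order = row_order, subject_order = subjects$subject_id
  )
}

#' Tile plot of an oncoprint matrix
#' @param object `oncoprint_matrix` from [build_oncoprint()]
#' @param ... unused
#' @return ggplot object
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.oncoprint_matrix <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(
      row_id = factor(.data$row_id, levels = rev(attr(object, "row_order"))),
      subject_id = factor(.data$subject_id, levels = attr(object, "subject_order")),
      altered = .data$labels != ""
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject_id, y = .data$row_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = ifelse(.data$altered, .data$labels, NA)), colour = "white") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$tumor_type), scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, fill = "alteration") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
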