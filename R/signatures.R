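#' Canonical 96 trinucleotide substitution contexts
#'
#' Substitution class major (C>A, C>G, C>T, T>A, T>C, T>G), then the 16
#' flanking contexts with the 5' base varying slowest, both flanks in
#' A, C, G, T order. Bin names follow the usual `"A[C>A]A"` convention.
#'
#' @return character vector of length 96
#' @export
context_bins <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(f5, f3) paste0(f5, "[", s, "]", f3))))
  }))
}

#' Bin SNVs into a 96-context mutation catalog
#'
#' Each SNV carrying a trinucleotide context is assigned to one of the 96
#' pyrimidine-centred bins; purine-centred contexts (reference A or G) are
#' reverse-complemented onto the pyrimidine strand first. Indels and SNVs
#' without a context are ignored.
#'
#' @param variants variant tibble (see [cohort-data-model])
#' @return named integer vector of length 96 in [context_bins()] order, with
#'   attribute `subject_id`
#' @export
catalog_from_variants <- function(variants) {
  bins <- context_bins()
  counts <- setNames(integer(96), bins)
  snv <- variants[variants$variant_class == "SNV" & !is.na(variants$trinucleotide_context), , drop = FALSE]
  if (nrow(snv) == 0L) {
    attr(counts, "subject_id") <- if (nrow(variants)) variants$subject_id[1] else NA_character_
    return(counts)
  }
  ctx <- snv$trinucleotide_context
  ref <- snv$ref
  alt <- snv$alt
  bad <- which(substr(ctx, 2, 2) != ref)
  if (length(bad)) {
    abort(sprintf(
      "variant %s:%d has context '%s' whose centre is not the reference base",
      snv$chrom[bad[1]], snv$pos[bad[1]], ctx[bad[1]]
    ))
  }
  purine <- ref %in% c("A", "G")
  ctx[purine] <- reverse_complement(ctx[purine])
  ref[purine] <- unname(REV_COMP[ref[purine]])
  alt[purine] <- unname(REV_COMP[alt[purine]])
  key <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  bad <- which(!key %in% bins)
  if (length(bad)) {
    abort(sprintf(
      "variant %s:%d maps to no canonical context bin ('%s')",
      snv$chrom[bad[1]], snv$pos[bad[1]], key[bad[1]]
    ))
  }
  tab <- table(factor(key, levels = bins))
  counts[] <- as.integer(tab)
  attr(counts, "subject_id") <- snv$subject_id[1]
  counts
}

#' Validate a signature matrix
#'
#' @param W numeric 96-by-S matrix; columns are signature profiles, each
#'   non-negative and summing to 1 (tolerance 1e-6), with signature colnames
#' @return `W`, invisibly
#' @export
validate_signature_matrix <- function(W) {
  if (nrow(W) != 96L) abort("signature matrix must have 96 rows")
  if (is.null(colnames(W))) abort("signature matrix needs signature colnames")
  if (any(W < 0)) abort("signature matrix has negative entries")
  if (any(abs(colSums(W) - 1) > 1e-6)) abort("signature columns must each sum to 1")
  invisible(W)
}

#' Decompose a mutation catalog into signature exposures
#'
#' Linear combination decomposition: non-negative least squares
#' `e = argmin_{e >= 0} || W e - m ||_2`, solved by the Lawson-Hanson
#' active-set algorithm. Exposures are on the mutation-count scale;
#' proportions are `e / sum(e)`. An optional per-signature proportion cutoff
#' (default 0, i.e. off) zeroes signatures below the cutoff and refits on the
#' survivors.
#'
#' @param catalog length-96 non-negative count vector (see
#'   [catalog_from_variants()])
#' @param W validated signature matrix
#' @param cutoff minimum exposure proportion a signature must reach to be
#'   retained (default 0)
#' @param subject_id optional identifier; taken from the catalog attribute
#'   when absent
#' @return object of class `signature_exposures`: tibble with `subject_id`,
#'   `signature`, `exposure`, `proportion`; residual norm in attribute
#'   `residual`
#' @export
decompose_lcd <- function(catalog, W, cutoff = 0, subject_id = NULL) {
  validate_signature_matrix(W)
  m <- as.numeric(catalog)
  if (length(m) != nrow(W)) abort("catalog length does not match signature matrix rows")
  if (any(m < 0)) abort("catalog has negative counts")
  if (sum(m) < 1) abort("all-zero catalog: exposure proportions are undefined")
  subject_id <- subject_id %||% attr(catalog, "subject_id") %||% NA_character_

  fit <- pracma::lsqnonneg(unclass(W), m)
  e <- setNames(fit$x, colnames(W))
  if (cutoff > 0 && sum(e) > 0) {
    keep <- (e / sum(e)) >= cutoff
    if (!any(keep)) keep <- e == max(e)
    e[] <- 0
    refit <- pracma::lsqnonneg(unclass(W)[, keep, drop = FALSE], m)
    e[keep] <- refit$x
    fit <- refit
  }
  pi <- if (sum(e) > 0) e / sum(e) else e * NA_real_
  out <- tibble(
    subject_id = subject_id,
    signature = colnames(W),
    exposure = unname(e),
    proportion = unname(pi)
  )
  structure(out,
    class = c("signature_exposures", class(out)),
    residual = sqrt(sum((unclass(W) %*% e - m)^2))
  )
}

#' Mean signature proportions per tumor type
#'
#' Unweighted arithmetic mean of per-subject exposure proportions within each
#' tumor-type label. Output rows (one per type) sum to 1.
#'
#' @param exposures `signature_exposures` tibbles bound together, or a single
#'   long tibble with `subject_id`, `signature`, `proportion`
#' @param labels tibble with `subject_id`, `tumor_type`
#' @return tibble with `tumor_type`, `signature`, `mean_proportion`
#' @export
average_exposures_by_type <- function(exposures, labels) {
  if (is.list(exposures) && !is.data.frame(exposures)) {
    exposures <- dplyr::bind_rows(exposures)
  }
  check_columns(exposures, c("subject_id", "signature", "proportion"), "exposure table")
  missing <- setdiff(unique(exposures$subject_id), labels$subject_id)
  if (length(missing)) {
    abort(sprintf("no tumor-type label for subject(s): %s", paste(missing, collapse = ", ")))
  }
  empty <- setdiff(unique(labels$tumor_type), unique(
    dplyr::inner_join(exposures, labels, by = "subject_id")$tumor_type
  ))
  if (length(empty)) {
    warn(sprintf("tumor type(s) with no exposures omitted: %s", paste(empty, collapse = ", ")))
  }
  exposures |>
    dplyr::inner_join(labels, by = "subject_id") |>
    dplyr::group_by(.data$tumor_type, .data$signature) |>
    dplyr::summarise(mean_proportion = mean(.data$proportion), .groups = "drop")
}

#' @rdname decompose_lcd
#' @param x `signature_exposures` object
#' @param ... unused
#' @export
#' @exportS3Method generics::tidy
tidy.signature_exposures <- function(x, ...) as_tibble(x)

#' @rdname decompose_lcd
#' @export
#' @exportS3Method generics::glance
glance.signature_exposures <- function(x, ...) {
  tibble(
    n_signatures = nrow(x),
    n_active = sum(x$exposure > 0),
    total_mutations_fit = sum(x$exposure),
    residual = attr(x, "residual")
  )
}

#' Bar plot of signature exposure proportions
#' @param object `signature_exposures`
#' @param ... unused
#' @return ggplot object
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.signature_exposures <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$signature, y = .data$proportion)) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::labs(x = NULL, y = "exposure proportion") +
    ggplot2::theme_minimal()
}
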