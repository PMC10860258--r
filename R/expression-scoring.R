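#' Median-of-ratios normalisation of raw counts
#'
#' Size factors are computed by the median-of-ratios method: a per-gene
#' pseudo-reference is the geometric mean across samples over genes with
#' all-positive counts, and each sample's size factor is the median ratio of
#' its counts to that reference. Output values are
#' `log2(count / size_factor + pseudocount)`. This is a light-weight stand-in
#' for a regularized-log transform: the outlier statistic downstream, not the
#' transform, carries the method, and pre-normalised matrices are accepted
#' directly via the `scale` attribute.
#'
#' @param matrix `expr_matrix` on the `raw_counts` scale
#' @param pseudocount positive offset added inside the log (default 1)
#' @return `expr_matrix` on the `normalized_log` scale, with the size factors
#'   attached as attribute `size_factors`
#' @export
normalize_counts <- function(matrix, pseudocount = 1) {
  if (expr_scale(matrix) != "raw_counts") abort("normalize_counts() expects raw counts")
  if (pseudocount <= 0) abort("pseudocount must be positive")
  zero_samples <- colnames(matrix)[colSums(matrix) == 0]
  if (length(zero_samples)) {
    abort(sprintf("sample(s) with all-zero counts: %s", paste(zero_samples, collapse = ", ")))
  }
  all_pos <- rowSums(matrix > 0) == ncol(matrix)
  if (!any(all_pos)) abort("no gene has positive counts in every sample")
  log_ref <- rowMeans(log(matrix[all_pos, , drop = FALSE]))
  sf <- apply(matrix[all_pos, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_ref))
  })
  out <- log2(sweep(unclass(matrix), 2, sf, "/") + pseudocount)
  out <- expression_matrix(out, scale = "normalized_log")
  attr(out, "size_factors") <- sf
  out
}

#' Summarise a normal-tissue reference panel
#'
#' Computes per-gene mean and standard deviation (n-1 denominator) of a
#' normalised-log expression matrix of normal tissues — in the intended use a
#' whole-body panel of 22 tissues. Standard deviations are floored at
#' `sd_floor` so that genes with (near-)constant reference expression cannot
#' produce unbounded Z-scores.
#'
#' @param reference `expr_matrix` on the `normalized_log` scale with >= 2
#'   samples
#' @param sd_floor positive floor on the per-gene SD, on the log2 scale
#'   (default 0.1)
#' @return object of class `normal_reference`: a tibble with `gene`, `mu`,
#'   `sigma`, plus attributes `n_reference_samples` and `sd_floor`
#' @export
build_normal_reference <- function(reference, sd_floor = 0.1) {
  if (ncol(reference) < 2L) abort("normal reference needs at least 2 samples")
  if (expr_scale(reference) != "normalized_log") {
    abort("build_normal_reference() expects a normalized_log matrix; run normalize_counts() first")
  }
  if (sd_floor <= 0) abort("sd_floor must be positive")
  out <- tibble(
    gene = rownames(reference),
    mu = unname(rowMeans(reference)),
    sigma = unname(pmax(apply(reference, 1, sd), sd_floor))
  )
  structure(out,
    class = c("normal_reference", class(out)),
    n_reference_samples = ncol(reference), sd_floor = sd_floor
  )
}

#' Expression-outlier Z-scores against the normal reference (NRZ)
#'
#' Standardises a tumor expression vector gene-by-gene against the normal
#' reference panel: `z = (x - mu) / sigma`. Genes at least `tau` SDs above
#' the normal mean are flagged `over`, at least `tau` below flagged `under`
#' (both boundaries inclusive), otherwise `neutral`. Tumor genes absent from
#' the reference are returned in the `unmatched` attribute, not scored.
#'
#' @param tumor_sample named numeric vector of normalised-log expression for
#'   one tumor, or a one-column `expr_matrix`
#' @param ref `normal_reference`
#' @param tau actionability threshold in SDs (default 2)
#' @param subject_id optional identifier carried into the result
#' @return object of class `nrz_scores`: tibble with `subject_id`, `gene`,
#'   `x`, `z`, `flag`
#' @export
nrz_score <- function(tumor_sample, ref, tau = 2, subject_id = NA_character_) {
  if (is.matrix(tumor_sample)) {
    if (ncol(tumor_sample) != 1L) abort("nrz_score() scores one sample at a time")
    if (is.na(subject_id)) subject_id <- colnames(tumor_sample)[1] %||% NA_character_
    tumor_sample <- setNames(as.numeric(tumor_sample[, 1]), rownames(tumor_sample))
  }
  genes <- intersect(names(tumor_sample), ref$gene)
  if (length(genes) == 0L) abort("no genes shared between tumor sample and normal reference")
  unmatched <- setdiff(names(tumor_sample), ref$gene)
  idx <- match(genes, ref$gene)
  z <- (tumor_sample[genes] - ref$mu[idx]) / ref$sigma[idx]
  out <- tibble(
    subject_id = subject_id,
    gene = genes,
    x = unname(tumor_sample[genes]),
    z = unname(z),
    flag = dplyr::case_when(z >= tau ~ "over", z <= -tau ~ "under", TRUE ~ "neutral")
  )
  structure(out,
    class = c("nrz_scores", class(out)),
    tau = tau, unmatched = unmatched
  )
}

#' Cancer-reference percentile of tumor expression (CRC)
#'
#' Places each gene of a tumor sample on the empirical distribution of a
#' cancer-reference cohort (other relapsed/refractory childhood tumors) using
#' the mid-rank empirical CDF:
#' `p = 100 * (#below + 0.5 * #tied) / n_ref`.
#'
#' @param tumor_sample named numeric expression vector
#' @param cancer_ref `expr_matrix` of the reference cohort (>= 2 samples), on
#'   the same scale as the tumor vector
#' @param subject_id optional identifier
#' @return tibble with `subject_id`, `gene`, `x`, `percentile`
#' @export
crc_score <- function(tumor_sample, cancer_ref, subject_id = NA_character_) {
  if (ncol(cancer_ref) < 2L) abort("cancer reference needs at least 2 samples")
  genes <- intersect(names(tumor_sample), rownames(cancer_ref))
  if (length(genes) == 0L) abort("no genes shared between tumor sample and cancer reference")
  n_ref <- ncol(cancer_ref)
  p <- vapply(genes, function(g) {
    refv <- cancer_ref[g, ]
    x <- tumor_sample[[g]]
    100 * (sum(refv < x) + 0.5 * sum(refv == x)) / n_ref
  }, numeric(1))
  tibble(subject_id = subject_id, gene = genes, x = unname(tumor_sample[genes]), percentile = unname(p))
}

#' @export
print.nrz_scores <- function(x, ...) {
  cat(sprintf(
    "<nrz_scores> %d genes scored at tau = %g (%d over, %d under)\n",
    nrow(x), attr(x, "tau"), sum(x$flag == "over"), sum(x$flag == "under")
  ))
  NextMethod()
}

#' @rdname nrz_score
#' @param x `nrz_scores` object
#' @param ... unused
#' @export
#' @exportS3Method generics::tidy
tidy.nrz_scores <- function(x, ...) {
  as_tibble(x)[c("subject_id", "gene", "x", "z", "flag")]
}

#' @rdname nrz_score
#' @export
#' @exportS3Method generics::glance
glance.nrz_scores <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_over = sum(x$flag == "over"),
    n_under = sum(x$flag == "under"),
    tau = attr(x, "tau"),
    n_unmatched = length(attr(x, "unmatched"))
  )
}

#' Volcano-style NRZ score plot
#'
#' Genes ranked by Z-score with the actionability band at +/- tau.
#'
#' @param object `nrz_scores` object
#' @param ... unused
#' @return ggplot object
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.nrz_scores <- function(object, ...) {
  tau <- attr(object, "tau")
  df <- as_tibble(object) |> dplyr::arrange(.data$z) |> dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$z, colour = .data$flag)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-tau, tau), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(over = "#c0392b", under = "#2980b9", neutral = "grey60")) +
    ggplot2::labs(
      x = "genes ranked by Z", y = "NRZ Z-score",
      title = sprintf("Expression outliers vs normal reference (tau = %g)", tau)
    ) +
    ggplot2::theme_minimal()
}
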