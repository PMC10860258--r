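#' Somatic variant, segment, fusion and rule tables
#'
#' The pipeline's in-memory data model is tidy: one tibble per record type,
#' one row per event. All coordinates are 1-based inclusive regardless of the
#' input file dialect; readers convert at the boundary. Gene identity is by
#' plain HGNC-style symbol, case-sensitive, with no alias resolution.
#'
#' @name cohort-data-model
#' @section Variant table columns:
#' `subject_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `variant_class` (one of `"SNV"`, `"insertion"`, `"deletion"`),
#' `gene`, `effect`, `protein_change` (optional, `NA` allowed),
#' `trinucleotide_context` (optional pyrimidine- or purine-centred 3-mer with
#' the variant base at the centre).
NULL

VARIANT_COLS <- c(
  "subject_id", "chrom", "pos", "ref", "alt", "variant_class",
  "gene", "effect", "protein_change", "trinucleotide_context"
)

#' Build a validated somatic-variant tibble
#'
#' @param df data frame holding the variant columns (see [cohort-data-model]);
#'   `protein_change` and `trinucleotide_context` may be absent and are filled
#'   with `NA`.
#' @return tibble with the canonical variant columns, validated.
#' @export
variant_table <- function(df) {
  df <- as_tibble(df)
  for (col in c("protein_change", "trinucleotide_context")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  check_columns(df, VARIANT_COLS, "variant table")
  df <- df[VARIANT_COLS]
  df$pos <- as.integer(df$pos)
  validate_variants(df)
  df
}

validate_variants <- function(df) {
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad)) abort(sprintf("variant row %d: pos must be >= 1", bad[1]))
  bad <- which(!df$variant_class %in% c("SNV", "insertion", "deletion"))
  if (length(bad)) {
    abort(sprintf("variant row %d: unknown variant_class '%s'", bad[1], df$variant_class[bad[1]]))
  }
  snv <- df$variant_class == "SNV"
  bad <- which(snv & (nchar(df$ref) != 1L | nchar(df$alt) != 1L))
  if (length(bad)) abort(sprintf("variant row %d: SNV must have 1-bp ref and alt", bad[1]))
  ctx <- df$trinucleotide_context
  has_ctx <- !is.na(ctx)
  bad <- which(has_ctx & (nchar(ctx) != 3L | !grepl("^[ACGT]{3}$", ctx)))
  if (length(bad)) abort(sprintf("variant row %d: malformed trinucleotide context '%s'", bad[1], ctx[bad[1]]))
  bad <- which(has_ctx & snv & substr(ctx, 2, 2) != df$ref)
  if (length(bad)) {
    abort(sprintf(
      "variant row %d: context '%s' does not have the reference base at its centre",
      bad[1], ctx[bad[1]]
    ))
  }
  invisible(df)
}

classify_alleles <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    nchar(alt) > nchar(ref) ~ "insertion",
    TRUE ~ "deletion"
  )
}

#' Default column map for MAF-like variant TSVs
#'
#' Maps the canonical in-memory column names to the names expected in the
#' file. Override individual entries to adapt to a local dialect.
#'
#' @return named character vector (canonical -> file column)
#' @export
default_variant_columns <- function() {
  c(
    subject_id = "subject", chrom = "chrom", pos = "pos", ref = "ref",
    alt = "alt", gene = "gene", effect = "effect",
    protein_change = "protein_change", trinucleotide_context = "context"
  )
}

#' Read somatic variants from a VCF or MAF-like TSV
#'
#' One output row per ALT allele; `variant_class` is derived from allele
#' lengths. For VCF input, annotation fields are pulled from INFO keys named
#' by `info_map`; for TSV input, columns are mapped by `column_map`.
#'
#' @param path VCF (`.vcf`) or tab-separated file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param subject_id subject identifier attached to every record when the file
#'   itself carries none (required for VCF input).
#' @param column_map named vector mapping canonical variant columns to file
#'   columns (TSV input); see [default_variant_columns()].
#' @param info_map named vector mapping canonical annotation fields
#'   (`gene`, `effect`, `protein_change`, `trinucleotide_context`) to VCF INFO
#'   keys.
#' @return validated variant tibble (see [cohort-data-model])
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          subject_id = NULL,
                          column_map = default_variant_columns(),
                          info_map = c(
                            gene = "GENE", effect = "EFFECT",
                            protein_change = "PCHANGE",
                            trinucleotide_context = "CONTEXT"
                          )) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    if (is.null(subject_id)) abort("subject_id is required when reading a VCF")
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) return(variant_table(empty_variant_df()))
    grab <- function(key) {
      if (is.na(key)) return(rep(NA_character_, nrow(fix)))
      v <- suppressWarnings(vcfR::extract.info(vcf, element = key))
      if (is.null(v)) rep(NA_character_, nrow(fix)) else as.character(v)
    }
    rows <- tibble(
      subject_id = subject_id,
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT,
      gene = grab(info_map[["gene"]]),
      effect = grab(info_map[["effect"]]),
      protein_change = grab(unname(info_map["protein_change"])[1]),
      trinucleotide_context = grab(unname(info_map["trinucleotide_context"])[1])
    )
    # split multi-allelic records: one row per ALT allele
    rows <- tidyr::separate_rows(rows, "alt", sep = ",")
    rows$variant_class <- classify_alleles(rows$ref, rows$alt)
    return(variant_table(rows))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) return(variant_table(empty_variant_df()))
  out <- tibble(.rows = nrow(raw))
  for (canon in names(column_map)) {
    file_col <- column_map[[canon]]
    out[[canon]] <- if (file_col %in% names(raw)) raw[[file_col]] else NA
  }
  for (req in c("subject_id", "chrom", "pos", "ref", "alt", "gene", "effect")) {
    if (all(is.na(out[[req]]))) {
      abort(sprintf("variant file %s: column '%s' (mapped from '%s') not found", path, req, column_map[[req]]))
    }
  }
  for (canon in setdiff(names(column_map), "pos")) {
    out[[canon]] <- as.character(out[[canon]])
  }
  out$pos <- suppressWarnings(as.integer(out$pos))
  bad <- which(is.na(out$pos))
  if (length(bad)) abort(sprintf("%s line %d: non-numeric position", path, bad[1] + 1L))
  out <- tidyr::separate_rows(out, "alt", sep = ",")
  out$variant_class <- classify_alleles(out$ref, out$alt)
  variant_table(out)
}

empty_variant_df <- function() {
  tibble(
    subject_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), variant_class = character(),
    gene = character(), effect = character(),
    protein_change = character(), trinucleotide_context = character()
  )
}

#' Write a variant tibble to a MAF-like TSV
#'
#' Inverse of [read_variants()] for the TSV dialect: `write_variants()` then
#' `read_variants()` round-trips field-for-field.
#'
#' @param variants validated variant tibble
#' @param path output path
#' @param column_map canonical -> file column map used for the header
#' @return `path`, invisibly
#' @export
write_variants <- function(variants, path, column_map = default_variant_columns()) {
  out <- variants[names(column_map)]
  names(out) <- unname(column_map)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read copy-number segments
#'
#' Expects columns `subject`, `chrom`, `start`, `end`, `log2_ratio`,
#' `n_genes`. Coordinates are normalised to 1-based inclusive: declare the
#' file's convention through `dialect`.
#'
#' @param path tab-separated SEG-like file
#' @param dialect `"one_based"` (start/end already 1-based inclusive) or
#'   `"zero_based_half_open"` (BED-style; start is shifted by +1)
#' @return tibble with columns `subject_id`, `chrom`, `start`, `end`,
#'   `log2_ratio`, `n_genes`, rows in file order
#' @export
read_segments <- function(path, dialect = c("one_based", "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(raw, c("subject", "chrom", "start", "end", "log2_ratio", "n_genes"), path)
  if (nrow(raw) == 0L) {
    return(tibble(
      subject_id = character(), chrom = character(), start = integer(),
      end = integer(), log2_ratio = double(), n_genes = integer()
    ))
  }
  lr <- suppressWarnings(as.numeric(raw$log2_ratio))
  bad <- which(is.na(lr) & !is.na(raw$log2_ratio))
  if (length(bad)) abort(sprintf("%s line %d: non-numeric log2_ratio", path, bad[1] + 1L))
  out <- tibble(
    subject_id = as.character(raw$subject),
    chrom = as.character(raw$chrom),
    start = as.integer(raw$start),
    end = as.integer(raw$end),
    log2_ratio = lr,
    n_genes = as.integer(raw$n_genes)
  )
  if (dialect == "zero_based_half_open") out$start <- out$start + 1L
  segment_table(out)
}

#' Validate a copy-number segment tibble
#' @param df data frame with segment columns
#' @return validated tibble
#' @export
segment_table <- function(df) {
  df <- as_tibble(df)
  check_columns(df, c("subject_id", "chrom", "start", "end", "log2_ratio", "n_genes"), "segment table")
  bad <- which(df$start > df$end)
  if (length(bad)) abort(sprintf("segment row %d: start > end", bad[1]))
  bad <- which(df$n_genes < 0L)
  if (length(bad)) abort(sprintf("segment row %d: negative n_genes", bad[1]))
  df
}

#' Write segments back to SEG-like TSV (1-based inclusive)
#' @param segments segment tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_segments <- function(segments, path) {
  out <- segments
  names(out)[names(out) == "subject_id"] <- "subject"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read fusion calls from a TSV
#'
#' Expects columns `subject`, `gene_5p`, `gene_3p` and optionally `label`;
#' a missing label is synthesised as `GENE5P_GENE3P`.
#'
#' @param path tab-separated fusion file
#' @return tibble with `subject_id`, `gene_5p`, `gene_3p`, `label`
#' @export
read_fusions <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(raw, c("subject", "gene_5p", "gene_3p"), path)
  out <- tibble(
    subject_id = as.character(raw$subject),
    gene_5p = as.character(raw$gene_5p),
    gene_3p = as.character(raw$gene_3p),
    label = if ("label" %in% names(raw)) as.character(raw$label) else
      paste(raw$gene_5p, raw$gene_3p, sep = "_")
  )
  fusion_table(out)
}

#' Validate a fusion tibble
#' @param df data frame with fusion columns
#' @return validated tibble
#' @export
fusion_table <- function(df) {
  df <- as_tibble(df)
  check_columns(df, c("subject_id", "gene_5p", "gene_3p", "label"), "fusion table")
  bad <- which(is.na(df$gene_5p) | df$gene_5p == "" | is.na(df$gene_3p) | df$gene_3p == "")
  if (length(bad)) abort(sprintf("fusion row %d: empty partner gene symbol", bad[1]))
  df
}

#' Read the drug-gene rules knowledge base
#'
#' Rules drive the three-tier matching algorithm. Each rule links a drug to a
#' gene at a tier (`direct`, `inferred`, `expression`), with a `direction`
#' (`over`/`under` for expression rules, `any` otherwise) and a `mode`
#' (`sensitivity` or `resistance`) plus a free-text `evidence` citation.
#' Duplicate (drug, gene, tier, direction, mode) rows are collapsed with
#' evidence strings concatenated by `"; "`.
#'
#' @param path TSV (columns `drug`, `gene`, `tier`, `direction`, `mode`,
#'   optional `evidence`) or a JSON array of objects with the same fields
#' @return validated rule tibble
#' @export
read_knowledge_base <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    raw <- as_tibble(raw)
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(drug_rule_set(tibble(
      drug = character(), gene = character(), tier = character(),
      direction = character(), mode = character(), evidence = character()
    )))
  }
  check_columns(raw, c("drug", "gene", "tier", "direction", "mode"), path)
  if (!"evidence" %in% names(raw)) raw$evidence <- NA_character_
  drug_rule_set(raw)
}

#' Validate and canonicalise a drug-rule tibble
#'
#' @param df data frame of rules
#' @return tibble with columns `drug`, `gene`, `tier`, `direction`, `mode`,
#'   `evidence`; duplicates collapsed
#' @export
drug_rule_set <- function(df) {
  df <- as_tibble(df)
  check_columns(df, c("drug", "gene", "tier", "direction", "mode"), "rule set")
  if (!"evidence" %in% names(df)) df$evidence <- NA_character_
  df <- df[c("drug", "gene", "tier", "direction", "mode", "evidence")]
  bad <- which(!df$tier %in% c("direct", "inferred", "expression"))
  if (length(bad)) abort(sprintf("rule row %d: unknown tier '%s'", bad[1], df$tier[bad[1]]))
  bad <- which(!df$mode %in% c("sensitivity", "resistance"))
  if (length(bad)) abort(sprintf("rule row %d: unknown mode '%s'", bad[1], df$mode[bad[1]]))
  bad <- which(df$tier == "expression" & !df$direction %in% c("over", "under"))
  if (length(bad)) {
    abort(sprintf(
      "expression rules must have direction 'over' or 'under'; offending rows: %s",
      paste(bad, collapse = ", ")
    ))
  }
  bad <- which(df$tier %in% c("direct", "inferred") & df$direction != "any")
  if (length(bad)) {
    abort(sprintf(
      "direct/inferred rules must have direction 'any'; offending rows: %s",
      paste(bad, collapse = ", ")
    ))
  }
  df |>
    dplyr::group_by(.data$drug, .data$gene, .data$tier, .data$direction, .data$mode) |>
    dplyr::summarise(
      evidence = paste(stats::na.omit(.data$evidence), collapse = "; "),
      .groups = "drop"
    )
}

#' Build a chromosome-arm map from a UCSC cytoBand table
#'
#' cytoBand files are 0-based half-open (`chrom`, `chromStart`, `chromEnd`,
#' `name`, `gieStain`). Bands whose names start with `p` form the p arm and
#' bands starting with `q` the q arm; each arm spans from its first to its
#' last band, converted to 1-based inclusive coordinates.
#'
#' @param path cytoBand-format TSV (no header)
#' @return arm tibble with `arm_id` (e.g. `"17q"`), `chrom`, `start`, `end`
#' @export
read_arm_map <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "chromStart", "chromEnd", "name", "gieStain"),
    show_col_types = FALSE, progress = FALSE
  )
  raw$arm_letter <- substr(raw$name, 1, 1)
  raw <- raw[raw$arm_letter %in% c("p", "q"), ]
  out <- raw |>
    dplyr::group_by(.data$chrom, .data$arm_letter) |>
    dplyr::summarise(
      start = min(.data$chromStart) + 1L,
      end = max(.data$chromEnd),
      .groups = "drop"
    ) |>
    dplyr::mutate(arm_id = paste0(sub("^chr", "", .data$chrom), .data$arm_letter)) |>
    dplyr::select("arm_id", "chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$arm_id)
  arm_map(out)
}

#' Validate an arm-map tibble
#' @param df data frame with `arm_id`, `chrom`, `start`, `end`
#' @return validated tibble
#' @export
arm_map <- function(df) {
  df <- as_tibble(df)
  check_columns(df, c("arm_id", "chrom", "start", "end"), "arm map")
  bad <- which(df$end <= df$start - 1L)
  if (length(bad)) abort(sprintf("arm map row %d: non-positive arm length", bad[1]))
  # arms on one chromosome must not overlap
  by_chr <- split(df, df$chrom)
  for (chr in names(by_chr)) {
    d <- by_chr[[chr]][order(by_chr[[chr]]$start), ]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      abort(sprintf("arm map: overlapping arms on chromosome %s", chr))
    }
  }
  df
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column holds gene symbols, remaining columns one sample each.
#'
#' @param path TSV file
#' @param scale `"raw_counts"` or `"normalized_log"`, recorded on the result
#' @return numeric matrix (genes x samples) with a `scale` attribute
#' @export
read_expression <- function(path, scale = c("raw_counts", "normalized_log")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(raw[[1]])
  m <- as.matrix(raw[-1])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_matrix(m, scale = scale)
}

#' Construct a validated expression matrix
#'
#' @param values numeric genes-by-samples matrix with gene rownames and sample
#'   colnames
#' @param scale `"raw_counts"` or `"normalized_log"`
#' @return the matrix, with class `expr_matrix` and a `scale` attribute
#' @export
expression_matrix <- function(values, scale = c("raw_counts", "normalized_log")) {
  scale <- match.arg(scale)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids in expression matrix")
  if (any(!is.finite(values))) abort("expression matrix contains non-finite values")
  if (scale == "raw_counts" && any(values < 0)) abort("raw counts must be non-negative")
  structure(values, class = c("expr_matrix", class(values)), scale = scale)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples [%s]\n",
    nrow(x), ncol(x), attr(x, "scale")
  ))
  invisible(x)
}

expr_scale <- function(x) attr(x, "scale") %||% "raw_counts"

#' Assemble and validate a cohort bundle
#'
#' A bundle holds everything one pipeline run needs: per-subject somatic
#' events and expression, the shared normal reference inputs, the arm map,
#' the rule set, and the clinical tables. Every subject referenced anywhere
#' must appear in `subjects` with a tumor-type label.
#'
#' @param subjects tibble with `subject_id` and `tumor_type`
#'   (`"neuroblastoma"`, `"CNS"` or `"rare"`)
#' @param variants,segments,fusions event tibbles (may be empty)
#' @param cnv_genes optional gene-level CNV table (`subject_id`, `gene`,
#'   `direction`, `log2_ratio`) used by tier-1/2 matching
#' @param expression named list of per-subject expression vectors or a matrix
#'   with one column per subject
#' @param normal_reference `normal_reference` object (see
#'   [build_normal_reference()])
#' @param arm_map arm tibble
#' @param rules drug-rule tibble
#' @param inference_map tibble (`gene`, `target_gene`, `evidence`) for tier-2
#' @param blacklist tibble of unordered conflicting drug pairs
#'   (`drug_a`, `drug_b`)
#' @param lesions lesion-series tibble (`subject_id`, `timepoint`, `sum_mm`,
#'   `ned_flag`); timepoint 0 is the pre-cycle-1 baseline
#' @param milestones milestone tibble (`subject_id`, `milestone`, `days`)
#' @return list with class `cohort_bundle`
#' @export
cohort_bundle <- function(subjects,
                          variants = empty_variant_df(),
                          segments = NULL, fusions = NULL, cnv_genes = NULL,
                          expression = NULL, normal_reference = NULL,
                          arm_map = NULL, rules = NULL, inference_map = NULL,
                          blacklist = NULL, lesions = NULL, milestones = NULL) {
  subjects <- as_tibble(subjects)
  check_columns(subjects, c("subject_id", "tumor_type"), "subject registry")
  bad <- which(!subjects$tumor_type %in% c("neuroblastoma", "CNS", "rare"))
  if (length(bad)) {
    abort(sprintf("subject %s: unknown tumor type '%s'", subjects$subject_id[bad[1]], subjects$tumor_type[bad[1]]))
  }
  bundle <- structure(
    list(
      subjects = subjects, variants = variants, segments = segments,
      fusions = fusions, cnv_genes = cnv_genes, expression = expression,
      normal_reference = normal_reference, arm_map = arm_map, rules = rules,
      inference_map = inference_map, blacklist = blacklist,
      lesions = lesions, milestones = milestones
    ),
    class = "cohort_bundle"
  )
  validate_bundle(bundle)
  bundle
}

#' Check cross-table consistency of a cohort bundle
#' @param bundle `cohort_bundle`
#' @return `bundle`, invisibly; errors on an orphan subject reference
#' @export
validate_bundle <- function(bundle) {
  known <- bundle$subjects$subject_id
  refs <- list(
    variants = bundle$variants, segments = bundle$segments,
    fusions = bundle$fusions, cnv_genes = bundle$cnv_genes,
    lesions = bundle$lesions, milestones = bundle$milestones
  )
  for (nm in names(refs)) {
    tab <- refs[[nm]]
    if (is.null(tab) || nrow(tab) == 0L) next
    orphan <- setdiff(unique(tab$subject_id), known)
    if (length(orphan)) {
      abort(sprintf("%s table references unknown subject(s): %s", nm, paste(orphan, collapse = ", ")))
    }
  }
  if (!is.null(bundle$expression)) {
    ids <- if (is.list(bundle$expression)) names(bundle$expression) else colnames(bundle$expression)
    orphan <- setdiff(ids, known)
    if (length(orphan)) {
      abort(sprintf("expression references unknown subject(s): %s", paste(orphan, collapse = ", ")))
    }
  }
  invisible(bundle)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d subjects (%s)\n",
    nrow(x$subjects),
    paste(sprintf("%s: %d", names(table(x$subjects$tumor_type)), table(x$subjects$tumor_type)), collapse = ", ")
  ))
  invisible(x)
}
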