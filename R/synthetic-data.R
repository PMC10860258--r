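#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the study conditions the pipeline was designed around:
#' a cohort of 144 subjects split 31 neuroblastoma / 41 CNS / 72 rare, a
#' 22-tissue whole-body normal reference, expression outliers spiked at
#' +/- 4 reference SDs on the log2 scale, mutation catalogs drawn from
#' 5-signature mixtures with per-type mutation loads spanning a low
#' (CNS-like) to higher (neuroblastoma-like) burden, arm-level gains/losses
#' planted at the recurrence frequencies reported for relapsed/refractory
#' childhood tumors (e.g. 17q gain in most neuroblastomas), and lesion
#' trajectories drawn over all five response classes at the pooled
#' best-response proportions.
#'
#' @param seed integer seed; all generator randomness flows through it
#' @param n_subjects named integer vector of subjects per tumor type
#' @param n_genes number of genes in the expression space
#' @param n_tissues normal-reference panel size
#' @param n_panel size of the targetable-gene panel at the top of the gene
#'   list from which spikes and expression rules are drawn
#' @param n_over,n_under genes spiked over/under per tumor
#' @param spike_sd spike effect size in reference SDs
#' @param n_signatures number of synthetic mutational signatures
#' @param mutations_per_subject named vector of mean mutation counts per type
#' @param response_probs named probabilities over `CR`, `PR`, `SD`, `PD`,
#'   `NED`
#' @param cycle_probs named probabilities over first-cycle-with-all-agents
#'   categories `c1`, `c2`, `c3`, `c5`, `never`
#' @return list with class `simulation_config`
#' @export
simulation_config <- function(seed = 1L,
                              n_subjects = c(neuroblastoma = 31L, CNS = 41L, rare = 72L),
                              n_genes = 1000L,
                              n_tissues = 22L,
                              n_panel = 60L,
                              n_over = 20L, n_under = 10L, spike_sd = 4,
                              n_signatures = 5L,
                              mutations_per_subject = c(neuroblastoma = 100, CNS = 21, rare = 36),
                              response_probs = c(CR = 11, PR = 11, SD = 41, PD = 43, NED = 18) / 124,
                              cycle_probs = c(c1 = 121, c2 = 12, c3 = 3, c5 = 1, never = 7) / 144) {
  if (spike_sd <= 0) abort("spike_sd must be positive")
  if (any(n_subjects < 0)) abort("n_subjects must be non-negative")
  if (n_over + n_under > n_panel) abort("spiked genes exceed the targetable panel")
  if (n_panel > n_genes) abort("targetable panel exceeds the gene space")
  if (abs(sum(response_probs) - 1) > 1e-9) abort("response_probs must sum to 1")
  if (abs(sum(cycle_probs) - 1) > 1e-9) abort("cycle_probs must sum to 1")
  structure(
    list(
      seed = as.integer(seed), n_subjects = n_subjects, n_genes = n_genes,
      n_tissues = n_tissues, n_panel = n_panel, n_over = n_over,
      n_under = n_under, spike_sd = spike_sd, n_signatures = n_signatures,
      mutations_per_subject = mutations_per_subject,
      response_probs = response_probs, cycle_probs = cycle_probs
    ),
    class = "simulation_config"
  )
}

#' Synthetic signature matrix
#'
#' S well-separated signature profiles over the 96 canonical contexts: each
#' signature concentrates most of its mass on its own block of contexts, so
#' mixtures are identifiable by NNLS.
#'
#' @param n_signatures number of signatures
#' @param seed integer seed
#' @return 96 x S column-normalised matrix with names `SBS_sim1`, ...
#' @export
synthetic_signature_matrix <- function(n_signatures = 5, seed = 1L) {
  withr::with_seed(seed, {
    W <- matrix(runif(96 * n_signatures, 0, 0.2), nrow = 96)
    block <- split(seq_len(96), cut(seq_len(96), n_signatures, labels = FALSE))
    for (s in seq_len(n_signatures)) W[block[[s]], s] <- W[block[[s]], s] + runif(length(block[[s]]), 1, 3)
    W <- sweep(W, 2, colSums(W), "/")
    dimnames(W) <- list(context_bins(), paste0("SBS_sim", seq_len(n_signatures)))
    validate_signature_matrix(W)
    W
  })
}

#' Synthetic chromosome-arm map
#'
#' Arm geometry for the chromosomes carrying planted events; 1-based
#' inclusive, centromere-free toy coordinates.
#'
#' @return arm tibble (`arm_id`, `chrom`, `start`, `end`)
#' @export
synthetic_arm_map <- function() {
  chroms <- c("chr1", "chr2", "chr3", "chr7", "chr8", "chr11", "chr16", "chr17")
  lengths <- c(249e6, 243e6, 198e6, 159e6, 145e6, 135e6, 90e6, 83e6)
  cen <- round(lengths * 0.4)
  arm_map(dplyr::bind_rows(
    tibble(arm_id = paste0(sub("chr", "", chroms), "p"), chrom = chroms,
           start = 1, end = cen),
    tibble(arm_id = paste0(sub("chr", "", chroms), "q"), chrom = chroms,
           start = cen + 1, end = lengths)
  ))
}

# per-type arm-event planting probabilities (cohort recurrence frequencies
# typical of relapsed childhood solid tumors)
arm_event_spec <- function() tibble::tibble(
  tumor_type = c(rep("neuroblastoma", 7), "CNS", rep("rare", 4)),
  arm_id = c("17q", "7q", "1q", "2p", "11q", "3p", "1p", "17p", "8q", "8p", "16q", "17p"),
  direction = c("gain", "gain", "gain", "gain", "loss", "loss", "loss",
                "loss", "gain", "gain", "loss", "loss"),
  prob = c(0.78, 0.43, 0.30, 0.08, 0.43, 0.43, 0.19, 0.27, 0.23, 0.14, 0.15, 0.08)
)

driver_spec <- function() tibble::tibble(
  tumor_type = c("neuroblastoma", "neuroblastoma", "CNS", "CNS", "rare", "rare"),
  gene = c("ALK", "ATRX", "H3F3A", "TP53", "EWSR1", "TP53"),
  kind = c("snv", "deletion", "snv", "snv", "fusion", "snv"),
  protein_change = c("R1275Q", NA, "K28M", "R175H", NA, "R248Q"),
  partner = c(NA, NA, NA, NA, "FLI1", NA),
  prob = c(0.11, 0.38, 0.29, 0.24, 0.22, 0.16)
)

#' Draw a mutation catalog from a signature mixture
#'
#' `multinomial(n, W %*% pi)` on the 96 contexts; reproducible by seed.
#'
#' @param W validated signature matrix
#' @param pi exposure proportions on the simplex (tolerance 1e-9)
#' @param n number of mutations to draw (>= 1)
#' @param seed integer seed
#' @return named length-96 integer count vector
#' @export
generate_mutation_catalog <- function(W, pi, n, seed) {
  validate_signature_matrix(W)
  if (abs(sum(pi) - 1) > 1e-9) abort("pi must lie on the simplex")
  if (any(pi < 0)) abort("pi must be non-negative")
  if (n < 1) abort("n must be >= 1")
  p <- as.numeric(unclass(W) %*% pi)
  withr::with_seed(seed, {
    counts <- as.integer(rmultinom(1, size = n, prob = p))
  })
  setNames(counts, rownames(W) %||% context_bins())
}

# expand a catalog into SNV rows; half the rows are emitted on the purine
# strand so the strand-collapse path is exercised end to end
catalog_to_variants <- function(counts, subject_id, seed) {
  bins <- names(counts)
  total <- sum(counts)
  if (total == 0L) return(empty_variant_df())
  bin_of <- rep(bins, counts)
  withr::with_seed(seed, {
    flip <- runif(total) < 0.5
    pos <- sample.int(1e8, total)
  })
  ref <- substr(bin_of, 3, 3)
  alt <- substr(bin_of, 5, 5)
  ctx <- paste0(substr(bin_of, 1, 1), ref, substr(bin_of, 7, 7))
  ctx[flip] <- reverse_complement(ctx[flip])
  alt[flip] <- unname(REV_COMP[alt[flip]])
  ref[flip] <- unname(REV_COMP[ref[flip]])
  variant_table(tibble(
    subject_id = subject_id, chrom = "chr1", pos = pos, ref = ref, alt = alt,
    variant_class = "SNV", gene = "BACKGROUND", effect = "missense",
    protein_change = NA_character_, trinucleotide_context = ctx
  ))
}

#' Generate a lesion-diameter series for an intended response class
#'
#' Trajectories are constructed to classify as intended under
#' [classify_best_response()]'s documented rules: CR series shrink to zero,
#' PR series reach a best change of at least -30%, SD series stay strictly
#' inside the (-30%, +20%) band without ever tripping the nadir-referenced
#' progression rule, PD series grow at least 20% and 5 mm above the nadir,
#' and NED series carry the post-surgical no-measurable-disease flag.
#'
#' @param intended_class one of `"CR"`, `"PR"`, `"SD"`, `"PD"`, `"NED"`
#' @param seed integer seed
#' @param subject_id identifier for the emitted rows
#' @return lesion tibble (`subject_id`, `timepoint`, `sum_mm`, `ned_flag`)
#' @export
generate_lesion_series <- function(intended_class, seed, subject_id = "S1") {
  if (!intended_class %in% RESPONSE_CLASSES) {
    abort(sprintf("unknown response class '%s'", intended_class))
  }
  withr::with_seed(seed, {
    if (intended_class == "NED") {
      return(tibble(subject_id = subject_id, timepoint = c(0L, 1L),
                    sum_mm = c(0, 0), ned_flag = TRUE))
    }
    baseline <- runif(1, 40, 150)
    sums <- switch(intended_class,
      CR = c(baseline * runif(1, 0.3, 0.6), 0),
      PR = baseline * (1 + runif(1, -0.9, -0.3)),
      SD = rep(baseline * (1 + runif(1, -0.299, 0.199)), 2),
      PD = baseline * (1 + runif(1, 0.25, 0.8))
    )
    tibble(
      subject_id = subject_id,
      timepoint = seq(0L, length(sums)),
      sum_mm = round(c(baseline, sums), 1),
      ned_flag = FALSE
    )
  })
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Produces a fully populated, validated [cohort_bundle()] — normal-tissue
#' reference, per-subject tumor expression with planted outlier spikes,
#' background SNVs drawn from signature mixtures plus tumor-type driver
#' events, copy-number segments realising planted arm-level events, fusions,
#' a drug-rule knowledge base aligned with the planted biology, lesion
#' series and milestone tables — together with the ground truth each
#' pipeline stage should recover. Deterministic for a fixed config.
#'
#' @param config `simulation_config`
#' @return list with `bundle` (`cohort_bundle`), `truth` (per-subject ground
#'   truth), `signatures` (the synthetic W), `normal_matrix` (the reference
#'   expression matrix)
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  panel <- genes[seq_len(config$n_panel)]
  types <- rep(names(config$n_subjects), config$n_subjects)
  n_total <- length(types)
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n_total)),
    tumor_type = types
  )
  arm_geo <- synthetic_arm_map()
  W <- synthetic_signature_matrix(config$n_signatures, seed = sample.int(2^31 - 1, 1))

  # gene-level location/scale of the normal panel (log2 scale, lognormal-like)
  gene_mu <- runif(config$n_genes, 3, 10)
  gene_sd <- runif(config$n_genes, 0.3, 0.8)
  normal_matrix <- matrix(
    rnorm(config$n_genes * config$n_tissues, gene_mu, gene_sd),
    nrow = config$n_genes,
    dimnames = list(genes, sprintf("tissue%02d", seq_len(config$n_tissues)))
  )
  normal_matrix <- expression_matrix(normal_matrix, scale = "normalized_log")

  # per-type Dirichlet(alpha) over signatures: each type favours one signature
  dirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), alpha, 1)
    g / sum(g)
  }
  type_alpha <- list(
    neuroblastoma = c(6, rep(1, config$n_signatures - 1)),
    CNS = c(1, 6, rep(1, config$n_signatures - 2)),
    rare = c(1, 1, 6, rep(1, config$n_signatures - 3))
  )

  arm_spec_all <- arm_event_spec()
  driver_all <- driver_spec()
  rules <- synthetic_rule_set(panel)
  inference_map <- tibble(
    gene = "NF1", target_gene = "MAP2K1",
    evidence = "loss of NF1 activates MEK signalling"
  )
  blacklist <- tibble(drug_a = "drug_over_1", drug_b = "drug_over_2")

  expr_list <- list(); truth <- list()
  variants <- list(); segments <- list(); fusions <- list(); cnv_genes <- list()
  lesions <- list(); milestones <- list()

  for (i in seq_len(n_total)) {
    sid <- subjects$subject_id[i]
    ttype <- subjects$tumor_type[i]

    # --- expression with spikes -------------------------------------------
    x <- rnorm(config$n_genes, gene_mu, gene_sd)
    names(x) <- genes
    spikable <- sample(panel, config$n_over + config$n_under)
    over_genes <- head(spikable, config$n_over)
    under_genes <- utils::tail(spikable, config$n_under)
    # spiked genes are pinned at k true SDs from the normal mean, so the only
    # noise in their recovered z is the 22-sample reference estimation
    io <- match(over_genes, genes); iu <- match(under_genes, genes)
    x[over_genes] <- gene_mu[io] + config$spike_sd * gene_sd[io]
    x[under_genes] <- gene_mu[iu] - config$spike_sd * gene_sd[iu]
    expr_list[[sid]] <- x

    # --- mutation catalog from the type's signature mixture ---------------
    pi_true <- dirichlet(type_alpha[[ttype]])
    n_mut <- max(5L, stats::rpois(1, config$mutations_per_subject[[ttype]]))
    cat_seed <- sample.int(2^31 - 1, 1)
    catalog <- generate_mutation_catalog(W, pi_true, n_mut, seed = cat_seed)
    subj_vars <- catalog_to_variants(catalog, sid, seed = sample.int(2^31 - 1, 1))

    # --- driver events ----------------------------------------------------
    drivers <- driver_all[driver_all$tumor_type == ttype, ]
    hit <- drivers[runif(nrow(drivers)) < drivers$prob, ]
    expected_drugs <- character()
    if (nrow(hit)) {
      snv_hits <- hit[hit$kind == "snv", ]
      if (nrow(snv_hits)) {
        subj_vars <- dplyr::bind_rows(subj_vars, variant_table(tibble(
          subject_id = sid, chrom = "chr2", pos = 29443695L + seq_len(nrow(snv_hits)),
          ref = "T", alt = "C", variant_class = "SNV", gene = snv_hits$gene,
          effect = "missense", protein_change = snv_hits$protein_change,
          trinucleotide_context = "ATA"
        )))
      }
      del_hits <- hit[hit$kind == "deletion", ]
      if (nrow(del_hits)) {
        subj_vars <- dplyr::bind_rows(subj_vars, variant_table(tibble(
          subject_id = sid, chrom = "chrX", pos = 76760000L + seq_len(nrow(del_hits)),
          ref = "TAC", alt = "T", variant_class = "deletion", gene = del_hits$gene,
          effect = "frameshift", protein_change = NA_character_,
          trinucleotide_context = NA_character_
        )))
      }
      fus_hits <- hit[hit$kind == "fusion", ]
      if (nrow(fus_hits)) {
        fusions[[sid]] <- fusion_table(tibble(
          subject_id = sid, gene_5p = fus_hits$gene, gene_3p = fus_hits$partner,
          label = paste(fus_hits$gene, fus_hits$partner, sep = "_")
        ))
      }
      direct_genes <- unique(c(hit$gene, hit$partner[!is.na(hit$partner)]))
      expected_drugs <- c(expected_drugs, rules$drug[
        rules$tier == "direct" & rules$mode == "sensitivity" & rules$gene %in% direct_genes
      ])
    }
    variants[[sid]] <- subj_vars

    # --- planted arm events as qualifying segments ------------------------
    spec <- arm_spec_all[arm_spec_all$tumor_type == ttype, ]
    planted <- spec[runif(nrow(spec)) < spec$prob, ]
    if (nrow(planted)) {
      seg_rows <- purrr::pmap(planted, function(tumor_type, arm_id, direction, prob) {
        arm <- arm_geo[arm_geo$arm_id == arm_id, ]
        frac <- runif(1, 0.6, 0.95)
        len <- round((arm$end - arm$start + 1) * frac)
        tibble(
          subject_id = sid, chrom = arm$chrom,
          start = arm$start, end = arm$start + len - 1,
          log2_ratio = if (direction == "gain") runif(1, 0.55, 1.2) else -runif(1, 0.55, 1.2),
          n_genes = sample(60:400, 1)
        )
      })
      segments[[sid]] <- segment_table(dplyr::bind_rows(seg_rows))
    }

    # expression-rule drugs expected to match (tier 3, sensitivity)
    expected_drugs <- c(
      expected_drugs,
      rules$drug[rules$tier == "expression" & rules$mode == "sensitivity" &
                   ((rules$direction == "over" & rules$gene %in% over_genes) |
                      (rules$direction == "under" & rules$gene %in% under_genes))]
    )

    # --- outcome and feasibility tables -----------------------------------
    intended <- sample(names(config$response_probs), 1, prob = config$response_probs)
    lesions[[sid]] <- generate_lesion_series(intended, seed = sample.int(2^31 - 1, 1),
                                             subject_id = sid)
    seq_days <- max(2, round(rnorm(1, 10, 3)))
    rep_days <- seq_days + max(2, round(rnorm(1, 7, 2)))
    dec_days <- rep_days + max(1, round(rnorm(1, 6, 2)))
    start_gap <- switch(ttype, neuroblastoma = 9, CNS = 24, rare = 13)
    start_days <- dec_days + max(3, round(rnorm(1, start_gap, 4)))
    end_days <- start_days + max(28, round(stats::rlnorm(1, log(120), 0.7)))
    milestones[[sid]] <- tibble(
      subject_id = sid,
      milestone = MILESTONE_LEVELS,
      days = c(seq_days, rep_days, dec_days, start_days, end_days)
    )

    truth[[sid]] <- list(
      tumor_type = ttype,
      spiked_over = over_genes, spiked_under = under_genes,
      pi_true = setNames(pi_true, colnames(W)),
      n_mutations = n_mut,
      planted_arms = planted[c("arm_id", "direction")],
      intended_class = intended,
      expected_drugs = sort(unique(expected_drugs))
    )
  }

  expression <- if (n_total) {
    expression_matrix(do.call(cbind, expr_list), scale = "normalized_log")
  } else {
    NULL
  }
  normal_ref <- build_normal_reference(normal_matrix)
  bundle <- cohort_bundle(
    subjects = subjects,
    variants = if (length(variants)) dplyr::bind_rows(variants) else empty_variant_df(),
    segments = if (length(segments)) dplyr::bind_rows(segments) else NULL,
    fusions = if (length(fusions)) dplyr::bind_rows(fusions) else NULL,
    expression = expression,
    normal_reference = normal_ref,
    arm_map = arm_geo,
    rules = rules,
    inference_map = inference_map,
    blacklist = blacklist,
    lesions = if (length(lesions)) dplyr::bind_rows(lesions) else NULL,
    milestones = if (length(milestones)) dplyr::bind_rows(milestones) else NULL
  )
  first_cycle <- if (n_total) {
    sample(names(config$cycle_probs), n_total, replace = TRUE, prob = config$cycle_probs)
  } else {
    character()
  }
  list(
    bundle = bundle, truth = truth, signatures = W,
    normal_matrix = normal_matrix, first_cycle = first_cycle
  )
}

# expression rules over the targetable panel plus direct rules on the driver
# genes; a sprinkling of resistance rules exercises the veto path
synthetic_rule_set <- function(panel) {
  over_genes <- panel[seq_len(min(20, length(panel)))]
  under_genes <- panel[seq(min(21, length(panel)), min(30, length(panel)))]
  drug_rule_set(dplyr::bind_rows(
    tibble(
      drug = paste0("drug_over_", seq_along(over_genes)), gene = over_genes,
      tier = "expression", direction = "over", mode = "sensitivity",
      evidence = paste0("overexpression of ", over_genes, " sensitises")
    ),
    tibble(
      drug = paste0("drug_under_", seq_along(under_genes)), gene = under_genes,
      tier = "expression", direction = "under", mode = "sensitivity",
      evidence = paste0("underexpression of ", under_genes, " sensitises")
    ),
    tibble(
      drug = "drug_res_1", gene = panel[1], tier = "expression",
      direction = "under", mode = "resistance",
      evidence = paste0("low ", panel[1], " predicts resistance")
    ),
    tibble(
      drug = c("crizotinib", "lapatinib", "YK-4-279"),
      gene = c("ALK", "ERBB4", "FLI1"),
      tier = "direct", direction = "any", mode = "sensitivity",
      evidence = c(
        "ALK inhibition in ALK-mutant neuroblastoma",
        "ERBB4 activating mutations respond to lapatinib",
        "ETS-fusion inhibition"
      )
    ),
    tibble(
      drug = "trametinib", gene = "MAP2K1", tier = "inferred", direction = "any",
      mode = "sensitivity", evidence = "MEK inhibition downstream of RAS-pathway activation"
    )
  ))
}
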