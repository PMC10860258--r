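# shared fixtures built in code

make_variants <- function(n = 10, subject = "S1", seed = 1) {
  withr::with_seed(seed, {
    cls <- sample(c("SNV", "insertion", "deletion"), n, replace = TRUE)
    ref <- ifelse(cls == "SNV", sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  ifelse(cls == "deletion", "TAC", "T"))
    alt <- ifelse(cls == "SNV", "G", ifelse(cls == "deletion", "T", "TGG"))
    alt[cls == "SNV" & ref == "G"] <- "A"
    variant_table(tibble::tibble(
      subject_id = subject,
      chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
      pos = sample.int(1e7, n),
      ref = ref, alt = alt, variant_class = cls,
      gene = sample(c("ALK", "TP53", "NF1", "MYCN", "EWSR1"), n, replace = TRUE),
      effect = "missense",
      protein_change = ifelse(runif(n) < 0.5, "R100Q", NA_character_),
      trinucleotide_context = NA_character_
    ))
  })
}

toy_arm_map <- function() {
  arm_map(tibble::tibble(
    arm_id = c("17p", "17q", "11q"),
    chrom = c("chr17", "chr17", "chr11"),
    start = c(1, 24e6 + 1, 54e6 + 1),
    end = c(24e6, 83e6, 135e6)
  ))
}

toy_rules <- function() {
  drug_rule_set(tibble::tibble(
    drug = c("crizotinib", "topotecan", "vorinostat", "drugY", "trametinib", "YK-4-279"),
    gene = c("ALK", "TOP2A", "HDAC2", "geneB", "MAP2K1", "FLI1"),
    tier = c("direct", "expression", "expression", "expression", "direct", "direct"),
    direction = c("any", "over", "over", "over", "any", "any"),
    mode = c("sensitivity", "sensitivity", "sensitivity", "resistance", "sensitivity", "sensitivity"),
    evidence = "fixture"
  ))
}

# random candidate/blacklist configurations for plan property tests
random_match_config <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(3:12, 1)
    drugs <- paste0("d", sample.int(15, n, replace = TRUE))
    cands <- tibble::tibble(
      drug = drugs,
      tier = sample(1:3, n, replace = TRUE),
      gene = paste0("g", seq_len(n)),
      event = "ev",
      mode = sample(c("sensitivity", "resistance"), n, replace = TRUE, prob = c(0.8, 0.2)),
      score = round(runif(n, 0, 5), 2),
      evidence = "x"
    )
    all_drugs <- unique(drugs)
    bl <- NULL
    if (length(all_drugs) >= 2 && runif(1) < 0.7) {
      k <- sample.int(3, 1)
      pairs <- t(replicate(k, sample(all_drugs, 2)))
      bl <- tibble::tibble(drug_a = pairs[, 1], drug_b = pairs[, 2])
    }
    list(candidates = cands, blacklist = bl)
  })
}

# exact NNLS oracle by enumerating active supports (small S only):
# the optimum restricted to each support is the unconstrained LS solution;
# the global optimum is the best support whose solution is feasible.
nnls_oracle <- function(W, m) {
  S <- ncol(W)
  best <- list(obj = sum(m^2), x = rep(0, S))  # empty support
  for (mask in 1:(2^S - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(0:(S - 1))))
    Wk <- W[, on, drop = FALSE]
    x <- tryCatch(solve(crossprod(Wk), crossprod(Wk, m)), error = function(e) NULL)
    if (is.null(x) || any(x < -1e-12)) next
    obj <- sum((Wk %*% x - m)^2)
    if (obj < best$obj) {
      full <- rep(0, S)
      full[on] <- pmax(x, 0)
      best <- list(obj = obj, x = full)
    }
  }
  best
}
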