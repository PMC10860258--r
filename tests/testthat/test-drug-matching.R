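rules <- toy_rules()

alk_variant <- variant_table(tibble::tibble(
  subject_id = "S1", chrom = "chr2", pos = 29443695L, ref = "T", alt = "C",
  variant_class = "SNV", gene = "ALK", effect = "missense",
  protein_change = "R1275Q"
))

test_that("tier-1 matches direct rules, including fusion partners", {
  ev <- somatic_events(variants = alk_variant)
  c1 <- match_tier1(ev, rules)
  expect_equal(c1$drug, "crizotinib")
  expect_equal(c1$tier, 1L)
  expect_match(c1$event, "R1275Q")

  # a variant in a gene with no rule yields nothing
  other <- alk_variant; other$gene <- "NORULE"
  expect_equal(nrow(match_tier1(somatic_events(variants = other), rules)), 0L)

  # an EWSR1_FLI1 fusion matches a rule on its 3' partner
  fus <- fusion_table(tibble::tibble(
    subject_id = "S1", gene_5p = "EWSR1", gene_3p = "FLI1", label = "EWSR1_FLI1"
  ))
  cf <- match_tier1(somatic_events(fusions = fus), rules)
  expect_equal(cf$drug, "YK-4-279")
  expect_equal(cf$gene, "FLI1")
})

test_that("tier-2 inference is strictly single-hop", {
  nf1_loss <- variant_table(tibble::tibble(
    subject_id = "S1", chrom = "chr17", pos = 100L, ref = "TAC", alt = "T",
    variant_class = "deletion", gene = "NF1", effect = "frameshift"
  ))
  ev <- somatic_events(variants = nf1_loss)
  map1 <- tibble::tibble(gene = "NF1", target_gene = "MAP2K1", evidence = "e")
  c2 <- match_tier2(ev, rules, map1)
  expect_equal(c2$drug, "trametinib")
  expect_equal(c2$tier, 2L)
  expect_equal(c2$gene, "NF1")  # the altered gene is reported

  expect_equal(nrow(match_tier2(ev, rules, map1[0, ])), 0L)

  # two-hop chain NF1 -> H -> MAP2K1 yields nothing: no chaining
  map2 <- tibble::tibble(
    gene = c("NF1", "H"), target_gene = c("H", "MAP2K1"), evidence = "e"
  )
  expect_equal(nrow(match_tier2(ev, rules, map2)), 0L)
})

test_that("tier-3 matches outlier flags to expression-rule directions", {
  nrz <- structure(
    tibble::tibble(
      subject_id = "S1",
      gene = c("TOP2A", "HDAC2", "geneB"),
      x = c(9, 6, 8), z = c(3.1, 1.5, 4.0),
      flag = c("over", "neutral", "over")
    ),
    class = c("nrz_scores", "tbl_df", "tbl", "data.frame"), tau = 2
  )
  c3 <- match_tier3(nrz, rules, tau = 2)
  expect_setequal(c3$drug, c("topotecan", "drugY"))
  top <- c3[c3$drug == "topotecan", ]
  expect_equal(top$mode, "sensitivity")
  expect_equal(top$score, 3.1)
  # HDAC2 at z = 1.5 is below tau: no vorinostat candidate
  expect_false("vorinostat" %in% c3$drug)
  # drugY matched in resistance mode: vetoed at assembly
  plan <- assemble_combination(c3)
  expect_false("drugY" %in% plan$drugs$drug)
  expect_true("drugY" %in% plan$excluded$drug[plan$excluded$reason == "resistance_veto"])
})

cand <- function(drug, tier, score, mode = "sensitivity") {
  tibble::tibble(drug = drug, tier = tier, gene = paste0("g_", drug),
                 event = "ev", mode = mode, score = score, evidence = "x")
}

test_that("greedy assembly follows the documented ranked-cycle trace", {
  # two non-conflicting candidates: plan of exactly 2
  p2 <- assemble_combination(dplyr::bind_rows(cand("a", 1, 3), cand("b", 3, 1)))
  expect_equal(p2$drugs$drug, c("a", "b"))

  # five candidates ranked 1..5 where #2 and #3 conflict: plan = {1,2,4,5}
  cands <- dplyr::bind_rows(
    cand("c1", 1, 5), cand("c2", 1, 4), cand("c3", 1, 3),
    cand("c4", 2, 5), cand("c5", 3, 5)
  )
  bl <- tibble::tibble(drug_a = "c2", drug_b = "c3")
  p <- assemble_combination(cands, blacklist = bl)
  expect_equal(p$drugs$drug, c("c1", "c2", "c4", "c5"))
  expect_true("c3" %in% p$excluded$drug[p$excluded$reason == "interaction_conflict"])

  # all candidates vetoed: explicit no-plan error
  expect_error(
    assemble_combination(cand("a", 1, 3, mode = "resistance")),
    class = "mtbkit_no_plan"
  )

  # a fully supported, conflict-free priority regimen seeds the plan
  pr <- assemble_combination(cands, blacklist = bl,
                             priority_regimens = list(c("c5", "c4")))
  expect_equal(pr$drugs$drug[1:2], c("c5", "c4"))
  expect_equal(pr$priority_regimen_used, "c5+c4")
})

test_that("tier dominance holds at equal scores", {
  withr::with_seed(31, {
    for (i in 1:50) {
      tiers <- sample(1:3, 6, replace = TRUE)
      cands <- dplyr::bind_rows(lapply(seq_along(tiers), function(j) {
        cand(paste0("d", j), tiers[j], score = 2)
      }))
      p <- assemble_combination(cands, max_drugs = 3)
      chosen_tiers <- p$drugs$tier
      left_out <- setdiff(cands$drug, p$drugs$drug)
      if (length(left_out)) {
        expect_lte(max(chosen_tiers), min(cands$tier[cands$drug %in% left_out]))
      }
      expect_true(all(diff(chosen_tiers) >= 0))
    }
  })
})

test_that("plan invariants hold over 1,000 random configurations", {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  n_plans <- 0
  for (s in 1:1000) {
    cfg <- random_match_config(s)
    p <- tryCatch(
      assemble_combination(cfg$candidates, blacklist = cfg$blacklist),
      mtbkit_no_plan = function(e) NULL
    )
    if (is.null(p)) next
    n_plans <- n_plans + 1
    drugs <- p$drugs$drug
    expect_gte(length(drugs), 1)
    expect_lte(length(drugs), 4)
    expect_false(any(duplicated(drugs)))
    # no vetoed drug in the plan
    vetoed <- unique(cfg$candidates$drug[cfg$candidates$mode == "resistance"])
    expect_length(intersect(drugs, vetoed), 0)
    # no blacklisted pair in the plan
    if (!is.null(cfg$blacklist) && length(drugs) > 1) {
      pairs <- utils::combn(drugs, 2)
      expect_false(any(key(pairs[1, ], pairs[2, ]) %in%
                         key(cfg$blacklist$drug_a, cfg$blacklist$drug_b)))
    }
  }
  expect_gt(n_plans, 500)  # most random configurations admit a plan
})

test_that("enlarging the blacklist never increases plan size", {
  withr::with_seed(55, {
    for (i in 1:30) {
      cfg <- random_match_config(2000 + i)
      small <- cfg$blacklist
      extra <- tibble::tibble(
        drug_a = sample(cfg$candidates$drug, 2),
        drug_b = sample(cfg$candidates$drug, 2)
      )
      big <- dplyr::bind_rows(small, extra)
      size <- function(bl) {
        p <- tryCatch(assemble_combination(cfg$candidates, blacklist = bl),
                      mtbkit_no_plan = function(e) NULL)
        if (is.null(p)) 0L else nrow(p$drugs)
      }
      expect_lte(size(big), size(small))
    }
  })
})

test_that("reports are deterministic and schema-valid", {
  p <- assemble_combination(dplyr::bind_rows(cand("a", 1, 3), cand("b", 3, 1)))
  r1 <- generate_report(p, "S1", parameters = list(tau = 2), seed = 7)
  r2 <- generate_report(p, "S1", parameters = list(tau = 2), seed = 7)
  expect_identical(r1$json, r2$json)  # byte-identical
  expect_true(validate_report(r1$json))
  expect_match(r1$markdown, "Drug prediction report")

  # empty veto list: exclusion section empty
  obj <- jsonlite::fromJSON(r1$json, simplifyVector = FALSE)
  expect_length(obj$excluded, 0)

  # reports for random synthetic subjects validate against the schema
  sim <- generate_cohort(simulation_config(
    seed = 3, n_subjects = c(neuroblastoma = 4, CNS = 3, rare = 3), n_genes = 200
  ))
  for (sid in sample(sim$bundle$subjects$subject_id, 10)) {
    run <- run_subject(sim$bundle, sid, seed = 3)
    if (run$status == "ok") expect_true(validate_report(run$report$json))
  }
})
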