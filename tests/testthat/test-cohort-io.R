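vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=2,length=243199373>",
  '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
  '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Consequence">',
  '##INFO=<ID=CONTEXT,Number=1,Type=String,Description="Trinucleotide context">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
)

test_that("VCF reading handles empty bodies and annotated records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_header, f)
  expect_equal(nrow(read_variants(f, subject_id = "S1")), 0L)

  writeLines(c(
    vcf_header,
    "2\t29443695\t.\tT\tC\t.\tPASS\tGENE=ALK;EFFECT=missense;CONTEXT=ATA"
  ), f)
  v <- read_variants(f, subject_id = "S1")
  expect_equal(nrow(v), 1L)
  expect_equal(v$variant_class, "SNV")
  expect_equal(v$gene, "ALK")
  expect_equal(v$pos, 29443695L)
  expect_equal(substr(v$trinucleotide_context, 2, 2), v$ref)

  # multi-allelic records split into one row per ALT
  writeLines(c(
    vcf_header,
    "2\t100\t.\tT\tC,G\t.\tPASS\tGENE=ALK;EFFECT=missense"
  ), f)
  v <- read_variants(f, subject_id = "S1")
  expect_equal(v$alt, c("C", "G"))
})

test_that("variant TSV writer round-trips field-for-field", {
  v <- make_variants(10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variants(v, f)
  back <- read_variants(f)
  expect_equal(as.data.frame(back), as.data.frame(v))
})

test_that("variant invariants are enforced", {
  bad <- tibble::tibble(
    subject_id = "S1", chrom = "chr1", pos = 0L, ref = "A", alt = "G",
    variant_class = "SNV", gene = "X", effect = "missense"
  )
  expect_error(variant_table(bad), "pos")
  bad$pos <- 5L; bad$ref <- "AA"
  expect_error(variant_table(bad), "SNV")
  bad$ref <- "A"; bad$trinucleotide_context <- "GGA"  # centre is not ref
  expect_error(variant_table(bad), "centre")
})

test_that("segment reading normalises coordinates and validates", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines("subject\tchrom\tstart\tend\tlog2_ratio\tn_genes", f)
  expect_equal(nrow(read_segments(f)), 0L)

  writeLines(c(
    "subject\tchrom\tstart\tend\tlog2_ratio\tn_genes",
    "S1\tchr17\t1\t22000000\t0.62\t310"
  ), f)
  s <- read_segments(f)
  expect_equal(s$start, 1L)
  expect_equal(s$end, 22000000L)
  expect_equal(s$log2_ratio, 0.62)
  expect_equal(s$n_genes, 310L)

  # 0-based half-open dialect: start 0 becomes 1, end stays
  writeLines(c(
    "subject\tchrom\tstart\tend\tlog2_ratio\tn_genes",
    "S1\tchr17\t0\t22000000\t0.62\t310"
  ), f)
  s0 <- read_segments(f, dialect = "zero_based_half_open")
  expect_equal(s0$start, 1L)
  expect_equal(s0$end, 22000000L)

  writeLines(c(
    "subject\tchrom\tstart\tend\tlog2_ratio\tn_genes",
    "S1\tchr17\t50\t20\t0.62\t310"
  ), f)
  expect_error(read_segments(f), "start > end")
  writeLines(c(
    "subject\tchrom\tstart\tend\tlog2_ratio\tn_genes",
    "S1\tchr17\t1\t20\tnot_a_number\t310"
  ), f)
  expect_error(read_segments(f), "line 2")
})

test_that("interval dialect conversion is consistent for random intervals", {
  withr::with_seed(42, {
    for (i in 1:50) {
      start1 <- sample.int(1e6, 1)
      len <- sample.int(1e4, 1)
      end1 <- start1 + len - 1L
      # the same interval written in BED convention
      f <- withr::local_tempfile(fileext = ".seg")
      writeLines(c(
        "subject\tchrom\tstart\tend\tlog2_ratio\tn_genes",
        sprintf("S1\tchr1\t%d\t%d\t0.6\t100", start1 - 1L, end1),
        ""
      ), f)
      s <- read_segments(f, dialect = "zero_based_half_open")
      expect_equal(s$start, start1)
      expect_equal(s$end, end1)
      expect_equal(s$end - s$start + 1L, len)
    }
  })
})

test_that("knowledge base reading validates and deduplicates rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("drug\tgene\ttier\tdirection\tmode\tevidence", f)
  expect_equal(nrow(read_knowledge_base(f)), 0L)

  writeLines(c(
    "drug\tgene\ttier\tdirection\tmode\tevidence",
    "lapatinib\tERBB4\texpression\tover\tsensitivity\tcitation A"
  ), f)
  kb <- read_knowledge_base(f)
  expect_equal(nrow(kb), 1L)
  expect_equal(kb$direction, "over")

  # duplicates collapse; both evidence strings retained (group-by oracle)
  writeLines(c(
    "drug\tgene\ttier\tdirection\tmode\tevidence",
    "lapatinib\tERBB4\texpression\tover\tsensitivity\tcitation A",
    "lapatinib\tERBB4\texpression\tover\tsensitivity\tcitation B"
  ), f)
  kb <- read_knowledge_base(f)
  expect_equal(nrow(kb), 1L)
  expect_true(grepl("citation A", kb$evidence) && grepl("citation B", kb$evidence))

  writeLines(c(
    "drug\tgene\ttier\tdirection\tmode\tevidence",
    "x\tG\texpression\tany\tsensitivity\tc"
  ), f)
  expect_error(read_knowledge_base(f), "over|under")
})

test_that("arm maps are built from cytoBand tables (p before, q after the centromere)", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "chr17\t0\t10000000\tp12\tgneg",
    "chr17\t10000000\t24000000\tp11.1\tacen",
    "chr17\t24000000\t50000000\tq11.1\tacen",
    "chr17\t50000000\t83257441\tq25\tgneg"
  ), f)
  arms <- read_arm_map(f)
  expect_equal(arms$arm_id, c("17p", "17q"))
  expect_equal(arms$start[arms$arm_id == "17p"], 1L)   # 0-based converted
  expect_equal(arms$end[arms$arm_id == "17p"], 24000000L)
  expect_equal(arms$start[arms$arm_id == "17q"], 24000001L)

  expect_error(arm_map(tibble::tibble(
    arm_id = c("1p", "1q"), chrom = "chr1", start = c(1, 50), end = c(100, 200)
  )), "overlap")
})

test_that("cohort bundles reject orphan subject references", {
  subjects <- tibble::tibble(subject_id = "S1", tumor_type = "neuroblastoma")
  expect_s3_class(cohort_bundle(subjects), "cohort_bundle")
  expect_error(
    cohort_bundle(subjects, variants = make_variants(3, subject = "S9")),
    "unknown subject"
  )
  expect_error(
    cohort_bundle(tibble::tibble(subject_id = "S1", tumor_type = "lung")),
    "tumor type"
  )
})
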