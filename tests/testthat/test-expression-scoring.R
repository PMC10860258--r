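counts_fixture <- function() {
  m <- matrix(
    c(10, 20, 30,
      100, 200, 300,
      5, 10, 15),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3"))
  )
  expression_matrix(m, scale = "raw_counts")
}

test_that("median-of-ratios normalisation matches the hand computation", {
  m <- counts_fixture()
  norm <- normalize_counts(m)
  # hand oracle: geometric mean per gene, per-sample median of count/ref
  ref <- apply(unclass(m), 1, function(r) exp(mean(log(r))))
  sf_hand <- apply(unclass(m), 2, function(col) median(col / ref))
  expect_equal(unname(attr(norm, "size_factors")), unname(sf_hand))
  expect_equal(unclass(norm)["g2", "s3"], log2(300 / sf_hand[["s3"]] + 1))
  expect_equal(attr(norm, "scale"), "normalized_log")
})

test_that("normalisation degenerate cases behave", {
  # identical samples: all size factors 1, output log2(count + 1)
  m <- expression_matrix(
    matrix(c(4, 8, 4, 8, 4, 8), nrow = 2,
           dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))),
    scale = "raw_counts"
  )
  norm <- normalize_counts(m, pseudocount = 1)
  expect_equal(unname(attr(norm, "size_factors")), rep(1, 3))
  expect_equal(unclass(norm)["g1", "s1"], log2(5))
  # a zero count at size factor 1 and pseudocount 1 maps to 0
  m2 <- expression_matrix(
    matrix(c(0, 8, 0, 8), nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
    scale = "raw_counts"
  )
  expect_equal(unclass(normalize_counts(m2))["g1", "s1"], 0)
  # all-zero sample is named in the error
  m3 <- expression_matrix(
    matrix(c(1, 2, 0, 0), nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "bad"))),
    scale = "raw_counts"
  )
  expect_error(normalize_counts(m3), "bad")
})

test_that("size factors agree with the canonical median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(11, {
    m <- matrix(rpois(50 * 6, lambda = 60), nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  })
  norm <- normalize_counts(expression_matrix(m, scale = "raw_counts"))
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(attr(norm, "size_factors")), unname(sf_ref), tolerance = 1e-8)
})

test_that("normal reference summarises mean and floored SD per gene", {
  m <- expression_matrix(
    matrix(c(4, 6, 5, 5), nrow = 2, byrow = TRUE,
           dimnames = list(c("gA", "gB"), c("t1", "t2"))),
    scale = "normalized_log"
  )
  ref <- build_normal_reference(m, sd_floor = 0.1)
  expect_equal(ref$mu, c(5, 5))
  expect_equal(ref$sigma[1], sqrt(2))    # two-point SD with n-1 denominator
  expect_equal(ref$sigma[2], 0.1)        # zero variance floored
  expect_equal(attr(ref, "n_reference_samples"), 2L)

  # 22 identical columns: every gene at the floor
  m22 <- expression_matrix(
    matrix(rep(c(3, 7), 22), nrow = 2,
           dimnames = list(c("gA", "gB"), paste0("t", 1:22))),
    scale = "normalized_log"
  )
  expect_equal(build_normal_reference(m22)$sigma, c(0.1, 0.1))

  expect_error(build_normal_reference(m22[, 1, drop = FALSE]), "2 samples")
})

test_that("reference moments match a brute-force gene-by-gene recomputation", {
  withr::with_seed(3, {
    m <- matrix(rnorm(100 * 22, 6, 1), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), paste0("t", 1:22)))
  })
  ref <- build_normal_reference(expression_matrix(m, scale = "normalized_log"))
  for (i in c(1, 17, 100)) {
    expect_equal(ref$mu[i], mean(m[i, ]))
    expect_equal(ref$sigma[i], max(sd(m[i, ]), 0.1))
  }
  expect_equal(ref$mu, unname(apply(m, 1, mean)))
  expect_equal(ref$sigma, pmax(unname(apply(m, 1, sd)), 0.1))
})

test_that("NRZ z-scores and flags follow the standardisation exactly", {
  ref <- build_normal_reference(expression_matrix(
    matrix(rnorm(3 * 22, rep(c(5, 8, 2), 22), 1), nrow = 3,
           dimnames = list(c("gA", "gB", "gC"), paste0("t", 1:22))),
    scale = "normalized_log"
  ))
  x <- setNames(c(ref$mu[1], ref$mu[2] + 2 * ref$sigma[2], ref$mu[3] - 2 * ref$sigma[3]),
                c("gA", "gB", "gC"))
  sc <- nrz_score(x, ref, tau = 2)
  expect_equal(sc$z, c(0, 2, -2))
  expect_equal(sc$flag, c("neutral", "over", "under"))  # boundary inclusive

  # random tumor vs brute force (x - mean) / sd per gene
  withr::with_seed(9, {
    m <- matrix(rnorm(50 * 22, 6, 1.5), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), paste0("t", 1:22)))
    tumor <- setNames(rnorm(50, 6, 3), rownames(m))
  })
  ref2 <- build_normal_reference(expression_matrix(m, scale = "normalized_log"))
  sc2 <- nrz_score(tumor, ref2)
  z_brute <- vapply(names(tumor), function(g) {
    (tumor[[g]] - mean(m[g, ])) / max(sd(m[g, ]), 0.1)
  }, numeric(1))
  expect_equal(sc2$z, unname(z_brute[sc2$gene]))

  # unmatched genes reported, not scored; empty intersection errors
  sc3 <- nrz_score(c(tumor, ZZZ = 1), ref2)
  expect_equal(attr(sc3, "unmatched"), "ZZZ")
  expect_error(nrz_score(c(QQQ = 1), ref2), "shared")
})

test_that("NRZ is invariant under joint location and scale changes", {
  withr::with_seed(21, {
    m <- matrix(rnorm(30 * 22, 5, 1), nrow = 30,
                dimnames = list(sprintf("g%02d", 1:30), paste0("t", 1:22)))
    tumor <- setNames(rnorm(30, 5, 2), rownames(m))
  })
  base <- nrz_score(tumor, build_normal_reference(expression_matrix(m, scale = "normalized_log")))
  shifted <- nrz_score(
    tumor + 7,
    build_normal_reference(expression_matrix(m + 7, scale = "normalized_log"))
  )
  expect_equal(shifted$z, base$z)
  scaled <- nrz_score(
    tumor * 3,
    build_normal_reference(expression_matrix(m * 3, scale = "normalized_log"))
  )
  expect_equal(scaled$z, base$z)  # no gene near the sd floor at this scale
})

test_that("CRC percentile is the mid-rank empirical CDF", {
  ref <- expression_matrix(
    matrix(c(1, 2, 3, 4, 5), nrow = 1, dimnames = list("gA", paste0("s", 1:5))),
    scale = "normalized_log"
  )
  expect_equal(crc_score(c(gA = 10), ref)$percentile, 100)
  expect_equal(crc_score(c(gA = 3), ref)$percentile, 50)  # tied median of odd n

  withr::with_seed(5, {
    m <- matrix(rnorm(20 * 30), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:30)))
    tumor <- setNames(rnorm(20), rownames(m))
  })
  got <- crc_score(tumor, expression_matrix(m, scale = "normalized_log"))
  brute <- vapply(got$gene, function(g) {
    100 * (sum(m[g, ] < tumor[[g]]) + 0.5 * sum(m[g, ] == tumor[[g]])) / ncol(m)
  }, numeric(1))
  expect_equal(got$percentile, unname(brute))

  # invariant under a joint strictly monotone transform
  f <- function(x) exp(x / 2)
  got2 <- crc_score(f(tumor), expression_matrix(f(m), scale = "normalized_log"))
  expect_equal(got2$percentile, got$percentile)
})
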