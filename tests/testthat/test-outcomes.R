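series <- function(sums, ned = FALSE, subject = "S1") {
  tibble::tibble(
    subject_id = subject,
    timepoint = seq_along(sums) - 1L,
    sum_mm = sums,
    ned_flag = ned
  )
}

cls_of <- function(sums, ...) classify_best_response(series(sums), ...)$class

test_that("percent change is the baseline-referenced ratio", {
  expect_equal(percent_change(100, 70), -30)
  expect_equal(percent_change(50, 50), 0)
  expect_equal(percent_change(80, 100), 25)
  expect_error(percent_change(0, 10), "positive")
})

test_that("best-response truth table covers every class and boundary", {
  expect_equal(cls_of(c(100, 50, 0)), "CR")       # sum reaches zero
  expect_equal(cls_of(c(100, 70)), "PR")          # exactly -30%: PR, inclusive
  expect_equal(cls_of(c(100, 70), pr_boundary = "exclusive"), "SD")
  expect_equal(cls_of(c(100, 69.9)), "PR")
  expect_equal(cls_of(c(100, 70.1)), "SD")
  expect_equal(cls_of(c(50, 61)), "PD")           # +22% and +11 mm: both conditions
  expect_equal(cls_of(c(50, 60)), "PD")           # exactly +20% and +10 mm: inclusive
  expect_equal(cls_of(c(20, 24)), "SD")           # +20% but only +4 mm: not PD
  expect_equal(cls_of(c(100, 90)), "SD")
  expect_equal(classify_best_response(series(c(0, 0), ned = TRUE))$class, "NED")
})

test_that("progression is nadir-referenced and ordered against response", {
  # PR reached before regrowth over the nadir: best response stays PR
  expect_equal(cls_of(c(100, 60, 80)), "PR")      # 80 >= 1.2*60 and +20mm, but after PR
  # regrowth over the nadir before any response: PD
  expect_equal(cls_of(c(100, 130, 65)), "PD")
  # nadir-referenced: baseline 100 -> 90 -> 110 (+22% of nadir 90, +20mm) is PD
  # even though +10% from baseline sits inside the SD band
  expect_equal(cls_of(c(100, 90, 110)), "PD")
  # best percent change is baseline-referenced regardless of class
  r <- classify_best_response(series(c(100, 130, 65)))
  expect_equal(r$best_percent_change, -35)
  expect_error(classify_best_response(series(100)), "post-baseline")
})

test_that("clinical benefit rate reproduces counting and rounding", {
  labels <- c(rep("NED", 18), rep("CR", 11), rep("PR", 11), rep("SD", 41), rep("PD", 43))
  r <- clinical_benefit_rate(labels)
  expect_equal(r$n_total, 124)
  expect_equal(r$percent, 65)
  expect_equal(clinical_benefit_rate(rep("PD", 10))$percent, 0)

  withr::with_seed(6, {
    for (i in 1:20) {
      v <- sample(c("CR", "PR", "SD", "PD", "NED"), sample(5:60, 1), replace = TRUE)
      brute <- sum(v != "PD") / length(v)
      expect_equal(clinical_benefit_rate(v)$proportion, brute)
    }
  })
  expect_error(clinical_benefit_rate(character()), "no responses")
  expect_error(clinical_benefit_rate(c("CR", "XX")), "unknown")
})

test_that("feasibility summaries recompute per-milestone statistics", {
  one <- tibble::tibble(subject_id = "S1", milestone = "biopsy_to_sequencing", days = 12)
  s <- feasibility_summary(one)
  expect_equal(s$mean_days, 12)
  expect_equal(s$median_days, 12)

  three <- tibble::tibble(
    subject_id = paste0("S", 1:3),
    milestone = "biopsy_to_treatment_start", days = c(31, 48, 35)
  )
  expect_equal(feasibility_summary(three)$mean_days, 38)

  withr::with_seed(14, {
    long <- tidyr::expand_grid(
      subject_id = paste0("S", 1:50),
      milestone = c("biopsy_to_sequencing", "biopsy_to_report", "biopsy_to_decision")
    )
    long$days <- rpois(nrow(long), c(10, 17, 23))
  })
  s3 <- feasibility_summary(long)
  for (m in unique(long$milestone)) {
    d <- long$days[long$milestone == m]
    row <- s3[s3$milestone == m, ]
    expect_equal(row$mean_days, mean(d))
    expect_equal(row$median_days, median(d))
    expect_equal(c(row$min_days, row$max_days), range(d))
  }
  # complete milestones: means non-decreasing in pipeline order
  expect_true(all(diff(s3$mean_days) >= 0))
})

test_that("cycle-start summaries compute per-category and ever-started percents", {
  r <- cycle_start_summary(c(c1 = 121, c2 = 12, c3 = 3, c5 = 1, never = 7), n = 144)
  expect_equal(r$ever_started_percent, 95.14)
  expect_equal(r$by_cycle$percent[r$by_cycle$category == "c1"], 84.03)
  expect_equal(cycle_start_summary(rep("c1", 30))$ever_started_percent, 100)
  expect_error(cycle_start_summary(c(c1 = 10), n = 5), "exceed")

  withr::with_seed(19, {
    for (i in 1:10) {
      v <- sample(c("c1", "c2", "c3", "c5", "never"), sample(10:80, 1), replace = TRUE)
      r <- cycle_start_summary(v)
      expect_equal(r$ever_started_percent,
                   round_half_up(100 * mean(v != "never"), 2))
      expect_equal(sum(r$by_cycle$count), length(v))
    }
  })
})

test_that("waterfall tables sort, sign-classify, and report percent decrease", {
  resp <- tibble::tibble(
    subject_id = paste0("S", 1:73),
    best_percent_change = c(runif(46, -90, -0.1), rep(0, 6), runif(21, 0.1, 80))
  )
  w <- waterfall_table(resp)
  expect_equal(attr(w, "counts"), c(decrease = 46L, no_change = 6L, increase = 21L))
  expect_equal(attr(w, "percent_decrease"), 63.01)
  expect_true(all(diff(w$best_percent_change) <= 0))

  flat <- tibble::tibble(subject_id = c("a", "b"), best_percent_change = c(0, 0))
  wf <- waterfall_table(flat)
  expect_equal(attr(wf, "percent_decrease"), 0)
  expect_equal(unname(attr(wf, "counts")["no_change"]), 2L)

  withr::with_seed(23, {
    for (i in 1:10) {
      x <- round(runif(sample(5:50, 1), -100, 100))
      w <- waterfall_table(tibble::tibble(subject_id = seq_along(x), best_percent_change = x))
      expect_equal(unname(attr(w, "counts")),
                   c(sum(x < 0), sum(x == 0), sum(x > 0)))
    }
  })
})

test_that("benefit rate is permutation-invariant and bounded", {
  withr::with_seed(40, {
    v <- sample(c("CR", "PR", "SD", "PD", "NED"), 40, replace = TRUE)
  })
  a <- clinical_benefit_rate(v)
  b <- clinical_benefit_rate(rev(v))
  expect_equal(a, b)
  expect_gte(a$proportion, 0)
  expect_lte(a$proportion, 1)
})
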