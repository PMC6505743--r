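test_that("median_iqr follows the Tukey-hinge convention", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)),
               c(median = 3, iqr = 2))  # hinges 2 and 4
  expect_equal(median_iqr(7), c(median = 7, iqr = 0))
  expect_equal(median_iqr(rep(4.2, 9))[["iqr"]], 0)
  expect_error(median_iqr(numeric(0)), "non-empty")
  # the linear rule is available and differs where it should
  expect_equal(median_iqr(1:4, "linear"),
               c(median = 2.5, iqr = 1.5))
})

test_that("rank_sum_test reproduces hand-enumerated exact p-values", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_two_sided, 0.1)     # 2 / C(6, 3)
  expect_equal(r$method, "exact")

  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$p_two_sided, 1 / 3)   # 2 / C(4, 2)

  # identical samples: symmetric, Z = 0, p = 1
  r <- rank_sum_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r$z_score, 0)
  expect_equal(r$p_two_sided, 1)

  # fully degenerate input
  r <- rank_sum_test(rep(2, 10), rep(2, 12))
  expect_equal(r$z_score, 0)
  expect_equal(r$p_two_sided, 1)
})

test_that("rank_sum_test matches enumeration and wilcox.test on random data", {
  set.seed(71)
  for (trial in 1:20) {
    x <- sample(1:60, sample(2:6, 1))
    y <- sample(61:120, sample(2:6, 1)) - 60.5  # tie-free vs x
    r <- rank_sum_test(x, y)
    expect_equal(r$p_two_sided, enumerate_rank_sum_p(x, y))
    w <- wilcox.test(x, y, exact = TRUE)
    expect_equal(r$u_statistic, unname(w$statistic))
    expect_equal(r$p_two_sided, w$p.value, tolerance = 1e-12)
  }
  # large-sample normal approximation with ties vs wilcox.test
  for (trial in 1:10) {
    x <- sample(1:15, 30, replace = TRUE)
    y <- sample(4:18, 25, replace = TRUE)
    r <- rank_sum_test(x, y)
    w <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(r$p_two_sided, w$p.value, tolerance = 1e-10)
    expect_true(r$tie_correction_applied)
  }
})

test_that("rank-sum U is complementary and invariant to monotone transforms", {
  set.seed(72)
  for (trial in 1:10) {
    x <- rnorm(12); y <- rnorm(9, 0.5)
    rx <- rank_sum_test(x, y)
    ry <- rank_sum_test(y, x)
    expect_equal(rx$u_statistic + ry$u_statistic, length(x) * length(y))
    f <- function(v) exp(3 * v) + 1  # strictly monotone
    rt <- rank_sum_test(f(x), f(y))
    expect_equal(rt$u_statistic, rx$u_statistic)
    expect_equal(rt$p_two_sided, rx$p_two_sided)
  }
})

test_that("contingency_test chooses and computes the right 2x2 test", {
  r <- contingency_test(10, 10, 10, 10)
  expect_equal(r$method, "pearson_chi_square")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_sided, 1)

  r <- contingency_test(5, 0, 0, 5)
  expect_equal(r$method, "fisher_exact")   # expected cells are 2.5
  expect_equal(r$p_two_sided, 2 / 252)     # hypergeometric enumeration

  # same-proportion groups from the baseline table: p approximately 0.88
  r <- contingency_test(204, 116, 173, 101)
  expect_equal(r$method, "pearson_chi_square")
  expect_equal(round(r$p_two_sided, 2), 0.88)

  expect_error(contingency_test(0, 0, 3, 4), "sums to 0")
  expect_error(contingency_test(1, -1, 3, 4), "non-negative")
})

test_that("contingency_test is invariant under transposition", {
  set.seed(73)
  for (trial in 1:15) {
    k <- sample(0:12, 4, replace = TRUE) + c(1, 0, 0, 1)
    a <- k[1]; b <- k[2]; c <- k[3]; d <- k[4]
    if (any(c(a + b, c + d, a + c, b + d) == 0)) next
    p1 <- contingency_test(a, b, c, d)$p_two_sided
    p2 <- contingency_test(a, c, b, d)$p_two_sided  # transposed table
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("missingness percentages conserve counts", {
  core_vals <- c(HEART_RATE = 80, SYSTOLIC_BP = 120, RESP_RATE = 12,
                 TEMPERATURE = 37, SPO2 = 97, AVPU = 0, URINE_4H = 150)
  full <- make_recordings(minutes = 0:6, elements = names(core_vals),
                          values = unname(core_vals))
  no_rr <- full[full$element != "RESP_RATE", ]
  a <- dplyr::bind_rows(
    build_assessments(full),
    build_assessments(dplyr::mutate(no_rr, patient_id = "p2")),
    build_assessments(dplyr::mutate(no_rr, patient_id = "p3")),
    build_assessments(dplyr::mutate(full, patient_id = "p4")))
  m <- missingness_by_element(a)
  rr <- m[m$element == "RESP_RATE", ]
  expect_equal(rr$percent_missing, 50)
  expect_equal(m$n_missing + (m$n_assessments - m$n_missing),
               rep(nrow(a), nrow(m)))
  expect_equal(m$percent_missing, 100 * m$n_missing / m$n_assessments)
})

test_that("hourly pattern conserves the assessment count", {
  a <- make_assessments(hours = c(8.1, 8.4, 8.9, 23.5), mews = 0)
  h <- hourly_pattern(a)
  expect_equal(sum(h$n), 4L)
  expect_equal(h$n[h$hour == 8], 3L)
  expect_equal(h$n[h$hour == 23], 1L)
})

test_that("percentages round half up at one decimal from integer counts", {
  expect_equal(percent_from_counts(204, 320), 63.8)   # 63.75 rounds up
  expect_equal(percent_from_counts(2237, 8781), 25.5) # 25.475
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(2.24, 1), 2.2)
  expect_equal(round_half_up(-0.5, 0), 0)
})

test_that("compare_arms of an arm against itself is null everywhere", {
  co <- generate_cohort(paper_like_config(n_per_arm = 12, seed = 9))
  a <- build_assessments(co$recordings)
  actl <- a[a$arm == "control", ]
  aint <- dplyr::mutate(actl, arm = "intervention")
  sctl <- co$stays[co$stays$arm == "control", ]
  sint <- dplyr::mutate(sctl, arm = "intervention")
  rep <- compare_arms(actl, aint, sctl, sint)
  # comparisons that are testable on identical arms are null; subgroup
  # comparisons without data (no automated recordings here) report NA
  expect_true(all(rep$adherence_tests$p > 0.99, na.rm = TRUE))
  panel1 <- rep$intervals[rep$intervals$group_a == "control" &
                            rep$intervals$group_b == "intervention", ]
  expect_equal(panel1$median_a, panel1$median_b)
  expect_true(all(rep$outcomes$p_value[!is.na(rep$outcomes$p_value)] > 0.99))
})

test_that("arms simulated with different compliance separate significantly", {
  cfg <- cohort_config(n_control = 60, n_intervention = 60, seed = 404,
                       compliance = c(control = 0.1, intervention = 0.5))
  co <- generate_cohort(cfg)
  a <- build_assessments(co$recordings)
  rep <- compare_arms(a[a$arm == "control", ], a[a$arm == "intervention", ],
                      co$stays[co$stays$arm == "control", ],
                      co$stays[co$stays$arm == "intervention", ])
  s <- rep$adherence_summary
  expect_gt(s$adherence_pct[s$group == "intervention"],
            s$adherence_pct[s$group == "control"])
  adh_test <- rep$adherence_tests[rep$adherence_tests$outcome == "n_adherent" &
    rep$adherence_tests$comparison == "control vs intervention", ]
  expect_lt(adh_test$p, 0.001)
})
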