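test_that("worked sub-scores match the scoring card", {
  tab <- default_scoring_table()
  expect_equal(score_element(tab, "HEART_RATE", 75), 0L)
  expect_equal(score_element(tab, "HEART_RATE", 135), 3L)
  expect_equal(score_element(tab, "SYSTOLIC_BP", 65), 3L)
  expect_equal(score_element(tab, "RESP_RATE", 25), 2L)
  expect_equal(score_element(tab, "SPO2", 88, oxygen_therapy = TRUE), 3L)
  expect_equal(score_element(tab, "SPO2", 88, oxygen_therapy = FALSE), 0L)
  expect_equal(score_element(tab, "URINE_4H", 50), 1L)
  expect_equal(score_element(tab, "URINE_4H", 75), 0L)  # 75 is not "below 75"
})

test_that("the card's asymmetric extremes are implemented literally", {
  tab <- default_scoring_table()
  # heart-rate bands left to right: 2,1,0,1,2,3
  expect_equal(score_element(tab, "HEART_RATE", c(30, 45, 80, 105, 120, 200)),
               c(2L, 1L, 0L, 1L, 2L, 3L))
  # systolic BP above 200 scores 2, not 3
  expect_equal(score_element(tab, "SYSTOLIC_BP", 230), 2L)
  # no temperature sub-score above 1 on the high side
  expect_equal(score_element(tab, "TEMPERATURE", c(39, 41, 45)),
               c(1L, 1L, 1L))
  # respiratory rate below 9 scores 2 (no low-side 3)
  expect_equal(score_element(tab, "RESP_RATE", 4), 2L)
  expect_equal(max_mews_total(tab), 19)
})

test_that("score_element equals the chained-conditional oracle on dense grids", {
  tab <- default_scoring_table()
  grids <- list(
    HEART_RATE = seq(0, 300, length.out = 1001),
    SYSTOLIC_BP = seq(0, 350, length.out = 1001),
    RESP_RATE = seq(0, 80, length.out = 1001),
    TEMPERATURE = round(seq(25, 45, by = 0.1), 1),
    SPO2 = 0:100,
    AVPU = 0:3,
    URINE_4H = seq(0, 400, length.out = 1001),
    WORRIED = 0:1)
  for (el in names(grids)) {
    for (oxy in c(FALSE, TRUE)) {
      got <- score_element(tab, el, grids[[el]], oxy)
      want <- vapply(grids[[el]], function(v) oracle_score(el, v, oxy),
                     numeric(1))
      expect_equal(got, as.integer(want), info = paste(el, "oxygen:", oxy))
    }
  }
})

test_that("banded sub-scores are weakly monotone away from the zero band", {
  tab <- default_scoring_table()
  for (el in c("HEART_RATE", "SYSTOLIC_BP", "RESP_RATE", "TEMPERATURE")) {
    rng <- if (el == "TEMPERATURE") seq(25, 45, by = 0.1) else
      seq(0, 350, by = 1)
    s <- score_element(tab, el, rng)
    zero <- range(rng[s == 0])
    below <- s[rng < zero[1]]
    above <- s[rng > zero[2]]
    # moving further below the zero band never decreases the sub-score
    expect_true(all(diff(below) <= 0), info = el)
    expect_true(all(diff(above) >= 0), info = el)
  }
})

test_that("compute_mews sums present elements and flags completeness", {
  all_zero <- c(HEART_RATE = 80, SYSTOLIC_BP = 120, RESP_RATE = 12,
                TEMPERATURE = 37.0, SPO2 = 98, AVPU = 0, URINE_4H = 200,
                WORRIED = 0)
  r <- compute_mews(all_zero)
  expect_equal(r$total, 0L)
  expect_true(r$complete)

  worst <- c(HEART_RATE = 140, SYSTOLIC_BP = 65, RESP_RATE = 35,
             TEMPERATURE = 34.0, SPO2 = 85, AVPU = 3, URINE_4H = 50,
             WORRIED = 1)
  r <- compute_mews(worst, oxygen_therapy = TRUE)
  oracle_total <- sum(vapply(names(worst),
                             function(el) oracle_score(el, worst[[el]], TRUE),
                             numeric(1)))
  expect_equal(r$total, as.integer(oracle_total))
  expect_equal(r$total, 19L)

  mixed <- c(HEART_RATE = 105, SYSTOLIC_BP = 95, RESP_RATE = 18,
             TEMPERATURE = 37.8, AVPU = 1, URINE_4H = 60, SPO2 = 95,
             WORRIED = 0)
  r <- compute_mews(mixed, oxygen_therapy = FALSE)
  oracle_total <- sum(vapply(names(mixed),
                             function(el) oracle_score(el, mixed[[el]], FALSE),
                             numeric(1)))
  expect_equal(r$total, as.integer(oracle_total))
  expect_equal(r$total, 6L)
  expect_true(r$complete)

  partial <- compute_mews(c(HEART_RATE = 75, SYSTOLIC_BP = 120))
  expect_equal(partial$total, 0L)
  expect_false(partial$complete)

  expect_error(compute_mews(numeric(0)), "at least one element")
})

test_that("removing an element never increases the total", {
  set.seed(202)
  for (i in 1:50) {
    vals <- c(HEART_RATE = runif(1, 0, 300), SYSTOLIC_BP = runif(1, 0, 350),
              RESP_RATE = runif(1, 0, 80), TEMPERATURE = runif(1, 25, 45),
              SPO2 = runif(1, 0, 100), AVPU = sample(0:3, 1),
              URINE_4H = runif(1, 0, 300), WORRIED = sample(0:1, 1))
    full <- compute_mews(vals, oxygen_therapy = TRUE)$total
    drop <- sample(names(vals), 1)
    reduced <- compute_mews(vals[setdiff(names(vals), drop)],
                            oxygen_therapy = TRUE)$total
    expect_lte(reduced, full)
    expect_gte(full, 0)
    expect_lte(full, 19)
  }
})

test_that("a scoring table round-trips through its YAML config form", {
  tab <- default_scoring_table()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scoring_table(tab, path)
  back <- read_scoring_table(path)
  grid <- seq(0, 350, by = 0.5)
  for (el in c("HEART_RATE", "SYSTOLIC_BP", "RESP_RATE")) {
    expect_equal(score_element(back, el, grid), score_element(tab, el, grid))
  }
  expect_equal(score_element(back, "TEMPERATURE", seq(25, 45, 0.1)),
               score_element(tab, "TEMPERATURE", seq(25, 45, 0.1)))
})

test_that("non-finite values and unknown elements are rejected", {
  tab <- default_scoring_table()
  expect_error(score_element(tab, "HEART_RATE", NaN), "non-finite")
  expect_error(score_element(tab, "PULSE", 70))
})
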