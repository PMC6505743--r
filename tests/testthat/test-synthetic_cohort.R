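small_cfg <- function(...) {
  cohort_config(n_control = 8, n_intervention = 8, seed = 2024, ...)
}

test_that("generation is deterministic and patients form prefix substreams", {
  c1 <- generate_cohort(small_cfg())
  c2 <- generate_cohort(small_cfg())
  expect_identical(c1$recordings, c2$recordings)
  expect_identical(c1$stays, c2$stays)
  expect_identical(c1$truth$events, c2$truth$events)

  bigger <- generate_cohort(cohort_config(n_control = 12, n_intervention = 12,
                                          seed = 2024))
  shared <- unique(c1$recordings$patient_id)
  expect_equal(
    as.data.frame(c1$recordings),
    as.data.frame(bigger$recordings[bigger$recordings$patient_id %in% shared, ]))
})

test_that("generated recordings pass the on-disk validation unchanged", {
  co <- generate_cohort(small_cfg())
  path <- withr::local_tempfile(fileext = ".csv")
  write_recordings(co$recordings, path)
  expect_equal(as.data.frame(read_recordings(path)),
               as.data.frame(co$recordings))
  write_stays(co$stays, path)
  expect_equal(nrow(read_stays(path)), nrow(co$stays))
  # automated recordings never occur in the control arm
  expect_false(any(co$recordings$source == "AUTOMATED" &
                     co$recordings$period == "control"))
})

test_that("no missingness and full compliance yield perfection downstream", {
  zero_miss <- default_missingness() * 0
  cfg <- small_cfg(missingness = zero_miss,
                   compliance = c(control = 1, intervention = 1))
  co <- generate_cohort(cfg)
  a <- build_assessments(co$recordings)
  cc <- completeness_counts(a)
  expect_equal(cc[["n_complete"]], cc[["n_total"]])
  expect_equal(adherence_rate(audit_cohort(a)), 1)
})

test_that("the builder reassembles intended events as single assessments", {
  co <- generate_cohort(small_cfg())
  a <- build_assessments(co$recordings)
  intended <- sum(co$truth$events$n_recorded > 0)
  expect_gte(nrow(a) / intended, 0.99)
  expect_lte(nrow(a), intended)
})

test_that("an impossible configuration is rejected", {
  all_miss <- default_missingness() * 0 + 1
  expect_error(cohort_config(missingness = all_miss), "impossible config")
  expect_error(cohort_config(automated_fraction = 1.4), "probabilities")
  expect_error(cohort_config(round_hours = c(7, 25)), "round hours")
})

test_that("the hourly pattern peaks at the configured round hours", {
  cfg <- cohort_config(n_control = 25, n_intervention = 25, seed = 77)
  co <- generate_cohort(cfg)
  a <- build_assessments(co$recordings)
  h <- hourly_pattern(a)
  top3 <- h$hour[order(h$n, decreasing = TRUE)][1:3]
  expect_setequal(top3, c(7, 14, 22))
})

test_that("deterioration episodes raise the true MEWS into every stratum", {
  cfg <- cohort_config(n_control = 30, n_intervention = 2, seed = 31,
                       episode_rate_per_day = 0.6,
                       episode_duration_hours = 8)
  co <- generate_cohort(cfg)
  ev <- co$truth$events
  expect_true(any(ev$severity > 0))
  # episodes force high scores; stable events stay at zero
  expect_true(all(ev$true_mews[ev$severity >= 1] >= 3))
  expect_gte(max(ev$true_mews), 4)
  expect_true(any(ev$true_mews == 0))
})

test_that("inject_episode shifts values deterministically", {
  core_vals <- c(HEART_RATE = 80, SYSTOLIC_BP = 120, RESP_RATE = 12,
                 TEMPERATURE = 37, SPO2 = 97, AVPU = 0, URINE_4H = 150,
                 WORRIED = 0)
  stream <- make_recordings(minutes = 0:7, elements = names(core_vals),
                            values = unname(core_vals))
  t0 <- min(stream$timestamp)

  # severity 0 is the identity
  expect_identical(inject_episode(stream, t0, t0 + 3600, 0), stream)

  # a severe episode drives the recomputed MEWS to 4 or more
  hit <- inject_episode(stream, t0, t0 + 3600, 2)
  a <- build_assessments(hit)
  expect_gte(a$mews_total, 4)
  expect_gt(hit$value[hit$element == "HEART_RATE"],
            stream$value[stream$element == "HEART_RATE"])
  expect_lt(hit$value[hit$element == "SYSTOLIC_BP"],
            stream$value[stream$element == "SYSTOLIC_BP"])

  # an interval outside the stay is rejected
  expect_error(inject_episode(stream, t0 + 86400 * 30, t0 + 86400 * 31, 1),
               "outside the stay")
  expect_error(inject_episode(stream, t0 + 3600, t0, 1), "positive duration")
})

test_that("pipeline estimates recover the configured truth at modest n", {
  # a faster, smaller companion to the full recovery analysis: missingness
  # and automated fraction at 40 patients/arm stay within 3 binomial SEs
  cfg <- cohort_config(n_control = 40, n_intervention = 40, seed = 555)
  co <- generate_cohort(cfg)
  a <- build_assessments(co$recordings)
  for (arm in c("control", "intervention")) {
    aa <- a[a$arm == arm, ]
    m <- missingness_by_element(aa)
    truth <- co$truth$missingness[arm, m$element]
    se <- sqrt(pmax(truth * (1 - truth), 1e-12) / m$n_assessments)
    dev <- abs(m$percent_missing / 100 - truth)
    expect_true(all(dev <= pmax(3 * se, 1e-9)),
                info = paste("missingness recovery,", arm))
  }
  ai <- a[a$arm == "intervention", ]
  af <- mean(ai$source_label == "AUTOMATED")
  expect_lt(abs(af - cfg$automated_fraction),
            3 * sqrt(0.39 * 0.61 / nrow(ai)))
})
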