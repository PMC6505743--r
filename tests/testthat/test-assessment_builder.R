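test_that("the 15-minute rule groups recordings as specified", {
  # 10 minutes apart -> one assessment
  rec <- make_recordings(minutes = c(0, 10),
                         elements = c("HEART_RATE", "SYSTOLIC_BP"),
                         values = c(80, 120))
  expect_equal(nrow(build_assessments(rec)), 1)

  # 20 minutes apart -> two assessments
  rec <- make_recordings(minutes = c(0, 20),
                         elements = c("HEART_RATE", "SYSTOLIC_BP"),
                         values = c(80, 120))
  expect_equal(nrow(build_assessments(rec)), 2)

  # anchored, not rolling: 0, 14, 28 -> {0, 14} and {28}
  rec <- make_recordings(minutes = c(0, 14, 28),
                         elements = c("HEART_RATE", "SYSTOLIC_BP", "RESP_RATE"),
                         values = c(80, 120, 12))
  a <- build_assessments(rec)
  expect_equal(nrow(a), 2)
  expect_equal(a$n_recordings, c(2L, 1L))

  # a recording at exactly anchor + window opens a new assessment
  rec <- make_recordings(minutes = c(0, 15),
                         elements = c("HEART_RATE", "HEART_RATE"),
                         values = c(80, 85))
  expect_equal(nrow(build_assessments(rec)), 2)

  expect_equal(nrow(build_assessments(make_recordings()[0, ])), 0)
})

test_that("a repeated element within the window keeps the latest value", {
  rec <- make_recordings(minutes = c(0, 5, 9),
                         elements = c("HEART_RATE", "HEART_RATE", "SPO2"),
                         values = c(80, 132, 97))
  a <- build_assessments(rec)
  expect_equal(nrow(a), 1)
  expect_equal(a$heart_rate, 132)
  expect_equal(a$n_recordings, 3L)      # superseded rows stay in the partition
  expect_equal(a$n_superseded, 1L)
  expect_equal(a$mews_total, 3L)        # recomputed from the kept value
})

test_that("assessment source is the majority source, ties to AUTOMATED", {
  expect_equal(label_source(rep("CONVENTIONAL", 3)), "CONVENTIONAL")
  expect_equal(label_source(rep("AUTOMATED", 2)), "AUTOMATED")
  expect_equal(label_source(rep(c("AUTOMATED", "CONVENTIONAL"), each = 4)),
               "AUTOMATED")
  rec <- make_recordings(minutes = c(0, 1, 2, 3),
                         elements = c("HEART_RATE", "SPO2", "RESP_RATE",
                                      "TEMPERATURE"),
                         values = c(80, 97, 12, 37),
                         source = c("AUTOMATED", "AUTOMATED",
                                    "CONVENTIONAL", "CONVENTIONAL"),
                         period = "intervention")
  expect_equal(build_assessments(rec)$source_label, "AUTOMATED")
})

test_that("completeness requires the seven core elements, worried optional", {
  core_vals <- c(HEART_RATE = 80, SYSTOLIC_BP = 120, RESP_RATE = 12,
                 TEMPERATURE = 37, SPO2 = 97, AVPU = 0, URINE_4H = 150)
  rec <- make_recordings(minutes = seq_along(core_vals) - 1,
                         elements = names(core_vals),
                         values = unname(core_vals))
  a <- build_assessments(rec)
  expect_true(a$complete)

  rec_norr <- rec[rec$element != "RESP_RATE", ]
  expect_false(build_assessments(rec_norr)$complete)

  four <- dplyr::bind_rows(
    build_assessments(rec), build_assessments(rec),
    build_assessments(rec_norr), build_assessments(rec_norr))
  expect_equal(completeness_counts(four),
               c(n_total = 4L, n_complete = 2L))
})

test_that("windowing invariants hold on randomized fixtures", {
  set.seed(909)
  for (trial in 1:5) {
    rec <- random_recordings(n_patients = 5, n_per_patient = 40)
    a <- build_assessments(rec, window_minutes = 15)

    # partition: every recording in exactly one assessment
    expect_equal(sum(a$n_recordings), nrow(rec))

    # window bound: intra-assessment spread < 15 minutes
    rec_sorted <- dplyr::arrange(rec, patient_id, timestamp)
    gid <- integer(0)
    for (p in split(rec_sorted, rec_sorted$patient_id)) {
      spread <- tapply(as.numeric(p$timestamp),
                       mewsaudit:::assign_window_groups(
                         p$patient_id, p$timestamp, 15 * 60),
                       function(t) diff(range(t)))
      expect_true(all(spread < 15 * 60))
    }

    # order independence: shuffled input gives the identical grouping
    shuffled <- rec[sample.int(nrow(rec)), ]
    expect_equal(as.data.frame(build_assessments(shuffled)),
                 as.data.frame(a))

    # monotonicity: shrinking the window never decreases assessment count
    n_by_window <- vapply(c(30, 15, 8, 3, 1), function(w) {
      nrow(build_assessments(rec, window_minutes = w))
    }, numeric(1))
    expect_true(all(diff(n_by_window) >= 0))

    # determinism
    expect_equal(as.data.frame(build_assessments(rec)), as.data.frame(a))
  }
})
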