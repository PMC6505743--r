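# Independent oracles and small fixture builders shared across tests.

# A naive chained-conditional transliteration of the hospital scoring card,
# written independently of the package's band data structure.
oracle_score <- function(element, value, oxygen = FALSE) {
  if (element == "HEART_RATE") {
    v <- round(value)
    if (v < 40) 2
    else if (v <= 50) 1
    else if (v <= 100) 0
    else if (v <= 110) 1
    else if (v <= 130) 2
    else 3
  } else if (element == "SYSTOLIC_BP") {
    v <- round(value)
    if (v < 70) 3
    else if (v <= 80) 2
    else if (v <= 100) 1
    else if (v <= 200) 0
    else 2
  } else if (element == "RESP_RATE") {
    v <- round(value)
    if (v < 9) 2
    else if (v <= 14) 0
    else if (v <= 20) 1
    else if (v <= 30) 2
    else 3
  } else if (element == "TEMPERATURE") {
    v <- round(value * 10)
    if (v < 351) 2
    else if (v <= 365) 1
    else if (v <= 375) 0
    else 1
  } else if (element == "AVPU") {
    c(0, 1, 2, 3)[round(value) + 1]
  } else if (element == "SPO2") {
    if (value < 90 && oxygen) 3 else 0
  } else if (element == "URINE_4H") {
    if (value < 75) 1 else 0
  } else if (element == "WORRIED") {
    if (round(value) >= 1) 1 else 0
  } else {
    stop("unknown element in oracle")
  }
}

# Two-sided exact Mann-Whitney p by full enumeration of rank assignments.
enumerate_rank_sum_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  subsets <- utils::combn(n, nx)
  us <- apply(subsets, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Long-format recordings fixture: one patient, elements at minute offsets.
make_recordings <- function(patient_id = "p1",
                            minutes = 0,
                            elements = "HEART_RATE",
                            values = 80,
                            oxygen = FALSE,
                            source = "CONVENTIONAL",
                            period = "control",
                            origin = as.POSIXct("2012-03-01 08:00",
                                                tz = "UTC")) {
  n <- max(length(minutes), length(elements), length(values))
  tibble::tibble(
    patient_id = rep_len(patient_id, n),
    timestamp = origin + rep_len(minutes, n) * 60,
    element = rep_len(elements, n),
    value = rep_len(values, n),
    oxygen_therapy = rep_len(oxygen, n),
    source = rep_len(source, n),
    period = rep_len(period, n))
}

# Assessment-table fixture for the auditor (scores and anchor hours given).
make_assessments <- function(patient_id = "p1", hours, mews,
                             arm = "control", source = "CONVENTIONAL",
                             complete = TRUE,
                             origin = as.POSIXct("2012-03-01 00:00",
                                                 tz = "UTC")) {
  tibble::tibble(
    patient_id = rep_len(patient_id, length(hours)),
    arm = rep_len(arm, length(hours)),
    anchor_time = origin + hours * 3600,
    source_label = rep_len(source, length(hours)),
    mews_total = as.integer(mews),
    complete = rep_len(complete, length(hours)))
}

# A random multi-patient recordings fixture for property tests.
random_recordings <- function(n_patients = 6, n_per_patient = 30,
                              spread_minutes = 360) {
  rows <- lapply(seq_len(n_patients), function(i) {
    make_recordings(
      patient_id = sprintf("rp%02d", i),
      minutes = sort(sample.int(spread_minutes, n_per_patient, replace = TRUE)),
      elements = sample(element_kinds(), n_per_patient, replace = TRUE),
      values = 0,
      period = "control")
  })
  out <- dplyr::bind_rows(rows)
  # physiologic values per element so validation-style invariants hold
  base <- c(HEART_RATE = 80, SYSTOLIC_BP = 120, RESP_RATE = 12,
            TEMPERATURE = 37, SPO2 = 97, AVPU = 0, URINE_4H = 150,
            WORRIED = 0)
  out$value <- unname(base[out$element])
  out
}
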