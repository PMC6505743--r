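#' Configure a synthetic two-arm HDU cohort
#'
#' Builds the parameter object for [generate_cohort()]. The defaults emulate
#' the operational structure of the study unit: two arms (control /
#' intervention) of postoperative high-dependency stays; log-normal HDU
#' length of stay (median 7.5 / 7.1 days, IQR width 7.0 / 6.0); three daily
#' nursing rounds (07:00, 14:00, 22:00) with Gaussian jitter; arm-specific
#' per-element missingness (e.g. respiratory rate missing from 96% of
#' control-arm assessments versus 3% under the automated device, level of
#' consciousness 100% versus 3%); a per-follow-up Bernoulli protocol
#' compliance (control 0.011, intervention 0.254 — the study's printed
#' adherence rates); 39% automated-device usage within the intervention arm;
#' and stay-level outcome frequencies taken from the study's outcome table.
#'
#' Baseline vitals are drawn truncated to their zero-score bands; score
#' elevation is produced by deterioration episodes (a Poisson process per
#' patient-day) whose severity shifts every element towards its abnormal
#' bands. Stay outcomes are drawn independently of the vitals process.
#'
#' @param n_control,n_intervention Patients per arm.
#' @param seed Integer seed; every patient gets an independent substream
#'   keyed by `(seed, arm, patient index)`, so cohorts of different sizes
#'   share their common patients.
#' @param hdu_los_median_days,hdu_los_iqr_days Named (`control`,
#'   `intervention`) log-normal stay-length parameters (median and Q3-Q1
#'   width, days).
#' @param round_hours Daily nursing-round hours (in `[0, 24)`).
#' @param round_jitter_sd_min Jitter s.d. of a round's actual time, minutes.
#' @param missingness 2 x 8 matrix (rows `control`, `intervention`; columns
#'   [element_kinds()]) of per-element recording-dropout probabilities.
#' @param compliance Named per-arm probability that a follow-up is scheduled
#'   within the response-protocol window; otherwise it is delayed past the
#'   window by a log-normal overshoot.
#' @param automated_fraction Probability that an intervention-arm assessment
#'   is recorded with the automated device (control is always conventional).
#' @param baselines Per-element baseline distributions, see
#'   `default_vital_baselines()`.
#' @param episode_rate_per_day,episode_duration_hours Deterioration-episode
#'   Poisson rate per patient-day and mean (exponential) duration.
#' @param episode_severity_range Uniform range of the episode severity
#'   multiplier; at severity 1 an episode already drives the true MEWS to 3
#'   or more.
#' @param overshoot_meanlog,overshoot_sdlog Log-normal parameters (hours) of
#'   the delay past the required window for non-compliant follow-ups.
#' @param outcome_probs Named list (`icu_readmission`, `in_hospital_death`,
#'   `death_within_28d`) of per-arm probabilities.
#' @param hospital_extra_los_median_days,hospital_extra_los_iqr_days
#'   Log-normal parameters of the additional (post-HDU) hospital stay.
#' @param age_median,age_iqr,male_fraction,unplanned_fraction,surgery_type_probs
#'   Stay-level covariate distributions per arm.
#' @param severity_scores Named list of (median, IQR) pairs for the opaque
#'   APACHE II / APACHE IV / SAPS II covariates (stored, never derived).
#' @param start_dates Named per-arm calendar start of the accrual window.
#' @param accrual_days Length of the accrual window, days.
#' @return A validated list of class `cohort_config`.
#' @seealso [paper_like_config()], [generate_cohort()]
#' @export
cohort_config <- function(
    n_control = 320, n_intervention = 274, seed = 20130601,
    hdu_los_median_days = c(control = 7.5, intervention = 7.1),
    hdu_los_iqr_days = c(control = 7.0, intervention = 6.0),
    round_hours = c(7, 14, 22), round_jitter_sd_min = 20,
    missingness = default_missingness(),
    compliance = c(control = 0.011, intervention = 0.254),
    automated_fraction = 0.39,
    baselines = default_vital_baselines(),
    episode_rate_per_day = 0.05, episode_duration_hours = 3,
    episode_severity_range = c(1, 2),
    overshoot_meanlog = log(2), overshoot_sdlog = 0.5,
    outcome_probs = list(
      icu_readmission = c(control = 0.134, intervention = 0.106),
      in_hospital_death = c(control = 0.016, intervention = 0.011),
      death_within_28d = c(control = 0.022, intervention = 0.007)),
    hospital_extra_los_median_days = c(control = 4.5, intervention = 4.0),
    hospital_extra_los_iqr_days = c(control = 6, intervention = 5),
    age_median = c(control = 67, intervention = 67),
    age_iqr = c(control = 15, intervention = 16),
    male_fraction = c(control = 0.638, intervention = 0.631),
    unplanned_fraction = c(control = 0.181, intervention = 0.135),
    surgery_type_probs = rbind(
      control = c(abdominal_oncology = 0.697, abdominal_benign = 0.103,
                  vascular_aortic = 0.200),
      intervention = c(abdominal_oncology = 0.803, abdominal_benign = 0.073,
                       vascular_aortic = 0.124)),
    severity_scores = list(apache2 = c(14, 6), apache4 = c(37, 15),
                           saps2 = c(31, 15)),
    start_dates = c(control = "2012-01-01", intervention = "2013-06-01"),
    accrual_days = 450) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @description `default_missingness()` returns the per-arm per-element
#'   dropout matrix. The respiratory-rate (0.96 / 0.03) and AVPU (1.00 /
#'   0.03) entries are the study's printed missingness percentages; the
#'   remaining entries reflect the usual charting pattern on such a unit
#'   (heart rate and blood pressure are the most reliably recorded elements,
#'   urine output and the worried flag the least).
#' @export
default_missingness <- function() {
  m <- rbind(
    control      = c(HEART_RATE = 0.03, SYSTOLIC_BP = 0.03, RESP_RATE = 0.96,
                     TEMPERATURE = 0.25, SPO2 = 0.20, AVPU = 1.00,
                     URINE_4H = 0.60, WORRIED = 0.98),
    intervention = c(HEART_RATE = 0.02, SYSTOLIC_BP = 0.02, RESP_RATE = 0.03,
                     TEMPERATURE = 0.08, SPO2 = 0.02, AVPU = 0.03,
                     URINE_4H = 0.40, WORRIED = 0.60))
  m[, element_kinds()]
}

#' @rdname cohort_config
#' @description `default_vital_baselines()` gives the baseline (stable
#'   patient) distributions: normals truncated to the zero-score band of
#'   each banded element, SpO2 truncated to 92-100%, urine as an offset
#'   log-normal well above the 75 ml threshold, AVPU fixed at alert and the
#'   worried flag at 0. `oxygen_therapy_prob` is the probability a stable
#'   patient is on supplemental oxygen (postoperative practice).
#' @export
default_vital_baselines <- function() {
  list(
    HEART_RATE  = list(mean = 78,   sd = 10,   lo = 51,    hi = 100),
    SYSTOLIC_BP = list(mean = 130,  sd = 15,   lo = 101,   hi = 200),
    RESP_RATE   = list(mean = 11.5, sd = 1.3,  lo = 9,     hi = 14),
    TEMPERATURE = list(mean = 37.0, sd = 0.2,  lo = 36.65, hi = 37.45),
    SPO2        = list(mean = 96.5, sd = 1.8,  lo = 92,    hi = 100),
    URINE_4H    = list(meanlog = log(150), sdlog = 0.5, offset = 90),
    oxygen_therapy_prob = 0.3)
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_control >= 1, cfg$n_intervention >= 1)
  probs <- c(cfg$compliance, cfg$automated_fraction, as.vector(cfg$missingness),
             unlist(cfg$outcome_probs), cfg$male_fraction,
             cfg$unplanned_fraction, as.vector(cfg$surgery_type_probs))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$round_hours < 0 | cfg$round_hours >= 24)) {
    stop("round hours must lie in [0, 24)", call. = FALSE)
  }
  if (!identical(dim(cfg$missingness), c(2L, 8L)) ||
      !setequal(colnames(cfg$missingness), element_kinds())) {
    stop("missingness must be a 2 x 8 matrix over the element kinds",
         call. = FALSE)
  }
  for (arm in arm_labels()) {
    if (all(cfg$missingness[arm, ] >= 1)) {
      stop("impossible config: every element always missing in the ", arm,
           " arm", call. = FALSE)
    }
  }
  stopifnot(cfg$episode_severity_range[1] <= cfg$episode_severity_range[2],
            cfg$episode_rate_per_day >= 0)
  cfg
}

#' Study-calibrated generator configuration
#'
#' The bundled configuration whose parameters are set from the study's
#' printed operational numbers: automated-device fraction 0.39,
#' respiratory-rate missingness 0.96 (control) / 0.03 (intervention), AVPU
#' missingness 1.00 / 0.03, HDU length of stay median 7.5 / 7.1 days, and
#' per-arm protocol compliance equal to the printed adherence rates.
#'
#' @param n_per_arm Patients per arm (the parameter-recovery analyses use
#'   300).
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
paper_like_config <- function(n_per_arm = 300, seed = 20130601) {
  cohort_config(n_control = n_per_arm, n_intervention = n_per_arm,
                seed = seed)
}

# ---- internal draws ----------------------------------------------------

# log-normal parameterized by its median and IQR width:
# sigma = asinh(iqr / (2 * median)) / qnorm(0.75)
rlnorm_med_iqr <- function(n, median, iqr) {
  sigma <- asinh(iqr / (2 * median)) / qnorm(0.75)
  rlnorm(n, log(median), sigma)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

patient_substream_seed <- function(seed, arm, index) {
  arm_code <- if (arm == "control") 1 else 2
  h <- (1103515245 * ((seed %% 65536) + arm_code * 1000003) +
          index * 2654435761 + 12345) %% 2147483647
  as.integer(h)
}

# deterministic abnormal shift applied by a deterioration episode;
# severity 0 is the identity; only elements present in `values` are touched
episode_shift_values <- function(values, severity) {
  s <- severity
  v <- values
  shift <- function(v, el, f) {
    if (el %in% names(v)) v[el] <- f(v[[el]])
    v
  }
  v <- shift(v, "HEART_RATE",  function(x) x + 40 * s)
  v <- shift(v, "SYSTOLIC_BP", function(x) x - 35 * s)
  v <- shift(v, "RESP_RATE",   function(x) x + 9 * s)
  v <- shift(v, "TEMPERATURE", function(x) x + 0.8 * s)
  v <- shift(v, "SPO2",        function(x) x - 7 * s)
  v <- shift(v, "AVPU",        function(x) min(3, x + floor(s + 0.5)))
  v <- shift(v, "URINE_4H",    function(x) x * exp(-1.5 * s))
  if (s >= 1) v <- shift(v, "WORRIED", function(x) 1)
  clamp_to_sanity(v)
}

clamp_to_sanity <- function(v) {
  rng <- element_sanity_ranges()
  for (el in names(v)) {
    v[el] <- min(max(v[el], rng[[el]][1]), rng[[el]][2])
  }
  v
}

# round to the storage precision of each element (integers; 0.1 degC for
# temperature); tolerates partial element vectors
round_to_precision <- function(v) {
  if ("TEMPERATURE" %in% names(v)) {
    v["TEMPERATURE"] <- round(v[["TEMPERATURE"]], 1)
  }
  int <- setdiff(names(v), "TEMPERATURE")
  v[int] <- round(v[int])
  v
}

draw_baseline_values <- function(baselines) {
  c(HEART_RATE = with(baselines$HEART_RATE, rtrunc_norm(1, mean, sd, lo, hi)),
    SYSTOLIC_BP = with(baselines$SYSTOLIC_BP, rtrunc_norm(1, mean, sd, lo, hi)),
    RESP_RATE = with(baselines$RESP_RATE, rtrunc_norm(1, mean, sd, lo, hi)),
    TEMPERATURE = with(baselines$TEMPERATURE, rtrunc_norm(1, mean, sd, lo, hi)),
    SPO2 = with(baselines$SPO2, rtrunc_norm(1, mean, sd, lo, hi)),
    AVPU = 0,
    URINE_4H = with(baselines$URINE_4H, offset + rlnorm(1, meanlog, sdlog)),
    WORRIED = 0)
}

true_mews_total <- function(values, oxygen_therapy, table) {
  sum(vapply(names(values), function(el) {
    score_element(table, el, values[[el]],
                  if (el == "SPO2") oxygen_therapy else FALSE)
  }, integer(1)))
}

# first daily-round time (seconds since epoch) after `threshold`; a round
# configured at hour h takes place during that hour, centred on its midpoint
# with Gaussian jitter
next_round_time <- function(threshold, round_hours, jitter_sd_min) {
  day0 <- floor(threshold / 86400) * 86400
  cands <- as.vector(outer(c(-1, 0, 1, 2) * 86400,
                           round_hours * 3600 + 1800, `+`)) + day0
  base <- min(cands[cands > threshold])
  base + rnorm(1, 0, jitter_sd_min * 60)
}

# ---- generator ---------------------------------------------------------

#' Generate a synthetic two-arm cohort with known ground truth
#'
#' Per patient: an HDU stay; a chain of assessment events in which the next
#' event is, with probability `compliance`, scheduled inside the response
#' window dictated by the patient's current true MEWS (snapped to the next
#' daily nursing round whenever one falls inside the window, which produces
#' the unit's three-peak 24-hour pattern) and otherwise delayed past the
#' window by a log-normal overshoot (then landing at the next round). At
#' each event all eight elements are drawn (baseline truncated to the
#' zero-score bands, shifted during deterioration episodes), time-stamped
#' within a 5-minute span, labelled with a recording source, and each
#' element is then independently dropped with its configured missingness
#' probability — the dropout structure the missingness analysis measures.
#'
#' Generation is deterministic for a fixed config and seed, with per-patient
#' substreams so that cohorts of different sizes share their common
#' patients.
#'
#' @param config A [cohort_config()].
#' @return List of class `mews_cohort`: `stays`, `recordings` (both in the
#'   on-disk schemas), and `truth` — a list with the configured per-arm
#'   missingness / compliance / automated fraction and per-event ground
#'   truth (`events`: pre-missingness element values, true MEWS, response
#'   window, whether the follow-up was scheduled within it, episode
#'   severity) plus the episode table.
#' @export
#' @examples
#' cohort <- generate_cohort(paper_like_config(n_per_arm = 5, seed = 1))
#' nrow(cohort$stays)
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  table <- default_scoring_table()
  arms <- list(control = config$n_control,
               intervention = config$n_intervention)
  stays <- list(); recs <- list(); events <- list(); episodes <- list()
  for (arm in names(arms)) {
    for (i in seq_len(arms[[arm]])) {
      p <- simulate_patient(config, arm, i, table)
      stays[[length(stays) + 1L]] <- p$stay
      recs[[length(recs) + 1L]] <- p$recordings
      events[[length(events) + 1L]] <- p$events
      episodes[[length(episodes) + 1L]] <- p$episodes
    }
  }
  recordings <- dplyr::bind_rows(recs)
  recordings <- dplyr::arrange(recordings, .data$patient_id, .data$timestamp,
                               .data$element)
  structure(
    list(
      stays = dplyr::bind_rows(stays),
      recordings = recordings,
      truth = list(
        missingness = config$missingness,
        compliance = config$compliance,
        automated_fraction = config$automated_fraction,
        events = dplyr::bind_rows(events),
        episodes = dplyr::bind_rows(episodes),
        config = config)),
    class = "mews_cohort")
}

simulate_patient <- function(config, arm, index, table) {
  set.seed(patient_substream_seed(config$seed, arm, index))
  pid <- sprintf("%s_%04d", substr(arm, 1, 3), index)

  # --- stay skeleton ---
  # The nominal stay duration is log-normal; the realized discharge falls
  # shortly after the final assessment (the chain runs until the nominal
  # duration elapses), so no scheduled follow-up is censored by discharge
  # and pipeline adherence is an unbiased estimate of the configured
  # compliance.
  t0 <- as.POSIXct(config$start_dates[[arm]], tz = "UTC")
  admit <- as.numeric(t0) + runif(1, 0, config$accrual_days) * 86400
  nominal_los <- max(0.5, rlnorm_med_iqr(1, config$hdu_los_median_days[[arm]],
                                         config$hdu_los_iqr_days[[arm]]))
  end_time <- admit + nominal_los * 86400

  # --- deterioration episodes ---
  n_ep <- rpois(1, config$episode_rate_per_day * nominal_los)
  ep <- if (n_ep > 0) {
    start <- admit + sort(runif(n_ep, 0, nominal_los * 86400))
    dur <- rexp(n_ep, 1 / config$episode_duration_hours) * 3600
    tibble::tibble(
      patient_id = pid,
      start = start, end = pmin(start + dur, end_time),
      severity = runif(n_ep, config$episode_severity_range[1],
                       config$episode_severity_range[2]))
  } else {
    tibble::tibble(patient_id = character(), start = numeric(),
                   end = numeric(), severity = numeric())
  }
  severity_at <- function(t) {
    hit <- ep$start <= t & t <= ep$end
    if (any(hit)) max(ep$severity[hit]) else 0
  }

  # --- assessment-event chain ---
  compliance <- config$compliance[[arm]]
  min_gap_h <- 0.35     # keeps consecutive events well past the 15-min rule
  margin_h <- 10 / 60   # guards the window boundary against anchor shifts
  ev_time <- c(); ev_sev <- c(); ev_timely <- c(); ev_mews <- c()
  ev_window <- c(); ev_source <- c(); ev_values <- list(); ev_o2 <- c()
  t <- admit + runif(1, 10, 60) * 60
  repeat {
    sev <- severity_at(t)
    vals <- draw_baseline_values(config$baselines)
    o2 <- runif(1) < config$baselines$oxygen_therapy_prob
    if (sev > 0) {
      vals <- episode_shift_values(vals, sev)
      o2 <- TRUE
    }
    vals <- round_to_precision(clamp_to_sanity(vals))
    mews <- true_mews_total(vals, o2, table)
    w <- required_interval_hours(mews)
    is_last <- t >= end_time
    if (is_last) {
      timely <- NA
      next_t <- NA_real_
    } else {
      timely <- runif(1) < compliance
      if (timely) {
        cand <- next_round_time(t + min_gap_h * 3600, config$round_hours,
                                config$round_jitter_sd_min)
        hi <- t + (w - margin_h) * 3600
        next_t <- if (cand > t + min_gap_h * 3600 && cand <= hi) cand else
          t + runif(1, min_gap_h, w - margin_h) * 3600
      } else {
        raw <- t + (w + margin_h) * 3600 +
          rlnorm(1, config$overshoot_meanlog, config$overshoot_sdlog) * 3600
        next_t <- max(raw, next_round_time(raw, config$round_hours,
                                           config$round_jitter_sd_min))
      }
    }
    src <- if (arm == "intervention" && runif(1) < config$automated_fraction)
      "AUTOMATED" else "CONVENTIONAL"
    k <- length(ev_time) + 1L
    ev_time[k] <- t; ev_sev[k] <- sev; ev_timely[k] <- timely
    ev_mews[k] <- mews; ev_window[k] <- w; ev_source[k] <- src
    ev_values[[k]] <- vals; ev_o2[k] <- o2
    if (is_last) break
    t <- next_t
  }

  # --- realized stay and outcomes ---
  discharge <- max(ev_time) + runif(1, 60, 180) * 60
  hdu_los <- (discharge - admit) / 86400
  hosp_los <- hdu_los +
    rlnorm_med_iqr(1, config$hospital_extra_los_median_days[[arm]],
                   config$hospital_extra_los_iqr_days[[arm]])
  age <- round(min(95, max(18, rnorm(1, config$age_median[[arm]],
                                     config$age_iqr[[arm]] / 1.349))))
  sev_draw <- function(par) max(0, round(rnorm(1, par[1], par[2] / 1.349)))
  stay <- tibble::tibble(
    patient_id = pid, arm = arm,
    hdu_admit = floor_minute(as.POSIXct(admit, origin = "1970-01-01",
                                        tz = "UTC")),
    hdu_discharge = floor_minute(as.POSIXct(discharge, origin = "1970-01-01",
                                            tz = "UTC")),
    age_years = age,
    sex = if (runif(1) < config$male_fraction[[arm]]) "male" else "female",
    surgery_type = sample(surgery_types(), 1,
                          prob = config$surgery_type_probs[arm, ]),
    unplanned_surgery = runif(1) < config$unplanned_fraction[[arm]],
    icu_readmitted = runif(1) < config$outcome_probs$icu_readmission[[arm]],
    in_hospital_death = runif(1) < config$outcome_probs$in_hospital_death[[arm]],
    death_within_28d = runif(1) < config$outcome_probs$death_within_28d[[arm]],
    hospital_los_days = round(hosp_los, 1),
    hdu_los_days = round(hdu_los, 1),
    apache2 = sev_draw(config$severity_scores$apache2),
    apache4 = sev_draw(config$severity_scores$apache4),
    saps2 = sev_draw(config$severity_scores$saps2))

  # --- emit recordings: per-element offsets within a 5-minute span, then
  #     independent per-element dropout ---
  miss <- config$missingness[arm, ]
  rec_rows <- vector("list", length(ev_time))
  n_recorded <- integer(length(ev_time))
  for (k in seq_along(ev_time)) {
    offsets <- sample(0:4, 8, replace = TRUE)
    keep <- runif(8) >= miss[element_kinds()]
    n_recorded[k] <- sum(keep)
    if (!any(keep)) next
    vals <- ev_values[[k]]
    rec_rows[[k]] <- tibble::tibble(
      patient_id = pid,
      timestamp = floor_minute(as.POSIXct(ev_time[k] + offsets[keep] * 60,
                                          origin = "1970-01-01", tz = "UTC")),
      element = element_kinds()[keep],
      value = unname(vals[element_kinds()[keep]]),
      oxygen_therapy = element_kinds()[keep] == "SPO2" & ev_o2[k],
      source = ev_source[k],
      period = arm)
  }

  truth_values <- do.call(rbind, ev_values)
  colnames(truth_values) <- paste0("true_", tolower(element_kinds()))
  events <- tibble::tibble(
    patient_id = pid, arm = arm,
    event_time = floor_minute(as.POSIXct(ev_time, origin = "1970-01-01",
                                         tz = "UTC")),
    severity = ev_sev, source = ev_source,
    true_mews = as.integer(ev_mews), window_hours = ev_window,
    followup_within_window = ev_timely,
    oxygen_therapy = ev_o2,
    n_recorded = n_recorded)
  events <- dplyr::bind_cols(events, tibble::as_tibble(truth_values))

  list(stay = stay, recordings = dplyr::bind_rows(rec_rows),
       events = events, episodes = episode_truth(ep))
}

episode_truth <- function(ep) {
  if (nrow(ep) == 0) return(NULL)
  tibble::tibble(
    patient_id = ep$patient_id,
    start = as.POSIXct(ep$start, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(ep$end, origin = "1970-01-01", tz = "UTC"),
    severity = ep$severity)
}

#' Inject a deterioration episode into a recording stream
#'
#' Shifts every recorded element value inside `[start, end]` towards its
#' abnormal score bands by the deterministic severity multiplier used by the
#' generator (severity 0 is the identity; at severity 1 heart rate rises by
#' 40 beats/min, systolic pressure falls by 35 mmHg, respiratory rate rises
#' by 9 breaths/min, temperature by 0.8 degC, SpO2 falls by 7 points, AVPU
#' worsens one level, urine output falls to ~22% and the worried flag is
#' set). Values are clamped to physiologic sanity ranges and re-rounded to
#' storage precision.
#'
#' @param stream Recordings tibble of a single patient.
#' @param start,end Episode interval (POSIXct); must intersect the stay
#'   (the stream's recording span, or `stay`'s admission/discharge when
#'   given).
#' @param severity Non-negative severity multiplier.
#' @param stay Optional one-row stay tibble used for the interval check.
#' @return The modified stream.
#' @export
inject_episode <- function(stream, start, end, severity, stay = NULL) {
  stopifnot(severity >= 0)
  if (end <= start) stop("episode must have positive duration", call. = FALSE)
  bounds <- if (!is.null(stay)) {
    c(stay$hdu_admit[1], stay$hdu_discharge[1])
  } else {
    range(stream$timestamp)
  }
  if (end < bounds[1] || start > bounds[2]) {
    stop("episode interval lies outside the stay", call. = FALSE)
  }
  hit <- stream$timestamp >= start & stream$timestamp <= end
  if (!any(hit) || severity == 0) return(stream)
  for (i in which(hit)) {
    v <- stats::setNames(stream$value[i], stream$element[i])
    v <- round_to_precision(episode_shift_values(v, severity))
    stream$value[i] <- unname(v)
  }
  stream
}

#' @export
print.mews_cohort <- function(x, ...) {
  cat("Synthetic HDU cohort:",
      nrow(x$stays), "stays,",
      nrow(x$recordings), "recordings,",
      nrow(x$truth$events), "true assessment events\n")
  invisible(x)
}
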