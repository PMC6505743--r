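#' Vital-sign element kinds
#'
#' The eight elements of the Modified Early Warning Score (MEWS) as used on
#' the surgical high-dependency unit: heart rate, systolic blood pressure,
#' respiratory rate, temperature, oxygen saturation, AVPU level of
#' consciousness, 4-hour urine production, and the nurse's "worried about the
#' patient" flag. The seven *core* elements exclude `WORRIED`: an assessment
#' is complete when all seven are present, the worried flag being optional.
#'
#' @return Character vector of element identifiers.
#' @export
#' @examples
#' element_kinds()
#' core_elements()
element_kinds <- function() {
  c("HEART_RATE", "SYSTOLIC_BP", "RESP_RATE", "TEMPERATURE",
    "SPO2", "AVPU", "URINE_4H", "WORRIED")
}

#' @rdname element_kinds
#' @export
core_elements <- function() {
  setdiff(element_kinds(), "WORRIED")
}

#' @rdname element_kinds
#' @export
recording_sources <- function() {
  c("CONVENTIONAL", "AUTOMATED")
}

#' @rdname element_kinds
#' @export
arm_labels <- function() {
  c("control", "intervention")
}

# Physiologic sanity ranges (closed intervals) per element; values outside
# are rejected at the IO boundary, not clamped.
element_sanity_ranges <- function() {
  list(
    HEART_RATE  = c(0, 300),
    SYSTOLIC_BP = c(0, 350),
    RESP_RATE   = c(0, 80),
    TEMPERATURE = c(25, 45),
    SPO2        = c(0, 100),
    AVPU        = c(0, 3),
    URINE_4H    = c(0, Inf),
    WORRIED     = c(0, 1)
  )
}

surgery_types <- function() {
  c("abdominal_oncology", "abdominal_benign", "vascular_aortic")
}

# Timestamps are ISO 8601, timezone-naive (stored as UTC), minute resolution.
timestamp_format <- "%Y-%m-%dT%H:%M"

parse_timestamp <- function(x) {
  out <- as.POSIXct(x, format = timestamp_format, tz = "UTC")
  # accept a space separator as well
  retry <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], format = "%Y-%m-%d %H:%M", tz = "UTC")
  }
  out
}

format_timestamp <- function(x) {
  format(x, format = timestamp_format, tz = "UTC")
}

floor_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

stop_validation <- function(rows, field, why) {
  stop(sprintf("validation error in field '%s' (row %s): %s",
               field, paste(rows, collapse = ", "), why), call. = FALSE)
}

check_field <- function(bad, field, why) {
  if (any(bad)) stop_validation(which(bad), field, why)
}

as_logical01 <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  out
}

# AVPU accepted as letters on input, stored numerically (A=0, V=1, P=2, U=3)
avpu_to_numeric <- function(x) {
  x <- toupper(trimws(as.character(x)))
  map <- c(A = 0, V = 1, P = 2, U = 3)
  out <- suppressWarnings(as.numeric(x))
  lettered <- x %in% names(map)
  out[lettered] <- map[x[lettered]]
  out
}

#' Read and validate vital-sign recordings
#'
#' Reads a long-format CSV of time-stamped per-element recordings
#' (`patient_id, timestamp, element, value, oxygen_therapy, source, period`),
#' validates every row against the element's physiologic sanity range and the
#' closed element/source/arm vocabularies, and returns a tibble sorted by
#' `(patient_id, timestamp, element)`. Validation failures name the offending
#' row and field; nothing is silently coerced (AVPU letters `A/V/P/U` are the
#' one documented exception, mapped to 0--3).
#'
#' @param path Path to a recordings CSV.
#' @return A tibble with columns `patient_id` (character), `timestamp`
#'   (POSIXct, minute resolution), `element`, `value`, `oxygen_therapy`
#'   (logical), `source`, `period`.
#' @seealso [write_recordings()], [read_stays()]
#' @export
read_recordings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  expected <- c("patient_id", "timestamp", "element", "value",
                "oxygen_therapy", "source", "period")
  if (!identical(names(raw), expected)) {
    stop("recordings header must be: ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_recordings())
  validate_recordings_raw(raw)
}

empty_recordings <- function() {
  tibble::tibble(
    patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    element = character(), value = numeric(), oxygen_therapy = logical(),
    source = character(), period = character()
  )
}

validate_recordings_raw <- function(raw) {
  check_field(is.na(raw$patient_id) | !nzchar(raw$patient_id),
              "patient_id", "missing patient id")
  ts <- parse_timestamp(raw$timestamp)
  check_field(is.na(ts), "timestamp",
              "malformed timestamp (expected ISO 8601 YYYY-MM-DDTHH:MM)")
  el <- toupper(trimws(raw$element))
  check_field(!el %in% element_kinds(), "element",
              paste0("unknown element (expected one of ",
                     paste(element_kinds(), collapse = ", "), ")"))
  val <- ifelse(el == "AVPU", avpu_to_numeric(raw$value),
                suppressWarnings(as.numeric(raw$value)))
  check_field(!is.finite(val), "value", "non-numeric value")
  rng <- element_sanity_ranges()
  lo <- vapply(rng, `[`, numeric(1), 1L)[el]
  hi <- vapply(rng, `[`, numeric(1), 2L)[el]
  check_field(val < lo | val > hi, "value",
              "value outside the element's physiologic sanity range")
  check_field(el == "AVPU" & val != round(val), "value",
              "AVPU must be one of A, V, P, U or 0-3")
  check_field(el == "WORRIED" & !val %in% c(0, 1), "value",
              "worried flag must be 0 or 1")
  o2 <- as_logical01(raw$oxygen_therapy)
  check_field(is.na(o2), "oxygen_therapy", "must be 0/1 or true/false")
  src <- toupper(trimws(raw$source))
  check_field(!src %in% recording_sources(), "source",
              "source must be CONVENTIONAL or AUTOMATED")
  per <- tolower(trimws(raw$period))
  check_field(!per %in% arm_labels(), "period",
              "period must be control or intervention")
  check_field(per == "control" & src == "AUTOMATED", "source",
              "AUTOMATED recordings cannot occur in the control arm")
  out <- tibble::tibble(
    patient_id = raw$patient_id, timestamp = floor_minute(ts),
    element = el, value = val, oxygen_therapy = o2, source = src, period = per
  )
  dplyr::arrange(out, .data$patient_id, .data$timestamp, .data$element)
}

#' Write vital-sign recordings
#'
#' Serializes a validated recordings tibble to CSV so that
#' `read_recordings(write_recordings(x, p))` is the identity.
#'
#' @param recordings Tibble as returned by [read_recordings()] or
#'   [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recordings <- function(recordings, path) {
  out <- data.frame(
    patient_id = recordings$patient_id,
    timestamp = format_timestamp(recordings$timestamp),
    element = recordings$element,
    value = recordings$value,
    oxygen_therapy = as.integer(recordings$oxygen_therapy),
    source = recordings$source,
    period = recordings$period
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate patient stays
#'
#' Reads the per-stay table (admission/discharge timestamps, demographics,
#' surgery type, clinical outcomes, and severity scores stored as opaque
#' numbers). Discharge must fall after admission and length-of-stay fields
#' must be non-negative; failures name the row and field.
#'
#' @param path Path to a stays CSV.
#' @return A tibble with one row per HDU stay.
#' @export
read_stays <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  expected <- stay_columns()
  if (!identical(names(raw), expected)) {
    stop("stays header must be: ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_stays())
  validate_stays_raw(raw)
}

stay_columns <- function() {
  c("patient_id", "arm", "hdu_admit", "hdu_discharge", "age_years", "sex",
    "surgery_type", "unplanned_surgery", "icu_readmitted",
    "in_hospital_death", "death_within_28d", "hospital_los_days",
    "hdu_los_days", "apache2", "apache4", "saps2")
}

empty_stays <- function() {
  tibble::tibble(
    patient_id = character(), arm = character(),
    hdu_admit = as.POSIXct(character(), tz = "UTC"),
    hdu_discharge = as.POSIXct(character(), tz = "UTC"),
    age_years = numeric(), sex = character(), surgery_type = character(),
    unplanned_surgery = logical(), icu_readmitted = logical(),
    in_hospital_death = logical(), death_within_28d = logical(),
    hospital_los_days = numeric(), hdu_los_days = numeric(),
    apache2 = numeric(), apache4 = numeric(), saps2 = numeric()
  )
}

validate_stays_raw <- function(raw) {
  check_field(is.na(raw$patient_id) | !nzchar(raw$patient_id),
              "patient_id", "missing patient id")
  arm <- tolower(trimws(raw$arm))
  check_field(!arm %in% arm_labels(), "arm",
              "arm must be control or intervention")
  admit <- parse_timestamp(raw$hdu_admit)
  check_field(is.na(admit), "hdu_admit", "malformed timestamp")
  disch <- parse_timestamp(raw$hdu_discharge)
  check_field(is.na(disch), "hdu_discharge", "malformed timestamp")
  check_field(disch <= admit, "hdu_discharge",
              "discharge must be after admission")
  num <- function(field) {
    v <- suppressWarnings(as.numeric(raw[[field]]))
    check_field(!is.finite(v), field, "non-numeric value")
    v
  }
  age <- num("age_years")
  check_field(age < 18 | age > 120, "age_years", "age outside 18-120")
  sex <- tolower(trimws(raw$sex))
  check_field(!sex %in% c("male", "female"), "sex",
              "sex must be male or female")
  surg <- tolower(trimws(raw$surgery_type))
  check_field(!surg %in% surgery_types(), "surgery_type",
              paste0("must be one of ", paste(surgery_types(), collapse = ", ")))
  lgl <- function(field) {
    v <- as_logical01(raw[[field]])
    check_field(is.na(v), field, "must be 0/1 or true/false")
    v
  }
  hosp_los <- num("hospital_los_days")
  hdu_los <- num("hdu_los_days")
  check_field(hosp_los < 0, "hospital_los_days", "negative length of stay")
  check_field(hdu_los < 0, "hdu_los_days", "negative length of stay")
  out <- tibble::tibble(
    patient_id = raw$patient_id, arm = arm,
    hdu_admit = floor_minute(admit), hdu_discharge = floor_minute(disch),
    age_years = age, sex = sex, surgery_type = surg,
    unplanned_surgery = lgl("unplanned_surgery"),
    icu_readmitted = lgl("icu_readmitted"),
    in_hospital_death = lgl("in_hospital_death"),
    death_within_28d = lgl("death_within_28d"),
    hospital_los_days = hosp_los, hdu_los_days = hdu_los,
    apache2 = num("apache2"), apache4 = num("apache4"), saps2 = num("saps2")
  )
  dplyr::arrange(out, .data$patient_id)
}

#' @rdname read_stays
#' @param stays Tibble of stays.
#' @param path Output file path.
#' @export
write_stays <- function(stays, path) {
  out <- data.frame(
    patient_id = stays$patient_id, arm = stays$arm,
    hdu_admit = format_timestamp(stays$hdu_admit),
    hdu_discharge = format_timestamp(stays$hdu_discharge),
    age_years = stays$age_years, sex = stays$sex,
    surgery_type = stays$surgery_type,
    unplanned_surgery = as.integer(stays$unplanned_surgery),
    icu_readmitted = as.integer(stays$icu_readmitted),
    in_hospital_death = as.integer(stays$in_hospital_death),
    death_within_28d = as.integer(stays$death_within_28d),
    hospital_los_days = stays$hospital_los_days,
    hdu_los_days = stays$hdu_los_days,
    apache2 = stays$apache2, apache4 = stays$apache4, saps2 = stays$saps2
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
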