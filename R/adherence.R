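#' Maximum time until the next assessment, by MEWS
#'
#' The hospital response protocol: a score of 0 requires the next assessment
#' within the next shift (24 h), 1 within 8 h, 2 within 4 h, and 3 or more
#' within 1 h (with escalation to the responsible physician, and for scores
#' of 4 or more consideration of the rapid response team — actions that are
#' not auditable from timestamps and are out of scope here).
#'
#' @param mews Non-negative integer score(s).
#' @return Numeric hours, vectorized.
#' @export
#' @examples
#' required_interval_hours(0:5)
required_interval_hours <- function(mews) {
  if (any(!is.finite(mews)) || any(mews < 0)) {
    stop("mews must be non-negative", call. = FALSE)
  }
  c(24, 8, 4, 1)[pmin(as.integer(mews), 3L) + 1L]
}

#' Audit one stay against the response protocol
#'
#' For each assessment of a single patient's stay, computes the
#' anchor-to-anchor interval to the next assessment and whether it met the
#' maximum interval dictated by the current (recomputed, possibly partial)
#' MEWS. The stay's last assessment has no successor: under the default
#' `exclude_terminal` policy it is not evaluable and leaves the denominator;
#' under `terminal_nonadherent` it counts as non-adherent, approximating an
#' accounting in which every assessment is in the denominator.
#'
#' @param assessments Assessments of one patient, chronologically sorted.
#' @param policy `"exclude_terminal"` (default) or `"terminal_nonadherent"`.
#' @param complete_only If `TRUE`, restrict the audit to complete
#'   assessments (intervals then run between consecutive complete ones).
#' @return A tibble of verdicts: `patient_id`, `arm`, `source_label`,
#'   `anchor_time`, `mews_total`, `interval_to_next_hours` (`NA` for the
#'   terminal assessment), `required_hours`, `adherent` (logical; `NA` =
#'   not evaluable).
#' @export
#' @examples
#' a <- tibble::tibble(
#'   patient_id = "p1", arm = "control", source_label = "CONVENTIONAL",
#'   anchor_time = as.POSIXct("2012-03-01 08:00", tz = "UTC") + c(0, 3, 7) * 3600,
#'   mews_total = c(2L, 0L, 1L), complete = TRUE)
#' audit_stay(a)
audit_stay <- function(assessments,
                       policy = c("exclude_terminal", "terminal_nonadherent"),
                       complete_only = FALSE) {
  policy <- match.arg(policy)
  if (length(unique(assessments$patient_id)) > 1) {
    stop("audit_stay expects assessments of a single patient", call. = FALSE)
  }
  if (is.unsorted(assessments$anchor_time)) {
    stop("assessments must be chronologically sorted", call. = FALSE)
  }
  if (complete_only) assessments <- assessments[assessments$complete, ]
  n <- nrow(assessments)
  if (n == 0) return(empty_verdicts())
  interval <- c(as.numeric(diff(assessments$anchor_time), units = "hours"),
                NA_real_)
  required <- required_interval_hours(assessments$mews_total)
  adherent <- interval <= required
  if (policy == "terminal_nonadherent") adherent[n] <- FALSE
  tibble::tibble(
    patient_id = assessments$patient_id,
    arm = assessments$arm,
    source_label = assessments$source_label,
    anchor_time = assessments$anchor_time,
    mews_total = assessments$mews_total,
    interval_to_next_hours = interval,
    required_hours = required,
    adherent = adherent)
}

empty_verdicts <- function() {
  tibble::tibble(
    patient_id = character(), arm = character(), source_label = character(),
    anchor_time = as.POSIXct(character(), tz = "UTC"),
    mews_total = integer(), interval_to_next_hours = numeric(),
    required_hours = numeric(), adherent = logical())
}

#' @rdname audit_stay
#' @description `audit_cohort()` applies `audit_stay()` to every patient of
#'   a multi-patient assessments table.
#' @export
audit_cohort <- function(assessments,
                         policy = c("exclude_terminal", "terminal_nonadherent"),
                         complete_only = FALSE) {
  policy <- match.arg(policy)
  if (nrow(assessments) == 0) return(empty_verdicts())
  parts <- split(assessments, assessments$patient_id)
  dplyr::bind_rows(lapply(parts, audit_stay, policy = policy,
                          complete_only = complete_only))
}

#' Protocol-adherence rate
#'
#' Proportion of adherent verdicts among evaluable ones (non-evaluable
#' terminal verdicts carry `NA` and leave the denominator; under the
#' `terminal_nonadherent` audit policy they are already `FALSE` and stay in).
#' An empty denominator yields `NA`.
#'
#' @param verdicts Tibble from [audit_stay()] / [audit_cohort()].
#' @return Proportion in `[0, 1]`, or `NA` when undefined.
#' @export
adherence_rate <- function(verdicts) {
  evaluable <- !is.na(verdicts$adherent)
  if (!any(evaluable)) return(NA_real_)
  mean(verdicts$adherent[evaluable])
}

#' Time-to-next-assessment strata
#'
#' Summarizes the interval to the next assessment by MEWS stratum, the way
#' the study tabulates the response behaviour. Each consecutive
#' assessment pair contributes one interval, assigned to the stratum of the
#' *earlier* assessment's score (the protocol clock starts at the scored
#' observation). Strata are the exact scores 0, 1, 2, 3, optionally plus a
#' pooled `"4+"` stratum.
#'
#' @param assessments Assessments tibble (any number of patients).
#' @param by Optional grouping column: `NULL`, `"arm"`, or `"source_label"`.
#' @param include_ge4 Include the pooled `"4+"` stratum (default `TRUE`).
#' @param quartile_rule Quartile convention for the IQR width, see
#'   [median_iqr()].
#' @return Tibble: (group), `mews_stratum`, `n`, `median_hours`, `iqr_hours`.
#' @export
interval_strata <- function(assessments, by = NULL, include_ge4 = TRUE,
                            quartile_rule = c("tukey", "linear")) {
  quartile_rule <- match.arg(quartile_rule)
  verdicts <- audit_cohort(assessments)
  intervals <- verdicts[!is.na(verdicts$interval_to_next_hours), ]
  levels <- c("0", "1", "2", "3", if (include_ge4) "4+")
  intervals$mews_stratum <- ifelse(intervals$mews_total >= 4, "4+",
                                   as.character(intervals$mews_total))
  intervals <- intervals[intervals$mews_stratum %in% levels, ]
  groups <- if (is.null(by)) list(intervals) else
    split(intervals, intervals[[by]])
  out <- dplyr::bind_rows(lapply(names(groups) %||% "", function(g) {
    d <- if (is.null(by)) groups[[1]] else groups[[g]]
    res <- lapply(levels, function(lv) {
      x <- d$interval_to_next_hours[d$mews_stratum == lv]
      if (length(x) == 0) {
        tibble::tibble(mews_stratum = lv, n = 0L, median_hours = NA_real_,
                       iqr_hours = NA_real_)
      } else {
        mi <- median_iqr(x, quartile_rule)
        tibble::tibble(mews_stratum = lv, n = length(x),
                       median_hours = mi[["median"]], iqr_hours = mi[["iqr"]])
      }
    })
    res <- dplyr::bind_rows(res)
    if (!is.null(by)) res <- tibble::add_column(res, !!by := g, .before = 1)
    res
  }))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an audit to CSV
#'
#' @param verdicts Tibble from [audit_cohort()].
#' @param path Output file path.
#' @export
write_audit <- function(verdicts, path) {
  out <- as.data.frame(verdicts)
  out$anchor_time <- format_timestamp(out$anchor_time)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
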