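#' The default MEWS scoring table
#'
#' Encodes the hospital's Modified Early Warning Score card. Four elements
#' are banded (heart rate, systolic blood pressure, respiratory rate,
#' temperature); AVPU maps categorically (Alert 0, Voice 1, Pain 2,
#' Unconscious 3); and three point rules cover the rest: 1 point when the
#' nurse is worried about the patient, 1 point when urine production over the
#' previous 4 hours is below 75 ml, and 3 points when oxygen saturation is
#' below 90% despite adequate oxygen therapy.
#'
#' Values are rounded to the card's printed precision before lookup (heart
#' rate, blood pressure and respiratory rate to whole units, temperature to
#' 0.1 degree C), after which the printed bands are exhaustive and disjoint and are
#' read as closed on their printed endpoints — exactly what a nurse reading
#' the card does. The card's asymmetries are implemented literally: systolic
#' BP above 200 scores 2 (there is no high-side 3), temperature never scores
#' above 1 on the high side, and respiratory rate below 9 scores 2. The
#' maximum attainable total is 19.
#'
#' Bands are stored on an integer grid (`scale` = 1, or 10 for temperature so
#' that 0.1-degree bands are exact): a rounded, scaled value `v` falls in band
#' `findInterval(v, breaks) + 1`.
#'
#' @return An object of class `mews_scoring_table`.
#' @seealso [score_element()], [compute_mews()], [read_scoring_table()]
#' @export
#' @examples
#' tab <- default_scoring_table()
#' score_element(tab, "HEART_RATE", 135)
default_scoring_table <- function() {
  new_scoring_table(
    bands = list(
      HEART_RATE  = list(scale = 1,  breaks = c(40, 51, 101, 111, 131),
                         scores = c(2, 1, 0, 1, 2, 3)),
      SYSTOLIC_BP = list(scale = 1,  breaks = c(70, 81, 101, 201),
                         scores = c(3, 2, 1, 0, 2)),
      RESP_RATE   = list(scale = 1,  breaks = c(9, 15, 21, 31),
                         scores = c(2, 0, 1, 2, 3)),
      TEMPERATURE = list(scale = 10, breaks = c(351, 366, 376),
                         scores = c(2, 1, 0, 1))
    ),
    avpu_scores = c(0, 1, 2, 3),
    worried_points = 1,
    urine_threshold_ml = 75, urine_points = 1,
    spo2_threshold_pct = 90, spo2_points = 3
  )
}

new_scoring_table <- function(bands, avpu_scores, worried_points,
                              urine_threshold_ml, urine_points,
                              spo2_threshold_pct, spo2_points) {
  tab <- structure(
    list(bands = bands, avpu_scores = avpu_scores,
         worried_points = worried_points,
         urine_threshold_ml = urine_threshold_ml, urine_points = urine_points,
         spo2_threshold_pct = spo2_threshold_pct, spo2_points = spo2_points),
    class = "mews_scoring_table")
  validate_scoring_table(tab)
}

validate_scoring_table <- function(tab) {
  banded <- c("HEART_RATE", "SYSTOLIC_BP", "RESP_RATE", "TEMPERATURE")
  if (!setequal(names(tab$bands), banded)) {
    stop("scoring table must band exactly: ", paste(banded, collapse = ", "),
         call. = FALSE)
  }
  for (el in banded) {
    b <- tab$bands[[el]]
    if (is.unsorted(b$breaks, strictly = TRUE)) {
      stop("band breaks for ", el, " must be strictly increasing", call. = FALSE)
    }
    if (length(b$scores) != length(b$breaks) + 1L) {
      stop("need one score per band (breaks + 1) for ", el, call. = FALSE)
    }
    if (!all(b$scores %in% 0:3)) {
      stop("sub-scores must lie in 0..3 (", el, ")", call. = FALSE)
    }
  }
  stopifnot(length(tab$avpu_scores) == 4, all(tab$avpu_scores %in% 0:3))
  tab
}

#' Maximum attainable MEWS total for a scoring table
#' @param table A `mews_scoring_table`.
#' @return Integer: the sum of the per-element maximal sub-scores (19 for the
#'   default card).
#' @export
max_mews_total <- function(table = default_scoring_table()) {
  sum(vapply(table$bands, function(b) max(b$scores), numeric(1))) +
    max(table$avpu_scores) + table$worried_points + table$urine_points +
    table$spo2_points
}

#' Score one MEWS element
#'
#' Looks up the sub-score of a measured value in a scoring table. Vectorized
#' over `value` (and `oxygen_therapy`). The oxygen-therapy flag is consulted
#' only for `SPO2`: a saturation below the threshold scores points only when
#' it persists despite adequate oxygen therapy; in every other case SpO2
#' contributes 0.
#'
#' @param table A [default_scoring_table()]-style table.
#' @param element One of [element_kinds()].
#' @param value Measured value(s) in the element's units.
#' @param oxygen_therapy Logical, recycled along `value`.
#' @return Integer sub-score(s) in 0..3.
#' @export
#' @examples
#' tab <- default_scoring_table()
#' score_element(tab, "RESP_RATE", 25)
#' score_element(tab, "SPO2", 88, oxygen_therapy = TRUE)
score_element <- function(table, element, value, oxygen_therapy = FALSE) {
  element <- match.arg(element, element_kinds())
  if (any(!is.finite(value))) {
    stop("non-finite value passed to score_element for ", element,
         call. = FALSE)
  }
  oxygen_therapy <- rep_len(as.logical(oxygen_therapy), length(value))
  if (element %in% names(table$bands)) {
    b <- table$bands[[element]]
    v <- round(value * b$scale)
    return(as.integer(b$scores[findInterval(v, b$breaks) + 1L]))
  }
  switch(element,
    AVPU = {
      v <- round(value)
      if (any(v < 0 | v > 3)) {
        stop("AVPU value must lie in 0..3", call. = FALSE)
      }
      as.integer(table$avpu_scores[v + 1L])
    },
    SPO2 = as.integer(
      ifelse(value < table$spo2_threshold_pct & oxygen_therapy,
             table$spo2_points, 0L)),
    URINE_4H = as.integer(
      ifelse(value < table$urine_threshold_ml, table$urine_points, 0L)),
    WORRIED = as.integer(ifelse(round(value) >= 1, table$worried_points, 0L))
  )
}

#' Compute a MEWS from the elements present at one assessment
#'
#' Sums the sub-scores of the elements present. An absent worried flag is
#' treated as "not worried" (0 points, not missing); any other absent element
#' simply contributes nothing, so the total of an incomplete assessment is a
#' lower bound on the fully-observed score. The assessment is complete when
#' all seven core elements are present.
#'
#' @param values Named numeric vector; names from [element_kinds()].
#' @param oxygen_therapy Logical scalar or named logical vector (only the
#'   `SPO2` entry matters).
#' @param table Scoring table.
#' @return A list of class `mews_result` with `total`, `breakdown` (named
#'   integer vector over the present elements), `elements_present`, and
#'   `complete`.
#' @export
#' @examples
#' compute_mews(c(HEART_RATE = 105, SYSTOLIC_BP = 95, RESP_RATE = 18,
#'                TEMPERATURE = 37.8, SPO2 = 95, AVPU = 1, URINE_4H = 60))
compute_mews <- function(values, oxygen_therapy = FALSE,
                         table = default_scoring_table()) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop("compute_mews needs at least one element", call. = FALSE)
  }
  els <- names(values)
  if (is.null(els) || !all(els %in% element_kinds())) {
    stop("values must be named by element kind", call. = FALSE)
  }
  if (anyDuplicated(els)) {
    stop("at most one value per element", call. = FALSE)
  }
  if (length(oxygen_therapy) == 1 && is.null(names(oxygen_therapy))) {
    o2 <- as.logical(oxygen_therapy)
  } else {
    o2 <- isTRUE(unname(oxygen_therapy["SPO2"]))
  }
  breakdown <- vapply(
    els,
    function(el) score_element(table, el, values[[el]],
                               if (el == "SPO2") o2 else FALSE),
    integer(1))
  structure(
    list(total = as.integer(sum(breakdown)),
         breakdown = breakdown,
         elements_present = els,
         complete = all(core_elements() %in% els)),
    class = "mews_result")
}

#' @export
print.mews_result <- function(x, ...) {
  cat("MEWS", x$total,
      if (x$complete) "(complete)" else "(incomplete)", "\n")
  cat("  ", paste0(names(x$breakdown), "=", x$breakdown, collapse = " "), "\n")
  invisible(x)
}

#' Read or write a scoring-table configuration file
#'
#' A scoring table can be stored as YAML so that other early-warning-score
#' variants can be audited with the same pipeline; the built-in default
#' reproduces the hospital card exactly. Bands are given in value units as
#' `lower`/`upper`/`score` rows (half-open on the rounded grid, `-Inf`/`Inf`
#' written as `.inf`).
#'
#' @param path File path.
#' @return For `read_scoring_table`, a `mews_scoring_table`.
#' @export
read_scoring_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  bands <- lapply(cfg$bands, function(b) {
    list(scale = b$scale,
         breaks = as.numeric(b$breaks),
         scores = as.numeric(b$scores))
  })
  new_scoring_table(
    bands = bands,
    avpu_scores = as.numeric(cfg$avpu_scores),
    worried_points = cfg$worried_points,
    urine_threshold_ml = cfg$urine_threshold_ml,
    urine_points = cfg$urine_points,
    spo2_threshold_pct = cfg$spo2_threshold_pct,
    spo2_points = cfg$spo2_points)
}

#' @rdname read_scoring_table
#' @param table A `mews_scoring_table`.
#' @export
write_scoring_table <- function(table, path) {
  yaml::write_yaml(unclass(table), path)
  invisible(path)
}
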