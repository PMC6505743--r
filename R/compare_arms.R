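#' Compare two study arms
#'
#' Runs the full operational and clinical comparison between a control arm
#' and an intervention arm: completeness and protocol-adherence proportions
#' with 2x2 tests, per-element missingness, time-to-next-assessment strata
#' with rank-sum tests for the three comparisons the study tabulates
#' (control vs whole intervention; conventional vs automated within the
#' intervention arm; control vs automated), clinical-outcome summaries from
#' the stay table, and the 24-hour assessment pattern per arm.
#'
#' Adherence within the intervention arm is attributed per assessment: each
#' interval belongs to the recording source (and score stratum) of its
#' earlier assessment, while the interval itself runs to the next assessment
#' of the stay regardless of how that one was recorded.
#'
#' @param assessments_control,assessments_intervention Assessments tibbles
#'   (see [build_assessments()]).
#' @param stays_control,stays_intervention Stay tibbles (see [read_stays()]).
#' @param policy Denominator policy for the audit, see [audit_stay()].
#' @param quartile_rule Quartile convention, see [median_iqr()].
#' @return List of class `mews_comparison` with components
#'   `adherence_summary`, `adherence_tests`, `missingness`, `intervals`,
#'   `outcomes`, `hourly`.
#' @export
compare_arms <- function(assessments_control, assessments_intervention,
                         stays_control, stays_intervention,
                         policy = c("exclude_terminal", "terminal_nonadherent"),
                         quartile_rule = c("tukey", "linear")) {
  policy <- match.arg(policy)
  quartile_rule <- match.arg(quartile_rule)
  if (nrow(assessments_control) == 0 || nrow(assessments_intervention) == 0) {
    stop("both arms must contain assessments", call. = FALSE)
  }

  v_ctrl <- audit_cohort(assessments_control, policy = policy)
  v_int <- audit_cohort(assessments_intervention, policy = policy)
  groups <- list(
    control = list(a = assessments_control, v = v_ctrl),
    intervention = list(a = assessments_intervention, v = v_int),
    intervention_conventional = list(
      a = assessments_intervention[
        assessments_intervention$source_label == "CONVENTIONAL", ],
      v = v_int[v_int$source_label == "CONVENTIONAL", ]),
    intervention_automated = list(
      a = assessments_intervention[
        assessments_intervention$source_label == "AUTOMATED", ],
      v = v_int[v_int$source_label == "AUTOMATED", ]))

  adherence_summary <- dplyr::bind_rows(lapply(names(groups), function(g) {
    a <- groups[[g]]$a; v <- groups[[g]]$v
    cc <- completeness_counts(a)
    evaluable <- sum(!is.na(v$adherent))
    adherent <- sum(v$adherent, na.rm = TRUE)
    tibble::tibble(
      group = g,
      n_assessments = unname(cc["n_total"]),
      n_complete = unname(cc["n_complete"]),
      completeness_pct = percent_from_counts(cc["n_complete"], cc["n_total"]),
      n_evaluable = evaluable,
      n_adherent = adherent,
      adherence_pct = if (evaluable == 0) NA_real_ else
        percent_from_counts(adherent, evaluable))
  }))

  # a degenerate 2x2 (a zero row or column) is reported as NA, not an error:
  # the comparison is simply not testable for that dataset
  safe_p <- function(a, b, c, d) {
    tryCatch(contingency_test(a, b, c, d)$p_two_sided,
             error = function(e) NA_real_)
  }
  test_pair <- function(g1, g2, yes, no) {
    s1 <- adherence_summary[adherence_summary$group == g1, ]
    s2 <- adherence_summary[adherence_summary$group == g2, ]
    tibble::tibble(
      comparison = paste(g1, "vs", g2),
      outcome = yes,
      p = safe_p(s1[[yes]], s1[[no]] - s1[[yes]],
                 s2[[yes]], s2[[no]] - s2[[yes]]))
  }
  adherence_tests <- dplyr::bind_rows(
    test_pair("control", "intervention", "n_complete", "n_assessments"),
    test_pair("control", "intervention", "n_adherent", "n_evaluable"),
    test_pair("intervention_conventional", "intervention_automated",
              "n_adherent", "n_evaluable"))

  missingness <- dplyr::bind_rows(lapply(names(groups), function(g) {
    tibble::add_column(missingness_by_element(groups[[g]]$a),
                       group = g, .before = 1)
  }))

  comparisons <- list(
    c("control", "intervention"),
    c("intervention_conventional", "intervention_automated"),
    c("control", "intervention_automated"))
  intervals <- dplyr::bind_rows(lapply(comparisons, function(pr) {
    interval_panel(groups[[pr[1]]]$v, groups[[pr[2]]]$v, pr[1], pr[2],
                   quartile_rule)
  }))

  outcomes <- outcome_panel(stays_control, stays_intervention, quartile_rule)

  hourly <- dplyr::bind_rows(
    tibble::add_column(hourly_pattern(assessments_control),
                       arm = "control", .before = 1),
    tibble::add_column(hourly_pattern(assessments_intervention),
                       arm = "intervention", .before = 1))

  structure(
    list(adherence_summary = adherence_summary,
         adherence_tests = adherence_tests,
         missingness = missingness, intervals = intervals,
         outcomes = outcomes, hourly = hourly, policy = policy),
    class = "mews_comparison")
}

# One three-column panel of the interval table: per MEWS stratum, n / median /
# IQR on each side plus the rank-sum p and z.
interval_panel <- function(v1, v2, label1, label2, quartile_rule) {
  strata <- c("0", "1", "2", "3")
  dplyr::bind_rows(lapply(strata, function(lv) {
    pick <- function(v) {
      s <- ifelse(v$mews_total >= 4, "4+", as.character(v$mews_total))
      v$interval_to_next_hours[s == lv & !is.na(v$interval_to_next_hours)]
    }
    x1 <- pick(v1); x2 <- pick(v2)
    summ <- function(x) {
      if (length(x) == 0) c(median = NA_real_, iqr = NA_real_) else
        median_iqr(x, quartile_rule)
    }
    s1 <- summ(x1); s2 <- summ(x2)
    if (length(x1) >= 1 && length(x2) >= 1) {
      rs <- rank_sum_test(x1, x2)
      p <- rs$p_two_sided; z <- rs$z_score
    } else {
      p <- NA_real_; z <- NA_real_
    }
    tibble::tibble(
      group_a = label1, group_b = label2, mews_stratum = lv,
      n_a = length(x1), median_a = s1[["median"]], iqr_a = s1[["iqr"]],
      n_b = length(x2), median_b = s2[["median"]], iqr_b = s2[["iqr"]],
      p_value = p, z_score = z)
  }))
}

outcome_panel <- function(stays_a, stays_b, quartile_rule) {
  cont <- function(name, col) {
    xa <- stays_a[[col]]; xb <- stays_b[[col]]
    ma <- median_iqr(xa, quartile_rule); mb <- median_iqr(xb, quartile_rule)
    rs <- rank_sum_test(xa, xb)
    tibble::tibble(
      outcome = name, type = "median_iqr",
      control_n = length(xa), control_value = ma[["median"]],
      control_spread = ma[["iqr"]],
      intervention_n = length(xb), intervention_value = mb[["median"]],
      intervention_spread = mb[["iqr"]], p_value = rs$p_two_sided)
  }
  prop <- function(name, col) {
    na <- nrow(stays_a); nb <- nrow(stays_b)
    ka <- sum(stays_a[[col]]); kb <- sum(stays_b[[col]])
    ct <- tryCatch(contingency_test(ka, na - ka, kb, nb - kb),
                   error = function(e) list(p_two_sided = NA_real_))
    tibble::tibble(
      outcome = name, type = "proportion",
      control_n = na, control_value = ka,
      control_spread = percent_from_counts(ka, na),
      intervention_n = nb, intervention_value = kb,
      intervention_spread = percent_from_counts(kb, nb),
      p_value = ct$p_two_sided)
  }
  dplyr::bind_rows(
    cont("hospital_los_days", "hospital_los_days"),
    cont("hdu_los_days", "hdu_los_days"),
    prop("in_hospital_death", "in_hospital_death"),
    prop("death_within_28d", "death_within_28d"),
    prop("icu_readmission", "icu_readmitted"))
}

#' @export
print.mews_comparison <- function(x, ...) {
  cat("MEWS arm comparison (policy:", x$policy, ")\n\n")
  s <- x$adherence_summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-26s %5d assessments, %5d complete (%.1f%%), adherence %s\n",
                s$group[i], s$n_assessments[i], s$n_complete[i],
                s$completeness_pct[i],
                ifelse(is.na(s$adherence_pct[i]), "NA",
                       sprintf("%d/%d (%.1f%%)", s$n_adherent[i],
                               s$n_evaluable[i], s$adherence_pct[i]))))
  }
  cat("\n  tests:\n")
  t <- x$adherence_tests
  for (i in seq_len(nrow(t))) {
    cat(sprintf("    %s [%s]: p = %.3g\n", t$comparison[i], t$outcome[i],
                t$p[i]))
  }
  invisible(x)
}

#' Write the comparison report tables
#'
#' Writes `adherence_summary.csv`, `missingness.csv`, `intervals.csv` (the
#' three-panel interval table: per stratum N, median, IQR, p, Z) and
#' `outcomes.csv` into a directory.
#'
#' @param report A `mews_comparison` from [compare_arms()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$adherence_summary,
            file.path(dir, "adherence_summary.csv"), row.names = FALSE)
  write.csv(report$missingness, file.path(dir, "missingness.csv"),
            row.names = FALSE)
  write.csv(report$intervals, file.path(dir, "intervals.csv"),
            row.names = FALSE)
  write.csv(report$outcomes, file.path(dir, "outcomes.csv"),
            row.names = FALSE)
  write.csv(report$hourly, file.path(dir, "hourly_pattern.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Plot helpers for the comparison report
#'
#' Bar charts of the 24-hour assessment pattern and of per-element
#' missingness. Requires ggplot2.
#'
#' @param report A `mews_comparison`.
#' @return A ggplot object.
#' @export
plot_hourly_pattern <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(report$hourly,
                  ggplot2::aes(x = .data$hour, y = .data$n,
                               fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "hour of day", y = "assessments",
                  title = "24-hour pattern of MEWS assessments")
}

#' @rdname plot_hourly_pattern
#' @export
plot_missingness <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- report$missingness[report$missingness$group %in%
                            c("control", "intervention"), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$element,
                                  y = .data$percent_missing,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "% of assessments missing the element", x = NULL,
                  title = "Missing MEWS elements")
}
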