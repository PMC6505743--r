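#' Pipeline runners
#'
#' Thin orchestration over the package's stages, mirroring the analysis
#' workflow: `run_simulate()` generates a synthetic cohort and writes its
#' files; `run_audit()` reads recordings and stays, builds assessments,
#' audits them against the response protocol and writes the audit tables;
#' `run_compare()` reads two audited datasets and writes the arm-comparison
#' report. Every run writes a machine-readable `manifest.json` (package
#' version, seed where applicable, input digests, row counts per stage) so
#' reruns are reconstructible, and removes its partial outputs on failure.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the main objects produced by the stage.
#' @name pipeline
NULL

run_manifest <- function(out_dir, entries) {
  manifest <- c(
    list(package = "mewsaudit",
         version = as.character(utils::packageVersion("mewsaudit")),
         generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

input_digests <- function(paths) {
  as.list(tools::md5sum(paths))
}

with_output_cleanup <- function(out_dir, files, expr) {
  tryCatch(expr, error = function(e) {
    unlink(file.path(out_dir, files))
    stop(e)
  })
}

#' @rdname pipeline
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("recordings.csv", "stays.csv", "ground_truth.yaml",
             "ground_truth_events.csv", "manifest.json")
  with_output_cleanup(out_dir, files, {
    cohort <- generate_cohort(config)
    write_recordings(cohort$recordings, file.path(out_dir, "recordings.csv"))
    write_stays(cohort$stays, file.path(out_dir, "stays.csv"))
    yaml::write_yaml(
      list(seed = config$seed,
           missingness = apply(cohort$truth$missingness, 1, as.list,
                               simplify = FALSE),
           compliance = as.list(cohort$truth$compliance),
           automated_fraction = cohort$truth$automated_fraction),
      file.path(out_dir, "ground_truth.yaml"))
    ev <- cohort$truth$events
    ev$event_time <- format_timestamp(ev$event_time)
    write.csv(ev, file.path(out_dir, "ground_truth_events.csv"),
              row.names = FALSE)
    message(sprintf("simulated %d stays, %d recordings (seed %d)",
                    nrow(cohort$stays), nrow(cohort$recordings), config$seed))
    run_manifest(out_dir, list(
      stage = "simulate", seed = config$seed,
      n_control = config$n_control, n_intervention = config$n_intervention,
      rows = list(stays = nrow(cohort$stays),
                  recordings = nrow(cohort$recordings),
                  truth_events = nrow(cohort$truth$events))))
    invisible(cohort)
  })
}

#' @rdname pipeline
#' @param recordings_path,stays_path Input CSV paths.
#' @param window_minutes Assessment window, see [build_assessments()].
#' @param policy Denominator policy, see [audit_stay()].
#' @param table_path Optional scoring-table YAML (defaults to the built-in
#'   card).
#' @param quartile_rule Quartile convention, see [median_iqr()].
#' @export
run_audit <- function(recordings_path, stays_path, out_dir,
                      window_minutes = 15,
                      policy = c("exclude_terminal", "terminal_nonadherent"),
                      table_path = NULL,
                      quartile_rule = c("tukey", "linear")) {
  policy <- match.arg(policy)
  quartile_rule <- match.arg(quartile_rule)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("assessments.csv", "audit.csv", "strata.csv", "stays.csv",
             "manifest.json")
  with_output_cleanup(out_dir, files, {
    table <- if (is.null(table_path)) default_scoring_table() else
      read_scoring_table(table_path)
    recordings <- read_recordings(recordings_path)
    stays <- read_stays(stays_path)
    assessments <- build_assessments(recordings, window_minutes, table)
    verdicts <- audit_cohort(assessments, policy = policy)
    strata <- interval_strata(assessments, quartile_rule = quartile_rule)
    write_assessments(assessments, file.path(out_dir, "assessments.csv"))
    write_audit(verdicts, file.path(out_dir, "audit.csv"))
    write.csv(strata, file.path(out_dir, "strata.csv"), row.names = FALSE)
    write_stays(stays, file.path(out_dir, "stays.csv"))
    message(sprintf(
      "audited %d recordings -> %d assessments (%d complete), adherence %.1f%%",
      nrow(recordings), nrow(assessments), sum(assessments$complete),
      100 * adherence_rate(verdicts)))
    run_manifest(out_dir, list(
      stage = "audit", window_minutes = window_minutes, policy = policy,
      inputs = input_digests(c(recordings_path, stays_path)),
      rows = list(recordings = nrow(recordings),
                  assessments = nrow(assessments),
                  verdicts = nrow(verdicts))))
    invisible(list(assessments = assessments, verdicts = verdicts,
                   strata = strata, stays = stays))
  })
}

#' @rdname pipeline
#' @param dir_control,dir_intervention Directories produced by [run_audit()]
#'   (each holding `assessments.csv` and `stays.csv`).
#' @export
run_compare <- function(dir_control, dir_intervention, out_dir,
                        policy = c("exclude_terminal", "terminal_nonadherent"),
                        quartile_rule = c("tukey", "linear")) {
  policy <- match.arg(policy)
  quartile_rule <- match.arg(quartile_rule)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("adherence_summary.csv", "missingness.csv", "intervals.csv",
             "outcomes.csv", "hourly_pattern.csv", "manifest.json")
  with_output_cleanup(out_dir, files, {
    a_ctrl <- read_assessments(file.path(dir_control, "assessments.csv"))
    a_int <- read_assessments(file.path(dir_intervention, "assessments.csv"))
    s_ctrl <- read_stays(file.path(dir_control, "stays.csv"))
    s_int <- read_stays(file.path(dir_intervention, "stays.csv"))
    report <- compare_arms(a_ctrl, a_int, s_ctrl, s_int,
                           policy = policy, quartile_rule = quartile_rule)
    write_report(report, out_dir)
    message(sprintf(
      "compared arms: control adherence %.1f%%, intervention %.1f%%",
      report$adherence_summary$adherence_pct[1],
      report$adherence_summary$adherence_pct[2]))
    run_manifest(out_dir, list(
      stage = "compare", policy = policy,
      inputs = input_digests(c(
        file.path(dir_control, c("assessments.csv", "stays.csv")),
        file.path(dir_intervention, c("assessments.csv", "stays.csv")))),
      rows = list(control_assessments = nrow(a_ctrl),
                  intervention_assessments = nrow(a_int))))
    invisible(report)
  })
}

#' Read an exported assessments table
#'
#' Parses `assessments.csv` as written by [write_assessments()] back into
#' the in-memory assessments representation.
#'
#' @param path File path.
#' @return Assessments tibble.
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) return(empty_assessments())
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    patient_id = raw$patient_id, arm = raw$arm,
    anchor_time = parse_timestamp(raw$anchor_time),
    source_label = raw$source_label,
    n_recordings = as.integer(raw$n_recordings),
    n_superseded = as.integer(raw$n_superseded),
    mews_total = as.integer(raw$mews_total),
    complete = as_logical01(raw$complete),
    spo2_oxygen = as_logical01(raw$spo2_oxygen))
  for (el in tolower(element_kinds())) out[[el]] <- num(raw[[el]])
  out
}
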