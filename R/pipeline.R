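# End-to-end orchestration: simulate (or load) -> validate -> cohorts ->
# rates -> episodes/courses -> survival -> reports.

#' Run the full analysis pipeline
#'
#' @param bundle A `claims_bundle`, or `NULL` to simulate one.
#' @param gc A [generator_config()] used when `bundle` is `NULL`.
#' @param out_dir Optional directory: bundle, truth (when simulated), cohort,
#'   rates, courses and reports are written there as CSV.
#' @return A list: `bundle`, `truth` (when simulated), `cohorts`, `rates`
#'   (annual prevalence/incidence plus the pooled person-year rate),
#'   `courses`, `km` (per index drug and overall), `reports`.
#' @export
run_pipeline <- function(bundle = NULL, gc = generator_config(), out_dir = NULL) {
  truth <- NULL
  if (is.null(bundle)) {
    sim <- generate_bundle(gc)
    bundle <- sim$bundle
    truth <- sim$truth
  }
  cfg <- bundle$config
  viol <- validate_bundle(bundle)
  if (nrow(viol)) {
    warn(paste0("bundle has ", nrow(viol), " invariant violation(s)"))
  }

  cohorts <- build_cohorts(bundle)
  years <- sort(unique(bundle$denominators$year))
  rates <- dplyr::bind_rows(
    purrr::map_dfr(years, function(y) {
      annual_prevalence(cohorts$prevalent, bundle$denominators, y, config = cfg,
                        diagnoses = bundle$diagnoses)
    }),
    purrr::map_dfr(years, function(y) {
      annual_incidence_proportion(cohorts$prevalent, bundle$denominators, y,
                                  config = cfg)
    }),
    overall_incidence_rate(cohorts$prevalent, bundle$denominators,
                           window = years, config = cfg)
  )

  courses <- build_courses(bundle, cohorts$incident)
  km <- list()
  if (nrow(courses)) {
    km$all <- km_fit(courses$event_time_days, courses$event)
    km <- c(km, purrr::map(
      split(courses, courses$index_drug),
      ~ km_fit(.x$event_time_days, .x$event)
    ))
  }

  reports <- build_reports(cohorts$incident, courses, rates = rates, config = cfg)

  if (!is.null(out_dir)) {
    write_bundle(bundle, file.path(out_dir, "bundle"))
    if (!is.null(truth)) export_truth(truth, file.path(out_dir, "truth"))
    readr::write_csv(cohorts$prevalent, file.path(out_dir, "cohort.csv"),
                     progress = FALSE)
    readr::write_csv(cohorts$flowchart, file.path(out_dir, "flowchart.csv"),
                     progress = FALSE)
    readr::write_csv(rates, file.path(out_dir, "rates.csv"), progress = FALSE)
    if (nrow(courses)) {
      readr::write_csv(courses, file.path(out_dir, "courses.csv"), progress = FALSE)
    }
    write_reports(reports, file.path(out_dir, "reports"))
  }

  list(bundle = bundle, truth = truth, cohorts = cohorts, rates = rates,
       courses = courses, km = km, reports = reports)
}
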