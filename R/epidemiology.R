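# Annual prevalence, annual incidence proportion, overall person-year
# incidence rate, and stratified rates.  All rates are crude (no age
# standardisation) and reported per 100,000.

rate_row <- function(numerator, denominator, year = NA_integer_,
                     age_group = "all", sex = "all",
                     measure = "rate") {
  if (any(denominator <= 0)) abort("rate denominator must be positive")
  tibble::tibble(
    measure = measure, year = as.integer(year), age_group = as.character(age_group),
    sex = as.character(sex), numerator = as.numeric(numerator),
    denominator = as.numeric(denominator),
    rate = 1e5 * as.numeric(numerator) / as.numeric(denominator)
  )
}

# members of `cohort` contributing to the prevalence numerator of `year`
prevalent_in_year <- function(cohort, year, config) {
  y_start <- as.Date(sprintf("%d-01-01", year))
  y_end <- as.Date(sprintf("%d-01-01", year + 1))
  diagnosed <- cohort$index_date < y_end
  enrolled <- cohort$followup_end >= y_start
  # age-eligible at some point during the year: cutoff birthday after year start
  under_cut <- (cohort$birth_date + round(config$age_cutoff * 365.25)) > y_start
  diagnosed & enrolled & under_cut
}

#' Annual prevalence of diagnosed JIA
#'
#' Numerator: cohort members diagnosed on or before the year who are still
#' enrolled and age-eligible during it (`prevalence_mode = "cumulative"`), or
#' additionally have at least one JIA claim in the year
#' (`"active_claim"`, requires `diagnoses`).  Denominator: the under-16
#' population of that year.
#'
#' @param cohort Prevalent cohort tibble from [build_cohorts()].
#' @param denominators Denominator tibble (`year`, `age_group`, `sex`,
#'   `person_count`, `person_years`).
#' @param year Calendar year.
#' @param config A [claims_config()].
#' @param diagnoses Diagnosis events, only needed for `"active_claim"` mode.
#' @return A one-row rate tibble (rate per 100,000).
#' @export
annual_prevalence <- function(cohort, denominators, year,
                              config = claims_config(), diagnoses = NULL) {
  den <- denominators[denominators$year == year, , drop = FALSE]
  if (!nrow(den)) abort(paste0("no denominator for year ", year))
  in_year <- prevalent_in_year(cohort, year, config)
  if (config$prevalence_mode == "active_claim") {
    if (is.null(diagnoses)) abort("active_claim prevalence needs `diagnoses`")
    y_start <- as.Date(sprintf("%d-01-01", year))
    y_end <- as.Date(sprintf("%d-01-01", year + 1))
    active <- diagnoses |>
      dplyr::filter(.data$dx_group == "JIA", .data$date >= y_start,
                    .data$date < y_end) |>
      dplyr::distinct(.data$person_id)
    in_year <- in_year & cohort$person_id %in% active$person_id
  }
  rate_row(sum(in_year), sum(den$person_count), year = year,
           measure = "prevalence")
}

#' Annual incidence proportion
#'
#' Numerator: incident members whose index date falls in the year.
#' Denominator: the under-16 population of the year minus those already
#' diagnosed before the year and still age-eligible (the population at risk).
#'
#' @inheritParams annual_prevalence
#' @param cohort Prevalent cohort tibble (used both for the incident numerator
#'   and to subtract the previously diagnosed from the denominator).
#' @return A one-row rate tibble (per 100,000 at-risk population).
#' @export
annual_incidence_proportion <- function(cohort, denominators, year,
                                        config = claims_config()) {
  den <- denominators[denominators$year == year, , drop = FALSE]
  if (!nrow(den)) abort(paste0("no denominator for year ", year))
  y_start <- as.Date(sprintf("%d-01-01", year))
  y_end <- as.Date(sprintf("%d-01-01", year + 1))
  new_cases <- sum(cohort$incident & cohort$index_date >= y_start &
                     cohort$index_date < y_end)
  prior <- prevalent_in_year(cohort, year, config) & cohort$index_date < y_start
  at_risk <- sum(den$person_count) - sum(prior)
  rate_row(new_cases, at_risk, year = year, measure = "incidence_proportion")
}

#' Overall incidence rate per 100,000 person-years
#'
#' @inheritParams annual_prevalence
#' @param window Integer vector of calendar years to pool (default 2012-2019).
#' @return A one-row rate tibble (per 100,000 person-years).
#' @export
overall_incidence_rate <- function(cohort, denominators, window = 2012:2019,
                                   config = claims_config()) {
  den <- denominators[denominators$year %in% window, , drop = FALSE]
  py <- sum(den$person_years)
  if (py <= 0) abort("no person-years in denominator window")
  yrs <- as.integer(format(cohort$index_date, "%Y"))
  n <- sum(cohort$incident & yrs %in% window)
  out <- rate_row(n, py, measure = "incidence_rate")
  out$year <- NA_integer_
  out
}

#' Age/sex-stratified prevalence or incidence
#'
#' Partitions numerator and denominator by the requested strata; stratum
#' numerators sum to the marginal numerator.
#'
#' @inheritParams annual_prevalence
#' @param by Subset of `c("year", "age_group", "sex")`.
#' @param measure `"prevalence"` or `"incidence_proportion"`.
#' @param years Years to cover (default: all denominator years).
#' @return A rate tibble with one row per stratum.
#' @export
stratified_rates <- function(cohort, denominators,
                             by = c("year", "sex"),
                             measure = c("prevalence", "incidence_proportion"),
                             years = sort(unique(denominators$year)),
                             config = claims_config()) {
  measure <- match.arg(measure)
  by <- match.arg(by, c("year", "age_group", "sex"), several.ok = TRUE)

  num <- purrr::map_dfr(years, function(y) {
    keep <- if (measure == "prevalence") {
      prevalent_in_year(cohort, y, config)
    } else {
      cohort$incident & as.integer(format(cohort$index_date, "%Y")) == y
    }
    m <- cohort[keep, , drop = FALSE]
    m$year <- y
    # age group at index for incidence; current-year age for prevalence
    if (measure == "prevalence") {
      mid <- as.Date(sprintf("%d-07-01", y))
      m$age_group <- as.character(age_group_of(
        pmin(completed_years(m$birth_date, mid), 15L)))
    } else {
      m$age_group <- as.character(m$age_group)
    }
    m
  })

  den <- denominators |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(denominator = sum(.data$person_count), .groups = "drop")

  counts <- num |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(numerator = dplyr::n(), .groups = "drop")

  out <- den |>
    dplyr::left_join(counts, by = by) |>
    dplyr::mutate(numerator = dplyr::coalesce(.data$numerator, 0L))
  if (any(out$denominator <= 0 & out$numerator > 0)) {
    abort("stratum with zero denominator but nonzero numerator")
  }
  out <- out[out$denominator > 0, , drop = FALSE]
  out |>
    dplyr::mutate(measure = measure,
                  rate = 1e5 * .data$numerator / .data$denominator) |>
    dplyr::select("measure", dplyr::all_of(by), "numerator", "denominator", "rate")
}

#' Plot annual prevalence or incidence with onset-age composition bars
#'
#' A line for the annual rate overlaid on stacked bars giving the share of the
#' three onset-age categories per year.
#'
#' @param rates Rate tibble with columns `year` and `rate` (one row per year).
#' @param age_shares Optional tibble with `year`, `age_group`, `numerator` as
#'   produced by [stratified_rates()] with `by = c("year", "age_group")`.
#' @return A ggplot object.
#' @export
plot_annual_rates <- function(rates, age_shares = NULL) {
  p <- ggplot2::ggplot(rates, ggplot2::aes(x = .data$year, y = .data$rate))
  if (!is.null(age_shares)) {
    shares <- age_shares |>
      dplyr::group_by(.data$year) |>
      dplyr::mutate(share = .data$numerator / sum(.data$numerator) *
                      max(rates$rate)) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_col(
      data = shares,
      ggplot2::aes(y = .data$share, fill = .data$age_group),
      alpha = 0.5, position = "stack"
    )
  }
  p +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "Rate per 100,000",
                  fill = "Onset age (scaled share)") +
    ggplot2::theme_minimal()
}
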