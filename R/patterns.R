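# The biologic treatment-pattern state machine.
#
# The first fill of an eligible biologic (etanercept, adalimumab, tocilizumab;
# abatacept is excluded as an index drug but counts as a switch target) anchors
# the course.  Episodes are built with the 60-day biologic grace; the first
# qualifying event after the index start fixes the terminal pattern:
#   switching        another biologic first filled on/before index episode
#                    end + 60 d (overlap with the index episode counts, gap 0)
#   restart          no biologic within 60 d of the index episode end, but a
#                    biologic (same or different) filled later
#   discontinuation  no biologic after the index episode, and the 60-day gap
#                    closes before follow-up ends
#   continuation     the index episode persists to within 60 d of follow-up end

#' Find the index biologic
#'
#' Earliest fill among the eligible index biologics; ties on the same date are
#' broken by larger days supply, then alphabetically.
#'
#' @param fills Prescription fills for one person (any drug).
#' @param config A [claims_config()].
#' @return A one-row tibble (`drug_name`, `index_start`), or `NULL` when the
#'   person has no eligible biologic fill.
#' @export
find_index_biologic <- function(fills, config = claims_config()) {
  el <- fills[fills$drug_name %in% config$index_biologics, , drop = FALSE]
  if (!nrow(el)) return(NULL)
  el <- el[order(el$fill_date, -el$days_supply, el$drug_name), , drop = FALSE]
  tibble::tibble(drug_name = el$drug_name[1], index_start = el$fill_date[1])
}

#' Classify one biologic treatment course
#'
#' @param episodes Biologic exposure episodes for one person (from
#'   [build_episodes()] with the biologic grace), columns `drug_name`,
#'   `start`, `end`.
#' @param index_drug,index_start Index biologic and its first fill date.
#' @param followup_end Last day of follow-up.
#' @param config A [claims_config()].
#' @return A one-row tibble: `index_drug`, `index_start`, `index_episode_end`,
#'   `pattern`, `switch_subtype`, `restart_drug_same`, `gap_to_restart_days`,
#'   `event_time_days`, `event`.
#' @export
classify_course <- function(episodes, index_drug, index_start, followup_end,
                            config = claims_config()) {
  grace <- config$grace_biologic
  own <- episodes[episodes$drug_name == index_drug &
                    episodes$start <= index_start & episodes$end > index_start, ,
                  drop = FALSE]
  if (nrow(own) != 1) abort("no index episode containing index_start")
  idx_end <- own$end[1]

  later <- episodes[episodes$start >= index_start &
                      !(episodes$drug_name == index_drug &
                          episodes$start <= index_start), , drop = FALSE]
  later <- later[order(later$start), , drop = FALSE]

  other <- later[later$drug_name != index_drug, , drop = FALSE]
  pattern <- switch_subtype <- NA_character_
  restart_same <- NA
  gap_restart <- NA_integer_

  if (nrow(other) && other$start[1] <= idx_end + grace) {
    pattern <- "switching"
    switch_subtype <- "within_gap"
    event_date <- other$start[1]
  } else {
    after_gap <- later[later$start > idx_end + grace, , drop = FALSE]
    if (nrow(after_gap)) {
      pattern <- "restart"
      restart_same <- after_gap$drug_name[1] == index_drug
      switch_subtype <- if (restart_same) "none" else "after_interruption"
      gap_restart <- as.integer(after_gap$start[1] - idx_end)
      event_date <- idx_end
    } else if (idx_end + grace < followup_end) {
      pattern <- "discontinuation"
      switch_subtype <- "none"
      event_date <- idx_end
    } else {
      pattern <- "continuation"
      switch_subtype <- "none"
      event_date <- followup_end
    }
  }

  if (config$event_definition == "index_stop_or_switch") {
    event <- as.integer(pattern != "continuation")
    etime <- if (pattern == "continuation") followup_end else event_date
  } else {
    event <- as.integer(pattern == "discontinuation")
    etime <- if (pattern == "discontinuation") event_date else followup_end
  }

  tibble::tibble(
    index_drug = index_drug, index_start = index_start,
    index_episode_end = idx_end, pattern = pattern,
    switch_subtype = switch_subtype, restart_drug_same = restart_same,
    gap_to_restart_days = gap_restart,
    event_time_days = max(1L, as.integer(etime - index_start)),
    event = event
  )
}

#' Time landmarks of a course
#'
#' @param course One-row course tibble from [classify_course()].
#' @param diagnosis_date Index JIA diagnosis date (must not follow the index
#'   biologic start).
#' @return The course with `time_to_index_years` and `index_duration_years`
#'   added (years = days / 365.25; duration covers the index episode only).
#' @export
course_times <- function(course, diagnosis_date) {
  if (diagnosis_date > course$index_start) {
    abort("diagnosis_date must be on or before index_start")
  }
  course$time_to_index_years <-
    as.numeric(course$index_start - diagnosis_date) / 365.25
  course$index_duration_years <-
    as.numeric(course$index_episode_end - course$index_start) / 365.25
  course
}

#' Build classified treatment courses for a cohort
#'
#' Runs index-drug detection, 60-day episode construction, pattern
#' classification and csDMARD-combination flags for every cohort member with
#' an eligible biologic fill.
#'
#' @param bundle A `claims_bundle`.
#' @param cohort Cohort tibble from [build_cohorts()] (typically the incident
#'   cohort).
#' @return A tibble with one classified course per biologic user.
#' @export
build_courses <- function(bundle, cohort) {
  cfg <- bundle$config
  bio <- bundle$prescriptions |>
    dplyr::filter(.data$drug_class == "biologic") |>
    dplyr::semi_join(cohort, by = "person_id")
  if (!nrow(bio)) return(empty_courses())
  csd <- bundle$prescriptions |>
    dplyr::filter(.data$drug_class == "csDMARD") |>
    dplyr::semi_join(cohort, by = "person_id")

  episodes <- build_episodes(bio, grace = cfg$grace_biologic, by = "drug_name")

  member <- cohort |>
    dplyr::select("person_id", "index_date", "followup_end", "subgroup")

  courses <- bio |>
    dplyr::group_by(.data$person_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(fills) {
      pid <- fills$person_id[1]
      idx <- find_index_biologic(fills, config = cfg)
      if (is.null(idx)) return(NULL)
      m <- member[member$person_id == pid, , drop = FALSE]
      eps <- episodes[episodes$person_id == pid, , drop = FALSE]
      course <- classify_course(eps, idx$drug_name, idx$index_start,
                                m$followup_end[1], config = cfg)
      course <- course_times(course, min(m$index_date[1], idx$index_start))
      comb <- combination_csdmard(fills, csd[csd$person_id == pid, , drop = FALSE],
                                  idx$index_start)
      course$person_id <- pid
      course$subgroup <- m$subgroup[1]
      course$followup_end <- m$followup_end[1]
      course$comb_first_year <- comb$first_year
      course$comb_after_first_year <- comb$after_first_year
      course
    })
  dplyr::relocate(courses, "person_id")
}

empty_courses <- function() {
  tibble::tibble(
    person_id = character(), index_drug = character(),
    index_start = as.Date(character()), index_episode_end = as.Date(character()),
    pattern = character(), switch_subtype = character(),
    restart_drug_same = logical(), gap_to_restart_days = integer(),
    event_time_days = integer(), event = integer(),
    time_to_index_years = numeric(), index_duration_years = numeric(),
    subgroup = character(), followup_end = as.Date(character()),
    comb_first_year = logical(), comb_after_first_year = logical()
  )
}

#' Tabulate treatment patterns
#'
#' Four-way pattern counts and percentages per index drug (or overall).
#' Switches after an interruption are already folded into `restart` by the
#' classifier; the subtype column retains the detail.
#'
#' @param courses Course tibble from [build_courses()].
#' @param by_drug Tabulate per index drug (default) or overall.
#' @return A tibble with `index_drug`, `pattern`, `n`, `pct` (percent of that
#'   drug's initiators, one decimal).
#' @export
tabulate_patterns <- function(courses, by_drug = TRUE) {
  pats <- c("continuation", "switching", "restart", "discontinuation")
  grp <- if (by_drug) "index_drug" else character()
  courses |>
    dplyr::mutate(pattern = factor(.data$pattern, levels = pats)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::count(.data$pattern, .drop = FALSE) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pattern = as.character(.data$pattern))
}

#' Plot treatment-pattern composition per index biologic
#'
#' @param pattern_tab Output of [tabulate_patterns()].
#' @return A ggplot object (stacked percentage bars).
#' @export
plot_patterns <- function(pattern_tab) {
  ggplot2::ggplot(pattern_tab,
                  ggplot2::aes(x = .data$index_drug, y = .data$pct,
                               fill = .data$pattern)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "Index biologic", y = "% of initiators",
                  fill = "Pattern") +
    ggplot2::theme_minimal()
}
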