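# Exposure-episode construction.
#
# Each fill covers the half-open interval [fill_date, fill_date + days_supply).
# Fills merge into one episode while the gap between the running coverage end
# and the next fill date does not exceed the class grace period (14 d for
# NSAIDs/steroids/csDMARDs, 60 d for biologics).  Overlapping fills extend
# coverage from the maximum end; overlapped supply is not stockpiled.

#' Merge prescription fills into exposure episodes
#'
#' @param fills Data frame of fills with columns `person_id`, `fill_date`,
#'   `days_supply` and a grouping column selected by `by` (default
#'   `drug_name`). Need not be sorted.
#' @param grace Grace period in days: a new fill extends the current episode
#'   iff `fill_date <= episode_end + grace`.
#' @param by Column(s) defining one drug stream per person (use
#'   `"drug_class"` to merge, e.g., all NSAIDs into one stream).
#' @return A tibble of episodes: `person_id`, the `by` columns, `start`,
#'   `end` (half-open), `n_fills`, `covered_days` (days covered by at least
#'   one fill; grace-period holes are not covered).
#' @export
build_episodes <- function(fills, grace, by = "drug_name") {
  stopifnot(is.data.frame(fills))
  if (!nrow(fills)) {
    out <- tibble::tibble(person_id = character(), start = as.Date(character()),
                          end = as.Date(character()), n_fills = integer(),
                          covered_days = integer())
    for (b in rev(by)) out <- tibble::add_column(out, !!b := character(), .after = 1)
    return(out)
  }
  if (any(fills$days_supply < 1)) abort("days_supply must be >= 1")
  grace <- as.integer(grace)
  stopifnot(grace >= 0)

  fills |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("person_id", by)))) |>
    dplyr::arrange(.data$fill_date, .by_group = TRUE) |>
    dplyr::group_modify(~ merge_one_stream(.x, grace)) |>
    dplyr::ungroup()
}

# one person x one drug stream, fills sorted by date
merge_one_stream <- function(fills, grace) {
  start <- as.numeric(fills$fill_date)
  end <- start + fills$days_supply
  cm_end <- cummax(end)
  # episode break when this fill starts more than `grace` past running coverage
  new_episode <- c(TRUE, start[-1] > head(cm_end, -1) + grace)
  ep <- cumsum(new_episode)
  # covered days: sorted starts => incremental union against the running max
  # end (episodes never reach back past a break, so resetting at breaks is
  # enough to keep the union per-episode)
  prev_cov <- c(-Inf, head(cm_end, -1))
  prev_cov[new_episode] <- -Inf
  covered <- pmax(0, end - pmax(start, prev_cov))
  tibble::tibble(
    start = as.Date(unname(tapply(start, ep, min)), origin = "1970-01-01"),
    end = as.Date(unname(tapply(end, ep, max)), origin = "1970-01-01"),
    n_fills = as.integer(tabulate(ep)),
    covered_days = as.integer(unname(tapply(covered, ep, sum)))
  )
}

#' Chronic medications for one patient
#'
#' A drug counts as a chronic treatment when at least one grace-merged episode
#' spans `chronic_days` or more ("used for more than three consecutive
#' months"), measured on the episode span `end - start`.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param chronic_days Threshold in days (default 90).
#' @param by Column naming the drug (default `drug_name`).
#' @return Character vector of chronic drug names (possibly empty).
#' @export
chronic_medications <- function(episodes, chronic_days = 90L, by = "drug_name") {
  if (!nrow(episodes)) return(character())
  span <- as.numeric(episodes$end - episodes$start)
  sort(unique(episodes[[by]][span >= chronic_days]))
}

#' csDMARD combination during biologic treatment
#'
#' A period is flagged when at least one csDMARD fill shares a `visit_id` with
#' a biologic fill whose fill date lies inside the period.  The first year is
#' `[index_start, index_start + 365)`; "after" is from day 365 onward.
#'
#' @param biologic_fills,csdmard_fills Fill tibbles with `fill_date`, `visit_id`.
#' @param index_start Date the index biologic starts.
#' @return A list with logical elements `first_year` and `after_first_year`.
#' @export
combination_csdmard <- function(biologic_fills, csdmard_fills, index_start) {
  if (!nrow(biologic_fills) || !nrow(csdmard_fills)) {
    return(list(first_year = FALSE, after_first_year = FALSE))
  }
  shared <- biologic_fills$visit_id %in% csdmard_fills$visit_id &
    !is.na(biologic_fills$visit_id)
  dates <- biologic_fills$fill_date[shared]
  list(
    first_year = any(dates >= index_start & dates < index_start + 365),
    after_first_year = any(dates >= index_start + 365)
  )
}
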