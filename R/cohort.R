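# Cohort assembly: the four-part case definition, the incident (new-user)
# restriction with the pre-2012 washout, and SpA-feature subgrouping.

#' Earliest date at which the diagnosis-code criterion is met
#'
#' The case definition is at least one inpatient JIA code, or three outpatient
#' JIA codes (distinct service dates) spanning no more than 365 days.  Returns
#' the earliest date at which either arm is satisfied: the first inpatient
#' date, or the date of the third outpatient code of the first qualifying
#' triple, whichever is earlier.
#'
#' @param dx Data frame of JIA diagnosis events (`date`, `setting`), sorted by
#'   date.
#' @return A `Date` of length 1, or `NA` if the criterion is never met.
#' @export
qualify_case <- function(dx) {
  if (!nrow(dx)) return(as.Date(NA))
  if (is.unsorted(dx$date)) abort("diagnosis events must be sorted by date")
  inpt <- dx$date[dx$setting == "inpatient"]
  q_in <- if (length(inpt)) min(inpt) else as.Date(NA)
  out_dates <- sort(unique(dx$date[dx$setting == "outpatient"]))
  q_out <- as.Date(NA)
  if (length(out_dates) >= 3) {
    # third code qualifies when the first and third of the triple lie within a
    # 365-day window: date_i - date_{i-2} <= 364 (half-open window of 365 days)
    span <- as.numeric(out_dates[-(1:2)] - head(out_dates, -2))
    hit <- which(span <= 364)
    if (length(hit)) q_out <- out_dates[hit[1] + 2]
  }
  cand <- c(q_in, q_out)
  cand <- cand[!is.na(cand)]
  if (!length(cand)) return(as.Date(NA))
  min(cand)
}

#' NSAID inclusion criterion
#'
#' True when some grace-merged NSAID exposure episode (14-day grace, merged at
#' class level) covers more than 14 days — i.e. at least 15 covered days — and
#' that episode's coverage intersects the 365 days following the first JIA
#' diagnosis (or starts within it, under `nsaid_rule = "start_within"`).
#'
#' @param fills NSAID prescription fills for one person.
#' @param first_dx_date Date of the first JIA diagnosis.
#' @param config A [claims_config()].
#' @return Logical scalar.
#' @export
nsaid_criterion <- function(fills, first_dx_date, config = claims_config()) {
  if (!nrow(fills)) return(FALSE)
  fills <- tibble::as_tibble(fills)
  if (!"person_id" %in% names(fills)) fills$person_id <- "-"
  fills$.stream <- "NSAID"
  eps <- build_episodes(fills, grace = config$grace_small_molecule, by = ".stream")
  eps <- eps[eps$covered_days >= config$nsaid_min_covered_days, , drop = FALSE]
  if (!nrow(eps)) return(FALSE)
  win_start <- first_dx_date
  win_end <- first_dx_date + 365
  if (config$nsaid_rule == "start_within") {
    return(any(eps$start >= win_start & eps$start < win_end))
  }
  any(eps$start < win_end & eps$end > win_start)
}

#' Classify a patient's spondyloarthritis-feature subgroup
#'
#' SpA when any spondyloarthritis-feature code (ankylosing spondylitis,
#' sacroiliitis, other inflammatory spondylopathies, psoriatic arthropathy)
#' appears in the patient's record; with `spa_same_day = TRUE` the feature code
#' must share a service date with a JIA code.
#'
#' @param dx All diagnosis events for the person (any `dx_group`).
#' @param config A [claims_config()].
#' @return `"SpA"` or `"non_SpA"`.
#' @export
classify_subgroup <- function(dx, config = claims_config()) {
  spa_dates <- dx$date[dx$dx_group == "SpA_feature"]
  if (!length(spa_dates)) return("non_SpA")
  if (config$spa_same_day) {
    jia_dates <- dx$date[dx$dx_group == "JIA"]
    if (!any(spa_dates %in% jia_dates)) return("non_SpA")
  }
  "SpA"
}

#' Build the prevalent and incident cohorts
#'
#' Inclusion (prevalent cohort): (1) diagnosis-code criterion met with the
#' index (first) JIA code inside the identification window — the 365-day
#' qualification window may extend to the end of claims coverage; (2) an
#' enrollment interval overlapping the identification window; (3) age under
#' the cutoff at index; (4) the NSAID criterion within 365 days after the
#' first diagnosis.  The incident cohort additionally requires no JIA code
#' before the identification window starts (the pre-2012 history is the
#' washout the data permits).
#'
#' @param bundle A validated `claims_bundle`.
#' @return A list with `prevalent` and `incident` cohort tibbles (one row per
#'   member: `person_id`, `index_date`, `incident`, `age_at_index`, `sex`,
#'   `birth_date`, `subgroup`, `followup_end`, `uveitis`, `psoriasis`) and a
#'   `flowchart` tibble of per-step exclusion counts.
#' @export
build_cohorts <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  cfg <- bundle$config
  id_win <- bundle$identification_window

  jia_dx <- bundle$diagnoses |>
    dplyr::filter(.data$dx_group == "JIA") |>
    dplyr::arrange(.data$person_id, .data$date)

  steps <- list()
  candidates <- jia_dx |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      first_dx_ever = min(.data$date),
      first_dx_window = suppressWarnings(min(.data$date[.data$date >= id_win[1] &
                                                          .data$date < id_win[2]])),
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(.data$first_dx_window))
  steps$any_jia_code_in_window <- nrow(candidates)

  # (1) diagnosis-code criterion, anchored at the in-window index date
  qual <- jia_dx |>
    dplyr::semi_join(candidates, by = "person_id") |>
    dplyr::left_join(dplyr::select(candidates, "person_id", "first_dx_window"),
                     by = "person_id") |>
    dplyr::filter(.data$date >= .data$first_dx_window) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(qual_date = qualify_case(dplyr::pick("date", "setting")),
                     .groups = "drop") |>
    dplyr::filter(!is.na(.data$qual_date))
  candidates <- dplyr::semi_join(candidates, qual, by = "person_id")
  steps$diagnosis_criterion <- nrow(candidates)

  # (2) enrollment overlapping the identification window
  ben <- dplyr::semi_join(bundle$beneficiaries, candidates, by = "person_id")
  persons <- ben |>
    dplyr::filter(.data$enroll_start < id_win[2], .data$enroll_end > id_win[1]) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(sex = dplyr::first(.data$sex),
                     birth_date = dplyr::first(.data$birth_date),
                     last_enroll_end = max(.data$enroll_end), .groups = "drop")
  candidates <- dplyr::inner_join(candidates, persons, by = "person_id")
  steps$enrollment <- nrow(candidates)

  # (3) age at index under the cutoff
  candidates <- candidates |>
    dplyr::mutate(index_date = .data$first_dx_window,
                  age_at_index = completed_years(.data$birth_date, .data$index_date)) |>
    dplyr::filter(.data$age_at_index < cfg$age_cutoff)
  steps$age_under_cutoff <- nrow(candidates)

  # (4) NSAID criterion
  nsaid <- bundle$prescriptions |>
    dplyr::filter(.data$drug_class == "NSAID") |>
    dplyr::semi_join(candidates, by = "person_id")
  nsaid_ok <- nsaid |>
    dplyr::left_join(dplyr::select(candidates, "person_id", "index_date"),
                     by = "person_id") |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(ok = nsaid_criterion(
      dplyr::pick("fill_date", "days_supply"),
      dplyr::first(.data$index_date), config = cfg), .groups = "drop") |>
    dplyr::filter(.data$ok)
  candidates <- dplyr::semi_join(candidates, nsaid_ok, by = "person_id")
  steps$nsaid_criterion <- nrow(candidates)

  # subgroup + comorbidity flags from the whole record
  dx_flags <- bundle$diagnoses |>
    dplyr::semi_join(candidates, by = "person_id") |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      subgroup = classify_subgroup(dplyr::pick("date", "dx_group"), config = cfg),
      uveitis = any(.data$dx_group == "uveitis"),
      psoriasis = any(.data$dx_group == "psoriasis"),
      .groups = "drop"
    )

  followup_cap <- bundle$study_window[2] - 1  # last covered calendar day

  prevalent <- candidates |>
    dplyr::left_join(dx_flags, by = "person_id") |>
    dplyr::mutate(
      followup_end = pmin(followup_cap, .data$last_enroll_end),
      incident = .data$first_dx_ever >= id_win[1],
      age_group = age_group_of(.data$age_at_index)
    ) |>
    dplyr::select("person_id", "index_date", "incident", "age_at_index",
                  "age_group", "sex", "birth_date", "subgroup", "uveitis",
                  "psoriasis", "followup_end") |>
    dplyr::arrange(.data$person_id)

  incident <- dplyr::filter(prevalent, .data$incident)
  steps$incident_no_prior_history <- nrow(incident)

  flowchart <- tibble::tibble(step = names(steps), n = unlist(steps, use.names = FALSE))
  list(prevalent = prevalent, incident = incident, flowchart = flowchart)
}
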