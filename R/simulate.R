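# Synthetic claims generator with known ground truth.
#
# Emulates the statistical structure of the study population: a closed
# pediatric population observed 2011-2020, a small annual JIA onset hazard,
# an SpA-feature subgroup with male predominance and adolescent onset,
# guideline-shaped treatment trajectories (NSAID induction, chronic csDMARD
# use, biologic uptake with piecewise per-cycle switch/gap hazards), and
# analytically derived population denominators.  A configurable fraction of
# "near-miss" patients fails exactly one inclusion criterion so the cohort
# filters are exercised.

DAYS_16Y <- 5844L  # round(16 * 365.25)

#' Generator configuration
#'
#' Defaults encode the study conditions: onset hazard 5.5/100,000/year, SpA
#' fraction 0.49, subgroup-specific sex and onset-age mixes, biologic uptake
#' about 19% with index-drug shares favouring the TNF-alpha inhibitors, 28-day
#' biologic refill cadence, and per-cycle switch/gap hazards tuned to the
#' observed continuation/switch/restart/discontinuation mix.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_population Number of simulated beneficiaries.
#' @param onset_hazard_per_100k Annual first-onset hazard per 100,000 at-risk
#'   person-years (applied 2011-2019; 2011 onsets become prevalent-only cases).
#' @param spa_fraction Probability a case belongs to the SpA-feature subgroup.
#' @param male_fraction Named vector: male probability by subgroup.
#' @param background_male Male probability among non-cases.
#' @param missing_sex_prob Probability a case's sex is recorded as missing.
#' @param onset_age_probs Per-subgroup probabilities over onset-age groups
#'   0-5 / 6-11 / 12-15.
#' @param uveitis_prob,psoriasis_prob Named vectors by subgroup.
#' @param inpatient_prob Probability the onset carries an inpatient code.
#' @param chronic_probs Named list by subgroup of chronic-use probabilities for
#'   NSAID, methotrexate, sulfasalazine, steroid.
#' @param biologic_prob Named vector: biologic uptake by subgroup.
#' @param index_shares Named list by subgroup: index-drug shares.
#' @param time_to_biologic_meanlog,time_to_biologic_sdlog Log-normal delay
#'   (days) from onset to the index biologic.
#' @param cycle_days,biologic_supply,fill_jitter Biologic refill cadence.
#' @param p_switch_cycle,p_gap_cycle Per-refill-cycle probabilities of a
#'   within-gap switch and of a treatment interruption.
#' @param p_restart_given_gap Probability an interruption is followed by a
#'   restart; `restart_same_prob` the restart reuses the index drug.
#' @param restart_gap_mean Mean extra days (beyond the 61-day minimum) to
#'   restart.
#' @param switch_within_14_prob Share of within-gap switches occurring within
#'   14 days of the index supply end.
#' @param comb_first_year_prob,comb_after_prob Probability of same-visit
#'   csDMARD combination in / after the first biologic year.
#' @param near_miss_fraction Near-miss patients as a fraction of true cases.
#' @param partial_enroll_fraction Beneficiaries with a shortened enrollment
#'   interval.
#' @param config A [claims_config()] supplying windows and code lists.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_population = 20000L,
                             onset_hazard_per_100k = 5.5,
                             spa_fraction = 0.49,
                             male_fraction = c(SpA = 0.71, non_SpA = 0.44),
                             background_male = 0.515,
                             missing_sex_prob = 0.005,
                             onset_age_probs = list(
                               SpA = c(0.008, 0.146, 0.846),
                               non_SpA = c(0.125, 0.357, 0.518)),
                             uveitis_prob = c(SpA = 0.073, non_SpA = 0.030),
                             psoriasis_prob = c(SpA = 0.029, non_SpA = 0),
                             inpatient_prob = 0.10,
                             chronic_probs = list(
                               SpA = c(NSAID = 0.511, methotrexate = 0.250,
                                       sulfasalazine = 0.388, steroid = 0.200),
                               non_SpA = c(NSAID = 0.511, methotrexate = 0.389,
                                           sulfasalazine = 0.160, steroid = 0.278)),
                             biologic_prob = c(SpA = 0.152, non_SpA = 0.231),
                             index_shares = list(
                               SpA = c(etanercept = 0.46, adalimumab = 0.50,
                                       tocilizumab = 0.04),
                               non_SpA = c(etanercept = 0.40, adalimumab = 0.50,
                                           tocilizumab = 0.10)),
                             time_to_biologic_meanlog = log(0.73 * 365.25),
                             time_to_biologic_sdlog = 0.8,
                             cycle_days = 28L,
                             biologic_supply = 28L,
                             fill_jitter = 3L,
                             p_switch_cycle = 0.0036,
                             p_gap_cycle = 0.0067,
                             p_restart_given_gap = 0.75,
                             restart_same_prob = 0.92,
                             restart_gap_mean = 60,
                             switch_within_14_prob = 0.8,
                             comb_first_year_prob = 0.9,
                             comb_after_prob = 0.5,
                             near_miss_fraction = 0.10,
                             partial_enroll_fraction = 0.05,
                             config = claims_config()) {
  probs <- c(spa_fraction, male_fraction, missing_sex_prob, uveitis_prob,
             psoriasis_prob, inpatient_prob, biologic_prob, p_switch_cycle,
             p_gap_cycle, p_restart_given_gap, restart_same_prob,
             switch_within_14_prob, comb_first_year_prob, comb_after_prob,
             near_miss_fraction, partial_enroll_fraction)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (onset_hazard_per_100k < 0 || onset_hazard_per_100k > 1e5) {
    abort("onset hazard must lie in [0, 100000] per 100,000")
  }
  out <- as.list(environment())
  out$probs <- NULL
  structure(out, class = "generator_config")
}

#' Generate a synthetic claims bundle with ground truth
#'
#' @param gc A [generator_config()].
#' @return A list: `bundle` (a valid `claims_bundle`), `truth` (list with
#'   per-person `persons` tibble and cohort-level `annual` rates plus
#'   `overall_incidence_rate`).
#' @export
generate_bundle <- function(gc = generator_config()) {
  stopifnot(inherits(gc, "generator_config"))
  cfg <- gc$config
  set.seed(gc$seed)
  n <- gc$n_population
  win <- cfg$study_window
  id_win <- cfg$identification_window
  followup_cap <- win[2] - 1

  # -- population ------------------------------------------------------------
  birth_lo <- as.Date("1996-01-01"); birth_hi <- as.Date("2020-12-31")
  birth <- birth_lo + floor(runif(n) * (as.numeric(birth_hi - birth_lo) + 1))
  person_id <- sprintf("P%07d", seq_len(n))
  enroll_start <- rep(win[1], n)
  enroll_end <- rep(win[2], n)
  part <- runif(n) < gc$partial_enroll_fraction
  span <- as.numeric(win[2] - win[1])
  ps <- floor(runif(sum(part)) * (span - 730))
  pl <- 365 + floor(runif(sum(part)) * (span - ps - 365))
  enroll_start[part] <- win[1] + ps
  enroll_end[part] <- pmin(win[2], enroll_start[part] + pl)
  enroll_start <- pmax(enroll_start, birth)
  enroll_end <- pmax(enroll_end, enroll_start + 1)

  # -- onsets: per-year Bernoulli on the at-risk fraction ---------------------
  onset <- rep(as.Date(NA), n)
  age16 <- birth + DAYS_16Y
  years <- 2011:2019
  for (y in years) {
    y0 <- as.Date(sprintf("%d-01-01", y)); y1 <- as.Date(sprintf("%d-01-01", y + 1))
    os <- pmax(enroll_start, y0, birth)
    oe <- pmin(enroll_end, y1, age16)
    frac <- pmax(0, as.numeric(oe - os)) / as.numeric(y1 - y0)
    if (y < as.integer(format(id_win[1], "%Y"))) {
      # pre-window onsets only for people observable into the window, so every
      # generated case can appear in the prevalent cohort
      frac[enroll_end <= id_win[1]] <- 0
    }
    p <- gc$onset_hazard_per_100k / 1e5 * frac
    hit <- is.na(onset) & runif(n) < p
    d <- floor(runif(sum(hit)) * pmax(1, as.numeric(oe - os)[hit]))
    onset[hit] <- os[hit] + d
  }
  case_idx <- which(!is.na(onset))
  n_cases <- length(case_idx)

  # -- case attributes --------------------------------------------------------
  spa <- runif(n_cases) < gc$spa_fraction
  subgroup <- ifelse(spa, "SpA", "non_SpA")
  sex <- ifelse(runif(n) < gc$background_male, "male", "female")
  p_male <- gc$male_fraction[subgroup]
  sex[case_idx] <- ifelse(runif(n_cases) < p_male, "male", "female")
  sex[case_idx][runif(n_cases) < gc$missing_sex_prob] <- "missing"

  # onset-age mix per subgroup: case birth dates are re-anchored to the drawn
  # onset age (a negligible perturbation of the population denominators)
  age_lo <- c(0, 6, 12); age_hi <- c(6, 12, 15.95)
  age_cat <- vapply(seq_len(n_cases), function(i) {
    sample.int(3, 1, prob = gc$onset_age_probs[[subgroup[i]]])
  }, integer(1))
  age_years <- age_lo[age_cat] + runif(n_cases) * (age_hi[age_cat] - age_lo[age_cat])
  # pre-window (prevalent-only) cases must still be age-eligible at their
  # in-window index date, which trails onset by up to ~1 year
  pre_win <- onset[case_idx] < id_win[1]
  if (any(pre_win)) {
    lag_y <- (as.numeric(id_win[1] - onset[case_idx][pre_win]) + 40) / 365.25
    age_years[pre_win] <- pmin(age_years[pre_win], 15.9 - lag_y)
  }
  birth[case_idx] <- onset[case_idx] - round(age_years * 365.25)
  enroll_start[case_idx] <- pmax(win[1], birth[case_idx])

  uveitis <- runif(n_cases) < unname(gc$uveitis_prob[subgroup])
  psoriasis <- runif(n_cases) < unname(gc$psoriasis_prob[subgroup])

  # -- near-misses ------------------------------------------------------------
  n_nm <- round(gc$near_miss_fraction * n_cases)
  nm_pool <- setdiff(which(is.na(onset) & enroll_start < id_win[2] - 365), case_idx)
  nm_idx <- if (n_nm > 0 && length(nm_pool) >= n_nm) sample(nm_pool, n_nm) else integer()
  nm_mode <- sample(c("few_dx", "nsaid_short", "too_old"), length(nm_idx),
                    replace = TRUE)
  nm_onset <- id_win[1] +
    floor(runif(length(nm_idx)) * (as.numeric(id_win[2] - id_win[1]) - 1))
  nm_age <- ifelse(nm_mode == "too_old", 16.1 + runif(length(nm_idx)) * 1.5,
                   6 + runif(length(nm_idx)) * 9)
  birth[nm_idx] <- nm_onset - round(nm_age * 365.25)
  enroll_start[nm_idx] <- pmax(win[1], birth[nm_idx])

  beneficiaries <- tibble::tibble(
    person_id = person_id, sex = sex, birth_date = birth,
    enroll_start = enroll_start, enroll_end = enroll_end
  )

  # -- claims for cases and near-misses --------------------------------------
  followup_end <- pmin(followup_cap, enroll_end)
  emit <- vector("list", n_cases + length(nm_idx))
  truth_rows <- vector("list", n_cases + length(nm_idx))
  for (k in seq_len(n_cases)) {
    i <- case_idx[k]
    emit[[k]] <- emit_case(
      pid = person_id[i], onset = onset[i], subgroup = subgroup[k],
      uveitis = uveitis[k], psoriasis = psoriasis[k],
      followup_end = followup_end[i], gc = gc, near_miss = NA_character_,
      window_start = id_win[1]
    )
    truth_rows[[k]] <- emit[[k]]$truth
  }
  for (k in seq_along(nm_idx)) {
    i <- nm_idx[k]
    emit[[n_cases + k]] <- emit_case(
      pid = person_id[i], onset = nm_onset[k],
      subgroup = sample(c("SpA", "non_SpA"), 1), uveitis = FALSE,
      psoriasis = FALSE, followup_end = followup_end[i], gc = gc,
      near_miss = nm_mode[k]
    )
    truth_rows[[n_cases + k]] <- emit[[n_cases + k]]$truth
  }

  diagnoses <- dplyr::bind_rows(purrr::map(emit, "dx"))
  prescriptions <- dplyr::bind_rows(purrr::map(emit, "rx"))
  if (nrow(diagnoses)) {
    diagnoses <- diagnoses[diagnoses$date >= win[1] & diagnoses$date < win[2], ]
    diagnoses$code_system <- code_system_for_date(diagnoses$date, cfg$dialect_switch)
    diagnoses$code <- vapply(seq_len(nrow(diagnoses)), function(j) {
      representative_code(diagnoses$group[j], diagnoses$code_system[j],
                          cfg$code_lists)
    }, character(1))
    diagnoses$group <- NULL
  } else {
    diagnoses <- tibble::tibble(person_id = character(), date = as.Date(character()),
                                setting = character(), code = character(),
                                code_system = character(), visit_id = character())
  }
  if (nrow(prescriptions)) {
    prescriptions <- prescriptions[prescriptions$fill_date >= win[1] &
                                     prescriptions$fill_date < win[2], ]
  } else {
    prescriptions <- tibble::tibble(person_id = character(),
                                    fill_date = as.Date(character()),
                                    days_supply = integer(), drug_name = character(),
                                    visit_id = character())
  }

  denominators <- analytic_denominators(beneficiaries, 2012:2019)

  bundle <- suppressWarnings(claims_bundle(
    beneficiaries, diagnoses, prescriptions, denominators, config = cfg
  ))

  persons <- dplyr::bind_rows(truth_rows)
  if (nrow(persons)) {
    persons$incident <- persons$is_case & persons$onset_date >= id_win[1]
  } else {
    persons <- tibble::tibble(
      person_id = character(), is_case = logical(), near_miss = character(),
      onset_date = as.Date(character()), subgroup = character(),
      uveitis = logical(), psoriasis = logical(),
      followup_end = as.Date(character()), biologic_user = logical(),
      index_drug = character(), index_start = as.Date(character()),
      index_episode_end = as.Date(character()), pattern = character(),
      incident = logical()
    )
  }
  annual <- truth_annual_rates(persons, denominators)
  py <- sum(denominators$person_years)
  overall <- if (nrow(persons)) {
    1e5 * sum(persons$incident & persons$onset_date < id_win[2]) / py
  } else 0
  truth <- list(persons = persons, annual = annual,
                overall_incidence_rate = overall)
  list(bundle = bundle, truth = truth)
}

truth_annual_rates <- function(persons, denominators) {
  den <- denominators |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(person_count = sum(.data$person_count),
                     person_years = sum(.data$person_years), .groups = "drop")
  if (!nrow(persons)) {
    den$true_incident_cases <- 0L
    den$true_incidence_per_100k <- 0
    return(den)
  }
  onset_year <- as.integer(format(persons$onset_date, "%Y"))
  den$true_incident_cases <- vapply(den$year, function(y) {
    sum(persons$incident & onset_year == y, na.rm = TRUE)
  }, integer(1))
  den$true_incidence_per_100k <- 1e5 * den$true_incident_cases / den$person_count
  den
}

analytic_denominators <- function(beneficiaries, years) {
  b <- beneficiaries[beneficiaries$sex %in% c("male", "female"), , drop = FALSE]
  age16 <- b$birth_date + DAYS_16Y
  purrr::map_dfr(years, function(y) {
    y0 <- as.Date(sprintf("%d-01-01", y)); y1 <- as.Date(sprintf("%d-01-01", y + 1))
    os <- pmax(b$enroll_start, y0, b$birth_date)
    oe <- pmin(b$enroll_end, y1, age16)
    days <- pmax(0, as.numeric(oe - os))
    keep <- days > 0
    mid <- as.Date(sprintf("%d-07-01", y))
    age <- pmax(0, floor(as.numeric(mid - b$birth_date[keep]) / 365.25))
    tibble::tibble(
      year = y,
      age_group = as.character(age_group_of(pmin(age, 15))),
      sex = b$sex[keep],
      frac = days[keep] / as.numeric(y1 - y0)  # full year contributes 1 PY
    ) |>
      dplyr::group_by(.data$year, .data$age_group, .data$sex) |>
      dplyr::summarise(person_count = dplyr::n(),
                       person_years = sum(.data$frac), .groups = "drop")
  })
}

new_dx <- function(pid, date, setting, group, visit_id) {
  tibble::tibble(person_id = pid, date = date, setting = setting,
                 group = group, visit_id = visit_id)
}

new_rx <- function(pid, fill_date, days_supply, drug_name, visit_id) {
  tibble::tibble(person_id = pid, fill_date = fill_date,
                 days_supply = as.integer(days_supply), drug_name = drug_name,
                 visit_id = visit_id)
}

# claims for one case (or near-miss); returns dx, rx, truth row
emit_case <- function(pid, onset, subgroup, uveitis, psoriasis, followup_end,
                      gc, near_miss = NA_character_, window_start = NULL) {
  dx <- list(); rx <- list()
  vid <- function(k) paste0(pid, "-v", k)
  is_case <- is.na(near_miss)
  # chronic disease onset before the identification window keeps generating
  # claims into the window, so prevalent cases qualify there
  pre_window_days <- if (!is.null(window_start) && onset < window_start) {
    as.numeric(window_start - onset)
  } else 0

  # outpatient visit schedule: three guaranteed early visits, then follow-up
  # visits every ~45-90 days while care continues
  care_days <- min(as.numeric(followup_end - onset),
                   365 + rexp(1, 1 / (365 * 2)))
  if (pre_window_days > 0) {
    care_days <- min(as.numeric(followup_end - onset), pre_window_days + 365)
  }
  visits <- onset + c(0, 55 + sample.int(15, 1), 115 + sample.int(15, 1))
  t <- as.numeric(visits[3] - onset)
  while (t + 45 < care_days) {
    t <- t + 45 + sample.int(45, 1)
    visits <- c(visits, onset + t)
  }
  if (pre_window_days > 0) {
    # guarantee an in-window index with a qualifying outpatient triple
    visits <- sort(unique(c(visits, window_start + c(10, 70, 130))))
  }
  if (!is.na(near_miss) && near_miss == "few_dx") visits <- visits[1:2]
  nv <- length(visits)
  dx$jia <- new_dx(pid, visits, "outpatient", "JIA", vid(seq_len(nv)))
  if (is_case && runif(1) < gc$inpatient_prob) {
    dx$inpt <- new_dx(pid, onset + sample.int(30, 1), "inpatient", "JIA",
                      vid(nv + 1))
  }
  if (subgroup == "SpA") {
    at <- visits[pmin(nv, c(1, 2))]
    dx$spa <- new_dx(pid, unique(at), "outpatient", "SpA_feature",
                     vid(match(unique(at), visits)))
  }
  if (uveitis) {
    at <- visits[sample.int(nv, 1)]
    dx$uv <- new_dx(pid, at, "outpatient", "uveitis", vid(match(at, visits)))
  }
  if (psoriasis) {
    at <- visits[sample.int(nv, 1)]
    dx$pso <- new_dx(pid, at, "outpatient", "psoriasis", vid(match(at, visits)))
  }

  # NSAID induction (inclusion criterion), chronic streams, biologics
  rxk <- 0L
  rvid <- function() { rxk <<- rxk + 1L; paste0(pid, "-r", rxk) }
  chronic <- gc$chronic_probs[[subgroup]]
  if (!is.na(near_miss) && near_miss == "nsaid_short") {
    rx$nsaid <- new_rx(pid, onset, 14L, "naproxen", vid(1))
  } else {
    dur <- if (runif(1) < chronic[["NSAID"]]) 100 + runif(1) * 400 else 30
    rx$nsaid <- refill_stream(pid, "naproxen", onset, dur, every = 30,
                              supply = 30, jitter = 2, followup_end, rvid)
    if (pre_window_days > 0) {
      # NSAID coverage intersecting the year after the in-window index
      rx$nsaid_window <- refill_stream(pid, "naproxen", window_start + 10, 90,
                                       every = 30, supply = 30, jitter = 2,
                                       followup_end, rvid)
    }
  }
  if (is_case) {
    for (drug in c("methotrexate", "sulfasalazine")) {
      if (runif(1) < chronic[[drug]]) {
        start <- onset + sample.int(60, 1)
        rx[[drug]] <- refill_stream(pid, drug, start, 120 + runif(1) * 900,
                                    every = 29, supply = 28, jitter = 2,
                                    followup_end, rvid)
      }
    }
    if (runif(1) < chronic[["steroid"]]) {
      start <- onset + sample.int(30, 1)
      rx$steroid <- refill_stream(pid, "prednisolone", start, 100 + runif(1) * 250,
                                  every = 30, supply = 30, jitter = 2,
                                  followup_end, rvid)
    }
  }

  index_drug <- NA_character_; index_start <- as.Date(NA)
  index_episode_end <- as.Date(NA); pattern <- NA_character_
  if (is_case && runif(1) < gc$biologic_prob[[subgroup]]) {
    delay <- rlnorm(1, gc$time_to_biologic_meanlog, gc$time_to_biologic_sdlog)
    start <- onset + round(delay)
    if (start <= followup_end - gc$cycle_days) {
      shares <- gc$index_shares[[subgroup]]
      drug <- sample(names(shares), 1, prob = shares)
      bio <- biologic_trajectory(pid, drug, start, followup_end, gc, rvid)
      rx$bio <- bio$fills
      index_drug <- drug; index_start <- start
      lab <- pattern_truth_from_fills(bio$fills, drug, start, followup_end,
                                      grace = gc$config$grace_biologic)
      pattern <- lab$pattern
      index_episode_end <- lab$index_episode_end
      # same-visit csDMARD combination
      comb <- combination_fills(pid, bio$fills, start, gc)
      if (!is.null(comb)) rx$comb <- comb
    }
  }

  truth <- tibble::tibble(
    person_id = pid, is_case = is_case, near_miss = near_miss,
    onset_date = onset, subgroup = subgroup, uveitis = uveitis,
    psoriasis = psoriasis, followup_end = followup_end,
    biologic_user = !is.na(index_drug), index_drug = index_drug,
    index_start = index_start, index_episode_end = index_episode_end,
    pattern = pattern
  )
  list(dx = dplyr::bind_rows(dx), rx = dplyr::bind_rows(rx), truth = truth)
}

# regular refills of one drug from `start` for ~`dur` days, capped at followup
refill_stream <- function(pid, drug, start, dur, every, supply, jitter,
                          followup_end, rvid) {
  dates <- as.Date(character())
  t <- start
  while (t <= min(start + dur, followup_end)) {
    dates <- c(dates, t)
    t <- t + every + sample(seq(-jitter, jitter), 1)
  }
  if (!length(dates)) dates <- start
  new_rx(pid, dates, supply, drug,
         vapply(dates, function(...) rvid(), character(1)))
}

# piecewise per-cycle competing events: within-gap switch, interruption
# (restart or stop), otherwise refill until follow-up ends
biologic_trajectory <- function(pid, drug, start, followup_end, gc, rvid) {
  fills <- list()
  t <- start
  cov_end <- start
  repeat {
    fills[[length(fills) + 1]] <-
      new_rx(pid, t, gc$biologic_supply, drug, rvid())
    cov_end <- max(cov_end, t + gc$biologic_supply)
    u <- runif(1)
    if (u < gc$p_switch_cycle) {
      gap <- if (runif(1) < gc$switch_within_14_prob) sample(0:14, 1) else sample(15:60, 1)
      sw_date <- cov_end + gap
      others <- setdiff(c("etanercept", "adalimumab", "tocilizumab", "abatacept"), drug)
      new_drug <- sample(others, 1, prob = c(0.45, 0.45, 0.10))
      if (sw_date <= followup_end) {
        fills[[length(fills) + 1]] <- refill_stream(
          pid, new_drug, sw_date, 180 + runif(1) * 700, every = gc$cycle_days,
          supply = gc$biologic_supply, jitter = gc$fill_jitter, followup_end, rvid)
      }
      break
    }
    if (u < gc$p_switch_cycle + gc$p_gap_cycle) {
      if (runif(1) < gc$p_restart_given_gap) {
        re_date <- cov_end + 61 + round(rexp(1, 1 / gc$restart_gap_mean))
        re_drug <- if (runif(1) < gc$restart_same_prob) drug else
          sample(setdiff(c("etanercept", "adalimumab", "tocilizumab"), drug), 1)
        if (re_date <= followup_end) {
          fills[[length(fills) + 1]] <- refill_stream(
            pid, re_drug, re_date, 180 + runif(1) * 700, every = gc$cycle_days,
            supply = gc$biologic_supply, jitter = gc$fill_jitter, followup_end, rvid)
        }
      }
      break
    }
    nxt <- t + gc$cycle_days + sample(seq(-gc$fill_jitter, gc$fill_jitter), 1)
    if (nxt > followup_end) break
    t <- nxt
  }
  list(fills = dplyr::bind_rows(fills))
}

# definitional pattern label from the emitted fills (generator-side truth;
# the classifier recomputes this independently from merged episodes)
pattern_truth_from_fills <- function(fills, index_drug, index_start,
                                     followup_end, grace = 60L) {
  own <- fills[fills$drug_name == index_drug, , drop = FALSE]
  own <- own[order(own$fill_date), , drop = FALSE]
  cov_end <- own$fill_date[1] + own$days_supply[1]
  for (j in seq_len(nrow(own))[-1]) {
    if (as.numeric(own$fill_date[j] - cov_end) > grace) break
    cov_end <- max(cov_end, own$fill_date[j] + own$days_supply[j])
  }
  idx_end <- cov_end
  other <- fills[fills$drug_name != index_drug, , drop = FALSE]
  first_other <- if (nrow(other)) min(other$fill_date) else as.Date(NA)
  later_any <- fills$fill_date[fills$fill_date > idx_end + grace]
  pattern <-
    if (!is.na(first_other) && first_other <= idx_end + grace) "switching"
    else if (length(later_any)) "restart"
    else if (idx_end + grace < followup_end) "discontinuation"
    else "continuation"
  list(pattern = pattern, index_episode_end = idx_end)
}

combination_fills <- function(pid, bio_fills, index_start, gc) {
  out <- list()
  fy <- bio_fills[bio_fills$fill_date >= index_start &
                    bio_fills$fill_date < index_start + 365, , drop = FALSE]
  af <- bio_fills[bio_fills$fill_date >= index_start + 365, , drop = FALSE]
  if (nrow(fy) && runif(1) < gc$comb_first_year_prob) {
    pick <- fy[sample.int(nrow(fy), 1), ]
    out$fy <- new_rx(pid, pick$fill_date, 28L, "methotrexate", pick$visit_id)
  }
  if (nrow(af) && runif(1) < gc$comb_after_prob) {
    pick <- af[sample.int(nrow(af), 1), ]
    out$af <- new_rx(pid, pick$fill_date, 28L, "methotrexate", pick$visit_id)
  }
  if (!length(out)) return(NULL)
  dplyr::bind_rows(out)
}

#' Generate an adversarial single-course fill timeline
#'
#' Emits fills that, run through episode construction and the pattern
#' classifier, yield exactly the requested terminal pattern; used as a fixture
#' generator for the state machine.  Gaps inside the index episode are drawn
#' up to exactly the 60-day grace; switch dates range over overlap to the
#' 60-day boundary; restarts start at 61 days or later.
#'
#' @param pattern One of `"continuation"`, `"switching"`, `"restart"`,
#'   `"discontinuation"`.
#' @param gc A [generator_config()] (supplies the grace via its
#'   `config`).
#' @param seed Integer seed.
#' @param index_drug Index biologic for the timeline (default: drawn at
#'   random).
#' @return A list: `fills` tibble, `index_drug`, `index_start`,
#'   `followup_end`, `pattern`.
#' @export
generate_course_timeline <- function(pattern = c("continuation", "switching",
                                                 "restart", "discontinuation"),
                                     gc = generator_config(), seed = 1L,
                                     index_drug = NULL) {
  pattern <- match.arg(pattern)
  set.seed(seed)
  grace <- gc$config$grace_biologic
  drugs <- c("etanercept", "adalimumab", "tocilizumab")
  if (is.null(index_drug)) index_drug <- sample(drugs, 1)
  index_start <- as.Date("2013-01-01") + sample.int(1800, 1)
  pid <- "T0000001"
  k <- 0L
  rvid <- function() { k <<- k + 1L; paste0(pid, "-r", k) }

  n_fills <- sample.int(12, 1)
  dates <- index_start
  supply <- sample(14:30, n_fills, replace = TRUE)
  cov_end <- index_start + supply[1]
  if (n_fills > 1) {
    for (j in 2:n_fills) {
      nxt <- cov_end + sample(-20:grace, 1)  # overlap up to exactly the grace
      nxt <- max(nxt, dates[j - 1] + 1)
      dates <- c(dates, nxt)
      cov_end <- max(cov_end, nxt + supply[j])
    }
  }
  fills <- new_rx(pid, dates, supply, index_drug,
                  vapply(dates, function(...) rvid(), character(1)))
  idx_end <- cov_end

  if (pattern == "continuation") {
    followup_end <- idx_end + sample(0:grace, 1)
  } else if (pattern == "switching") {
    other <- sample(setdiff(c(drugs, "abatacept"), index_drug), 1)
    sw <- idx_end + sample(-10:grace, 1)
    sw <- max(sw, index_start + 1)
    fills <- dplyr::bind_rows(fills, new_rx(pid, sw + c(0, 28, 56), 28L, other,
                                            c(rvid(), rvid(), rvid())))
    followup_end <- sw + 56 + 28 + sample.int(200, 1)
  } else if (pattern == "restart") {
    same <- runif(1) < 0.5
    re_drug <- if (same) index_drug else sample(setdiff(drugs, index_drug), 1)
    re <- idx_end + grace + 1 + sample(0:300, 1)
    fills <- dplyr::bind_rows(fills, new_rx(pid, re + c(0, 28), 28L, re_drug,
                                            c(rvid(), rvid())))
    followup_end <- re + 28 + 28 + sample.int(200, 1)
  } else {
    followup_end <- idx_end + grace + 1 + sample(0:600, 1)
  }
  list(fills = fills, index_drug = index_drug, index_start = index_start,
       followup_end = followup_end, pattern = pattern)
}

#' Write ground truth to CSV
#'
#' @param truth Truth list from [generate_bundle()].
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
export_truth <- function(truth, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", dir))
  }
  p1 <- file.path(dir, "truth_persons.csv")
  p2 <- file.path(dir, "truth_annual.csv")
  readr::write_csv(truth$persons, p1, progress = FALSE)
  readr::write_csv(truth$annual, p2, progress = FALSE)
  invisible(c(p1, p2))
}

#' Read ground truth written by [export_truth()]
#'
#' @param dir Directory with `truth_persons.csv` and `truth_annual.csv`.
#' @return A truth list (without the derived overall rate).
#' @export
read_truth <- function(dir) {
  persons <- readr::read_csv(
    file.path(dir, "truth_persons.csv"),
    col_types = readr::cols(person_id = "c", is_case = "l", near_miss = "c",
                            onset_date = "D", subgroup = "c", uveitis = "l",
                            psoriasis = "l", followup_end = "D",
                            biologic_user = "l", index_drug = "c",
                            index_start = "D", index_episode_end = "D",
                            pattern = "c", incident = "l"),
    progress = FALSE)
  annual <- readr::read_csv(file.path(dir, "truth_annual.csv"),
                            col_types = readr::cols(), progress = FALSE)
  list(persons = persons, annual = annual)
}
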