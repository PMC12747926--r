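# Small programmatic fixtures.

d <- function(x) as.Date(x)

# minimal hand-built bundle: three beneficiaries, one qualifying case, one
# pre-window (prevalent-only) case, one too-old patient
tiny_bundle <- function(config = claims_config()) {
  ben <- tibble::tibble(
    person_id = c("A", "B", "C"),
    sex = c("male", "female", "male"),
    birth_date = d(c("2004-03-01", "2000-06-15", "1997-01-01")),
    enroll_start = d(c("2011-01-01", "2011-01-01", "2011-01-01")),
    enroll_end = d(c("2021-01-01", "2021-01-01", "2021-01-01"))
  )
  dx <- tibble::tibble(
    person_id = c("A", "A", "A", "B", "B", "B", "B", "C"),
    date = d(c("2013-05-01", "2013-07-01", "2013-09-01",
               "2011-06-01", "2012-02-01", "2012-04-01", "2012-06-01",
               "2013-03-01")),
    setting = c("outpatient", "outpatient", "outpatient",
                "outpatient", "outpatient", "outpatient", "outpatient",
                "inpatient"),
    code = c("714.30", "714.30", "714.30", "714.30", "714.30", "714.30",
             "714.30", "714.30"),
    code_system = "ICD9CM",
    visit_id = paste0("v", 1:8)
  )
  rx <- tibble::tibble(
    person_id = c("A", "B", "C"),
    fill_date = d(c("2013-05-01", "2012-02-01", "2013-03-01")),
    days_supply = c(30L, 30L, 30L),
    drug_name = "naproxen",
    visit_id = c("v1", "v5", "v8")
  )
  den <- tidyr::expand_grid(
    year = 2012:2019,
    age_group = c("0-5", "6-11", "12-15"),
    sex = c("male", "female")
  )
  den$person_count <- 1000
  den$person_years <- 1000
  claims_bundle(ben, dx, rx, den, config = config)
}

# classified courses realizing given per-drug pattern counts, produced by
# running adversarial timelines through the real episode/classifier machinery
courses_from_counts <- function(counts, seed0 = 1000) {
  rows <- list()
  k <- 0
  for (j in seq_len(nrow(counts))) {
    for (i in seq_len(counts$n[j])) {
      k <- k + 1
      tl <- generate_course_timeline(counts$pattern[j], seed = seed0 + k,
                                     index_drug = counts$index_drug[j])
      course <- classify_timeline(tl)
      course <- course_times(course, tl$index_start - 200)
      course$person_id <- sprintf("W%04d", k)
      course$followup_end <- tl$followup_end
      course$subgroup <- "non_SpA"
      course$comb_first_year <- FALSE
      course$comb_after_first_year <- FALSE
      rows[[k]] <- course
    }
  }
  dplyr::bind_rows(rows)
}

# cohort rebuilt from the published subgroup counts: 586/243 male/female +6
# missing in the SpA-feature group, 381/478 +2 missing in the non-SpA group,
# uveitis 61 vs 26, psoriasis 24 vs 0, onset-age mix 7/122/706 vs 108/307/446
demographic_fixture <- function() {
  mk <- function(n, subgroup, sex, age, uveitis = FALSE, psoriasis = FALSE) {
    if (n == 0) return(NULL)
    tibble::tibble(
      person_id = paste0(subgroup, sex, age, seq_len(n)),
      index_date = as.Date("2015-06-01"), incident = TRUE,
      age_at_index = age, age_group = as.character(age_group_of(age)),
      sex = sex, birth_date = as.Date("2015-06-01") - round(age * 365.25),
      subgroup = subgroup, uveitis = uveitis, psoriasis = psoriasis,
      followup_end = as.Date("2020-12-31")
    )
  }
  sex_rows <- dplyr::bind_rows(
    mk(586, "SpA", "male", 13), mk(243, "SpA", "female", 13),
    mk(6, "SpA", "missing", 13),
    mk(381, "non_SpA", "male", 9), mk(478, "non_SpA", "female", 9),
    mk(2, "non_SpA", "missing", 9)
  )
  # overwrite age groups to the published onset mix, preserving subgroup sizes
  set_ages <- function(df, counts, ages = c(3, 9, 14)) {
    idx <- seq_len(nrow(df))
    ag <- rep(ages, counts)
    df$age_at_index <- ag
    df$age_group <- as.character(age_group_of(ag))
    df
  }
  spa <- set_ages(sex_rows[sex_rows$subgroup == "SpA", ], c(7, 122, 706))
  non <- set_ages(sex_rows[sex_rows$subgroup == "non_SpA", ], c(108, 307, 446))
  spa$uveitis <- c(rep(TRUE, 61), rep(FALSE, nrow(spa) - 61))
  non$uveitis <- c(rep(TRUE, 26), rep(FALSE, nrow(non) - 26))
  spa$psoriasis <- c(rep(TRUE, 24), rep(FALSE, nrow(spa) - 24))
  dplyr::bind_rows(spa, non)
}
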