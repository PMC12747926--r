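# hand-built cohort of diagnosed children against a fixed denominator table
mk_cohort <- function(n, index_year, incident = TRUE, sex = "male",
                      age = 10) {
  if (n == 0) return(tibble::tibble())
  idx <- as.Date(sprintf("%d-06-01", index_year))
  tibble::tibble(
    person_id = sprintf("E%d_%02d", index_year, seq_len(n)),
    index_date = idx, incident = incident,
    age_at_index = age, age_group = as.character(age_group_of(age)),
    sex = sex, birth_date = idx - round(age * 365.25),
    subgroup = "non_SpA", uveitis = FALSE, psoriasis = FALSE,
    followup_end = as.Date("2020-12-31")
  )
}

flat_denoms <- function(count = 100000 / 6) {
  den <- tidyr::expand_grid(year = 2012:2019,
                            age_group = c("0-5", "6-11", "12-15"),
                            sex = c("male", "female"))
  den$person_count <- count
  den$person_years <- count
  den
}

test_that("annual prevalence is cases over the under-16 population", {
  cohort <- mk_cohort(18, 2014)
  den <- flat_denoms()  # 100,000 under-16 per year
  r <- annual_prevalence(cohort, den, 2014)
  expect_equal(r$rate, 18)
  expect_equal(annual_prevalence(cohort[0, ], den, 2014)$rate, 0)
  expect_error(annual_prevalence(cohort, den, 2030), "denominator")
  # cumulative: the same children still count the next year...
  expect_equal(annual_prevalence(cohort, den, 2015)$rate, 18)
  # ...but not before their index year
  expect_equal(annual_prevalence(cohort, den, 2013)$rate, 0)
})

test_that("children age out of the prevalence numerator", {
  cohort <- mk_cohort(5, 2013, age = 15)
  den <- flat_denoms()
  expect_equal(annual_prevalence(cohort, den, 2013)$numerator, 5)
  # by 2016 they are 18: no longer in the pediatric numerator
  expect_equal(annual_prevalence(cohort, den, 2016)$numerator, 0)
})

test_that("incidence proportion subtracts the previously diagnosed", {
  cohort <- dplyr::bind_rows(mk_cohort(6, 2014), mk_cohort(4, 2015))
  den <- flat_denoms()
  r14 <- annual_incidence_proportion(cohort, den, 2014)
  expect_equal(r14$numerator, 6)
  expect_equal(r14$denominator, 100000)
  expect_equal(r14$rate, 6)
  r15 <- annual_incidence_proportion(cohort, den, 2015)
  expect_equal(r15$denominator, 100000 - 6)  # at-risk shrinks in a closed population
  expect_equal(r15$numerator, 4)
})

test_that("overall person-year rate pools cases over person-years", {
  cohort <- mk_cohort(91, 2013)
  den <- flat_denoms(250000 / 6)  # 2,000,000 PY over 8 years
  r <- overall_incidence_rate(cohort, den)
  expect_equal(r$rate, 1e5 * 91 / 2e6)
  expect_equal(round(r$rate, 2), 4.55)
  expect_equal(overall_incidence_rate(cohort[0, ], den)$rate, 0)
  bad <- den; bad$person_years <- 0
  expect_error(overall_incidence_rate(cohort, bad), "person-years")
})

test_that("overall rate equals the person-year-weighted average of annual rates", {
  cohort <- dplyr::bind_rows(mk_cohort(10, 2013), mk_cohort(30, 2016))
  den <- flat_denoms()
  annual <- vapply(2012:2019, function(y) {
    sum(cohort$incident & format(cohort$index_date, "%Y") == y) / 1e5
  }, numeric(1))
  expect_equal(overall_incidence_rate(cohort, den)$rate,
               1e5 * mean(annual))  # constant PY per year -> simple mean
})

test_that("stratified numerators sum to the marginal count", {
  cohort <- dplyr::bind_rows(
    mk_cohort(12, 2014, sex = "male", age = 13),
    mk_cohort(8, 2014, sex = "female", age = 4),
    mk_cohort(5, 2016, sex = "female", age = 9)
  )
  den <- flat_denoms()
  by_sex <- stratified_rates(cohort, den, by = c("year", "sex"),
                             measure = "incidence_proportion")
  expect_equal(sum(by_sex$numerator), nrow(cohort))
  y14 <- by_sex[by_sex$year == 2014, ]
  expect_equal(sum(y14$numerator), 20)
  by_age <- stratified_rates(cohort, den, by = c("year", "age_group"),
                             measure = "incidence_proportion")
  expect_equal(sum(by_age$numerator[by_age$year == 2014]), 20)
  expect_setequal(by_age$age_group[by_age$numerator > 0 & by_age$year == 2014],
                  c("12-15", "0-5"))
  # equal strata give the marginal rate in each stratum
  eq <- stratified_rates(mk_cohort(6, 2014), den, by = "sex",
                         measure = "incidence_proportion", years = 2014)
  expect_equal(eq$rate[eq$sex == "male"],
               1e5 * 6 / (100000 / 2))
})

test_that("pipeline rates agree with generator ground truth counts", {
  sim <- generate_bundle(generator_config(seed = 5, n_population = 10000,
                                          onset_hazard_per_100k = 300))
  ch <- build_cohorts(sim$bundle)
  tp <- sim$truth$persons
  for (y in c(2013, 2016, 2019)) {
    r <- annual_incidence_proportion(ch$prevalent, sim$bundle$denominators, y)
    truth_n <- sum(tp$incident & format(tp$onset_date, "%Y") == y)
    expect_equal(r$numerator, truth_n)
  }
  overall <- overall_incidence_rate(ch$prevalent, sim$bundle$denominators)
  expect_equal(overall$rate, sim$truth$overall_incidence_rate)
})
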