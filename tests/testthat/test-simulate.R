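test_that("the same seed reproduces the bundle exactly", {
  gc1 <- generator_config(seed = 12, n_population = 2000,
                          onset_hazard_per_100k = 400)
  a <- generate_bundle(gc1)
  b <- generate_bundle(gc1)
  expect_equal(a$bundle$beneficiaries, b$bundle$beneficiaries)
  expect_equal(a$bundle$diagnoses, b$bundle$diagnoses)
  expect_equal(a$bundle$prescriptions, b$bundle$prescriptions)
  expect_equal(a$truth$persons, b$truth$persons)
  # a different seed moves the claims
  c <- generate_bundle(generator_config(seed = 13, n_population = 2000,
                                        onset_hazard_per_100k = 400))
  expect_false(identical(a$bundle$diagnoses, c$bundle$diagnoses))
})

test_that("degenerate configurations behave as contracted", {
  # zero hazard: no JIA events at all
  z <- generate_bundle(generator_config(seed = 2, n_population = 2000,
                                        onset_hazard_per_100k = 0))
  expect_equal(nrow(z$bundle$diagnoses), 0)
  expect_equal(sum(z$truth$persons$is_case), 0)
  expect_equal(nrow(validate_bundle(z$bundle)), 0)

  # SpA fraction 1: every case labelled SpA
  s <- generate_bundle(generator_config(seed = 2, n_population = 4000,
                                        onset_hazard_per_100k = 500,
                                        spa_fraction = 1))
  cases <- s$truth$persons[s$truth$persons$is_case, ]
  expect_gt(nrow(cases), 0)
  expect_true(all(cases$subgroup == "SpA"))

  # infeasible hazard rejected
  expect_error(generator_config(onset_hazard_per_100k = 2e5), "hazard")
})

test_that("generated bundles pass validation and support every case claim", {
  sim <- generate_bundle(generator_config(seed = 4, n_population = 6000,
                                          onset_hazard_per_100k = 400))
  expect_equal(nrow(validate_bundle(sim$bundle)), 0)
  tp <- sim$truth$persons
  cases <- tp[tp$is_case, ]
  dx <- sim$bundle$diagnoses
  rx <- sim$bundle$prescriptions
  # every true case has qualifying JIA codes and NSAID exposure on file
  for (pid in cases$person_id) {
    expect_gte(sum(dx$person_id == pid & dx$dx_group == "JIA"), 3 - 2 *
                 any(dx$person_id == pid & dx$setting == "inpatient"))
    expect_gte(sum(rx$person_id == pid & rx$drug_class == "NSAID"), 1)
  }
  # every truth biologic course is supported by fills of the index drug
  users <- cases[cases$biologic_user, ]
  for (j in seq_len(nrow(users))) {
    expect_true(any(rx$person_id == users$person_id[j] &
                      rx$drug_name == users$index_drug[j] &
                      rx$fill_date == users$index_start[j]))
  }
  # ICD dialect honoured on both sides of the switch
  expect_true(all(dx$code_system[dx$date < as.Date("2016-01-01")] == "ICD9CM"))
  expect_true(all(dx$code_system[dx$date >= as.Date("2016-01-01")] == "ICD10CM"))
})

test_that("subgroup mix is recovered within the binomial 99% interval", {
  sim <- generate_bundle(generator_config(seed = 9, n_population = 30000,
                                          onset_hazard_per_100k = 600))
  cases <- sim$truth$persons[sim$truth$persons$is_case, ]
  n <- nrow(cases)
  expect_gt(n, 100)
  ci <- stats::binom.test(sum(cases$subgroup == "SpA"), n,
                          conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.49 && 0.49 <= ci[2])
})

test_that("estimated incidence tracks the configured hazard at moderate n", {
  rates <- vapply(1:5, function(s) {
    sim <- generate_bundle(generator_config(seed = s, n_population = 50000,
                                            onset_hazard_per_100k = 40))
    ch <- build_cohorts(sim$bundle)
    overall_incidence_rate(ch$prevalent, sim$bundle$denominators)$rate
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 40), 4 * se + 1e-9)
})

test_that("adversarial timelines realize each requested pattern", {
  for (pat in c("continuation", "switching", "restart", "discontinuation")) {
    for (s in 1:25) {
      tl <- generate_course_timeline(pat, seed = 100 * s + nchar(pat))
      expect_equal(classify_timeline(tl)$pattern, pat)
    }
  }
})

test_that("ground truth round-trips through CSV", {
  sim <- generate_bundle(generator_config(seed = 14, n_population = 3000,
                                          onset_hazard_per_100k = 300))
  dir <- withr::local_tempdir()
  export_truth(sim$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$persons, sim$truth$persons)
  expect_equal(as.data.frame(back$annual), as.data.frame(sim$truth$annual),
               tolerance = 1e-12)
  # empty truth writes a header-only persons file
  z <- generate_bundle(generator_config(seed = 2, n_population = 500,
                                        onset_hazard_per_100k = 0))
  dir2 <- withr::local_tempdir()
  export_truth(z$truth, dir2)
  expect_equal(nrow(readr::read_csv(file.path(dir2, "truth_persons.csv"),
                                    show_col_types = FALSE)), 0)
})
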