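bio_fill <- function(days, drug, supply = 28, origin = as.Date("2015-01-01")) {
  tibble::tibble(person_id = "B1", fill_date = origin + days,
                 days_supply = as.integer(supply), drug_name = drug,
                 visit_id = NA_character_)
}

test_that("index biologic is the earliest eligible fill with stated tie-breaks", {
  f <- dplyr::bind_rows(bio_fill(100, "etanercept"), bio_fill(200, "adalimumab"))
  idx <- find_index_biologic(f)
  expect_equal(idx$drug_name, "etanercept")
  expect_equal(idx$index_start, as.Date("2015-01-01") + 100)

  # abatacept is not an eligible index drug
  f2 <- dplyr::bind_rows(bio_fill(50, "abatacept"), bio_fill(80, "adalimumab"))
  expect_equal(find_index_biologic(f2)$drug_name, "adalimumab")
  expect_null(find_index_biologic(bio_fill(50, "abatacept")))

  # same-day tie: larger days supply wins, then alphabetical
  f3 <- dplyr::bind_rows(bio_fill(0, "etanercept", 28), bio_fill(0, "adalimumab", 56))
  expect_equal(find_index_biologic(f3)$drug_name, "adalimumab")
  f4 <- dplyr::bind_rows(bio_fill(0, "etanercept", 28), bio_fill(0, "adalimumab", 28))
  expect_equal(find_index_biologic(f4)$drug_name, "adalimumab")
})

classify_fills <- function(fills, index_drug, index_start, followup_end) {
  eps <- build_episodes(fills, grace = 60, by = "drug_name")
  classify_course(eps, index_drug, index_start, followup_end)
}

test_that("the four terminal patterns are assigned per the 60-day gap rules", {
  origin <- as.Date("2015-01-01")
  idx <- bio_fill(c(0, 28, 56), "etanercept")  # index episode [0, 84)

  # single index episode persisting to follow-up end: continuation
  c1 <- classify_fills(idx, "etanercept", origin, origin + 100)
  expect_equal(c1$pattern, "continuation")
  expect_equal(c1$event, 0L)

  # different biologic within the 60-day gap: switching
  c2 <- classify_fills(dplyr::bind_rows(idx, bio_fill(114, "adalimumab")),
                       "etanercept", origin, origin + 800)
  expect_equal(c2$pattern, "switching")
  expect_equal(c2$switch_subtype, "within_gap")
  expect_equal(c2$event_time_days, 114L)

  # same drug refilled after a 150-day hole: restart, same drug
  c3 <- classify_fills(dplyr::bind_rows(idx, bio_fill(250, "etanercept")),
                       "etanercept", origin, origin + 800)
  expect_equal(c3$pattern, "restart")
  expect_true(c3$restart_drug_same)
  expect_equal(c3$gap_to_restart_days, 250L - 84L)

  # different drug after the gap closes: restart with switch-after-interruption
  c4 <- classify_fills(dplyr::bind_rows(idx, bio_fill(250, "tocilizumab")),
                       "etanercept", origin, origin + 800)
  expect_equal(c4$pattern, "restart")
  expect_equal(c4$switch_subtype, "after_interruption")
  expect_false(c4$restart_drug_same)

  # nothing after the index episode, ample follow-up: discontinuation
  c5 <- classify_fills(idx, "etanercept", origin, origin + 400)
  expect_equal(c5$pattern, "discontinuation")
  expect_equal(c5$event_time_days, 84L)

  # boundary: different biologic at exactly episode end + 60 switches ...
  c6 <- classify_fills(dplyr::bind_rows(idx, bio_fill(84 + 60, "adalimumab")),
                       "etanercept", origin, origin + 800)
  expect_equal(c6$pattern, "switching")
  # ... and at + 61 it is a restart
  c7 <- classify_fills(dplyr::bind_rows(idx, bio_fill(84 + 61, "adalimumab")),
                       "etanercept", origin, origin + 800)
  expect_equal(c7$pattern, "restart")

  # overlapping different biologic counts as a within-gap switch at its date
  c8 <- classify_fills(dplyr::bind_rows(idx, bio_fill(30, "adalimumab")),
                       "etanercept", origin, origin + 800)
  expect_equal(c8$pattern, "switching")
  expect_equal(c8$event_time_days, 30L)

  expect_error(classify_fills(idx, "adalimumab", origin, origin + 100),
               "index episode")
})

test_that("course times convert day intervals to 365.25-day years", {
  course <- classify_fills(bio_fill(c(0, 28), "etanercept"), "etanercept",
                           as.Date("2015-01-01"), as.Date("2015-06-01"))
  ct <- course_times(course, as.Date("2014-01-01"))
  expect_equal(ct$time_to_index_years, 365 / 365.25)
  expect_equal(ct$index_duration_years, 56 / 365.25)
  expect_error(course_times(course, as.Date("2016-01-01")), "diagnosis_date")
})

test_that("classifier agrees with the event-by-event reference interpreter", {
  set.seed(2024)
  for (i in 1:1000) {
    pat <- sample(c("continuation", "switching", "restart", "discontinuation"), 1)
    tl <- generate_course_timeline(pat, seed = sample.int(1e6, 1))
    got <- classify_timeline(tl)
    want <- oracle_classify(tl$fills, tl$index_drug, tl$index_start,
                            tl$followup_end)
    expect_equal(got$pattern, want$pattern)
    expect_equal(got$index_episode_end, want$index_episode_end)
    if (want$pattern == "restart") {
      expect_equal(got$restart_drug_same, want$same)
    }
  }
})

test_that("patterns partition biologic users and percentages recompute", {
  counts <- tibble::tibble(
    index_drug = "etanercept",
    pattern = c("continuation", "switching", "restart", "discontinuation"),
    n = c(5, 3, 2, 2)
  )
  courses <- courses_from_counts(counts)
  expect_equal(nrow(courses), 12)
  tab <- tabulate_patterns(courses)
  expect_equal(sum(tab$n), nrow(courses))
  expect_equal(tab$pct, round(100 * tab$n / 12, 1))
  # all-continuation fixture
  all_cont <- courses_from_counts(tibble::tibble(
    index_drug = "adalimumab", pattern = "continuation", n = 4), seed0 = 5000)
  t2 <- tabulate_patterns(all_cont)
  expect_equal(t2$pct[t2$pattern == "continuation"], 100)
  expect_equal(sum(t2$n[t2$pattern != "continuation"]), 0)
})

test_that("cohort-level course building matches generator truth", {
  sim <- generate_bundle(generator_config(seed = 31, n_population = 20000,
                                          onset_hazard_per_100k = 400))
  ch <- build_cohorts(sim$bundle)
  courses <- build_courses(sim$bundle, ch$incident)
  tp <- sim$truth$persons
  users <- tp[tp$biologic_user & tp$incident, ]
  expect_setequal(courses$person_id, users$person_id)
  m <- merge(courses, users, by = "person_id")
  expect_equal(m$pattern.x, m$pattern.y)
  expect_equal(m$index_drug.x, m$index_drug.y)
  expect_equal(m$index_episode_end.x, m$index_episode_end.y)
  expect_true(all(m$time_to_index_years >= 0))
  expect_true(all(m$event_time_days >= 1))
})
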