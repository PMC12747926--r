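# Report assembly: demographics-by-subgroup and per-drug treatment-pattern
# tables, with small-count suppression applied as the last step.

fmt_pct <- function(n, d) ifelse(d > 0, sprintf("%.1f%%", 100 * n / d), "")

table1_row <- function(characteristic, level, n_spa, n_nonspa,
                       d_spa, d_nonspa) {
  tibble::tibble(
    characteristic = characteristic, level = level,
    spa_n = n_spa, nonspa_n = n_nonspa,
    spa_pct = round(100 * n_spa / d_spa, 1),
    nonspa_pct = round(100 * n_nonspa / d_nonspa, 1)
  )
}

#' Demographics-by-subgroup report (Table-1 style)
#'
#' Counts and percentages per SpA / non-SpA subgroup for onset-age groups,
#' sex and comorbidity flags, with a comparison test per characteristic.
#' Sex percentages use the non-missing denominator; members with missing sex
#' are reported as their own row without percentages.
#'
#' @param cohort Cohort tibble from [build_cohorts()].
#' @param config A [claims_config()].
#' @return A tibble with per-level counts/percentages and a per-characteristic
#'   `p_value` and `test` on its first row.
#' @export
report_demographics <- function(cohort, config = claims_config()) {
  spa <- cohort[cohort$subgroup == "SpA", , drop = FALSE]
  non <- cohort[cohort$subgroup == "non_SpA", , drop = FALSE]
  n_spa <- nrow(spa); n_non <- nrow(non)

  blocks <- list()

  # onset age groups
  lv <- levels(age_group_of(0))
  cnt <- function(df) table(factor(as.character(df$age_group), levels = lv))
  a_spa <- cnt(spa); a_non <- cnt(non)
  blk <- table1_row("age_group", lv, as.integer(a_spa), as.integer(a_non),
                    n_spa, n_non)
  blk$p_value <- NA_real_; blk$test <- NA_character_
  keep <- a_spa + a_non > 0
  if (sum(keep) >= 2 && n_spa > 0 && n_non > 0) {
    tst <- compare_groups(cbind(as.integer(a_spa[keep]), as.integer(a_non[keep])))
    blk$p_value[1] <- tst$p_value; blk$test[1] <- tst$test
  }
  blocks$age <- blk

  # sex (non-missing denominator)
  s_spa <- c(male = sum(spa$sex == "male"), female = sum(spa$sex == "female"),
             missing = sum(spa$sex == "missing"))
  s_non <- c(male = sum(non$sex == "male"), female = sum(non$sex == "female"),
             missing = sum(non$sex == "missing"))
  d_spa <- s_spa[["male"]] + s_spa[["female"]]
  d_non <- s_non[["male"]] + s_non[["female"]]
  blk <- table1_row("sex", names(s_spa), as.integer(s_spa), as.integer(s_non),
                    d_spa, d_non)
  blk$spa_pct[3] <- NA_real_; blk$nonspa_pct[3] <- NA_real_
  blk$p_value <- NA_real_; blk$test <- NA_character_
  if (d_spa > 0 && d_non > 0) {
    tst <- compare_groups(rbind(c(s_spa[["male"]], s_non[["male"]]),
                                c(s_spa[["female"]], s_non[["female"]])))
    blk$p_value[1] <- tst$p_value; blk$test[1] <- tst$test
  }
  blocks$sex <- blk

  # comorbidity flags
  for (flag in c("uveitis", "psoriasis")) {
    y_spa <- sum(spa[[flag]]); y_non <- sum(non[[flag]])
    blk <- table1_row(flag, "yes", y_spa, y_non, n_spa, n_non)
    blk$p_value <- NA_real_; blk$test <- NA_character_
    tab <- rbind(c(y_spa, y_non), c(n_spa - y_spa, n_non - y_non))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      tst <- compare_groups(tab)
      blk$p_value[1] <- tst$p_value; blk$test[1] <- tst$test
    }
    blocks[[flag]] <- blk
  }

  dplyr::bind_rows(blocks)
}

#' Per-drug treatment-pattern report (Table-2 style)
#'
#' For each index biologic: initiator count, median (IQR) time from diagnosis
#' to index biologic and index duration, csDMARD combination counts, the
#' four-way pattern counts/percentages, and 1/3/5-year cumulative
#' discontinuation from the per-drug Kaplan-Meier fit.
#'
#' @param courses Course tibble from [build_courses()].
#' @param config A [claims_config()].
#' @return A list of tibbles: `summary` (one row per drug), `patterns`
#'   (pattern counts with suppression columns), `discontinuation` (per-drug
#'   horizon rates).
#' @export
report_treatment_patterns <- function(courses, config = claims_config()) {
  if (!nrow(courses)) {
    return(list(summary = tibble::tibble(), patterns = tibble::tibble(),
                discontinuation = tibble::tibble()))
  }
  med_iqr <- function(x) sprintf("%.2f (%.2f)", median(x), stats::IQR(x))

  summary <- courses |>
    dplyr::group_by(.data$index_drug) |>
    dplyr::summarise(
      n = dplyr::n(),
      time_to_index = med_iqr(.data$time_to_index_years),
      index_duration = med_iqr(.data$index_duration_years),
      comb_first_year_n = sum(.data$comb_first_year),
      comb_after_first_year_n = sum(.data$comb_after_first_year),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      comb_first_year_pct = round(100 * .data$comb_first_year_n / .data$n, 2),
      comb_after_first_year_pct = round(100 * .data$comb_after_first_year_n / .data$n, 2)
    )

  patterns <- tabulate_patterns(courses, by_drug = TRUE)
  sup <- suppress_counts(patterns$n)
  patterns$display <- sup$display
  patterns$masked <- sup$masked
  patterns$pct <- ifelse(patterns$masked, NA_real_, patterns$pct)

  discontinuation <- courses |>
    dplyr::group_by(.data$index_drug) |>
    dplyr::group_modify(function(df, key) {
      cumulative_discontinuation(km_fit(df$event_time_days, df$event))
    }) |>
    dplyr::ungroup()

  list(summary = summary, patterns = patterns, discontinuation = discontinuation)
}

#' Build all reports
#'
#' @param cohort Cohort tibble (incident cohort for the pattern analyses).
#' @param courses Course tibble from [build_courses()].
#' @param rates Optional rate tibble (bound through unchanged for writing).
#' @param config A [claims_config()].
#' @return A list: `table1`, `table2` (list of tibbles), `rates`.
#' @export
build_reports <- function(cohort, courses, rates = NULL,
                          config = claims_config()) {
  list(
    table1 = report_demographics(cohort, config),
    table2 = report_treatment_patterns(courses, config),
    rates = rates
  )
}

#' Write reports to CSV files
#'
#' @param reports Output of [build_reports()].
#' @param dir Output directory (created if needed).
#' @return Written paths, invisibly.
#' @export
write_reports <- function(reports, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  wr(reports$table1, "table1_demographics")
  wr(reports$table2$summary, "table2_summary")
  wr(reports$table2$patterns, "table2_patterns")
  wr(reports$table2$discontinuation, "table2_discontinuation")
  wr(reports$rates, "rates")
  invisible(paths)
}
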