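# Code lists and analysis configuration.
#
# Raw claims carry ICD-9-CM / ICD-10-CM diagnosis codes and drug names; the
# pipeline works on analytic groups (JIA, SpA_feature, uveitis, psoriasis /
# NSAID, steroid, csDMARD, biologic).  The mapping lives in a versioned YAML
# file so it can be swapped without touching code.

the_cache <- new.env(parent = emptyenv())

#' Read a code-list file
#'
#' @param path Path to a YAML file with `diagnoses` (per-group `icd9`/`icd10`
#'   prefix vectors) and `drugs` (per-class drug-name vectors) entries.
#' @return A list with elements `diagnoses` and `drugs`.
#' @export
read_code_lists <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("code list file not found: ", path))
  }
  cl <- yaml::read_yaml(path)
  if (!all(c("diagnoses", "drugs") %in% names(cl))) {
    abort("code list file must contain 'diagnoses' and 'drugs' entries")
  }
  cl
}

#' Default diagnosis and drug code lists
#'
#' The shipped lists are a documented stand-in for the operational lists used
#' against the restricted source database (see the packaged
#' `extdata/code_lists.yaml` for provenance notes).
#'
#' @return A list with elements `diagnoses` and `drugs`.
#' @export
default_code_lists <- function() {
  if (is.null(the_cache$code_lists)) {
    path <- system.file("extdata", "code_lists.yaml", package = "jiaepi")
    the_cache$code_lists <- read_code_lists(path)
  }
  the_cache$code_lists
}

#' Map diagnosis codes to analytic groups
#'
#' Matches by longest code prefix within the relevant dialect, so `"L40.5"`
#' (a spondyloarthritis feature) takes precedence over `"L40"` (psoriasis).
#' Unmatched codes map to `"other"`.
#'
#' @param code Character vector of raw diagnosis codes.
#' @param code_system Character vector, `"ICD9CM"` or `"ICD10CM"`, recycled.
#' @param code_lists Code lists as returned by [default_code_lists()].
#' @return Character vector of diagnosis groups.
#' @export
dx_group_for_code <- function(code, code_system, code_lists = default_code_lists()) {
  tab <- dx_prefix_table(code_lists)
  out <- rep("other", length(code))
  code_system <- rep_len(code_system, length(code))
  for (sys in c("ICD9CM", "ICD10CM")) {
    idx <- which(code_system == sys)
    if (!length(idx)) next
    prefixes <- tab[tab$system == sys, ]
    # longest prefix first so specific codes beat generic ones
    prefixes <- prefixes[order(-nchar(prefixes$prefix)), ]
    unresolved <- rep(TRUE, length(idx))
    for (j in seq_len(nrow(prefixes))) {
      hit <- unresolved & startsWith(code[idx], prefixes$prefix[j])
      out[idx[hit]] <- prefixes$group[j]
      unresolved <- unresolved & !hit
    }
  }
  out
}

dx_prefix_table <- function(code_lists) {
  groups <- names(code_lists$diagnoses)
  purrr::map_dfr(groups, function(g) {
    entry <- code_lists$diagnoses[[g]]
    tibble::tibble(
      group = g,
      system = rep(c("ICD9CM", "ICD10CM"), c(length(entry$icd9), length(entry$icd10))),
      prefix = c(as.character(entry$icd9), as.character(entry$icd10))
    )
  })
}

#' Map drug names to drug classes
#'
#' @param drug_name Character vector of drug names (case-insensitive).
#' @param code_lists Code lists as returned by [default_code_lists()].
#' @return Character vector of drug classes (`"other"` when unknown).
#' @export
drug_class_for_name <- function(drug_name, code_lists = default_code_lists()) {
  classes <- names(code_lists$drugs)
  out <- rep("other", length(drug_name))
  lname <- tolower(drug_name)
  for (cl in classes) {
    out[lname %in% tolower(code_lists$drugs[[cl]])] <- cl
  }
  out
}

#' A representative diagnosis code for a group under a given dialect
#'
#' Used by the synthetic generator so emitted codes honour the dialect switch.
#'
#' @param group Diagnosis group.
#' @param code_system `"ICD9CM"` or `"ICD10CM"`.
#' @param code_lists Code lists.
#' @return A single code string.
#' @keywords internal
representative_code <- function(group, code_system, code_lists = default_code_lists()) {
  entry <- code_lists$diagnoses[[group]]
  if (is.null(entry)) abort(paste0("unknown diagnosis group: ", group))
  if (code_system == "ICD9CM") entry$icd9[[1]] else entry$icd10[[1]]
}

#' Analysis configuration
#'
#' Central knob set for the pipeline: grace periods, study windows, the age
#' cutoff and the rule variants that the source-study text leaves open.
#'
#' @param grace_small_molecule Grace period in days for NSAIDs, systemic
#'   steroids and csDMARDs (default 14).
#' @param grace_biologic Grace period in days for biologics (default 60).
#' @param chronic_days Minimum covered days in one episode for a drug to count
#'   as a chronic treatment ("more than three consecutive months", default 90).
#' @param nsaid_min_covered_days Minimum covered NSAID days for cohort
#'   inclusion; "more than 14 consecutive days" means at least 15 (default 15).
#' @param study_window Half-open date interval `[start, end)` with claims
#'   coverage (default 2011-01-01 to 2021-01-01).
#' @param identification_window Half-open date interval in which the index
#'   (first) JIA diagnosis must fall (default 2012-01-01 to 2020-01-01).
#' @param dialect_switch Date at which ICD-10-CM replaces ICD-9-CM
#'   (default 2016-01-01; ICD-9-CM is used strictly before this date).
#' @param age_cutoff Age (completed years) strictly below which a patient is
#'   eligible at index: 16 for "under 16", 17 to emulate an "age 16 or below"
#'   reading (default 16).
#' @param prevalence_mode `"cumulative"` (registry prevalence: diagnosed on or
#'   before the year, still age-eligible and enrolled) or `"active_claim"`
#'   (requires at least one JIA claim in the year).
#' @param spa_same_day If `TRUE`, spondyloarthritis-feature codes only count
#'   toward subgrouping when issued on the same day as a JIA code; by default
#'   any co-occurrence in the record counts.
#' @param nsaid_rule `"intersect"` (qualifying NSAID episode must intersect the
#'   365 days after first diagnosis) or `"start_within"` (must start inside it).
#' @param event_definition Drug-survival event definition:
#'   `"index_stop_or_switch"` counts any end of index-biologic use (switch,
#'   interruption-with-restart, discontinuation) as the event;
#'   `"discontinuation_only"` counts only terminal discontinuation, censoring
#'   the rest.
#' @param index_biologics Drug names eligible as index biologics (abatacept is
#'   excluded from the pattern analysis).
#' @param code_lists Code lists, see [default_code_lists()].
#' @return A list of class `claims_config`.
#' @export
claims_config <- function(grace_small_molecule = 14L,
                          grace_biologic = 60L,
                          chronic_days = 90L,
                          nsaid_min_covered_days = 15L,
                          study_window = c(as.Date("2011-01-01"), as.Date("2021-01-01")),
                          identification_window = c(as.Date("2012-01-01"), as.Date("2020-01-01")),
                          dialect_switch = as.Date("2016-01-01"),
                          age_cutoff = 16L,
                          prevalence_mode = c("cumulative", "active_claim"),
                          spa_same_day = FALSE,
                          nsaid_rule = c("intersect", "start_within"),
                          event_definition = c("index_stop_or_switch", "discontinuation_only"),
                          index_biologics = c("etanercept", "adalimumab", "tocilizumab"),
                          code_lists = default_code_lists()) {
  study_window <- as.Date(study_window)
  identification_window <- as.Date(identification_window)
  stopifnot(length(study_window) == 2, length(identification_window) == 2)
  if (identification_window[1] < study_window[1] ||
      identification_window[2] > study_window[2]) {
    abort("identification_window must lie inside study_window")
  }
  structure(
    list(
      grace_small_molecule = as.integer(grace_small_molecule),
      grace_biologic = as.integer(grace_biologic),
      chronic_days = as.integer(chronic_days),
      nsaid_min_covered_days = as.integer(nsaid_min_covered_days),
      study_window = study_window,
      identification_window = identification_window,
      dialect_switch = as.Date(dialect_switch),
      age_cutoff = as.integer(age_cutoff),
      prevalence_mode = match.arg(prevalence_mode),
      spa_same_day = isTRUE(spa_same_day),
      nsaid_rule = match.arg(nsaid_rule),
      event_definition = match.arg(event_definition),
      index_biologics = index_biologics,
      code_lists = code_lists
    ),
    class = "claims_config"
  )
}

#' @export
print.claims_config <- function(x, ...) {
  cat("<claims_config>\n")
  cat("  grace: ", x$grace_small_molecule, " d (small molecule), ",
      x$grace_biologic, " d (biologic)\n", sep = "")
  cat("  study window: [", format(x$study_window[1]), ", ",
      format(x$study_window[2]), ")\n", sep = "")
  cat("  identification window: [", format(x$identification_window[1]), ", ",
      format(x$identification_window[2]), ")\n", sep = "")
  cat("  age cutoff: <", x$age_cutoff, " y; prevalence mode: ",
      x$prevalence_mode, "\n", sep = "")
  invisible(x)
}

# completed years between two dates (birthday arithmetic, not day counts)
completed_years <- function(birth_date, at_date) {
  yb <- as.integer(format(birth_date, "%Y"))
  ya <- as.integer(format(at_date, "%Y"))
  md_b <- format(birth_date, "%m%d")
  md_a <- format(at_date, "%m%d")
  ya - yb - as.integer(md_a < md_b)
}

age_group_of <- function(age) {
  cut(age, breaks = c(0, 6, 12, 16), labels = c("0-5", "6-11", "12-15"),
      right = FALSE, include.lowest = TRUE)
}

code_system_for_date <- function(date, dialect_switch = as.Date("2016-01-01")) {
  ifelse(date < dialect_switch, "ICD9CM", "ICD10CM")
}
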