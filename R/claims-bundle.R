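# The claims bundle: four flat tables plus the study windows.
#
# beneficiaries: person_id, sex, birth_date, enroll_start, enroll_end
#   (one row per enrollment interval; intervals half-open [start, end))
# diagnoses:    person_id, date, setting, code, code_system, visit_id, dx_group
# prescriptions: person_id, fill_date, days_supply, drug_name, visit_id, drug_class
# denominators: year, age_group, sex, person_count, person_years

#' Assemble a claims bundle
#'
#' @param beneficiaries,diagnoses,prescriptions,denominators Data frames with
#'   the columns documented above (derived columns `dx_group` / `drug_class`
#'   are recomputed from the configured code lists).
#' @param config A [claims_config()].
#' @return A `claims_bundle` object (a list of tibbles plus the windows).
#' @export
claims_bundle <- function(beneficiaries, diagnoses, prescriptions, denominators,
                          config = claims_config()) {
  beneficiaries <- tibble::as_tibble(beneficiaries)
  diagnoses <- tibble::as_tibble(diagnoses)
  prescriptions <- tibble::as_tibble(prescriptions)
  denominators <- tibble::as_tibble(denominators)

  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(paste0("missing required column(s) in ", what, ": ",
                   paste(miss, collapse = ", ")))
    }
  }
  req(beneficiaries, c("person_id", "sex", "birth_date", "enroll_start", "enroll_end"),
      "beneficiaries")
  req(diagnoses, c("person_id", "date", "setting", "code", "code_system"), "diagnoses")
  req(prescriptions, c("person_id", "fill_date", "days_supply", "drug_name"),
      "prescriptions")
  req(denominators, c("year", "age_group", "sex", "person_count", "person_years"),
      "denominators")

  if (!"visit_id" %in% names(diagnoses)) diagnoses$visit_id <- NA_character_
  if (!"visit_id" %in% names(prescriptions)) prescriptions$visit_id <- NA_character_

  diagnoses$dx_group <- dx_group_for_code(diagnoses$code, diagnoses$code_system,
                                          config$code_lists)
  prescriptions$drug_class <- drug_class_for_name(prescriptions$drug_name,
                                                  config$code_lists)
  n_unknown_dx <- sum(diagnoses$dx_group == "other" & nzchar(diagnoses$code))
  n_unknown_rx <- sum(prescriptions$drug_class == "other")
  if (n_unknown_rx > 0) {
    warn(paste0(n_unknown_rx, " prescription fill(s) with unmapped drug name; ",
                "kept with drug_class = 'other'"))
  }

  structure(
    list(
      beneficiaries = beneficiaries,
      diagnoses = diagnoses,
      prescriptions = prescriptions,
      denominators = denominators,
      study_window = config$study_window,
      identification_window = config$identification_window,
      config = config,
      n_unmapped = c(diagnoses = n_unknown_dx, prescriptions = n_unknown_rx)
    ),
    class = "claims_bundle"
  )
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat("  beneficiaries: ", nrow(x$beneficiaries), " enrollment rows, ",
      dplyr::n_distinct(x$beneficiaries$person_id), " persons\n", sep = "")
  cat("  diagnoses:     ", nrow(x$diagnoses), " events\n", sep = "")
  cat("  prescriptions: ", nrow(x$prescriptions), " fills\n", sep = "")
  cat("  denominators:  ", nrow(x$denominators), " strata\n", sep = "")
  cat("  study window:  [", format(x$study_window[1]), ", ",
      format(x$study_window[2]), ")\n", sep = "")
  invisible(x)
}

#' Validate a claims bundle against its structural invariants
#'
#' Checks (1) the code-dialect rule (ICD-9-CM strictly before the dialect
#' switch date, ICD-10-CM from it), (2) non-overlapping, sorted enrollment
#' intervals per person with birth date preceding enrollment, (3) all event
#' dates inside the study window, (4) positive days supply, and (5) denominator
#' person-years not exceeding person counts.
#'
#' @param bundle A `claims_bundle`.
#' @return A tibble of violations (zero rows when the bundle is valid) with
#'   columns `table`, `row`, `person_id`, `rule`, `detail`.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  cfg <- bundle$config
  v <- list()
  add <- function(table, row, person_id, rule, detail) {
    tibble::tibble(table = table, row = as.integer(row),
                   person_id = as.character(person_id), rule = rule,
                   detail = detail)
  }

  dx <- bundle$diagnoses
  if (nrow(dx)) {
    want <- code_system_for_date(dx$date, cfg$dialect_switch)
    bad <- which(dx$code_system != want)
    if (length(bad)) {
      v <- c(v, list(add("diagnoses", bad, dx$person_id[bad], "code_dialect",
                         paste0(dx$code_system[bad], " used on ", format(dx$date[bad])))))
    }
    out <- which(dx$date < bundle$study_window[1] | dx$date >= bundle$study_window[2])
    if (length(out)) {
      v <- c(v, list(add("diagnoses", out, dx$person_id[out], "out_of_window",
                         format(dx$date[out]))))
    }
  }

  rx <- bundle$prescriptions
  if (nrow(rx)) {
    out <- which(rx$fill_date < bundle$study_window[1] |
                   rx$fill_date >= bundle$study_window[2])
    if (length(out)) {
      v <- c(v, list(add("prescriptions", out, rx$person_id[out], "out_of_window",
                         format(rx$fill_date[out]))))
    }
    bad <- which(rx$days_supply < 1)
    if (length(bad)) {
      v <- c(v, list(add("prescriptions", bad, rx$person_id[bad],
                         "nonpositive_days_supply", as.character(rx$days_supply[bad]))))
    }
  }

  ben <- bundle$beneficiaries
  if (nrow(ben)) {
    ord <- order(ben$person_id, ben$enroll_start)
    b <- ben[ord, ]
    same <- c(FALSE, b$person_id[-1] == b$person_id[-nrow(b)])
    prev_end <- c(as.Date(NA), b$enroll_end[-nrow(b)])
    overlap <- which(same & b$enroll_start < prev_end)
    if (length(overlap)) {
      v <- c(v, list(add("beneficiaries", ord[overlap], b$person_id[overlap],
                         "enrollment_overlap",
                         paste0("starts ", format(b$enroll_start[overlap]),
                                " before previous interval ends"))))
    }
    bad_birth <- which(ben$birth_date > ben$enroll_start)
    if (length(bad_birth)) {
      v <- c(v, list(add("beneficiaries", bad_birth, ben$person_id[bad_birth],
                         "birth_after_enrollment", format(ben$birth_date[bad_birth]))))
    }
    bad_iv <- which(ben$enroll_start >= ben$enroll_end)
    if (length(bad_iv)) {
      v <- c(v, list(add("beneficiaries", bad_iv, ben$person_id[bad_iv],
                         "empty_enrollment_interval", "")))
    }
  }

  den <- bundle$denominators
  if (nrow(den)) {
    bad <- which(den$person_years > den$person_count + 1e-9)
    if (length(bad)) {
      v <- c(v, list(add("denominators", bad, NA, "person_years_exceed_count",
                         paste0(den$person_years[bad], " > ", den$person_count[bad]))))
    }
  }

  if (!length(v)) {
    return(tibble::tibble(table = character(), row = integer(),
                          person_id = character(), rule = character(),
                          detail = character()))
  }
  dplyr::bind_rows(v)
}

bundle_paths <- function(dir) {
  list(
    beneficiaries = file.path(dir, "beneficiaries.csv"),
    diagnoses = file.path(dir, "diagnoses.csv"),
    prescriptions = file.path(dir, "prescriptions.csv"),
    denominators = file.path(dir, "denominators.csv")
  )
}

#' Read a claims bundle from four CSV files
#'
#' @param dir Directory containing `beneficiaries.csv`, `diagnoses.csv`,
#'   `prescriptions.csv` and `denominators.csv`.
#' @param config A [claims_config()].
#' @return A `claims_bundle`.
#' @export
read_bundle <- function(dir, config = claims_config()) {
  paths <- bundle_paths(dir)
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing)) {
    abort(paste0("missing bundle file(s): ",
                 paste(unlist(missing), collapse = ", ")))
  }
  rd <- function(path, col_types) {
    out <- tryCatch(
      readr::read_csv(path, col_types = col_types, progress = FALSE),
      error = function(e) abort(paste0("failed to parse ", path, ": ",
                                       conditionMessage(e)))
    )
    probs <- readr::problems(out)
    if (nrow(probs)) {
      abort(paste0("failed to parse ", path, " (first problem at row ",
                   probs$row[1], ": ", probs$expected[1], ")"))
    }
    out
  }
  ben <- rd(paths$beneficiaries,
            readr::cols(person_id = "c", sex = "c", birth_date = "D",
                        enroll_start = "D", enroll_end = "D"))
  dx <- rd(paths$diagnoses,
           readr::cols(person_id = "c", date = "D", setting = "c", code = "c",
                       code_system = "c", visit_id = "c", .default = "c"))
  rx <- rd(paths$prescriptions,
           readr::cols(person_id = "c", fill_date = "D", days_supply = "i",
                       drug_name = "c", visit_id = "c", .default = "c"))
  den <- rd(paths$denominators,
            readr::cols(year = "i", age_group = "c", sex = "c",
                        person_count = "d", person_years = "d"))
  dx$dx_group <- NULL
  rx$drug_class <- NULL
  claims_bundle(ben, dx, rx, den, config = config)
}

#' Write a claims bundle to four CSV files
#'
#' Round-trip property: `read_bundle()` of a written bundle reproduces it
#' field-for-field (derived group columns are recomputed from the same code
#' lists on read).
#'
#' @param bundle A `claims_bundle`.
#' @param dir Output directory (created if needed).
#' @return The paths of the written files, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", dir))
  }
  paths <- bundle_paths(dir)
  readr::write_csv(bundle$beneficiaries, paths$beneficiaries, progress = FALSE)
  readr::write_csv(dplyr::select(bundle$diagnoses, -dplyr::any_of("dx_group")),
                   paths$diagnoses, progress = FALSE)
  readr::write_csv(dplyr::select(bundle$prescriptions, -dplyr::any_of("drug_class")),
                   paths$prescriptions, progress = FALSE)
  readr::write_csv(bundle$denominators, paths$denominators, progress = FALSE)
  invisible(paths)
}
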