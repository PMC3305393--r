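#' Disease groups recognised by the SUPPORT model
#'
#' The SUPPORT model stratifies seriously ill patients into eight major
#' diagnostic groupings. Exactly one group applies per patient; multiple
#' organ system failure may additionally carry a malignancy flag
#' (`mosf_with_malignancy`).
#'
#' @return Character vector of the eight group labels.
#' @export
#' @examples
#' support_disease_groups()
support_disease_groups <- function() {
  c("ARF", "MOSF", "COPD", "CHF", "Cirrhosis", "Coma",
    "LungCancer", "ColonCancer")
}

# physiology columns of a patient record, in input order
physiology_fields <- function() {
  c("alb", "aresp", "bil", "cr", "na", "pao2_fio2",
    "mean_bp", "wbc", "temp", "hr")
}

patient_fields <- function() {
  c("group", "mosf_with_malignancy", "age", "scoma", "hday", "cancer",
    physiology_fields())
}

#' Normal physiology values used by impute-normal mode
#'
#' When a physiologic measure is missing and `impute = TRUE`, the
#' documented normal value is substituted (the practice used when the
#' SUPPORT score was originally deployed). Every substitution is
#' reported via a message.
#'
#' @return Named list of normal values, one per physiologic field.
#' @export
support_normal_values <- function() {
  list(alb = 3.5, aresp = 0, bil = 1.01, cr = 1.01, na = 137,
       pao2_fio2 = 333.3, mean_bp = 90, wbc = 9, temp = 37, hr = 100)
}

# validation ranges; temp and na bounds are part of the contract, the rest
# are data-entry sanity bounds documented here
validation_ranges <- function() {
  list(
    age       = c(18, 120),
    scoma     = c(0, 100),
    hday      = c(1, Inf),
    cancer    = c(0, 2),
    alb       = c(0, 10),
    aresp     = c(0, Inf),
    bil       = c(0, 80),
    cr        = c(0, 40),
    na        = c(100, 180),
    pao2_fio2 = c(0, 700),
    mean_bp   = c(0, 250),
    wbc       = c(0, 200),
    temp      = c(25, 45),
    hr        = c(0, 300)
  )
}

#' Validate (and optionally impute) patient records
#'
#' Checks a data frame of patient records against the input contract of
#' the SUPPORT model: a recognised disease group, the malignancy flag
#' only for MOSF patients, and all demographic and physiologic values
#' present, finite and inside their validation ranges.
#'
#' @param patients Data frame with columns `group`, `age`, `scoma`,
#'   `hday`, `cancer` and the ten physiologic measures `alb`, `aresp`,
#'   `bil`, `cr`, `na`, `pao2_fio2`, `mean_bp`, `wbc`, `temp`, `hr`.
#'   `mosf_with_malignancy` is optional and defaults to `FALSE`.
#' @param impute If `TRUE`, missing physiologic values are replaced by
#'   [support_normal_values()] (each substitution is messaged); missing
#'   values otherwise raise an incomplete-record error naming the field.
#' @return A validated tibble with all columns present.
#' @export
#' @examples
#' validate_patients(example_patients())
validate_patients <- function(patients, impute = FALSE) {
  patients <- as_tibble(patients)
  if (nrow(patients) == 0) {
    abort("`patients` must contain at least one record.",
          class = "regretdca_validation")
  }
  if (!"group" %in% names(patients)) {
    abort("incomplete record: missing field `group`.",
          class = "regretdca_incomplete_record")
  }
  if (!"mosf_with_malignancy" %in% names(patients)) {
    patients$mosf_with_malignancy <- FALSE
  }
  patients$mosf_with_malignancy[is.na(patients$mosf_with_malignancy)] <- FALSE

  missing_cols <- setdiff(patient_fields(), names(patients))
  if (length(missing_cols) > 0) {
    abort(paste0("incomplete record: missing field `", missing_cols[1], "`."),
          class = "regretdca_incomplete_record")
  }

  bad_group <- !patients$group %in% support_disease_groups()
  if (any(bad_group)) {
    abort(paste0("validation: unknown disease group `",
                 patients$group[which(bad_group)[1]], "`."),
          class = "regretdca_validation")
  }
  flag_no_mosf <- patients$mosf_with_malignancy & patients$group != "MOSF"
  if (any(flag_no_mosf)) {
    abort("validation: `mosf_with_malignancy` is only allowed when group = MOSF.",
          class = "regretdca_validation")
  }

  if (impute) {
    normals <- support_normal_values()
    for (f in physiology_fields()) {
      idx <- which(is.na(patients[[f]]))
      if (length(idx) > 0) {
        patients[[f]][idx] <- normals[[f]]
        inform(paste0("imputed normal value ", normals[[f]], " for `", f,
                      "` in ", length(idx), " record(s)."))
      }
    }
  }

  numeric_fields <- setdiff(patient_fields(), c("group", "mosf_with_malignancy"))
  for (f in numeric_fields) {
    x <- patients[[f]]
    if (anyNA(x)) {
      abort(paste0("incomplete record: missing field `", f, "`."),
            class = "regretdca_incomplete_record")
    }
    if (any(!is.finite(x))) {
      abort(paste0("validation: non-finite value in `", f, "`."),
            class = "regretdca_validation")
    }
  }
  rng <- validation_ranges()
  for (f in names(rng)) {
    x <- patients[[f]]
    if (any(x < rng[[f]][1] | x > rng[[f]][2])) {
      abort(paste0("validation: `", f, "` outside [", rng[[f]][1], ", ",
                   rng[[f]][2], "]."),
            class = "regretdca_validation")
    }
  }
  if (any(patients$hday != round(patients$hday))) {
    abort("validation: `hday` must be a whole number of days.",
          class = "regretdca_validation")
  }
  if (any(!patients$cancer %in% 0:2)) {
    abort("validation: `cancer` must be 0 (none), 1 (present) or 2 (metastatic).",
          class = "regretdca_validation")
  }
  patients
}

#' Read patient records from CSV or JSON
#'
#' One record per CSV row, or a JSON object (single patient) / array of
#' objects. Column names follow the input contract of
#' [validate_patients()].
#'
#' @param path File path ending in `.csv` or `.json`.
#' @inheritParams validate_patients
#' @return A validated tibble of patient records.
#' @export
read_patients <- function(path, impute = FALSE) {
  ext <- tolower(tools::file_ext(path))
  patients <- switch(ext,
    csv  = readr::read_csv(path, show_col_types = FALSE),
    json = {
      x <- jsonlite::fromJSON(path)
      if (!is.data.frame(x)) x <- as_tibble(as.list(x))
      x
    },
    abort(paste0("unsupported patient file extension `", ext, "`."),
          class = "regretdca_validation")
  )
  validate_patients(patients, impute = impute)
}

#' Example patient records, one per disease group
#'
#' A small synthetic panel of eight seriously ill patients (one per
#' SUPPORT diagnostic grouping) with plausible day-3 physiology, used
#' throughout the documentation and tests. These are invented records,
#' not data from any study.
#'
#' @return A tibble of eight validated patient records.
#' @export
#' @examples
#' death_probability(example_patients())
example_patients <- function() {
  pts <- tibble(
    group = support_disease_groups(),
    mosf_with_malignancy =
      c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    age    = c(64, 58, 71, 77, 52, 68, 63, 70),
    scoma  = c(0, 26, 0, 0, 9, 61, 0, 0),
    hday   = c(2, 4, 1, 3, 6, 2, 1, 5),
    cancer = c(0, 1, 0, 0, 0, 0, 2, 2),
    alb    = c(2.6, 2.1, 3.1, 3.4, 2.4, 3.0, 2.9, 2.7),
    aresp  = c(6, 8, 4, 2, 0, 3, 2, 1),
    bil    = c(1.2, 4.8, 0.8, 1.0, 8.6, 0.9, 1.4, 2.2),
    cr     = c(1.6, 3.2, 1.1, 1.8, 1.3, 1.0, 0.9, 1.2),
    na     = c(135, 131, 139, 133, 128, 141, 136, 134),
    pao2_fio2 = c(110, 95, 180, 240, 310, 260, 220, 300),
    mean_bp   = c(62, 48, 74, 58, 66, 85, 78, 72),
    wbc    = c(14.2, 22.5, 11.8, 8.4, 6.1, 12.6, 9.7, 13.3),
    temp   = c(38.1, 39.0, 37.2, 36.4, 36.9, 38.6, 37.0, 37.8),
    hr     = c(112, 128, 96, 104, 88, 118, 92, 100)
  )
  validate_patients(pts)
}
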