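#' Read a patient-level admission table
#'
#' One row per surgical admission. Expected header:
#' `patient_id,home_zip,hospital_id,state,age,sex,race_ethnicity,rural_urban,payer,sdi,died_in_hospital`.
#' ZIP codes and ids are read as character so zero-padded codes survive.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Data frame with the columns above; `died_in_hospital` logical.
#' @export
read_patients <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("patient_id", "home_zip", "hospital_id", "state", "age", "sex",
            "race_ethnicity", "rural_urban", "payer", "sdi", "died_in_hospital")
  if (!all(need %in% names(x))) {
    stop("patient table must have columns: ", paste(need, collapse = ", "))
  }
  x <- x[need]
  x$age <- as.numeric(x$age)
  x$sdi <- as.numeric(x$sdi)
  x$died_in_hospital <- as.logical(x$died_in_hospital)
  x
}

#' Read a hospital attribute table
#'
#' Expected header: `hospital_id,zip,state,med_school,rural,coc,centralized`;
#' the four characteristics are read as logical.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Data frame with one row per hospital.
#' @export
read_hospitals <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", stringsAsFactors = FALSE)
  need <- c("hospital_id", "zip", "state", "med_school", "rural", "coc",
            "centralized")
  if (!all(need %in% names(x))) {
    stop("hospital table must have columns: ", paste(need, collapse = ", "))
  }
  x <- x[need]
  for (v in c("med_school", "rural", "coc", "centralized")) {
    x[[v]] <- as.logical(x[[v]])
    if (anyNA(x[[v]])) stop("hospital column '", v, "' has missing values")
  }
  if (anyDuplicated(x$hospital_id)) stop("duplicate hospital_id in hospital table")
  x
}

#' Apply the cohort exclusion rules
#'
#' Removes, in order: (1) records with a missing or unresolvable patient or
#' hospital ZIP code (unresolvable = absent from the centroid table);
#' (2) records whose home ZIP lies in a state outside `valid_states`
#' (out-of-state patients, whose in-state hospital options are not observed).
#' The order of the remaining records is preserved.
#'
#' @param patients Patient data frame (see [read_patients()]).
#' @param hospitals Hospital data frame; supplies each hospital's ZIP.
#' @param centroids Centroid table giving each ZIP's state.
#' @param valid_states Character vector of study states.
#' @return List with `included` (filtered patient data frame) and `log`,
#'   a one-row data frame `n_input, n_missing_zip, n_out_of_state, n_included`.
#' @export
apply_exclusions <- function(patients, hospitals, centroids, valid_states) {
  stopifnot(length(valid_states) > 0)
  n_input <- nrow(patients)
  hosp_zip <- hospitals$zip[match(patients$hospital_id, hospitals$hospital_id)]
  bad_zip <- is.na(patients$home_zip) | is.na(hosp_zip) |
    !(patients$home_zip %in% centroids$zip) | !(hosp_zip %in% centroids$zip)
  home_state <- centroids$state[match(patients$home_zip, centroids$zip)]
  out_state <- !bad_zip & !(home_state %in% valid_states)
  included <- patients[!bad_zip & !out_state, , drop = FALSE]
  log <- data.frame(n_input = n_input,
                    n_missing_zip = sum(bad_zip),
                    n_out_of_state = sum(out_state),
                    n_included = nrow(included))
  list(included = included, log = log)
}

#' Hospital volume from the included cohort
#'
#' Volume of hospital j is the number of cohort patients treated there,
#' including each index patient (full-cohort volume, not prior-year volume).
#'
#' @param included Included patient data frame.
#' @return Named integer vector, one entry per hospital observed in the
#'   cohort; the values sum to `nrow(included)`.
#' @export
compute_hospital_volume <- function(included) {
  if (nrow(included) == 0) stop("empty cohort: no included patients")
  v <- table(included$hospital_id)
  stats::setNames(as.integer(v), names(v))
}

#' Median and interquartile range of hospital volume, by state
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param volumes Named vector from [compute_hospital_volume()].
#' @param hospital_states Named character vector mapping hospital id to
#'   state; if `NULL`, a single `overall` stratum is reported.
#' @return Data frame with columns `state, n_hospitals, median, q1, q3`.
#' @export
volume_summary <- function(volumes, hospital_states = NULL) {
  stopifnot(length(volumes) > 0)
  states <- if (is.null(hospital_states)) rep("overall", length(volumes))
            else as.character(hospital_states[names(volumes)])
  out <- lapply(split(as.numeric(volumes), states), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n_hospitals = length(v), median = q[2], q1 = q[1], q3 = q[3])
  })
  res <- do.call(rbind, out)
  data.frame(state = rownames(res), res, row.names = NULL)
}

#' ICD-10-PCS procedure codes defining the index operation
#'
#' Pancreatoduodenectomy admissions are identified by at least one
#' duodenal resection code together with at least one pancreatic head
#' resection code. Shipped for documentation of the cohort definition;
#' the package starts from an already-coded patient table and performs no
#' claims parsing.
#'
#' @format List with character vectors `duodenum` and `pancreas`.
#' @export
pd_icd10_codes <- list(
  duodenum = c("0DB90ZX", "0DB90ZZ", "0DB94ZX", "0DB94ZZ", "0DT90ZZ", "0DT94ZZ"),
  pancreas = c("0FBG0ZX", "0FBG0ZZ", "0FBG4ZX", "0FBG4ZZ", "0FTG0ZZ", "0FTG4ZZ")
)
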