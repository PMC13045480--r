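#' One virtual or measured subject
#'
#' Bundles the per-subject scalars (id, age, heart rate, stroke volume) with
#' the aortic root pressure and flow beats.  Pressure and flow must share the
#' sampling rate and sample count so that landmarks detected on one wave can
#' be read off the other.
#'
#' @param id Subject identifier (scalar, coerced to character).
#' @param age Age in years, within `[18, 90]`.
#' @param hr Heart rate in bpm, within `[40, 120]`.
#' @param sv Stroke volume in mL (positive); in dataset mode this is the
#'   value supplied by the source table and is what the proportional EF1
#'   estimate is scaled to.
#' @param pressure,flow `waveform` objects of kind `"pressure"` / `"flow"`.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(id, age, hr, sv, pressure, flow) {
  rec <- structure(list(id = as.character(id)[1L], age = as.numeric(age)[1L],
                        hr = as.numeric(hr)[1L], sv = as.numeric(sv)[1L],
                        pressure = pressure, flow = flow),
                   class = "subject_record")
  validate_subject(rec)
  rec
}

#' Validate a subject record
#'
#' @param rec A `subject_record`.
#' @return `rec` invisibly; errors name the violated invariant.
#' @export
validate_subject <- function(rec) {
  stopifnot(inherits(rec, "subject_record"))
  if (is.na(rec$age) || rec$age < 18 || rec$age > 90) {
    stop(sprintf("subject %s: age %s outside [18, 90]", rec$id, rec$age))
  }
  if (is.na(rec$hr) || rec$hr < 40 || rec$hr > 120) {
    stop(sprintf("subject %s: HR %s outside [40, 120] bpm", rec$id, rec$hr))
  }
  if (is.na(rec$sv) || rec$sv <= 0) {
    stop(sprintf("subject %s: SV must be positive", rec$id))
  }
  if (!inherits(rec$pressure, "waveform") || rec$pressure$kind != "pressure") {
    stop(sprintf("subject %s: 'pressure' must be a pressure waveform", rec$id))
  }
  if (!inherits(rec$flow, "waveform") || rec$flow$kind != "flow") {
    stop(sprintf("subject %s: 'flow' must be a flow waveform", rec$id))
  }
  if (rec$pressure$fs != rec$flow$fs ||
      length(rec$pressure$samples) != length(rec$flow$samples)) {
    stop(sprintf("subject %s: pressure and flow must share fs and length",
                 rec$id))
  }
  # aortic pressure plausibility doubles as a unit check (kPa exports ~ 12)
  if (max(rec$pressure$samples) > 300 || min(rec$pressure$samples) < 20) {
    stop(sprintf("subject %s: pressure outside [20, 300] mmHg - wrong units?",
                 rec$id))
  }
  validate_waveform(rec$pressure, hr = rec$hr)
  validate_waveform(rec$flow, hr = rec$hr)
  invisible(rec)
}

#' A cohort of subjects
#'
#' @param records List of `subject_record`s with unique ids; non-empty.
#' @param provenance `"synthetic"` or `"dataset"`.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(records, provenance = c("synthetic", "dataset")) {
  provenance <- match.arg(provenance)
  if (length(records) == 0L) stop("cohort must contain at least one subject")
  if (!all(vapply(records, inherits, logical(1), "subject_record"))) {
    stop("'records' must be a list of subject_record objects")
  }
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(records = records, provenance = provenance),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  ages <- vapply(x$records, `[[`, numeric(1), "age")
  cat(sprintf("<cohort_table: %d subjects (%s), ages %g-%g>\n",
              length(x$records), x$provenance, min(ages), max(ages)))
  invisible(x)
}

#' @export
length.cohort_table <- function(x) length(x$records)

#' Per-subject scalars of a cohort as a tibble
#'
#' @param cohort A `cohort_table`.
#' @return A tibble with columns `id`, `age`, `hr`, `sv`.
#' @export
cohort_scalars <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  tibble::tibble(
    id  = vapply(cohort$records, `[[`, character(1), "id"),
    age = vapply(cohort$records, `[[`, numeric(1), "age"),
    hr  = vapply(cohort$records, `[[`, numeric(1), "hr"),
    sv  = vapply(cohort$records, `[[`, numeric(1), "sv"))
}
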