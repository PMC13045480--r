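#' Column-mapping configuration for cohort files
#'
#' The reader and writer use one CSV per subject (time, pressure, flow
#' columns) plus a cohort-level CSV of scalar haemodynamics.  Exports from
#' other sources can be adapted by renaming the expected columns here.
#'
#' @param id,age,hr,sv Column names of the scalar haemodynamics table.
#' @param time,pressure,flow Column names of the per-subject waveform
#'   files (seconds, mmHg, mL/s).
#' @param fs Sampling frequency in Hz; `NULL` (default) infers it from the
#'   time column spacing.
#' @return A list of class `io_config`.
#' @export
io_config <- function(id = "id", age = "age", hr = "hr", sv = "sv",
                      time = "time_s", pressure = "pressure_mmHg",
                      flow = "flow_ml_s", fs = NULL) {
  structure(list(id = id, age = age, hr = hr, sv = sv, time = time,
                 pressure = pressure, flow = flow, fs = fs),
            class = "io_config")
}

#' Write a cohort to delimited files
#'
#' Writes one `<id>.csv` per subject (columns per the default
#' [io_config()]) and a `cohort.csv` of scalar haemodynamics
#' (id, age, hr, sv, fs) into `out_dir`.  Values keep full double
#' precision.
#'
#' @param cohort A [cohort_table()].
#' @param out_dir Target directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  ids <- vapply(cohort$records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: nothing written")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  for (rec in cohort$records) {
    df <- data.frame(time_s = wf_time(rec$pressure),
                     pressure_mmHg = rec$pressure$samples,
                     flow_ml_s = rec$flow$samples)
    utils::write.csv(df, file.path(out_dir, paste0(rec$id, ".csv")),
                     row.names = FALSE)
  }
  scal <- cohort_scalars(cohort)
  scal$fs <- vapply(cohort$records, function(r) r$pressure$fs, numeric(1))
  utils::write.csv(scal, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Read a cohort from delimited files
#'
#' Reads the scalar haemodynamics table and the per-subject waveform CSVs,
#' validates every subject, and drops (with a logged reason) any subject
#' that fails validation — for example pressures outside the 20-300 mmHg
#' plausibility band, which catches exports in kPa.
#'
#' @param waveform_dir Directory holding `<id>.csv` waveform files.
#' @param haemo_table Path of the scalar haemodynamics CSV.
#' @param config An [io_config()] mapping column names.
#' @return A [cohort_table()] with provenance `"dataset"`.  Dropped
#'   subjects are recorded in `attr(result, "exclusions")` (tibble with
#'   `id`, `reason`).  A missing required column in the table is a
#'   configuration error; an empty result after validation is an error.
#' @export
read_cohort <- function(waveform_dir, haemo_table, config = io_config()) {
  stopifnot(inherits(config, "io_config"))
  if (!file.exists(haemo_table)) stop("haemo table not found: ", haemo_table)
  tab <- utils::read.csv(haemo_table, check.names = FALSE)
  need <- c(config$id, config$age, config$hr, config$sv)
  if (!all(need %in% names(tab))) {
    stop("configuration error: haemo table lacks required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  records <- list()
  excl <- list()
  for (i in seq_len(nrow(tab))) {
    id <- as.character(tab[[config$id]][i])
    res <- tryCatch({
      path <- file.path(waveform_dir, paste0(id, ".csv"))
      if (!file.exists(path)) stop("waveform file missing: ", basename(path))
      wf <- utils::read.csv(path, check.names = FALSE)
      for (cl in c(config$time, config$pressure, config$flow)) {
        if (!cl %in% names(wf)) stop("waveform column missing: ", cl)
      }
      fs <- config$fs
      if (is.null(fs)) {
        dtm <- diff(wf[[config$time]])
        if (any(dtm <= 0) || diff(range(dtm)) > 1e-6 * mean(dtm)) {
          stop("time column is not uniformly increasing")
        }
        fs <- 1 / mean(dtm)
      }
      subject_record(
        id = id, age = tab[[config$age]][i], hr = tab[[config$hr]][i],
        sv = tab[[config$sv]][i],
        pressure = waveform(wf[[config$pressure]], fs, "pressure"),
        flow = waveform(wf[[config$flow]], fs, "flow"))
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "subject_record")) {
      records[[length(records) + 1L]] <- res
    } else {
      excl[[length(excl) + 1L]] <- tibble::tibble(id = id, reason = res)
    }
  }
  if (length(records) == 0L) {
    stop("no subject passed validation (", length(excl), " dropped)")
  }
  out <- cohort_table(records, provenance = "dataset")
  attr(out, "exclusions") <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(id = character(), reason = character())
  out
}
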