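#' Per-subject haemodynamic indices
#'
#' Runs the full single-subject analysis chain on one record: peak-flow
#' landmark, dicrotic notch (ESP), diastolic time constant, pressure-only
#' LVEF, absolute volumes anchored to the subject's stroke volume, EF1
#' from the flow wave, and the coupling indices Ea, Ees, Ea/Ees.
#'
#' @param rec A [subject_record()].
#' @param notch_w_max Notch search window after peak flow, s.
#' @param tau_delta_start,tau_delta_end Diastolic fit-window margins, s
#'   (see [estimate_tau()]).
#' @return A one-row tibble: `id, age, hr, sv, sv1, edv, esv, lvef, ef1,
#'   esp, ea, ees, ea_over_ees, tau, t_peak_flow, t_notch, qc_flags`
#'   (empty string when clean).  If any stage fails, the scalar columns
#'   are NA and `qc_flags` holds the failing stage and message.
#' @export
subject_indices <- function(rec, notch_w_max = 0.35,
                            tau_delta_start = 0.03, tau_delta_end = 0.01) {
  stopifnot(inherits(rec, "subject_record"))
  base <- tibble::tibble(id = rec$id, age = rec$age, hr = rec$hr, sv = rec$sv)
  na_row <- function(flag) {
    dplyr::bind_cols(base, tibble::tibble(
      sv1 = NA_real_, edv = NA_real_, esv = NA_real_, lvef = NA_real_,
      ef1 = NA_real_, esp = NA_real_, ea = NA_real_, ees = NA_real_,
      ea_over_ees = NA_real_, tau = NA_real_, t_peak_flow = NA_real_,
      t_notch = NA_real_, qc_flags = flag))
  }
  stage <- "peak_flow"
  out <- tryCatch({
    t_pf <- detect_peak_flow(rec$flow)
    stage <- "dicrotic_notch"
    nd <- detect_dicrotic_notch(rec$pressure, t_pf, w_max = notch_w_max)
    stage <- "tau"
    ta <- estimate_tau(rec$pressure, nd$t_notch,
                       delta_start = tau_delta_start,
                       delta_end = tau_delta_end)
    stage <- "lvef"
    lv <- estimate_lvef(rec$pressure, ta, nd$t_notch)
    vol <- absolute_volumes(lv, rec$sv)
    stage <- "ef1"
    ef <- compute_ef1(rec$flow, sv = rec$sv, edv = vol$edv)
    vac <- compute_vac(nd$esp, sv = rec$sv, esv = vol$esv)
    flags <- c(if (ta$low_r2) "tau_low_r2",
               if (lv$implausible) "lvef_implausible")
    dplyr::bind_cols(base, tibble::tibble(
      sv1 = ef$sv1, edv = vol$edv, esv = vol$esv, lvef = lv$lvef,
      ef1 = ef$ef1, esp = nd$esp, ea = vac$ea, ees = vac$ees,
      ea_over_ees = vac$ea_over_ees, tau = ta$tau,
      t_peak_flow = t_pf, t_notch = nd$t_notch,
      qc_flags = paste(flags, collapse = ";")))
  }, error = function(e) na_row(paste0(stage, ": ", conditionMessage(e))))
  out
}

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a virtual cohort) or `"dataset"`
#'   (read waveform exports from disk).
#' @param n,age_levels,seed Synthetic-mode cohort settings (see
#'   [generate_cohort()]).
#' @param waveform_dir,haemo_table,io Dataset-mode input paths and column
#'   mapping ([io_config()]).
#' @param notch_w_max,tau_delta_start,tau_delta_end Landmark/fit settings
#'   passed to [subject_indices()].
#' @param dunn_method Dependent-correlation variant (see
#'   [dunn_clark_test()]).
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "dataset"), n = 300,
                       age_levels = c(25, 35, 45, 55, 65, 75), seed = 1L,
                       waveform_dir = NULL, haemo_table = NULL,
                       io = io_config(),
                       notch_w_max = 0.35, tau_delta_start = 0.03,
                       tau_delta_end = 0.01,
                       dunn_method = "pooled", out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "dataset") {
    for (pth in c(waveform_dir, haemo_table)) {
      if (is.null(pth) || !file.exists(pth)) {
        stop("dataset mode requires existing 'waveform_dir' and 'haemo_table'")
      }
    }
  }
  structure(list(mode = mode, n = n, age_levels = age_levels,
                 seed = as.integer(seed), waveform_dir = waveform_dir,
                 haemo_table = haemo_table, io = io,
                 notch_w_max = notch_w_max,
                 tau_delta_start = tau_delta_start,
                 tau_delta_end = tau_delta_end,
                 dunn_method = dunn_method, out_dir = out_dir),
            class = "run_config")
}

# mean (SD) summary of the per-subject indices within each age level
summarize_by_age <- function(indices) {
  vars <- c("sv", "sv1", "edv", "esv", "ef1", "lvef", "ea", "ees",
            "ea_over_ees")
  ok <- indices[indices$qc_flags == "" | is.na(indices$qc_flags) |
                  !grepl(":", indices$qc_flags), ]
  ok <- ok[stats::complete.cases(ok[vars]), ]
  dplyr::summarise(
    dplyr::group_by(ok, age),
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(vars),
                  list(mean = mean, sd = stats::sd)),
    .groups = "drop")
}

# correlation battery: EF1 and LVEF against each coupling index, with the
# dependent-correlation comparison between the two
correlation_battery <- function(indices, dunn_method = "pooled") {
  rows <- list()
  r_ef1_lvef <- pearson_with_ci(indices$ef1, indices$lvef)
  for (v in c("ees", "ea", "ea_over_ees")) {
    c1 <- pearson_with_ci(indices$ef1, indices[[v]])
    c2 <- pearson_with_ci(indices$lvef, indices[[v]])
    r12 <- stats::cor(indices$ef1, indices$lvef)
    dc <- dunn_clark_test(c1$r, c2$r, r12, n = c1$n, method = dunn_method)
    rows[[v]] <- tibble::tibble(
      variable = v,
      r_ef1 = c1$r, r_ef1_lo = c1$ci[1], r_ef1_hi = c1$ci[2],
      r_lvef = c2$r, r_lvef_lo = c2$ci[1], r_lvef_hi = c2$ci[2],
      z_diff = dc$z_stat, p_diff = dc$p)
  }
  list(table = dplyr::bind_rows(rows),
       ef1_lvef = r_ef1_lvef)
}

# regression battery mirroring the published layout: per coupling index,
# unadjusted and age/HR-adjusted standardized coefficients for both
# outcomes, plus the simple age models
regression_battery <- function(indices) {
  rows <- list()
  for (outc in c("lvef", "ef1")) {
    agefit <- fit_regression(indices, outc, "age")
    rows[[paste0(outc, "_age")]] <- dplyr::bind_cols(
      tibble::tibble(outcome = outc, predictor = "age", model = "age_only"),
      agefit$coefficients[1L, -1L])
    for (v in c("ees", "ea", "ea_over_ees")) {
      un <- fit_regression(indices, outc, v)
      ad <- fit_regression(indices, outc, v, covariates = c("age", "hr"))
      rows[[paste0(outc, "_", v, "_un")]] <- dplyr::bind_cols(
        tibble::tibble(outcome = outc, predictor = v, model = "unadjusted"),
        un$coefficients[1L, -1L])
      rows[[paste0(outc, "_", v, "_adj")]] <- dplyr::bind_cols(
        tibble::tibble(outcome = outc, predictor = v, model = "adjusted_age_hr"),
        ad$coefficients[ad$coefficients$term == v, -1L])
    }
  }
  dplyr::bind_rows(rows)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; an optional `io`
#' block maps column names (see [io_config()]).
#'
#' @param path Path of the YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  io_args <- y$io %||% list()
  y$io <- NULL
  args <- y
  args$io <- do.call(io_config, io_args)
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full cohort analysis pipeline
#'
#' Builds (or reads) the cohort, computes per-subject indices, and
#' assembles the cohort-level outputs: an age-stratified mean/SD summary,
#' the EF1-vs-LVEF correlation battery with dependent-correlation
#' comparisons, the standardized regression table (unadjusted and
#' age/HR-adjusted), and a run manifest with the seed and exclusion log.
#' With `out_dir` set, each table is written as CSV plus a JSON manifest.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `indices`, `summary_by_age`,
#'   `correlations` (tibble), `ef1_lvef` (correlation of the two indices),
#'   `regressions`, `exclusions`, `manifest`, and (synthetic mode) `truth`.
#'   Emits a warning when more than 20% of subjects fail QC.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  input_exclusions <- tibble::tibble(id = character(), reason = character())
  if (config$mode == "synthetic") {
    gen <- generate_cohort(config$n, config$age_levels, seed = config$seed)
    cohort <- gen$cohort
    truth <- gen$truth
    n_in <- config$n
    if (gen$n_rejected > 0) {
      input_exclusions <- tibble::tibble(
        id = sprintf("draw_rejected_%03d", seq_len(gen$n_rejected)),
        reason = "plausibility filter (SBP/DBP out of range)")
    }
  } else {
    cohort <- read_cohort(config$waveform_dir, config$haemo_table, config$io)
    input_exclusions <- attr(cohort, "exclusions")
    n_in <- length(cohort) + nrow(input_exclusions)
  }

  indices <- dplyr::bind_rows(lapply(
    cohort$records, subject_indices,
    notch_w_max = config$notch_w_max,
    tau_delta_start = config$tau_delta_start,
    tau_delta_end = config$tau_delta_end))

  failed <- grepl(":", indices$qc_flags)
  qc_exclusions <- tibble::tibble(id = indices$id[failed],
                                  reason = indices$qc_flags[failed])
  exclusions <- dplyr::bind_rows(input_exclusions, qc_exclusions)
  ok <- indices[!failed, ]
  if (nrow(ok) == 0L) stop("every subject failed QC")
  frac_failed <- sum(failed) / nrow(indices)
  if (frac_failed > 0.2) {
    warning(sprintf("QC excluded %.0f%% of subjects (> 20%%)",
                    100 * frac_failed))
  }

  if (nrow(ok) >= 30L) {
    cb <- correlation_battery(ok, config$dunn_method)
    regs <- regression_battery(ok)
  } else {
    warning("fewer than 30 analyzable subjects: cohort statistics skipped")
    cb <- list(table = NULL, ef1_lvef = NULL)
    regs <- NULL
  }
  result <- structure(list(
    indices = indices,
    summary_by_age = summarize_by_age(ok),
    correlations = cb$table,
    ef1_lvef = cb$ef1_lvef,
    regressions = regs,
    exclusions = exclusions,
    truth = truth,
    manifest = list(
      mode = config$mode, seed = config$seed,
      n_input = n_in, n_analyzed = nrow(ok),
      n_excluded = nrow(exclusions),
      dunn_method = config$dunn_method,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(result$indices,
                     file.path(config$out_dir, "indices.csv"),
                     row.names = FALSE)
    utils::write.csv(result$summary_by_age,
                     file.path(config$out_dir, "summary_by_age.csv"),
                     row.names = FALSE)
    if (!is.null(result$correlations)) {
      utils::write.csv(result$correlations,
                       file.path(config$out_dir, "correlations.csv"),
                       row.names = FALSE)
    }
    if (!is.null(result$regressions)) {
      utils::write.csv(result$regressions,
                       file.path(config$out_dir, "regressions.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(result$exclusions,
                     file.path(config$out_dir, "exclusions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(result$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result (%s): %d analyzed / %d input, %d excluded>\n",
    x$manifest$mode, x$manifest$n_analyzed, x$manifest$n_input,
    x$manifest$n_excluded))
  cat("  mean EF1 %.1f%%, mean LVEF %.1f%%\n" |>
        sprintf(mean(x$indices$ef1, na.rm = TRUE),
                mean(x$indices$lvef, na.rm = TRUE)))
  invisible(x)
}
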