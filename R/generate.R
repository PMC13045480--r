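#' Age-specific simulation parameter templates
#'
#' Mean and SD of the beat-simulation parameters for the six decade levels
#' of the virtual cohort (ages 25-75).  The templates encode the expected
#' haemodynamic ageing pattern of healthy adults: aortic systolic pressure
#' rising ~15 mmHg and pulse pressure widening as arterial compliance
#' falls, diastolic pressure drifting down a few mmHg from midlife, mean
#' pressure roughly constant (resistance rising mildly), heart rate
#' roughly constant, end-diastolic volume shrinking ~20%, and end-systolic
#' elastance rising.
#'
#' @return A tibble with one row per age level and columns
#'   `age`, `edv_mean`, `edv_sd`, `emax_mean`, `emax_sd`, `hr_mean`,
#'   `hr_sd`, `r_mean`, `r_sd`, `c_mean`, `c_sd`, `tsys_mean`, `tsys_sd`.
#' @export
age_templates <- function() {
  tibble::tibble(
    age       = c(25,   35,   45,   55,   65,   75),
    edv_mean  = c(100,  95,   91,   88,   84,   81),
    edv_sd    = c(12,   11.5, 11,   10.5, 10,   9.5),
    emax_mean = c(2.90, 3.20, 3.35, 3.50, 3.65, 3.80),
    emax_sd   = c(0.33, 0.35, 0.36, 0.38, 0.39, 0.41),
    hr_mean   = c(73,   76,   77,   77,   76,   74),
    hr_sd     = c(9,    9,    9,    9,    9,    9),
    r_mean    = c(1.08, 1.20, 1.33, 1.27, 1.39, 1.53),
    r_sd      = c(0.08, 0.09, 0.10, 0.09, 0.10, 0.11),
    c_mean    = c(1.91, 1.51, 1.24, 1.10, 0.89, 0.82),
    c_sd      = c(0.15, 0.12, 0.10, 0.09, 0.07, 0.07),
    tsys_mean = c(0.41, 0.41, 0.41, 0.41, 0.41, 0.41),
    tsys_sd   = c(0.025, 0.025, 0.025, 0.025, 0.025, 0.025))
}

# draw one truncated-normal value (redraw, then clamp as a last resort)
rtrunc <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Generate a virtual cohort with known ground truth
#'
#' Draws per-subject simulation parameters from the age-specific templates,
#' simulates each beat with [simulate_beat()], and applies a fixed-range
#' plausibility filter on the resulting aortic pressures (SBP within
#' 85-140 mmHg, DBP within 55-95 mmHg); subjects failing the filter are
#' dropped, so the returned cohort may be smaller than `n`.  Fully
#' deterministic under a fixed `seed`.
#'
#' @param n Number of subjects to draw (>= 1), allocated to the age levels
#'   in rotation.
#' @param age_levels Subset of `c(25, 35, 45, 55, 65, 75)` (years).
#' @param seed Integer seed.
#' @param template Parameter templates, see [age_templates()].
#' @param fs Sampling frequency of the generated waveforms, Hz.
#' @return A list with `cohort` (a [cohort_table()], provenance
#'   `"synthetic"`), `truth` (tibble: `id`, `age`, simulation ground truth
#'   per subject, including the drawn `e_max` and the Windkessel `r_art`,
#'   `c_art`), and `n_rejected` (subjects dropped by the plausibility
#'   filter).
#' @examples
#' \donttest{
#' gc <- generate_cohort(12, seed = 1)
#' gc$cohort
#' }
#' @export
generate_cohort <- function(n, age_levels = c(25, 35, 45, 55, 65, 75),
                            seed = 1L, template = age_templates(),
                            fs = 500) {
  if (!(n >= 1)) stop("'n' must be at least 1")
  if (!all(age_levels %in% template$age)) {
    stop("'age_levels' must be a subset of the template ages: ",
         paste(template$age, collapse = ", "))
  }
  set.seed(as.integer(seed))
  ages <- rep_len(age_levels, n)
  records <- vector("list", n)
  truths <- vector("list", n)
  n_rejected <- 0L
  kept <- 0L
  for (i in seq_len(n)) {
    tp <- template[template$age == ages[i], ]
    params <- simulation_params(
      edv_true = rtrunc(tp$edv_mean, tp$edv_sd, 55, 180),
      e_max = rtrunc(tp$emax_mean, tp$emax_sd, 1.2, 6),
      hr = rtrunc(tp$hr_mean, tp$hr_sd, 45, 115),
      r_art = rtrunc(tp$r_mean, tp$r_sd, 0.6, 2.0),
      c_art = rtrunc(tp$c_mean, tp$c_sd, 0.6, 4.0),
      t_sys = rtrunc(tp$tsys_mean, tp$tsys_sd, 0.3, 0.5),
      fs = fs)
    id <- sprintf("S%04d", i)
    sim <- tryCatch(simulate_beat(params, id = id, age = ages[i]),
                    error = function(e) NULL)
    if (is.null(sim) ||
        sim$truth$sbp < 85 || sim$truth$sbp > 140 ||
        sim$truth$dbp < 55 || sim$truth$dbp > 95) {
      n_rejected <- n_rejected + 1L
      next
    }
    kept <- kept + 1L
    records[[kept]] <- sim$record
    truths[[kept]] <- tibble::tibble(
      id = id, age = ages[i],
      e_max = params$e_max, r_art = params$r_art, c_art = params$c_art,
      sim$truth)
  }
  if (kept == 0L) stop("plausibility filter rejected every subject")
  if (n_rejected > n / 2) {
    warning(sprintf(
      "plausibility filter rejected %d of %d draws (> 50%%); age templates may be miscalibrated",
      n_rejected, n))
  }
  list(cohort = cohort_table(records[seq_len(kept)], provenance = "synthetic"),
       truth = dplyr::bind_rows(truths[seq_len(kept)]),
       n_rejected = n_rejected)
}
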