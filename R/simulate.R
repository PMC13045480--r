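#' Parameters of one simulated beat
#'
#' Defines a virtual left ventricle (time-varying elastance, raised-cosine
#' activation) ejecting through a one-way aortic valve into a two-element
#' Windkessel (compliance `c_art`, resistance `r_art`).  The diastolic
#' arterial time constant is `tau = r_art * c_art`.
#'
#' @param edv_true End-diastolic volume, mL.
#' @param v0 Ventricular unstressed volume, mL (default 0, the convention
#'   used throughout the volume and elastance calculations).
#' @param e_min,e_max Minimal / maximal ventricular elastance, mmHg/mL;
#'   `e_max` is the ground-truth contractility when the valve closes at peak
#'   elastance (operationally, Ees = ESP/ESV is stored as truth).
#' @param t_sys Systolic rise time of the elastance (onset to peak), s.
#' @param t_fall Relaxation time of the elastance (peak back to `e_min`), s.
#' @param r_art Windkessel resistance, mmHg·s/mL.
#' @param c_art Windkessel compliance, mL/mmHg.
#' @param hr Heart rate, bpm.
#' @param fs Sampling (and fixed-step integration) frequency, Hz.
#' @param r_valve Resistance of the open aortic valve, mmHg·s/mL.  A small
#'   positive value makes ejection flow start from zero and rise smoothly
#'   (with an ideal zero-resistance valve the lumped model would eject with
#'   an unphysiological flow step at opening); the resulting trans-valvular
#'   gradient at peak flow is a few mmHg, as in health.
#' @param backflow_frac Valve-closure backflow transient as a fraction of
#'   stroke volume; shapes the incisura on the synthetic pressure wave.
#' @param t_backflow Duration of the closure transient, s.
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(edv_true = 100, v0 = 0, e_min = 0.06,
                              e_max = 2.9, t_sys = 0.30, t_fall = 0.15,
                              r_art = 1.15, c_art = 2.2, hr = 75, fs = 500,
                              r_valve = 0.01,
                              backflow_frac = 0.008, t_backflow = 0.012) {
  p <- list(edv_true = edv_true, v0 = v0, e_min = e_min, e_max = e_max,
            t_sys = t_sys, t_fall = t_fall, r_art = r_art, c_art = c_art,
            hr = hr, fs = fs, r_valve = r_valve,
            backflow_frac = backflow_frac, t_backflow = t_backflow)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num)) stop("all simulation parameters must be finite scalars")
  pos <- c("edv_true", "e_min", "e_max", "t_sys", "t_fall", "r_art",
           "c_art", "hr", "fs", "r_valve")
  if (any(unlist(p[pos]) <= 0)) stop("simulation parameters must be positive")
  if (p$v0 < 0 || p$v0 >= p$edv_true) stop("'v0' must lie in [0, edv_true)")
  if (p$e_max <= p$e_min) stop("'e_max' must exceed 'e_min'")
  if (p$t_sys >= 60 / p$hr) stop("'t_sys' must be shorter than the beat")
  if (p$backflow_frac < 0 || p$t_backflow < 0) {
    stop("backflow settings must be non-negative")
  }
  p$tau_true <- p$r_art * p$c_art
  class(p) <- "simulation_params"
  p
}

# Raised-cosine activation on a time grid: 0 -> 1 over [0, t_sys],
# mirrored 1 -> 0 over (t_sys, t_sys + t_fall], e_min thereafter.
elastance_vec <- function(t, p) {
  f <- numeric(length(t))
  rise <- t <= p$t_sys
  f[rise] <- (1 - cos(pi * t[rise] / p$t_sys)) / 2
  fall <- !rise & t <= p$t_sys + p$t_fall
  f[fall] <- (1 + cos(pi * (t[fall] - p$t_sys) / p$t_fall)) / 2
  p$e_min + (p$e_max - p$e_min) * f
}

# classic fixed-step RK4 on a (possibly vector) state
rk4_step <- function(t, y, dt, deriv, p) {
  k1 <- deriv(t, y, p)
  k2 <- deriv(t + dt / 2, y + dt / 2 * k1, p)
  k3 <- deriv(t + dt / 2, y + dt / 2 * k2, p)
  k4 <- deriv(t + dt, y + dt * k3, p)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# One cardiac cycle on the fixed grid, starting at elastance onset with
# aortic pressure pd0.  Returns the sampled pressure/flow plus event indices
# (1-based grid index of valve opening / closure).  Outside ejection the
# Windkessel decay is advanced in closed form; ejection uses RK4 with a few
# substeps per sample (the valve equation is faster than the sampling grid).
simulate_cycle <- function(pd0, p, n, n_sub = 4L, egrid = NULL) {
  dt <- 1 / p$fs
  dts <- dt / n_sub
  if (is.null(egrid)) {
    # elastance on the half-substep grid used by the RK4 stages
    egrid <- elastance_vec((0:(2L * n_sub * n)) * (dts / 2), p)
  }
  pressure <- numeric(n)
  flow <- numeric(n)
  volume <- numeric(n)
  phase <- "iso"                       # iso -> eject -> backflow -> diastole
  P <- pd0
  V <- p$edv_true
  k_open <- NA_integer_
  k_close <- NA_integer_
  n_bf <- if (p$backflow_frac > 0) max(1L, round(p$t_backflow * p$fs)) else 0L
  bf_left <- 0L
  q_bf_peak <- 0
  decay <- exp(-dt / p$tau_true)
  rv <- p$r_valve; ra <- p$r_art; ca <- p$c_art; v0 <- p$v0

  for (k in seq_len(n)) {
    t <- (k - 1) * dt
    pressure[k] <- P
    volume[k] <- V
    m0 <- (k - 1L) * 2L * n_sub + 1L   # egrid index of time t

    if (phase == "eject") {
      Q <- (egrid[m0] * (V - v0) - P) / rv
      if (Q <= 0 && k > k_open) {
        # valve closes; LV volume freezes, closure transient begins
        flow[k] <- 0
        k_close <- k
        phase <- if (n_bf > 0L) "backflow" else "diastole"
        if (n_bf > 0L) {
          # triangular backflow lobe whose area is backflow_frac * SV
          q_bf_peak <- 2 * p$backflow_frac * (p$edv_true - V) / (n_bf * dt)
          bf_left <- n_bf
        }
      } else {
        flow[k] <- Q
      }
    }

    # advance state from t to t + dt
    if (phase == "iso") {
      P <- P * decay
      if (egrid[m0 + 2L * n_sub] * (p$edv_true - v0) >= P && is.na(k_open)) {
        phase <- "eject"
        k_open <- k + 1L
      }
    } else if (phase == "eject") {
      # RK4 substeps on (V, P_ao), elastance read off the precomputed grid
      for (s in seq_len(n_sub)) {
        m <- m0 + (s - 1L) * 2L
        e0 <- egrid[m]; eh <- egrid[m + 1L]; e1 <- egrid[m + 2L]
        q1 <- (e0 * (V - v0) - P) / rv
        k1v <- -q1; k1p <- (q1 - P / ra) / ca
        V2 <- V + dts / 2 * k1v; P2 <- P + dts / 2 * k1p
        q2 <- (eh * (V2 - v0) - P2) / rv
        k2v <- -q2; k2p <- (q2 - P2 / ra) / ca
        V3 <- V + dts / 2 * k2v; P3 <- P + dts / 2 * k2p
        q3 <- (eh * (V3 - v0) - P3) / rv
        k3v <- -q3; k3p <- (q3 - P3 / ra) / ca
        V4 <- V + dts * k3v; P4 <- P + dts * k3p
        q4 <- (e1 * (V4 - v0) - P4) / rv
        k4v <- -q4; k4p <- (q4 - P4 / ra) / ca
        V <- V + dts / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
        P <- P + dts / 6 * (k1p + 2 * k2p + 2 * k3p + k4p)
      }
    } else if (phase == "backflow") {
      i <- n_bf - bf_left + 1L           # position within the lobe
      frac <- if (i <= n_bf / 2) i / (n_bf / 2) else 2 - i / (n_bf / 2)
      Qb <- -q_bf_peak * frac
      if (k > k_close) flow[k] <- Qb
      wk <- function(t, y, p) (Qb - y / p$r_art) / p$c_art
      P <- rk4_step(t, P, dt, wk, p)
      bf_left <- bf_left - 1L
      if (bf_left == 0L) phase <- "diastole"
    } else {
      P <- P * decay
    }
  }
  if (is.na(k_open)) {
    stop("aortic valve never opened: peak LV pressure below arterial pressure",
         " (e_max too low?)")
  }
  if (is.na(k_close)) {
    stop("aortic valve never closed within the beat; check t_sys/t_fall vs HR")
  }
  list(pressure = pressure, flow = flow, volume = volume,
       k_open = k_open, k_close = k_close, p_end = P)
}

#' Simulate one steady-state beat of the elastance-Windkessel model
#'
#' Integrates the coupled ventricle/Windkessel system with a fixed-step
#' fourth-order Runge-Kutta scheme on the output sampling grid, iterating
#' whole cycles until the diastolic starting pressure reaches its periodic
#' steady state.  The returned beat is re-origined so that t = 0 is ejection
#' onset (the foot of the pressure upstroke), matching the single-beat
#' storage convention.
#'
#' @param params A [simulation_params()] object.
#' @param id,age Metadata stored on the returned `subject_record`
#'   (defaults: `"sim"`, 50 years).
#' @return A list with elements `record` (a [subject_record()]) and `truth`,
#'   a one-row tibble of ground-truth quantities: `edv`, `esv`, `sv`, `lvef`
#'   (%), `ees`, `ea` (mmHg/mL), `ea_over_ees`, `tau` (s), `t_peak_flow` (s,
#'   from ejection onset), `esp` (mmHg), plus `lvet`, `sbp`, `dbp`, `map`.
#' @examples
#' beat <- simulate_beat(simulation_params())
#' beat$truth$lvef
#' @export
simulate_beat <- function(params, id = "sim", age = 50) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  n <- round(p$fs * 60 / p$hr)
  if (n < 16L) stop("fewer than 16 samples per beat; raise fs or lower hr")

  # periodic steady state: fixed point of the end-diastolic pressure map,
  # with secant acceleration
  pd0 <- 0.75 * p$e_max * (p$edv_true - p$v0)
  pd_prev <- NA_real_; f_prev <- NA_real_
  cyc <- NULL
  n_sub <- 4L
  egrid <- elastance_vec((0:(2L * n_sub * n)) / (2 * n_sub * p$fs), p)
  for (it in seq_len(200L)) {
    cyc <- simulate_cycle(pd0, p, n, n_sub = n_sub, egrid = egrid)
    f <- cyc$p_end - pd0
    if (abs(f) < 1e-8) break
    if (!is.na(pd_prev) && abs(f - f_prev) > 1e-12) {
      step <- f * (pd0 - pd_prev) / (f - f_prev)
      pd_new <- pd0 - step
    } else {
      pd_new <- cyc$p_end
    }
    pd_prev <- pd0; f_prev <- f
    pd0 <- pd_new
  }

  # rotate so the beat starts at ejection onset
  idx <- ((cyc$k_open - 1L):(cyc$k_open + n - 2L)) %% n + 1L
  pr <- cyc$pressure[idx]
  fl <- cyc$flow[idx]

  esv <- cyc$volume[cyc$k_close]
  esp <- cyc$pressure[cyc$k_close]
  sv <- p$edv_true - esv
  k_pf <- which.max(fl)                  # peak flow, relative to new origin
  truth <- tibble::tibble(
    edv = p$edv_true, esv = esv, sv = sv,
    lvef = 100 * sv / p$edv_true,
    ees = esp / (esv - p$v0), ea = esp / sv, ea_over_ees = (esv - p$v0) / sv,
    tau = p$tau_true,
    t_peak_flow = (k_pf - 1L) / p$fs,
    esp = esp,
    lvet = (cyc$k_close - cyc$k_open) / p$fs,
    sbp = max(pr), dbp = min(pr), map = mean(pr))

  rec <- tryCatch(
    subject_record(
      id = id, age = age, hr = p$hr, sv = sv,
      pressure = waveform(pr, fs = p$fs, kind = "pressure"),
      flow = waveform(fl, fs = p$fs, kind = "flow")),
    error = function(e) {
      stop("simulation produced an invalid beat: ", conditionMessage(e))
    })
  list(record = rec, truth = truth)
}
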