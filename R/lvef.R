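#' Arterial time constant from the diastolic pressure decay
#'
#' In a two-element Windkessel the aortic pressure after valve closure
#' decays as `P(t) = P0 exp(-t/tau)` with `tau = R * C`.  The constant is
#' recovered by a least-squares fit of `ln P(t)` against time over a window
#' inside diastole, `[notch_time + delta_start, beat_end - delta_end]`.
#'
#' @param pressure A pressure `waveform` (one beat, t = 0 at ejection
#'   onset).
#' @param notch_time Time of the dicrotic notch, s (see
#'   [detect_dicrotic_notch()]).
#' @param delta_start Gap after the notch before the fit window opens, s;
#'   skips the valve-closure transient (default 0.03).
#' @param delta_end Gap excluded at the end of the beat, s (default 0.01).
#' @return A list of class `tau_estimate`: `tau` (s), `fit_window`
#'   (`c(t_start, t_end)`), `r2` of the log-linear fit, and `low_r2`
#'   (TRUE when r2 < 0.8, flagging a poor exponential fit).
#' @examples
#' t <- (0:399) / 500
#' p <- waveform(100 * exp(-t / 1.5), fs = 500, kind = "pressure")
#' estimate_tau(p, notch_time = 0.1)$tau
#' @export
estimate_tau <- function(pressure, notch_time, delta_start = 0.03,
                         delta_end = 0.01) {
  stopifnot(inherits(pressure, "waveform"), pressure$kind == "pressure")
  dur <- wf_duration(pressure)
  if (notch_time < 0 || notch_time >= dur) stop("'notch_time' outside beat")
  t0 <- notch_time + delta_start
  t1 <- dur - 1 / pressure$fs - delta_end
  tt <- wf_time(pressure)
  keep <- which(tt >= t0 & tt <= t1)
  if (length(keep) < 5L) stop("fewer than 5 samples in the tau fit window")
  pr <- pressure$samples[keep]
  if (any(pr <= 0)) stop("non-positive pressure in the tau fit window")
  fit <- stats::lm.fit(cbind(1, tt[keep]), log(pr))
  slope <- fit$coefficients[[2L]]
  if (slope >= -1e-9) stop("diastolic pressure does not decay; tau undefined")
  tau <- -1 / slope
  if (tau < 0.3 || tau > 5) {
    stop(sprintf("fitted tau %.3f s outside the plausible range [0.3, 5] s",
                 tau))
  }
  tss <- sum((log(pr) - mean(log(pr)))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  structure(list(tau = tau, fit_window = c(t0, t1), r2 = r2,
                 low_r2 = r2 < 0.8),
            class = "tau_estimate")
}

# Rising raised-cosine activation used by the estimator: 0 before the
# onset, (1 - cos(pi (t - onset)/width))/2 during the rise, clamped at 1
# beyond the peak.
activation_shape <- function(t, width, onset) {
  x <- pmin(pmax((t - onset) / width, 0), 1)
  (1 - cos(pi * x)) / 2
}

#' Estimate LVEF from the aortic pressure waveform alone
#'
#' Implements the lumped-model pressure-only ejection fraction estimate.
#' The two-element Windkessel relation reconstructs the ejected volume up
#' to an unknown compliance scale,
#' `v_ej(t) = C * (P(t) - P(0)) + (C / tau) * integral(P)`, evaluated here
#' with C = 1.  A raised-cosine elastance (amplitude, width, onset;
#' unstressed volume fixed at 0) is then fitted so that
#' `E(t) * (V_ed - v_ej(t))` tracks the systolic pressure.  Two reductions
#' make this single-beat fit well posed: the activation is anchored so
#' that it peaks at end-systole (`onset = t_notch - width`, the usual
#' single-beat assumption that end-systole coincides with maximal
#' elastance — without it, amplitude-for-volume trade-offs leave the
#' decomposition unidentifiable on one beat), and for a given width the
#' model `P = amplitude*f(t)*V_ed - amplitude*f(t)*v_ej(t)` is linear in
#' `amplitude*V_ed` and `amplitude`, so those are profiled out by linear
#' least squares and only the width is searched numerically.  LVEF is the
#' ratio `100 * (1 - ESV_rel / EDV_rel)`, in which the compliance scale
#' cancels.
#'
#' @param pressure A pressure `waveform`, t = 0 at ejection onset.
#' @param tau A `tau_estimate` from [estimate_tau()] (or a plain number,
#'   seconds).
#' @param t_notch End of systole, s; the dicrotic notch time from
#'   [detect_dicrotic_notch()].
#' @param width_bounds Box constraint for the elastance width (s).
#' @param tol Convergence tolerance of the one-dimensional width search.
#' @return A list of class `lvef_result`: `lvef` (%), `relative_edv`,
#'   `relative_esv` (compliance-scaled volume units), `tau`, `fit` (list:
#'   `amplitude`, `width`, `onset`, `residual_rmse`), and `implausible`
#'   (TRUE when LVEF falls outside (5, 95)).
#' @export
estimate_lvef <- function(pressure, tau, t_notch,
                          width_bounds = c(0.1, 0.6), tol = 1e-6) {
  stopifnot(inherits(pressure, "waveform"), pressure$kind == "pressure")
  tau_est <- if (inherits(tau, "tau_estimate")) tau else
    structure(list(tau = as.numeric(tau), fit_window = c(NA, NA), r2 = NA,
                   low_r2 = FALSE), class = "tau_estimate")
  tt <- wf_time(pressure)
  sys <- which(tt <= t_notch)
  if (length(sys) < 10L) stop("too few systolic samples before the notch")
  ts <- tt[sys]
  ps <- pressure$samples[sys]

  # proportional ejected volume from the Windkessel relation (C = 1)
  v_ej <- (ps - ps[1L]) + pracma::cumtrapz(ts, ps)[, 1L] / tau_est$tau

  profile_fit <- function(w) {
    f <- activation_shape(ts, w, t_notch - w)
    stats::lm.fit(cbind(f, -f * v_ej), ps)
  }
  profile_rss <- function(w) {
    qr_fit <- tryCatch(profile_fit(w), error = function(e) NULL)
    if (is.null(qr_fit) || anyNA(qr_fit$coefficients)) return(1e12)
    cf <- qr_fit$coefficients
    if (cf[2L] <= 0 || cf[1L] <= 0) return(1e12)
    sum(qr_fit$residuals^2)
  }

  opt <- stats::optimize(profile_rss, width_bounds, tol = tol)
  if (opt$objective >= 1e12) {
    stop("elastance fit failed to converge within bounds")
  }
  w <- opt$minimum
  o <- t_notch - w
  cf <- profile_fit(w)$coefficients
  rmse <- sqrt(opt$objective / length(sys))

  edv_rel <- cf[[1L]] / cf[[2L]]
  sv_rel <- v_ej[length(v_ej)]
  esv_rel <- edv_rel - sv_rel
  lvef <- 100 * (1 - esv_rel / edv_rel)
  if (!is.finite(lvef) || lvef <= 0 || lvef >= 100) {
    stop(sprintf("estimated LVEF %.1f%% outside (0, 100)", lvef))
  }
  structure(list(
    lvef = lvef, relative_edv = edv_rel, relative_esv = esv_rel,
    tau = tau_est,
    fit = list(amplitude = cf[[2L]], width = w, onset = o,
               residual_rmse = rmse),
    implausible = lvef <= 5 || lvef >= 95),
    class = "lvef_result")
}

#' @export
print.lvef_result <- function(x, ...) {
  cat(sprintf(
    "<lvef_result: LVEF %.1f%% (tau %.2f s, fit rmse %.2f mmHg%s)>\n",
    x$lvef, x$tau$tau, x$fit$residual_rmse,
    if (x$implausible) ", IMPLAUSIBLE" else ""))
  invisible(x)
}

#' Absolute ventricular volumes from LVEF and stroke volume
#'
#' The pressure-only method yields volumes on an arbitrary compliance
#' scale; anchoring with an absolute stroke volume gives
#' `EDV = SV / (LVEF/100)` and `ESV = EDV - SV`.
#'
#' @param lvef_result An `lvef_result`, or a plain LVEF percentage.
#' @param sv Stroke volume, mL.
#' @return A list with `edv`, `esv`, `sv` (mL).
#' @examples
#' absolute_volumes(67, sv = 60)  # EDV ~ 89.6, ESV ~ 29.6
#' @export
absolute_volumes <- function(lvef_result, sv) {
  lvef <- if (inherits(lvef_result, "lvef_result")) lvef_result$lvef
          else as.numeric(lvef_result)
  if (!(lvef > 0) || lvef >= 100) stop("'lvef' must lie in (0, 100)")
  if (!(sv > 0)) stop("'sv' must be positive")
  edv <- sv / (lvef / 100)
  list(edv = edv, esv = edv - sv, sv = sv)
}
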