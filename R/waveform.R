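#' Single-beat haemodynamic waveform
#'
#' A `waveform` holds one cardiac cycle of a uniformly sampled aortic root
#' signal: pressure in mmHg or flow in mL/s.  By convention the beat starts
#' at ejection onset (t = 0 at the foot of the pressure upstroke), so the
#' systolic portion occupies the first part of the record and diastole the
#' remainder.
#'
#' @param samples Numeric vector of signal values (mmHg for pressure,
#'   mL/s for flow), at least 16 samples.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param kind Either `"pressure"` or `"flow"`.
#' @param hr Optional heart rate in bpm; when supplied, the record duration
#'   `length(samples)/fs` must equal `60/hr` to within one sample period.
#'
#' @return An object of class `waveform`: a list with elements `samples`,
#'   `fs` and `kind`.
#' @examples
#' p <- waveform(80 + 20 * sin(pi * (0:399) / 400), fs = 500, kind = "pressure")
#' wf_duration(p)
#' @export
waveform <- function(samples, fs, kind = c("pressure", "flow"), hr = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(samples) || length(samples) < 16L || anyNA(samples)) {
    stop("'samples' must be a numeric vector of at least 16 finite values")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a positive scalar (Hz)")
  }
  wf <- structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                       kind = kind),
                  class = "waveform")
  validate_waveform(wf, hr = hr)
  wf
}

#' Validate a waveform object
#'
#' Checks the invariants of the single-beat convention: positive sampling
#' rate, strictly positive pressures (physiological aortic pressure never
#' reaches 0 mmHg), flow non-negative apart from a small valve-closure
#' backflow transient, and — when a heart rate is supplied — record duration
#' consistent with one cardiac cycle.
#'
#' @param wf A `waveform`.
#' @param hr Optional heart rate (bpm) for the duration check.
#' @param backflow_tol Most negative flow admitted as a closure transient,
#'   in units of the peak forward flow (default 0.25).
#' @return `wf`, invisibly; errors describe the violated invariant.
#' @export
validate_waveform <- function(wf, hr = NULL, backflow_tol = 0.25) {
  stopifnot(inherits(wf, "waveform"))
  if (wf$kind == "pressure" && any(wf$samples <= 0)) {
    stop("pressure waveform must be strictly positive")
  }
  if (wf$kind == "flow") {
    qmax <- max(wf$samples)
    if (!(qmax > 0)) stop("flow waveform must have a positive maximum")
    if (min(wf$samples) < -backflow_tol * qmax) {
      stop("flow waveform has negative values beyond a small closure transient")
    }
  }
  if (!is.null(hr)) {
    if (abs(wf_duration(wf) - 60 / hr) > 1 / wf$fs) {
      stop(sprintf(
        "waveform duration %.4f s inconsistent with one beat at HR %.1f bpm",
        wf_duration(wf), hr))
    }
  }
  invisible(wf)
}

#' Duration and time axis of a waveform
#'
#' @param wf A `waveform`.
#' @return `wf_duration`: the record length in seconds (`n/fs`);
#'   `wf_time`: the vector of sample times, starting at 0.
#' @export
wf_duration <- function(wf) length(wf$samples) / wf$fs

#' @rdname wf_duration
#' @export
wf_time <- function(wf) (seq_along(wf$samples) - 1L) / wf$fs

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %s, %d samples @ %g Hz (%.3f s), range [%.1f, %.1f]>\n",
              x$kind, length(x$samples), x$fs, wf_duration(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}
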