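#' Time of peak aortic flow
#'
#' The time of maximal ventricular fiber shortening is taken as the time of
#' peak aortic flow; this is the landmark that splits the ejection into the
#' first phase (used for EF1) and the remainder.
#'
#' @param flow A flow `waveform`.
#' @return Time of the global flow maximum in seconds from the start of the
#'   beat; ties are broken by the earliest occurrence.
#' @examples
#' q <- waveform(c(seq(0, 300, length.out = 20), seq(290, 0, length.out = 30)),
#'               fs = 100, kind = "flow")
#' detect_peak_flow(q)
#' @export
detect_peak_flow <- function(flow) {
  stopifnot(inherits(flow, "waveform"), flow$kind == "flow")
  if (max(flow$samples) <= 0) stop("flow waveform has no positive maximum")
  (which.max(flow$samples) - 1L) / flow$fs
}

# first zero-crossing of flow after its peak, by linear interpolation;
# beat end if the flow never returns to zero
flow_ejection_end <- function(flow) {
  q <- flow$samples
  k_pk <- which.max(q)
  after <- which(q[(k_pk + 1L):length(q)] <= 0)
  if (length(after) == 0L) return(wf_duration(flow) - 1 / flow$fs)
  k0 <- k_pk + after[1L]                 # first non-positive sample
  t0 <- (k0 - 2L) / flow$fs              # last positive sample time
  if (q[k0] == 0) return((k0 - 1L) / flow$fs)
  t0 + (q[k0 - 1L] / (q[k0 - 1L] - q[k0])) / flow$fs
}

#' Fraction of the ejected volume up to a cut time
#'
#' Trapezoidal area of the flow curve over `[0, t_cut]` divided by the area
#' over the whole ejection.  Ejection ends at the first zero-crossing of
#' flow after its peak (or the end of the beat); any small negative
#' valve-closure transient is excluded from both numerator and denominator.
#' A `t_cut` falling between samples splits the trapezoid by linear
#' interpolation, so the result is reproducible to machine precision.
#'
#' @param flow A flow `waveform`.
#' @param t_cut Cut time in seconds, within the beat.
#' @return The area fraction, in `[0, 1]`.
#' @examples
#' tri <- waveform(c(seq(0, 100, length.out = 11), seq(90, 0, length.out = 10)),
#'                 fs = 100, kind = "flow")
#' integrate_flow_fraction(tri, t_cut = 0.10)  # symmetric triangle -> 0.5
#' @export
integrate_flow_fraction <- function(flow, t_cut) {
  stopifnot(inherits(flow, "waveform"), flow$kind == "flow")
  if (t_cut < 0 || t_cut > wf_duration(flow)) {
    stop("'t_cut' outside the beat")
  }
  t_end <- flow_ejection_end(flow)
  tt <- wf_time(flow)
  q <- pmax(flow$samples, 0)
  area_to <- function(tc) {
    if (tc <= 0) return(0)
    k <- findInterval(tc, tt)            # tc >= tt[k]
    a <- if (k >= 2L) pracma::trapz(tt[1:k], q[1:k]) else 0
    if (k < length(tt) && tc > tt[k]) {
      # partial trapezoid, flow linearly interpolated at tc
      qc <- q[k] + (q[k + 1L] - q[k]) * (tc - tt[k]) / (tt[k + 1L] - tt[k])
      a <- a + (tc - tt[k]) * (q[k] + qc) / 2
    }
    a
  }
  total <- area_to(t_end)
  if (total <= 0) stop("total flow area is not positive")
  min(1, area_to(min(t_cut, t_end)) / total)
}

#' First-phase ejection fraction from a flow wave
#'
#' The fraction of the flow-curve area accrued up to peak aortic flow is
#' scaled to the subject's stroke volume to give SV1 in mL; EF1 is then
#' `100 * SV1 / EDV`.
#'
#' @param flow A flow `waveform`.
#' @param sv Stroke volume in mL (the value the proportional area estimate
#'   is scaled to).
#' @param edv End-diastolic volume in mL.
#' @return A list with `ef1` (%) and `sv1` (mL).
#' @examples
#' tri <- waveform(c(seq(0, 100, length.out = 11), seq(90, 0, length.out = 10)),
#'                 fs = 100, kind = "flow")
#' compute_ef1(tri, sv = 60, edv = 120)  # half the area by the apex -> 25%
#' @export
compute_ef1 <- function(flow, sv, edv) {
  if (!(sv > 0) || !(edv > 0)) stop("'sv' and 'edv' must be positive")
  if (sv >= edv) stop("'sv' must be smaller than 'edv'")
  t_pk <- detect_peak_flow(flow)
  sv1 <- integrate_flow_fraction(flow, t_pk) * sv
  list(ef1 = ef1_from_volumes(sv1, edv), sv1 = sv1)
}

#' Ejection fractions from volumes
#'
#' Desk-calculator forms of the two indices: `ef1_from_volumes` is
#' `100 * SV1 / EDV`, `lvef_from_volumes` is `100 * SV / EDV`.
#'
#' @param sv1,sv,edv Volumes in mL; `edv` positive.
#' @return Percentage values.
#' @examples
#' ef1_from_volumes(45, 90)   # 50
#' lvef_from_volumes(60, 90)  # 66.7
#' @export
ef1_from_volumes <- function(sv1, edv) {
  if (!(edv > 0)) stop("'edv' must be positive")
  100 * sv1 / edv
}

#' @rdname ef1_from_volumes
#' @export
lvef_from_volumes <- function(sv, edv) {
  if (!(edv > 0)) stop("'edv' must be positive")
  100 * sv / edv
}

#' Dicrotic notch detection
#'
#' Locates the incisura on the aortic pressure wave — the landmark for
#' aortic valve closure, whose pressure is read as the end-systolic pressure
#' (ESP).  Within a search window after peak flow the detector first looks
#' for a local pressure minimum; if the decay is monotone (as on smooth
#' Windkessel-generated beats, where valve closure leaves a curvature
#' transient rather than a true dip), it falls back to the maximum of the
#' second derivative of pressure.
#'
#' @param pressure A pressure `waveform`.
#' @param t_peak_flow Anchor time (s): peak aortic flow, from
#'   [detect_peak_flow()].
#' @param w_max Search window length after the anchor, s.  The default
#'   (0.35 s) comfortably covers the ~200 ms between peak flow and end of
#'   ejection seen at normal ejection times; it is truncated at the beat end.
#' @param method `"minimum_then_d2"` (default) or `"d2"` to use curvature
#'   only.
#' @return A list with `t_notch` (s) and `esp` (mmHg, pressure at the
#'   notch).  Errors if no candidate exists in the window.
#' @export
detect_dicrotic_notch <- function(pressure, t_peak_flow,
                                  w_max = 0.35,
                                  method = c("minimum_then_d2", "d2")) {
  stopifnot(inherits(pressure, "waveform"), pressure$kind == "pressure")
  method <- match.arg(method)
  fs <- pressure$fs
  pr <- pressure$samples
  k0 <- floor(t_peak_flow * fs) + 1L
  k1 <- min(length(pr), k0 + ceiling(w_max * fs))
  if (k1 - k0 < 4L) stop("notch search window too short")
  win <- pr[k0:k1]

  if (method == "minimum_then_d2") {
    # first interior local minimum in the window
    dlt <- diff(win)
    turn <- which(dlt[-length(dlt)] < 0 & dlt[-1L] > 0)
    if (length(turn) > 0L) {
      k <- k0 + turn[1L]                 # index of the minimum sample
      return(list(t_notch = (k - 1L) / fs, esp = pr[k]))
    }
  }
  # curvature fallback: an interior maximum of the second derivative.  A
  # smoothly convex decay (no closure transient) peaks at the window edge
  # instead, which is rejected as "no notch".
  if (length(win) < 5L) stop("no dicrotic notch candidate in search window")
  d2 <- diff(win, differences = 2L)
  j <- which.max(d2)
  if (max(d2) <= 0 || j == 1L || j == length(d2)) {
    stop("no dicrotic notch candidate in search window")
  }
  k <- k0 + j                            # centre sample of the d2 stencil
  list(t_notch = (k - 1L) / fs, esp = pr[k])
}

#' Ventricular-arterial coupling indices
#'
#' Effective arterial elastance `Ea = ESP/SV`, end-systolic elastance
#' `Ees = ESP/ESV` (unstressed volume taken as 0 mL), and their ratio.
#' ESP cancels in the ratio, so `ea_over_ees == esv/sv` exactly.
#'
#' @param esp End-systolic pressure, mmHg (pressure at the dicrotic notch).
#' @param sv Stroke volume, mL.
#' @param esv End-systolic volume, mL.
#' @return A list with `ea`, `ees` (mmHg/mL) and `ea_over_ees`.
#' @examples
#' compute_vac(esp = 90, sv = 60, esv = 30)
#' @export
compute_vac <- function(esp, sv, esv) {
  if (!(esp > 0) || !(sv > 0)) stop("'esp' and 'sv' must be positive")
  if (!(esv > 0)) stop("'esv' must be positive for a defined Ees")
  list(ea = esp / sv, ees = esp / esv, ea_over_ees = esv / sv)
}
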