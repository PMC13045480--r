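test_that("peak flow detection: maximum, tie rule, degenerate input", {
  fs <- 100
  ramp <- waveform(c(seq(0, 50, length.out = 11),
                     seq(45, 0, length.out = 10)), fs, "flow")
  expect_equal(detect_peak_flow(ramp), 10 / fs)
  # plateau of equal maxima: earliest sample wins
  plat <- waveform(c(0, 10, 50, 50, 50, 10, rep(0, 10)), fs, "flow")
  expect_equal(detect_peak_flow(plat), 2 / fs)
  expect_error(detect_peak_flow(waveform(rep(0, 20) - 0.0, fs, "flow")),
               "positive maximum")
})

test_that("flow-area fraction matches hand-computed trapezoids", {
  # symmetric triangle: half the area lies before the apex
  tri <- triangle_flow(q_peak = 100, n_up = 11, n_down = 11, fs = 100)
  expect_equal(integrate_flow_fraction(tri, detect_peak_flow(tri)), 0.5,
               tolerance = 1e-12)
  # samples [0, 2, 1, 0] at unit spacing: area to peak 1, total 3
  q <- waveform(c(0, 2, 1, rep(0, 14)), fs = 1, kind = "flow")
  expect_equal(integrate_flow_fraction(q, 1), 1 / 3)
  # full window: fraction 1
  expect_equal(integrate_flow_fraction(tri, wf_duration(tri)), 1)
  expect_error(integrate_flow_fraction(tri, -0.01), "outside")
  expect_error(integrate_flow_fraction(tri, 10), "outside")
})

test_that("flow-area fraction agrees with a 10x-oversampled Riemann sum", {
  set.seed(31)
  fs <- 100
  for (rep in 1:20) {
    # random piecewise-linear ejection: rise to a peak, fall to zero, tail
    n_up <- sample(5:15, 1); n_down <- sample(5:15, 1)
    qpk <- runif(1, 50, 400)
    q <- c(seq(0, qpk, length.out = n_up),
           seq(qpk, 0, length.out = n_down)[-1],
           rep(0, 8))
    # roughen the limbs but keep positivity and a unique support
    jit <- runif(length(q), 0.7, 1.3); jit[q == 0] <- 1
    q <- q * jit
    wf <- waveform(q, fs, "flow")
    t_end <- (n_up + n_down - 2) / fs
    t_cut <- runif(1, 1 / fs, t_end - 1 / fs)
    # oracle: dense linear interpolation + left Riemann sum at 10x fs
    tt <- wf_time(wf)
    dense_t <- seq(0, t_end, by = 1 / (10 * fs))
    dense_q <- approx(tt, q, xout = dense_t)$y
    num <- sum((dense_q[-1] + dense_q[-length(dense_q)]) / 2) /
      (10 * fs)
    cut_t <- seq(0, t_cut, length.out = 2000L)
    cut_q <- approx(tt, q, xout = cut_t)$y
    den <- sum((cut_q[-1] + cut_q[-length(cut_q)]) / 2) *
      (cut_t[2] - cut_t[1])
    expect_equal(integrate_flow_fraction(wf, t_cut), den / num,
                 tolerance = 1e-3)
  }
})

test_that("EF1 arithmetic: triangular flow, half the stroke by the apex", {
  tri <- triangle_flow(q_peak = 100, n_up = 11, n_down = 11, fs = 100)
  out <- compute_ef1(tri, sv = 60, edv = 120)
  expect_equal(out$sv1, 30)
  expect_equal(out$ef1, 25)
  expect_error(compute_ef1(tri, sv = 120, edv = 60), "smaller")
})

test_that("EF1 on a simulated subject matches the flow-integral truth", {
  beat <- default_beat()
  tr <- beat$truth
  out <- compute_ef1(beat$record$flow, sv = tr$sv, edv = tr$edv)
  fl <- beat$record$flow$samples
  tt <- wf_time(beat$record$flow)
  kpf <- which.max(fl)
  ef1_true <- 100 * pracma::trapz(tt[1:kpf], fl[1:kpf]) / tr$edv
  expect_lt(abs(out$ef1 - ef1_true), 1)
})

test_that("dicrotic notch: constructed minimum, fallback, degenerate", {
  fs <- 500
  tt <- (0:399) / fs
  # decaying pressure with an explicit local minimum inserted at 0.30 s
  pr <- 110 * exp(-tt / 1.5)
  dip <- exp(-((tt - 0.315) / 0.01)^2) * 4
  pr2 <- pr + dip                       # rebound after 0.30 s creates a dip
  w <- waveform(pr2, fs, "pressure")
  nd <- detect_dicrotic_notch(w, t_peak_flow = 0.1)
  expect_equal(nd$t_notch, 0.30, tolerance = 0.01)
  # monotone decay without any curvature transient: no candidate
  smooth <- waveform(110 * exp(-tt / 1.5), fs, "pressure")
  expect_error(detect_dicrotic_notch(smooth, 0.1, method = "d2"),
               "no dicrotic notch")
})

test_that("notch on a simulated beat sits within 10 ms of valve closure", {
  beat <- default_beat()
  t_pf <- detect_peak_flow(beat$record$flow)
  nd <- detect_dicrotic_notch(beat$record$pressure, t_pf)
  expect_lt(abs(nd$t_notch - beat$truth$lvet), 0.010)
  expect_lt(abs(nd$esp - beat$truth$esp), 2)
})

test_that("coupling indices: arithmetic, ESP cancellation, invariance", {
  v <- compute_vac(esp = 90, sv = 60, esv = 30)
  expect_equal(v$ea, 1.5)
  expect_equal(v$ees, 3.0)
  expect_equal(v$ea_over_ees, 0.5)
  # ESP cancels in the ratio
  expect_identical(compute_vac(77, 45, 45)$ea_over_ees, 1)
  expect_identical(compute_vac(90, 60, 30)$ea_over_ees,
                   compute_vac(180, 60, 30)$ea_over_ees)
  expect_error(compute_vac(90, 60, 0), "esv")
})
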