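# Shared fixtures, built in code and cached across test files.

.beat_cache <- new.env(parent = emptyenv())

# one steady-state beat at the default parameters (memoised)
default_beat <- function() {
  if (is.null(.beat_cache$default)) {
    .beat_cache$default <- simulate_beat(simulation_params())
  }
  .beat_cache$default
}

# a small cohort with ground truth (memoised per n/seed)
cached_cohort <- function(n = 36, seed = 7) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.beat_cache[[key]])) {
    .beat_cache[[key]] <- generate_cohort(n, seed = seed)
  }
  .beat_cache[[key]]
}

# per-subject analysis chain on one record (landmarks -> tau -> lvef)
analyze_record <- function(rec) {
  t_pf <- detect_peak_flow(rec$flow)
  nd <- detect_dicrotic_notch(rec$pressure, t_pf)
  ta <- estimate_tau(rec$pressure, nd$t_notch)
  lv <- estimate_lvef(rec$pressure, ta, nd$t_notch)
  list(t_pf = t_pf, notch = nd, tau = ta, lvef = lv)
}

# triangular single-beat flow wave: linear up to the apex, linear down,
# zero tail; apex exactly on a sample
triangle_flow <- function(q_peak = 100, n_up = 11, n_down = 11, n_tail = 10,
                          fs = 100) {
  samp <- c(seq(0, q_peak, length.out = n_up),
            seq(q_peak, 0, length.out = n_down)[-1],
            rep(0, n_tail))
  waveform(samp, fs = fs, kind = "flow")
}
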