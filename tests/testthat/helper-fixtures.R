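# Shared fixtures built in code.

default_times <- function(acq = acquisition_config()) {
  (seq_len(acq$n_frames) - 1) * acq$dt
}

# random valid residue tuples under the coordinate orderings
random_residue <- function() {
  t_end <- stats::runif(1, 2, 20)
  xs <- sort(stats::runif(2, 0, t_end))
  ys <- sort(stats::runif(2, 0, 1), decreasing = TRUE)
  bezier_residue(xs[1], ys[1], xs[2], ys[2], t_end)
}

# exponential-like Bezier residue scaled to a target MTT
exp_like_residue <- function(target_mtt) {
  mk <- function(s) bezier_residue(0.30 * s, 0.62, 1.6 * s, 0.145, 5.2 * s)
  mk(target_mtt / mtt(mk(1)))
}

# Table of per-subject paired values used throughout the cohort tests
cohort_fixture <- function() cohort_table()
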