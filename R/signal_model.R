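# Signal model: MRI signal <-> contrast-agent concentration, and the
# tracer-kinetic forward model C_m(t) = (CBF/k_H) * [R conv C_a(t - delta)].

#' Acquisition configuration
#'
#' Bundles the gradient-echo EPI acquisition parameters needed to convert
#' dynamic signal into contrast-agent concentration and to discretise the
#' tracer-kinetic convolution. Defaults mirror a 75 s bolus-tracking
#' acquisition at 1.65 s temporal resolution with TE = 54 ms and 11
#' pre-contrast (baseline) frames.
#'
#' @param te Echo time in seconds.
#' @param dt Frame interval in seconds.
#' @param n_frames Number of dynamic frames.
#' @param n_baseline Number of pre-contrast baseline frames (>= 1).
#' @param r2star Transverse relaxivity in (concentration x s)^-1. The
#'   absolute value is unknown for a given agent/field strength, so
#'   concentration is carried in arbitrary relaxivity-scaled units; all
#'   derived transit-time and extraction parameters are invariant to it.
#' @param k_h Dimensionless haematocrit/brain-density correction factor in
#'   the tracer-kinetic relation. It rescales CBF and CBV only and cancels
#'   from MTT, CTH, AOEF and delay; defaults to 1.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(te = 0.054, dt = 1.65, n_frames = 46,
                               n_baseline = 11, r2star = 87, k_h = 1.0) {
  stopifnot(te > 0, dt > 0, n_baseline >= 1, n_frames > n_baseline,
            r2star > 0, k_h > 0)
  structure(list(te = te, dt = dt, n_frames = as.integer(n_frames),
                 n_baseline = as.integer(n_baseline), r2star = r2star,
                 k_h = k_h),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "DSC acquisition: %d frames, dt = %.3g s (%.3g s), TE = %.3g ms, %d baseline frames\n",
    x$n_frames, x$dt, x$n_frames * x$dt, 1000 * x$te, x$n_baseline))
  cat(sprintf("  r2* = %.4g (conc s)^-1, k_H = %.3g\n", x$r2star, x$k_h))
  invisible(x)
}

#' Dynamic signal time series
#'
#' @param times Acquisition times in seconds, strictly increasing.
#' @param values Signal values (arbitrary units, strictly positive).
#' @param baseline_count Number of leading pre-contrast frames.
#' @return An object of class `signal_ts`.
#' @export
signal_ts <- function(times, values, baseline_count) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("signal times must be strictly increasing")
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive or non-finite signal value at frame %d", bad[1]))
  }
  baseline_count <- as.integer(baseline_count)
  if (baseline_count < 1) stop("baseline_count must be at least 1")
  if (baseline_count > length(values)) stop("baseline_count exceeds series length")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 baseline_count = baseline_count),
            class = "signal_ts")
}

#' Concentration time series
#'
#' Contrast-agent concentration (relaxivity-scaled, arbitrary units) on a
#' time grid, tagged with its role (tissue curve or arterial input function).
#'
#' @param times Times in seconds, strictly increasing.
#' @param values Finite concentration values.
#' @param role Either `"tissue"` or `"arterial"`.
#' @return An object of class `conc_ts`.
#' @export
conc_ts <- function(times, values, role = c("tissue", "arterial")) {
  role <- match.arg(role)
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("concentration values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 role = role),
            class = "conc_ts")
}

# frame interval of a uniformly sampled series; errors if visibly non-uniform
.grid_dt <- function(times) {
  d <- diff(times)
  if (max(d) - min(d) > 1e-8 * max(d)) {
    stop("time grid is not uniform")
  }
  mean(d)
}

#' Convert dynamic signal to contrast-agent concentration
#'
#' Applies the standard single-exponential transverse-relaxation model:
#' the concentration at each frame is `-log(S/S0) / (te * r2star)`, where
#' `S0` is the arithmetic mean of the leading baseline frames.
#'
#' @param signal A [signal_ts] object.
#' @param acq An [acquisition_config].
#' @param role Role tag for the returned series.
#' @return A [conc_ts] on the same time grid.
#' @export
signal_to_concentration <- function(signal, acq, role = "tissue") {
  stopifnot(inherits(signal, "signal_ts"), inherits(acq, "acquisition_config"))
  s0 <- mean(signal$values[seq_len(signal$baseline_count)])
  conc <- -log(signal$values / s0) / (acq$te * acq$r2star)
  conc_ts(signal$times, conc, role = role)
}

#' Shift an arterial input function by a bolus delay
#'
#' Returns the AIF evaluated at `t - delta` on the original grid by linear
#' interpolation; points before the shifted support are zero. Sub-grid
#' delays are supported (reported tissue delays are typically far below the
#' frame interval).
#'
#' @param aif A [conc_ts].
#' @param delta Delay in seconds, `>= 0` (a physical lag from the AIF
#'   measurement site to the tissue inlet).
#' @return A [conc_ts] on the same grid.
#' @export
shift_aif <- function(aif, delta) {
  stopifnot(inherits(aif, "conc_ts"))
  if (delta < 0) stop("delta must be non-negative (a physical arrival lag)")
  if (delta == 0) return(aif)
  v <- stats::approx(aif$times, aif$values, xout = aif$times - delta,
                     yleft = 0, yright = aif$values[length(aif$values)])$y
  conc_ts(aif$times, v, role = aif$role)
}

# rectangle-rule convolution of residue samples with an AIF on a uniform grid
.convolve_residue_samples <- function(rvals, aif_values, dt) {
  n <- length(aif_values)
  full <- stats::convolve(rvals, rev(aif_values), type = "open")
  dt * full[seq_len(n)]
}

#' Tracer-kinetic forward model
#'
#' Evaluates the bolus-tracking convolution
#' `C_m(t) = (cbf / k_h) * sum_j R(t_j) C_a(t - delta - t_j) dt`
#' on the AIF grid, using the rectangle rule so that the forward and
#' inverse (deconvolution) problems share one discretisation.
#'
#' @param residue A [bezier_residue], or a numeric vector of residue-function
#'   samples on the grid `times - times[1]` (used by synthetic ground-truth
#'   families that are not Bezier curves).
#' @param cbf Flow scale (non-negative, concentration-normalised units).
#' @param delta Bolus delay in seconds.
#' @param aif Arterial input [conc_ts] on a uniform grid.
#' @param acq An [acquisition_config] (supplies `k_h`).
#' @return A tissue [conc_ts] of the same length as the AIF.
#' @export
forward_model <- function(residue, cbf, delta, aif, acq) {
  stopifnot(inherits(aif, "conc_ts"), inherits(acq, "acquisition_config"),
            cbf >= 0)
  dt <- .grid_dt(aif$times)
  tau <- aif$times - aif$times[1]
  rvals <- if (is.numeric(residue)) {
    if (length(residue) != length(tau)) {
      stop("numeric residue samples must match the AIF grid length")
    }
    residue
  } else {
    evaluate_residue(residue, tau)
  }
  ca <- shift_aif(aif, delta)$values
  cm <- (cbf / acq$k_h) * .convolve_residue_samples(rvals, ca, dt)
  conc_ts(aif$times, cm, role = "tissue")
}

#' Read / write a time series as CSV
#'
#' Plain two-column CSV with header `time_s,value`.
#'
#' @param path File path.
#' @param role Role tag for the returned [conc_ts] (`read_timeseries_csv`).
#' @return `read_timeseries_csv` returns a [conc_ts];
#'   `write_timeseries_csv` invisibly returns `path`.
#' @export
read_timeseries_csv <- function(path, role = "arterial") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("time series CSV must have columns time_s,value")
  }
  conc_ts(df$time_s, df$value, role = role)
}

#' @rdname read_timeseries_csv
#' @param ts A [conc_ts] or [signal_ts].
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(data.frame(time_s = ts$times, value = ts$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an acquisition configuration from YAML
#'
#' Expects keys `te_s`, `dt_s`, `n_frames`, `n_baseline`, `r2star`, `k_h`
#' (missing keys fall back to the [acquisition_config] defaults).
#'
#' @param path YAML file path.
#' @return An [acquisition_config].
#' @export
read_acquisition_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- formals(acquisition_config)
  get_or <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  acquisition_config(
    te = get_or("te_s", eval(defaults$te)),
    dt = get_or("dt_s", eval(defaults$dt)),
    n_frames = get_or("n_frames", eval(defaults$n_frames)),
    n_baseline = get_or("n_baseline", eval(defaults$n_baseline)),
    r2star = get_or("r2star", eval(defaults$r2star)),
    k_h = get_or("k_h", eval(defaults$k_h)))
}
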