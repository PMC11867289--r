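# Synthetic DSC-MRI phantoms with known ground truth: gamma-variate AIF,
# residue-function families (Bezier / linear / boxcar / gamma-h), bolus
# delay, CBF, and baseline-SNR-controlled Gaussian signal noise. The
# default acquisition mirrors the bolus-tracking protocol the pipeline
# targets: 46 frames at 1.65 s (75 s), TE 54 ms, 11 baseline frames.

#' Gamma-variate arterial input function
#'
#' `C_a(t) = amplitude * (t - t0)^alpha * exp(-(t - t0)/beta)` for
#' `t > t0`, zero before. The peak sits at `t0 + alpha * beta` and the
#' area from `t0` to infinity is `amplitude * beta^(alpha+1) *
#' gamma(alpha+1)`.
#'
#' @param times Sampling grid in seconds.
#' @param t0 Bolus arrival time in seconds (the default 20 s places the
#'   bolus after an 11-frame pre-contrast window at 1.65 s resolution).
#' @param alpha,beta Shape and scale parameters (`> 0`).
#' @param amplitude Overall scale. The default, together with the default
#'   tissue class (CBV about 4.5 percent), produces a peak tissue signal
#'   drop of about 50 percent at TE 54 ms — representative of a
#'   double-dose (0.2 mmol/kg) injection at 1.5 T.
#' @return An arterial [conc_ts].
#' @export
gamma_variate_aif <- function(times, t0 = 20, alpha = 3, beta = 1.5,
                              amplitude = 0.85) {
  stopifnot(alpha > 0, beta > 0)
  v <- ifelse(times > t0,
              amplitude * (times - t0)^alpha * exp(-(times - t0) / beta), 0)
  conc_ts(times, v, role = "arterial")
}

#' Ground-truth tissue class for a phantom
#'
#' @param residue_family `"bezier"`, `"linear"`, `"boxcar"` or
#'   `"gamma_h"`. `"linear"` gives a uniform transit-time distribution on
#'   `[0, 2 MTT]`; `"boxcar"` is plug flow (`R = 1` for `t < MTT`);
#'   `"gamma_h"` draws the transit-time density from a gamma distribution
#'   with the given shape and mean MTT — its residue is not exactly
#'   representable by a cubic Bezier curve, making it a model-mismatch
#'   stress test.
#' @param mtt Ground-truth mean transit time (seconds).
#' @param cbf Flow scale.
#' @param delta Bolus delay (seconds, `>= 0`).
#' @param shape Gamma shape parameter (gamma_h family only).
#' @param residue A [bezier_residue] (bezier family only; overrides
#'   `mtt`).
#' @return A list of class `phantom_class`.
#' @export
phantom_class <- function(residue_family = c("linear", "bezier", "boxcar",
                                             "gamma_h"),
                          mtt = 3.8, cbf = 0.012, delta = 0.5,
                          shape = 3, residue = NULL) {
  residue_family <- match.arg(residue_family)
  stopifnot(mtt > 0, cbf >= 0, delta >= 0, shape > 0)
  if (residue_family == "bezier") {
    if (is.null(residue)) residue <- linear_residue(mtt)
    mtt <- mtt(residue)
  }
  structure(list(residue_family = residue_family, mtt = mtt, cbf = cbf,
                 delta = delta, shape = shape, residue = residue),
            class = "phantom_class")
}

# residue-function samples of a ground-truth class on a tau grid
.class_residue_samples <- function(cls, tau) {
  switch(cls$residue_family,
         bezier = evaluate_residue(cls$residue, tau),
         linear = pmax(1 - tau / (2 * cls$mtt), 0),
         boxcar = as.numeric(tau < cls$mtt),
         gamma_h = 1 - stats::pgamma(tau, shape = cls$shape,
                                     scale = cls$mtt / cls$shape))
}

#' Synthesise a tissue concentration curve
#'
#' Forward tracer-kinetic model output for one ground-truth class:
#' the class residue function (sampled on the acquisition grid) convolved
#' with the delayed AIF and scaled by CBF.
#'
#' @param cls A [phantom_class].
#' @param aif Arterial [conc_ts].
#' @param acq An [acquisition_config].
#' @return A tissue [conc_ts].
#' @export
make_tissue_curve <- function(cls, aif, acq) {
  stopifnot(inherits(cls, "phantom_class"))
  tau <- aif$times - aif$times[1]
  rvals <- .class_residue_samples(cls, tau)
  forward_model(rvals, cls$cbf, cls$delta, aif, acq)
}

#' Convert concentration to MRI signal
#'
#' Exact inverse of [signal_to_concentration()]:
#' `S = s0 * exp(-te * r2star * C)`.
#'
#' @param conc A [conc_ts].
#' @param acq An [acquisition_config].
#' @param s0 Baseline signal level (`> 0`).
#' @param baseline_count Baseline frames recorded on the output series.
#' @return A [signal_ts].
#' @export
concentration_to_signal <- function(conc, acq, s0 = 100,
                                    baseline_count = acq$n_baseline) {
  stopifnot(inherits(conc, "conc_ts"), s0 > 0)
  signal_ts(conc$times, s0 * exp(-acq$te * acq$r2star * conc$values),
            baseline_count = baseline_count)
}

#' Add baseline-SNR-controlled noise to a signal
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' `s0 / baseline_snr`, where `s0` is the mean of the clean baseline
#' frames. Gaussian (rather than Rician) noise is appropriate at the
#' baseline SNR levels of bolus-tracking data (SNR of order 20 and
#' above). Fully reproducible for a fixed seed.
#'
#' @param signal A [signal_ts].
#' @param baseline_snr Target baseline SNR (`> 0`; `Inf` returns the
#'   clean signal).
#' @param seed Integer RNG seed.
#' @return A noisy [signal_ts].
#' @export
add_noise <- function(signal, baseline_snr, seed) {
  stopifnot(inherits(signal, "signal_ts"), baseline_snr > 0)
  if (!is.finite(baseline_snr)) return(signal)
  s0 <- mean(signal$values[seq_len(signal$baseline_count)])
  set.seed(seed)
  noisy <- signal$values + stats::rnorm(length(signal$values),
                                        sd = s0 / baseline_snr)
  signal_ts(signal$times, noisy, baseline_count = signal$baseline_count)
}

#' Phantom specification
#'
#' @param shape 3D grid dimensions, e.g. `c(8, 8, 2)`.
#' @param classes List of [phantom_class()] ground truths; voxels are
#'   assigned to classes in contiguous blocks of equal size (remainder to
#'   the last class).
#' @param acq An [acquisition_config].
#' @param aif_params Named list passed to [gamma_variate_aif()].
#' @param baseline_snr Baseline SNR of the synthetic signal (`Inf` =
#'   noiseless).
#' @param s0 Baseline signal level.
#' @param seed Mandatory integer seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(8, 8, 2),
                         classes = list(phantom_class()),
                         acq = acquisition_config(),
                         aif_params = list(),
                         baseline_snr = Inf, s0 = 100, seed) {
  if (missing(seed)) stop("a seed is mandatory for phantom generation")
  stopifnot(length(shape) == 3, all(shape >= 1), baseline_snr > 0, s0 > 0)
  structure(list(shape = as.integer(shape), classes = classes, acq = acq,
                 aif_params = aif_params, baseline_snr = baseline_snr,
                 s0 = s0, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build a synthetic DSC-MRI phantom
#'
#' Generates a 4D signal volume, a full brain mask, ground-truth maps
#' (MTT, delay, CBF, class index) and the AIF series, all with known
#' per-voxel ground truth and deterministic for a fixed seed. With
#' `outdir` set, writes `volume.nii.gz`, `mask.nii.gz`,
#' `truth_<param>.nii.gz`, `aif.csv` and `spec-echo.yaml`.
#'
#' @param spec A [phantom_spec].
#' @param outdir Optional output directory.
#' @return A list with `volume` (4D array), `mask`, `truth` (named list
#'   of 3D arrays), `aif` ([conc_ts] of arterial concentration), `acq`,
#'   and `spec`.
#' @export
build_phantom <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  acq <- spec$acq
  times <- (seq_len(acq$n_frames) - 1) * acq$dt
  aif <- do.call(gamma_variate_aif, c(list(times = times), spec$aif_params))
  n_vox <- prod(spec$shape)
  n_cls <- length(spec$classes)
  cls_id <- rep(seq_len(n_cls), each = ceiling(n_vox / n_cls))[seq_len(n_vox)]

  clean_signals <- lapply(spec$classes, function(cls) {
    conc <- make_tissue_curve(cls, aif, acq)
    concentration_to_signal(conc, acq, s0 = spec$s0)$values
  })
  sig <- matrix(0, nrow = acq$n_frames, ncol = n_vox)
  for (k in seq_len(n_cls)) sig[, cls_id == k] <- clean_signals[[k]]
  if (is.finite(spec$baseline_snr)) {
    set.seed(spec$seed)
    sig <- sig + matrix(stats::rnorm(length(sig),
                                     sd = spec$s0 / spec$baseline_snr),
                        nrow = nrow(sig))
  }
  volume <- aperm(array(sig, dim = c(acq$n_frames, spec$shape)),
                  c(2, 3, 4, 1))
  mask <- array(TRUE, dim = spec$shape)
  truth_of <- function(field) {
    array(vapply(spec$classes, `[[`, numeric(1), field)[cls_id],
          dim = spec$shape)
  }
  truth <- list(mtt_s = truth_of("mtt"), delta_s = truth_of("delta"),
                cbf = truth_of("cbf"),
                class = array(cls_id, dim = spec$shape))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    RNifti::writeNifti(volume, file.path(outdir, "volume.nii.gz"))
    RNifti::writeNifti(array(as.numeric(mask), dim = spec$shape),
                       file.path(outdir, "mask.nii.gz"))
    for (nm in names(truth)) {
      RNifti::writeNifti(truth[[nm]],
                         file.path(outdir, paste0("truth_", nm, ".nii.gz")))
    }
    write_timeseries_csv(aif, file.path(outdir, "aif.csv"))
    yaml::write_yaml(list(
      shape = spec$shape, n_classes = n_cls, seed = spec$seed,
      baseline_snr = spec$baseline_snr, s0 = spec$s0,
      acquisition = list(te_s = acq$te, dt_s = acq$dt,
                         n_frames = acq$n_frames,
                         n_baseline = acq$n_baseline,
                         r2star = acq$r2star, k_h = acq$k_h)),
      file.path(outdir, "spec-echo.yaml"))
  }
  list(volume = volume, mask = mask, truth = truth, aif = aif, acq = acq,
       spec = spec)
}

#' Model AOEF for paired MTT values
#'
#' For each subject pair, builds linear residue functions with the given
#' normal-breathing and hyperventilation MTTs and evaluates the capillary
#' model AOEF under the corresponding [condition_presets()]. Used to
#' check the expected ordering (longer transit times and the hypocapnic
#' blood-gas shift both raise the extraction index).
#'
#' @param mtt_n,mtt_h Paired MTT vectors in seconds.
#' @param ... Overrides passed to [condition_presets()].
#' @return A `data.frame` with columns `mtt_n`, `mtt_h`, `aoef_n`,
#'   `aoef_h` (percent scale).
#' @export
aoef_for_mtt_pairs <- function(mtt_n, mtt_h, ...) {
  stopifnot(length(mtt_n) == length(mtt_h))
  par_n <- condition_presets("normal_breathing", ...)
  par_h <- condition_presets("hyperventilation", ...)
  tau_max <- 2 * max(mtt_n, mtt_h)
  q_n <- extraction_curve(par_n, tau_max = tau_max)
  q_h <- extraction_curve(par_h, tau_max = tau_max)
  data.frame(
    mtt_n = mtt_n, mtt_h = mtt_h,
    aoef_n = vapply(mtt_n, function(m) aoef(linear_residue(m), qcurve = q_n),
                    numeric(1)),
    aoef_h = vapply(mtt_h, function(m) aoef(linear_residue(m), qcurve = q_h),
                    numeric(1)))
}
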