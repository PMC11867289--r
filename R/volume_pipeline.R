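# Voxel-wise pipeline: signal -> concentration -> deconvolution -> maps
# (MTT, CTH, AOEF, delay, CBF, CBV) -> whole-brain summary values.

#' Cerebral blood volume from concentration curves
#'
#' `CBV = k_h * integral(C_m) / integral(C_a)` by trapezoid integration;
#' no deconvolution is involved.
#'
#' @param tissue Tissue [conc_ts].
#' @param aif Arterial [conc_ts] with positive area.
#' @param acq An [acquisition_config] (supplies `k_h`).
#' @return Dimensionless volume fraction.
#' @export
compute_cbv <- function(tissue, aif, acq) {
  stopifnot(inherits(tissue, "conc_ts"), inherits(aif, "conc_ts"),
            inherits(acq, "acquisition_config"))
  area_a <- .trapz(aif$times, aif$values)
  if (area_a <= 0) stop("AIF area must be positive")
  acq$k_h * .trapz(tissue$times, tissue$values) / area_a
}

#' Scaled-MAD outlier filter
#'
#' Removes values lying more than three scaled median absolute deviations
#' from the median (scaled MAD = 1.4826 * MAD, the normal-consistent
#' estimate of the standard deviation). Survivors keep their input order.
#' With a zero MAD (e.g. all values identical) only values equal to the
#' median survive, the literal reading of the rule.
#'
#' @param values Non-empty numeric vector.
#' @return The retained values.
#' @export
mad_outlier_filter <- function(values) {
  if (length(values) == 0) stop("mad_outlier_filter needs a non-empty input")
  med <- stats::median(values)
  smad <- 1.4826 * stats::median(abs(values - med))
  values[abs(values - med) <= 3 * smad]
}

#' Whole-brain mean of a parameter map
#'
#' Mean over in-mask voxels with non-zero values; for delay maps the
#' scaled-MAD outlier filter is applied before averaging
#' (`apply_mad = TRUE`).
#'
#' @param map Numeric array (any shape).
#' @param mask Logical/0-1 array of the same shape.
#' @param apply_mad Apply [mad_outlier_filter()] before averaging.
#' @return The summary mean.
#' @export
whole_brain_mean <- function(map, mask, apply_mad = FALSE) {
  stopifnot(length(map) == length(mask))
  v <- map[as.logical(mask) & abs(map) > 0]
  if (length(v) == 0) stop("no non-zero in-mask voxels")
  if (apply_mad) v <- mad_outlier_filter(v)
  mean(v)
}

#' Baseline SNR of a region of interest
#'
#' SNR is the temporal mean of the ROI-mean signal over the baseline
#' (pre-contrast) frames divided by its temporal standard deviation.
#'
#' @param roi_signal Either a matrix (voxels x frames) of signals in the
#'   ROI, or the ROI-mean signal series as a vector.
#' @param n_baseline Number of leading baseline frames (`>= 2`).
#' @param label ROI label, e.g. `"arterial"` or `"venous"`.
#' @return A list with `label` and `snr`.
#' @export
roi_snr <- function(roi_signal, n_baseline, label = "venous") {
  if (n_baseline < 2) stop("need at least 2 baseline frames for SNR")
  series <- if (is.matrix(roi_signal)) colMeans(roi_signal) else as.numeric(roi_signal)
  if (n_baseline > length(series)) stop("n_baseline exceeds series length")
  base <- series[seq_len(n_baseline)]
  sdv <- stats::sd(base)
  if (sdv == 0) stop("zero temporal variance in baseline frames")
  list(label = label, snr = mean(base) / sdv)
}

.as_volume <- function(x) {
  if (is.character(x)) return(RNifti::readNifti(x))
  x
}

#' Run the full perfusion pipeline over a masked 4D volume
#'
#' Converts each in-mask voxel's signal to concentration, deconvolves it
#' against the AIF, and assembles parameter maps (MTT, CTH, AOEF, delay,
#' CBF, CBV) plus the whole-brain summary: means of the non-zero in-mask
#' MTT/CTH/AOEF/CBV values, and the delay mean after scaled-MAD outlier
#' removal. Voxels whose fit fails are flagged and set to zero in all
#' maps. The computation is deterministic: the multi-start schedule is a
#' fixed low-discrepancy sequence.
#'
#' @param volume 4D numeric array (x, y, z, frame) or NIfTI path.
#' @param mask 3D logical/0-1 array or NIfTI path; must contain at least
#'   one voxel.
#' @param aif Arterial input: a [conc_ts] on the acquisition grid
#'   (already in concentration units), or a CSV path (`time_s,value`).
#' @param acq An [acquisition_config].
#' @param oxygen An [oxygen_params] (or `NULL` to skip the AOEF map).
#' @param options A [fit_options].
#' @param outdir Optional output directory: writes `<param>.nii.gz` maps
#'   and `summary.csv`.
#' @return A list with `maps` (named list of 3D arrays), `summary`
#'   (one-row `data.frame`), and `results` (per-voxel fit table).
#' @export
run_pipeline <- function(volume, mask, aif, acq,
                         oxygen = condition_presets("normal_breathing"),
                         options = fit_options(), outdir = NULL) {
  volume <- .as_volume(volume)
  mask <- .as_volume(mask)
  if (is.character(aif)) aif <- read_timeseries_csv(aif, role = "arterial")
  stopifnot(inherits(aif, "conc_ts"), inherits(acq, "acquisition_config"))
  # NIfTI readers may drop trailing singleton dimensions
  pad_dim <- function(x, nd) {
    d <- dim(x)
    if (is.null(d)) d <- length(x)
    if (length(d) > nd) stop("array has more than ", nd, " dimensions")
    array(as.numeric(x), dim = c(d, rep(1L, nd - length(d))))
  }
  if (length(dim(volume)) != 4) {
    stop("volume must be a 4D array (x, y, z, frame)")
  }
  vdim <- dim(volume)
  mask <- pad_dim(mask, 3)
  if (!all(dim(mask) == vdim[1:3])) stop("mask shape does not match volume")
  if (vdim[4] != length(aif$times)) stop("AIF grid does not match volume frames")
  mask <- array(as.logical(mask), dim = vdim[1:3])
  idx <- which(mask)
  if (length(idx) == 0) stop("mask is empty")

  sig <- matrix(aperm(volume, c(4, 1, 2, 3)), nrow = vdim[4])[, idx, drop = FALSE]
  curves <- lapply(seq_along(idx), function(j) {
    s <- signal_ts(aif$times, sig[, j], baseline_count = acq$n_baseline)
    signal_to_concentration(s, acq)
  })
  fits <- fit_region(curves, aif, acq, options)

  qcurve <- NULL
  if (!is.null(oxygen)) {
    duration <- length(aif$times) * .grid_dt(aif$times)
    qcurve <- extraction_curve(oxygen, tau_max = options$t_end_frac * duration)
  }
  zero3 <- array(0, dim = vdim[1:3])
  maps <- list(mtt_s = zero3, cth = zero3, aoef = zero3, delta_s = zero3,
               cbf = zero3, cbv = zero3)
  for (j in seq_along(idx)) {
    f <- fits[[j]]
    if (!f$converged) next
    v <- idx[j]
    maps$mtt_s[v] <- mtt(f$residue)
    maps$cth[v] <- cth(f$residue)
    maps$delta_s[v] <- f$delta
    maps$cbf[v] <- f$cbf
    maps$cbv[v] <- compute_cbv(curves[[j]], aif, acq)
    if (!is.null(qcurve)) maps$aoef[v] <- aoef(f$residue, qcurve = qcurve)
  }

  summary <- data.frame(
    mtt_s = whole_brain_mean(maps$mtt_s, mask),
    cth = whole_brain_mean(maps$cth, mask),
    aoef = if (is.null(qcurve)) NA_real_ else whole_brain_mean(maps$aoef, mask),
    delta_s = if (any(maps$delta_s[mask] != 0)) {
      whole_brain_mean(maps$delta_s, mask, apply_mad = TRUE)
    } else 0,
    cbf = whole_brain_mean(maps$cbf, mask),
    cbv = whole_brain_mean(maps$cbv, mask),
    n_voxels = length(idx),
    n_converged = sum(vapply(fits, `[[`, logical(1), "converged")))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(maps)) {
      RNifti::writeNifti(maps[[nm]], file.path(outdir, paste0(nm, ".nii.gz")))
    }
    utils::write.csv(summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(maps = maps, summary = summary, results = results_table(fits))
}
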