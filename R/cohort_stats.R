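# Paired-cohort statistics: normal breathing (N) vs hyperventilation (H)
# comparison of whole-brain MTT, AOEF, venous SNR and arterial delay, plus
# ETCO2 regressions. The per-subject values of the eight-subject
# hyperventilation cohort are packaged as CSV fixtures.

.fixture_md5 <- c(
  table1_etco2.csv  = "667f1a44adf07541a95d9cf71e917b1c",
  table3_params.csv = "1da1f691f073126b2dc028c1fd9d7aee")

#' Load the paired cohort table
#'
#' Reads the packaged eight-subject fixture (per-subject ETCO2, MTT, AOEF,
#' venous SNR and arterial delay under normal breathing `_n` and
#' hyperventilation `_h`), or a user CSV with the same columns. Packaged
#' fixtures are checksum-verified.
#'
#' @param path Optional path to a user CSV replacing the packaged
#'   parameter table (columns `subject`, `mtt_n_s`, `mtt_h_s`, `aoef_n`,
#'   `aoef_h`, `snr_n`, `snr_h`, `delta_n_s`, `delta_h_s`).
#' @return A `data.frame`, one row per subject, merged with the ETCO2
#'   table when the packaged fixture is used.
#' @export
cohort_table <- function(path = NULL) {
  if (is.null(path)) {
    f1 <- system.file("extdata", "table1_etco2.csv", package = "dscbezier",
                      mustWork = TRUE)
    f3 <- system.file("extdata", "table3_params.csv", package = "dscbezier",
                      mustWork = TRUE)
    for (f in c(f1, f3)) {
      got <- unname(tools::md5sum(f))
      if (!identical(got, unname(.fixture_md5[basename(f)]))) {
        warning("fixture checksum mismatch for ", basename(f))
      }
    }
    merge(utils::read.csv(f1), utils::read.csv(f3), by = "subject")
  } else {
    utils::read.csv(path)
  }
}

#' Paired t-test
#'
#' Classical paired t-test on the per-subject differences `y - x`, with a
#' two-sided p-value on `n - 1` degrees of freedom.
#'
#' @param x,y Paired numeric vectors of equal length (`>= 2`).
#' @return A list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- y - x
  if (stats::sd(d) == 0) stop("paired differences have zero variance")
  ht <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}

# null distribution of the positive-rank sum by full sign enumeration
.signrank_exact_p <- function(ranks, w_obs) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% ranks)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided exact test on paired differences `y - x`. The null
#' distribution of the positive-rank sum is obtained by full enumeration
#' of all `2^n` sign assignments (midranks for tied magnitudes); zero
#' differences are dropped with a warning. Enumeration is limited to
#' `n <= 16` usable pairs (65536 assignments).
#'
#' @param x,y Paired numeric vectors.
#' @return A list with `statistic` (positive-rank sum `V`), `p` (exact
#'   two-sided), and `n_used`.
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- y - x
  if (any(d == 0)) {
    warning(sum(d == 0), " zero difference(s) dropped")
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  if (n > 16) stop("exact enumeration limited to 16 non-zero pairs")
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  list(statistic = w_obs, p = .signrank_exact_p(ranks, w_obs), n_used = n)
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample with `3 <= n <= 50` and non-zero variance.
#' @return A list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  stopifnot(length(x) >= 3, length(x) <= 50)
  if (stats::sd(x) == 0) stop("constant sample")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Bonferroni significance gate
#'
#' Flags `p < alpha / m` (strict inequality), controlling the family-wise
#' error rate over `m` tests.
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Family-wise level.
#' @param m Number of tests in the family (defaults to
#'   `length(p_values)`).
#' @return Logical vector of significance flags.
#' @export
bonferroni_gate <- function(p_values, alpha = 0.05, m = length(p_values)) {
  stopifnot(m >= 1)
  p_values < alpha / m
}

#' Pearson correlation with least-squares line
#'
#' @param x,y Numeric vectors (`n >= 3`, non-constant).
#' @return A list with `r`, `slope`, `intercept`, `p` (two-sided, from
#'   the t transform of `r`), and `n`.
#' @export
pearson_with_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), p = ct$p.value,
       n = length(x))
}

#' Paired change summaries per parameter
#'
#' For each parameter, reports the column means under both conditions, the
#' mean and median of the per-subject H/N ratios, the ratio of the column
#' means, and the corresponding percent changes. The mean of per-subject
#' ratios is the "average increase" convention; the ratio of means is the
#' group-level alternative (both are reported — they differ whenever the
#' per-subject ratios are heterogeneous, as for the arterial delay).
#'
#' @param table A cohort `data.frame` (see [cohort_table()]).
#' @param params Parameter stems to summarise; each needs paired columns
#'   `<stem>_n*` and `<stem>_h*`.
#' @return A `data.frame`, one row per parameter.
#' @export
change_summaries <- function(table,
                             params = c("mtt", "aoef", "snr", "delta")) {
  find_col <- function(stem, cond) {
    hits <- grep(paste0("^", stem, "_", cond, "(_|$)"), names(table))
    if (length(hits) != 1) stop("cannot locate column for ", stem, "_", cond)
    table[[hits]]
  }
  rows <- lapply(params, function(p) {
    vn <- find_col(p, "n")
    vh <- find_col(p, "h")
    if (any(is.na(vn)) || any(is.na(vh))) stop("missing paired values for ", p)
    ratios <- vh / vn
    data.frame(parameter = p,
               mean_n = mean(vn), mean_h = mean(vh),
               sd_n = stats::sd(vn), sd_h = stats::sd(vh),
               mean_subject_ratio = mean(ratios),
               median_subject_ratio = stats::median(ratios),
               ratio_of_means = mean(vh) / mean(vn),
               pct_change_subject = 100 * (mean(ratios) - 1),
               pct_change_of_means = 100 * (mean(vh) / mean(vn) - 1))
  })
  do.call(rbind, rows)
}

#' Central-volume-theorem transit-time factor
#'
#' With `MTT = CBV / CBF`, relative changes in CBV and CBF imply a
#' relative change in MTT of `(CBV ratio) / (CBF ratio)`. Useful for
#' translating literature CBV/CBF changes into the expected MTT change.
#'
#' @param cbv_ratio Ratio of CBV between conditions (e.g. `1 - 0.072`
#'   for a 7.2 % decrease).
#' @param cbf_ratio Ratio of CBF between conditions.
#' @return The implied MTT ratio.
#' @export
mtt_change_factor <- function(cbv_ratio, cbf_ratio) {
  stopifnot(cbv_ratio > 0, cbf_ratio > 0)
  cbv_ratio / cbf_ratio
}

#' Velocity change implied by a delay change
#'
#' The arterial bolus delay is inversely proportional to arterial blood
#' velocity for a fixed path length, so a delay ratio `rho` implies a
#' fractional velocity change of `1/rho - 1`.
#'
#' @param delay_ratio Ratio of delays between conditions (H/N).
#' @return Fractional velocity change (negative = slowdown).
#' @export
implied_velocity_change <- function(delay_ratio) {
  stopifnot(delay_ratio > 0)
  1 / delay_ratio - 1
}
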