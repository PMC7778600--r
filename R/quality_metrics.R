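#' Band definition for SNR and peak readouts
#'
#' @param signal_peak Centre of the signal band in cm^-1 (default 1650,
#'   the amide I protein band).
#' @param window_half_width Half-width of the peak search window in
#'   cm^-1 (default 10).
#' @param noise_lo,noise_hi Bounds of the silent noise-estimation band in
#'   cm^-1 (defaults 1780 and 1820, above the biological fingerprint).
#' @return A list of class `praman_band`.
#' @export
band_def <- function(signal_peak = 1650, window_half_width = 10,
                     noise_lo = 1780, noise_hi = 1820) {
  if (noise_lo >= noise_hi) stop("noise_lo must be < noise_hi")
  if (window_half_width <= 0) stop("window_half_width must be positive")
  structure(list(signal_peak = signal_peak,
                 window_half_width = window_half_width,
                 noise_lo = noise_lo, noise_hi = noise_hi),
            class = "praman_band")
}

#' Replicate signal-to-noise ratio
#'
#' SNR of a set of replicate spectra: the mean (over replicates) of the
#' maximum intensity within the signal window, divided by the mean (over
#' channels in the silent noise band) of the per-channel sample standard
#' deviation across replicates. Invariant to global intensity scaling.
#'
#' @param coll Collection of >= 2 replicates on a shared axis.
#' @param band A [band_def()].
#' @return A dimensionless scalar.
#' @export
snr <- function(coll, band = band_def()) {
  a <- require_shared_axis(coll, "snr")
  if (n_spectra(coll) < 2) stop("snr needs at least 2 replicate spectra")
  stopifnot(inherits(band, "praman_band"))
  sig <- abs(a - band$signal_peak) <= band$window_half_width
  if (!any(sig)) stop("signal window overlaps no channels")
  noise <- a >= band$noise_lo & a <= band$noise_hi
  if (!any(noise)) stop("noise band overlaps no channels on this axis")
  m <- as.matrix(coll)
  numerator <- mean(apply(m[, sig, drop = FALSE], 1, max))
  denominator <- mean(apply(m[, noise, drop = FALSE], 2, stats::sd))
  if (denominator == 0) stop("zero noise estimate")
  numerator / denominator
}

#' Mean spectral coefficient of variation
#'
#' Per-channel standard deviation across replicates divided by the
#' per-channel absolute mean, averaged over channels whose absolute mean
#' exceeds 1e-12 of the largest absolute mean (near-zero channels would
#' make the ratio unstable).
#'
#' @param coll Collection of >= 2 replicates on a shared axis.
#' @return A dimensionless scalar.
#' @export
spectral_cv <- function(coll) {
  require_shared_axis(coll, "spectral_cv")
  if (n_spectra(coll) < 2) stop("spectral_cv needs at least 2 replicates")
  m <- as.matrix(coll)
  mu <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  keep <- abs(mu) > 1e-12 * max(abs(mu))
  if (!any(keep)) stop("all channels have near-zero mean")
  mean(sds[keep] / abs(mu[keep]))
}

#' Difference spectrum between two groups
#'
#' Channelwise `mean(A) - mean(B)`; antisymmetric in its arguments.
#' Used to track tumour-vs-control molecular differences over treatment.
#'
#' @param group_a,group_b Collections sharing one common axis.
#' @return A spectrum of the mean difference; its metadata records the
#'   group sizes.
#' @export
difference_spectrum <- function(group_a, group_b) {
  a <- require_shared_axis(group_a, "difference_spectrum")
  b <- require_shared_axis(group_b, "difference_spectrum")
  if (length(a) != length(b) || any(a != b))
    stop("the two groups must share the same axis")
  ma <- mean_spectrum(group_a); mb <- mean_spectrum(group_b)
  new_spectrum(a, ma$intensity - mb$intensity,
               group_a$spectra[[1]]$axis_kind,
               meta = list(n_a = n_spectra(group_a),
                           n_b = n_spectra(group_b)))
}

#' Windowed peak intensity
#'
#' Maximum intensity within `[center - half_width, center + half_width]`.
#' The window tolerates small calibration shifts of the peak position.
#'
#' @param s A spectrum.
#' @param center Window centre in axis units.
#' @param half_width Window half-width in axis units (default 10).
#' @return The maximum intensity in the window.
#' @export
peak_intensity <- function(s, center, half_width = 10) {
  stopifnot(is_spectrum(s))
  keep <- abs(s$axis - center) <= half_width
  if (!any(keep)) stop("peak window overlaps no channels")
  max(s$intensity[keep])
}

# signed extremum in a window: the value largest in magnitude, keeping
# its sign (difference-spectrum features may point downwards)
peak_extremum <- function(s, center, half_width = 10) {
  keep <- abs(s$axis - center) <= half_width
  if (!any(keep)) stop("peak window overlaps no channels")
  v <- s$intensity[keep]
  v[which.max(abs(v))]
}

#' Post-treatment monitoring time course
#'
#' From per-day difference spectra (tumour minus control tissue),
#' extracts the signed extremum in a peak window (by default around
#' 1440 cm^-1, where both a downward CH2 deformation difference and
#' calibration shifts of the 1445 cm^-1 band fall) and normalises each
#' day to day 0. A shrinking tumour signature gives values decreasing
#' below 1.
#'
#' @param diffs_by_day Named list of difference spectra; names are day
#'   numbers and must include `"0"`.
#' @param center,half_width Peak window (axis units).
#' @param absolute If `TRUE`, use absolute extrema instead of signed
#'   values.
#' @return Named numeric vector of per-day ratios; day 0 is 1 by
#'   construction.
#' @export
monitoring_timecourse <- function(diffs_by_day, center = 1440,
                                  half_width = 10, absolute = FALSE) {
  if (!is.list(diffs_by_day) || is.null(names(diffs_by_day)))
    stop("diffs_by_day must be a named list of spectra")
  if (!"0" %in% names(diffs_by_day)) stop("day 0 difference spectrum required")
  pk <- function(s) {
    v <- peak_extremum(s, center, half_width)
    if (absolute) abs(v) else v
  }
  p0 <- pk(diffs_by_day[["0"]])
  if (p0 == 0) stop("day-0 peak is zero; cannot normalise")
  vapply(diffs_by_day, function(s) pk(s) / p0, numeric(1))
}

#' Flag outliers by the 1.5 x IQR rule
#'
#' Flags values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, with
#' quartiles computed by linear interpolation of the order statistics
#' (quantile type 7).
#'
#' @param values Numeric vector of length >= 4.
#' @return Logical mask, `TRUE` for flagged values.
#' @export
iqr_outliers <- function(values) {
  if (length(values) < 4) stop("iqr_outliers needs at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-tailed p-value. If both groups have zero variance
#' and equal means the test is vacuous and `p = 1` is returned; zero
#' variance in both groups with unequal means is an error (the statistic
#' is undefined).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df` and `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = Inf, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- min(1, max(.Machine$double.xmin, 2 * stats::pt(-abs(t), df)))
  list(t = t, df = df, p = p)
}

#' Normalise a longitudinal signal to a baseline day
#'
#' Divides each day's value (e.g. bioluminescence total flux as a tumour
#' burden proxy) by the baseline-day value.
#'
#' @param signal_by_day Named numeric vector; names are day numbers.
#' @param baseline_day Day to normalise to (default `0`).
#' @return Named numeric vector of fractions; the baseline day maps to 1.
#' @export
normalized_growth <- function(signal_by_day, baseline_day = 0) {
  key <- as.character(baseline_day)
  if (!key %in% names(signal_by_day)) stop("baseline day not present")
  base <- signal_by_day[[key]]
  if (!is.finite(base) || base <= 0) stop("baseline value must be positive")
  signal_by_day / base
}
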