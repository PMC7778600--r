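#' Raman preprocessing configuration
#'
#' Bundles every parameter of the single-point Raman preprocessing chain
#' with the defaults used throughout the package: crop to 510-1825 cm^-1,
#' asymmetric Whittaker baseline subtraction with penalty `lam = 1e5`,
#' modified-z despiking at threshold 8, first-order Savitzky-Golay
#' smoothing with a 7-channel frame, and area-under-curve normalisation.
#'
#' @param crop_lo,crop_hi Crop window in cm^-1 (closed interval).
#' @param lam Whittaker baseline roughness penalty (dimensionless; applied
#'   on the channel index, not the physical spacing).
#' @param asym_p Asymmetry weight in (0, 1) given to points above the
#'   running baseline estimate; small values push the fit under the peaks.
#' @param baseline_iters Number of reweighting iterations.
#' @param spike_z Despike threshold in modified z-score units.
#' @param sg_order,sg_frame Savitzky-Golay polynomial order and odd frame
#'   width.
#' @param normalize `"auc"` (divide by trapezoidal area) or `"none"`.
#' @param mean_center Logical; recorded for downstream model fitting.
#'   Mean-centring is *not* applied by [preprocess_spectra()]: it belongs
#'   to model fitting, where it must be computed on training data only.
#' @return A list of class `praman_preprocess_config`.
#' @export
preprocess_config <- function(crop_lo = 510, crop_hi = 1825,
                              lam = 1e5, asym_p = 0.001,
                              baseline_iters = 10, spike_z = 8,
                              sg_order = 1, sg_frame = 7,
                              normalize = c("auc", "none"),
                              mean_center = TRUE) {
  normalize <- match.arg(normalize)
  if (crop_lo >= crop_hi) stop("crop_lo must be < crop_hi")
  if (lam <= 0) stop("lam must be positive")
  if (asym_p <= 0 || asym_p >= 1) stop("asym_p must lie in (0, 1)")
  if (baseline_iters < 1) stop("baseline_iters must be >= 1")
  if (sg_frame %% 2 != 1) stop("sg_frame must be odd")
  if (sg_frame <= sg_order) stop("sg_frame must exceed sg_order")
  structure(list(crop_lo = crop_lo, crop_hi = crop_hi, lam = lam,
                 asym_p = asym_p, baseline_iters = baseline_iters,
                 spike_z = spike_z, sg_order = sg_order,
                 sg_frame = sg_frame, normalize = normalize,
                 mean_center = mean_center),
            class = "praman_preprocess_config")
}

#' Crop a spectrum to a closed axis interval
#'
#' @param s A spectrum.
#' @param lo,hi Interval bounds in axis units; channels with
#'   `lo <= axis <= hi` are kept (both endpoints inclusive).
#' @return The cropped spectrum; metadata is carried over.
#' @export
crop_spectrum <- function(s, lo, hi) {
  stopifnot(is_spectrum(s))
  if (lo > hi) stop("lo must be <= hi")
  keep <- s$axis >= lo & s$axis <= hi
  if (!any(keep)) stop("crop window excludes all channels")
  respectrum(s, axis = s$axis[keep], intensity = s$intensity[keep])
}

#' Asymmetric Whittaker baseline estimation
#'
#' Estimates a smooth fluorescence baseline by asymmetric penalised least
#' squares: the baseline `z` solves `(W + lam * D'D) z = W y` where `D`
#' is the second-difference operator on the channel index and `W` is a
#' diagonal weight matrix, iteratively reweighted so that points above
#' the baseline (Raman peaks) get weight `asym_p` and points below get
#' `1 - asym_p`. The first pass uses unit weights, so `iters = 1` gives
#' the plain symmetric Whittaker smoother.
#'
#' @param s A spectrum with >= 4 channels.
#' @param lam Roughness penalty; larger values give stiffer baselines.
#' @param asym_p Asymmetry weight in (0, 1).
#' @param iters Maximum reweighting iterations; stops early when the
#'   weight assignment no longer changes.
#' @return A list with spectra `baseline` and `corrected`
#'   (`intensity - baseline`, not clipped at zero).
#' @export
whittaker_baseline <- function(s, lam = 1e5, asym_p = 0.001, iters = 10) {
  stopifnot(is_spectrum(s))
  if (lam <= 0) stop("lam must be positive")
  if (asym_p <= 0 || asym_p >= 1) stop("asym_p must lie in (0, 1)")
  y <- s$intensity
  n <- length(y)
  if (n < 4) stop("whittaker baseline needs at least 4 channels")
  D <- Matrix::diff(Matrix::Diagonal(n), differences = 2)
  P <- lam * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (k in seq_len(iters)) {
    A <- Matrix::forceSymmetric(Matrix::Diagonal(x = w) + P)
    ch <- Matrix::Cholesky(A, LDL = FALSE)
    b <- w * y
    z <- as.numeric(Matrix::solve(ch, b))
    # one step of iterative refinement: lam spans many orders of
    # magnitude and the raw solve loses ~cond(A) * eps in accuracy.
    # The residual is evaluated in structured form, w*(y-z) - lam*D'(Dz):
    # differencing nearly-equal neighbours is exact, so the correction
    # is not drowned by matvec round-off.
    r <- w * (y - z) -
      lam * as.numeric(Matrix::crossprod(D, D %*% z))
    z <- z + as.numeric(Matrix::solve(ch, r))
    w_new <- ifelse(y > z, asym_p, 1 - asym_p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  list(baseline = respectrum(s, intensity = z),
       corrected = respectrum(s, intensity = y - z))
}

# flag cosmic-ray channels by the modified z-score of the first
# differences; a channel is flagged when every first difference touching
# it is anomalous (a one-channel spike flips both adjacent differences)
despike_flags <- function(y, spike_z) {
  d <- diff(y)
  med <- stats::median(d)
  mad <- stats::median(abs(d - med))
  if (mad == 0) return(rep(FALSE, length(y)))
  z <- 0.6745 * abs(d - med) / mad
  n <- length(y)
  hot <- z > spike_z
  left <- c(TRUE, hot)    # difference ending at channel i (d[i-1])
  right <- c(hot, TRUE)   # difference starting at channel i (d[i])
  flags <- left & right
  # interior channels need both sides anomalous; at the edges only the
  # single existing difference is available
  flags[1] <- hot[1]
  flags[n] <- hot[n - 1]
  flags
}

#' Remove cosmic-ray spikes from a spectrum
#'
#' Channels whose adjacent first differences both have a modified
#' z-score (`0.6745 * |d - median(d)| / MAD(d)`) above `spike_z` are
#' treated as cosmic-ray hits and replaced by linear interpolation
#' between the nearest unflagged neighbours; every other channel is
#' returned bit-identical.
#'
#' @param s A spectrum (>= 5 channels).
#' @param spike_z Threshold in modified z-score units.
#' @return The despiked spectrum.
#' @export
despike <- function(s, spike_z = 8) {
  stopifnot(is_spectrum(s))
  y <- s$intensity
  if (length(y) < 5) stop("despike needs at least 5 channels")
  flags <- despike_flags(y, spike_z)
  if (!any(flags)) return(s)
  if (all(flags)) stop("degenerate spectrum: all channels flagged")
  good <- which(!flags)
  fixed <- y
  fixed[flags] <- stats::approx(x = good, y = y[good], xout = which(flags),
                                rule = 2)$y
  respectrum(s, intensity = fixed)
}

# centre weights of the SG smoother: first row of (A'A)^{-1} A'
sg_center_weights <- function(order, frame) {
  h <- (frame - 1) / 2
  A <- outer(-h:h, 0:order, `^`)
  as.numeric((solve(crossprod(A)) %*% t(A))[1, ])
}

#' Savitzky-Golay smoothing
#'
#' Each channel is replaced by the centre value of a least-squares
#' polynomial of degree `order` fitted over a window of `frame`
#' channels. Near the edges the same polynomial is fitted to the
#' truncated one-sided window, so the spectrum keeps its length and a
#' degree-`order` signal is reproduced exactly everywhere.
#'
#' @param s A spectrum.
#' @param order Polynomial degree (default 1).
#' @param frame Odd window width in channels (default 7); must exceed
#'   `order` and be smaller than the number of channels.
#' @return The smoothed spectrum.
#' @export
savgol <- function(s, order = 1, frame = 7) {
  stopifnot(is_spectrum(s))
  if (frame %% 2 != 1) stop("frame must be odd")
  if (frame <= order) stop("frame must exceed order")
  y <- s$intensity
  n <- length(y)
  if (frame >= n) stop("frame must be smaller than the number of channels")
  h <- (frame - 1) / 2
  wts <- sg_center_weights(order, frame)
  out <- as.numeric(stats::filter(y, wts, method = "convolution", sides = 2))
  for (i in c(seq_len(h), seq(n - h + 1, n))) {
    idx <- max(1L, i - h):min(n, i + h)
    A <- outer(idx - i, 0:order, `^`)
    out[i] <- qr.solve(A, y[idx])[1]
  }
  respectrum(s, intensity = out)
}

#' Normalise a spectrum to unit area under the curve
#'
#' Divides the intensity by its trapezoidal integral over the physical
#' axis, so the result integrates to exactly one. Idempotent and
#' invariant to global intensity scaling.
#'
#' @param s A spectrum whose trapezoidal area is positive.
#' @return The normalised spectrum.
#' @export
normalize_auc <- function(s) {
  stopifnot(is_spectrum(s))
  area <- trapz_area(s$axis, s$intensity)
  if (!is.finite(area) || area <= 0)
    stop("cannot normalise: total area is zero or negative")
  respectrum(s, intensity = s$intensity / area)
}

#' Mean-centre a collection of spectra
#'
#' Subtracts the per-channel mean across spectra; the column sums of the
#' centred data are zero to numerical precision.
#'
#' @param coll A collection with a shared axis and >= 2 spectra.
#' @return A list with `centered` (the centred collection) and `mean`
#'   (the subtracted mean spectrum).
#' @export
mean_center <- function(coll) {
  a <- require_shared_axis(coll, "mean_center")
  if (n_spectra(coll) < 2) stop("mean_center needs at least 2 spectra")
  m <- as.matrix(coll)
  mu <- colMeans(m)
  centered <- spectrum_collection(
    lapply(seq_len(nrow(m)), function(i)
      respectrum(coll$spectra[[i]], intensity = m[i, ] - mu)),
    labels = coll$labels)
  list(centered = centered,
       mean = new_spectrum(a, mu, coll$spectra[[1]]$axis_kind))
}

#' Run the full Raman preprocessing chain on a collection
#'
#' Applies, per spectrum and in this fixed order: crop, asymmetric
#' Whittaker baseline subtraction (keeping the corrected signal),
#' cosmic-ray despiking, Savitzky-Golay smoothing, and area
#' normalisation (if configured). Each spectrum is processed
#' independently; no information flows between spectra, so the chain is
#' safe to apply before any train/test split. Mean-centring is left to
#' model fitting.
#'
#' @param coll A [spectrum_collection()] (may be empty).
#' @param cfg A [preprocess_config()].
#' @return The processed collection, labels preserved.
#' @export
preprocess_spectra <- function(coll, cfg = preprocess_config()) {
  stopifnot(is_collection(coll), inherits(cfg, "praman_preprocess_config"))
  if (n_spectra(coll) == 0) return(coll)
  one <- function(s) {
    s <- tryCatch(crop_spectrum(s, cfg$crop_lo, cfg$crop_hi),
                  error = function(e) stop_stage("crop", e))
    s <- tryCatch(whittaker_baseline(s, cfg$lam, cfg$asym_p,
                                     cfg$baseline_iters)$corrected,
                  error = function(e) stop_stage("baseline", e))
    s <- tryCatch(despike(s, cfg$spike_z),
                  error = function(e) stop_stage("despike", e))
    s <- tryCatch(savgol(s, cfg$sg_order, cfg$sg_frame),
                  error = function(e) stop_stage("smooth", e))
    if (cfg$normalize == "auc")
      s <- tryCatch(normalize_auc(s),
                    error = function(e) stop_stage("normalize", e))
    s
  }
  collection_map(coll, one)
}
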