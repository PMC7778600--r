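#' Fluorescence quantification configuration
#'
#' Parameters of the PPIX tissue-quantification assay: crop window,
#' autofluorescence background penalty, smoothing, and the wavelength
#' band over which the PPIX emission is integrated (620-640 nm, around
#' the ~630 nm PPIX emission maximum).
#'
#' @param crop_lo_nm,crop_hi_nm Crop window in nm.
#' @param lam_bg Whittaker penalty for the tissue autofluorescence
#'   background (default 10; the background is broad and the penalty may
#'   be small).
#' @param asym_p,bg_iters Asymmetry weight and reweighting iterations of
#'   the background fit. The default asymmetry (1e-5) is much smaller
#'   than for Raman baselines: with the weak penalty `lam_bg = 10` a
#'   larger asymmetry would let the background climb into the narrow
#'   PPIX emission line and attenuate the quantification signal.
#' @param sg_order,sg_frame Savitzky-Golay parameters.
#' @param signal_band_nm Length-2 numeric, integration band in nm; must
#'   lie inside the crop window.
#' @return A list of class `praman_fluor_config`.
#' @export
fluor_quant_config <- function(crop_lo_nm = 450, crop_hi_nm = 750,
                               lam_bg = 10, asym_p = 1e-5, bg_iters = 10,
                               sg_order = 1, sg_frame = 7,
                               signal_band_nm = c(620, 640)) {
  if (crop_lo_nm >= crop_hi_nm) stop("crop_lo_nm must be < crop_hi_nm")
  if (length(signal_band_nm) != 2 || signal_band_nm[1] >= signal_band_nm[2])
    stop("signal_band_nm must be an increasing length-2 interval")
  if (signal_band_nm[1] < crop_lo_nm || signal_band_nm[2] > crop_hi_nm)
    stop("signal_band_nm must lie inside the crop window")
  structure(list(crop_lo_nm = crop_lo_nm, crop_hi_nm = crop_hi_nm,
                 lam_bg = lam_bg, asym_p = asym_p, bg_iters = bg_iters,
                 sg_order = sg_order, sg_frame = sg_frame,
                 signal_band_nm = signal_band_nm),
            class = "praman_fluor_config")
}

#' Process a fluorescence emission spectrum for PPIX readout
#'
#' Stages, in order: crop to the configured window, subtract the blank
#' (pure solvent) spectrum channelwise, subtract the tissue
#' autofluorescence background with the asymmetric Whittaker fit, then
#' Savitzky-Golay smooth.
#'
#' @param s Sample emission spectrum (`axis_kind == "wavelength"`).
#' @param blank Blank (solvent-only) spectrum on the same axis.
#' @param cfg A [fluor_quant_config()].
#' @return The processed spectrum.
#' @export
process_fluorescence <- function(s, blank, cfg = fluor_quant_config()) {
  stopifnot(is_spectrum(s), is_spectrum(blank),
            inherits(cfg, "praman_fluor_config"))
  if (s$axis_kind != "wavelength" || blank$axis_kind != "wavelength")
    stop("fluorescence processing requires wavelength-axis spectra")
  if (length(s$axis) != length(blank$axis) || any(s$axis != blank$axis))
    stop("sample and blank must share the same wavelength grid")
  s <- crop_spectrum(s, cfg$crop_lo_nm, cfg$crop_hi_nm)
  blank <- crop_spectrum(blank, cfg$crop_lo_nm, cfg$crop_hi_nm)
  sub <- respectrum(s, intensity = s$intensity - blank$intensity)
  corr <- whittaker_baseline(sub, lam = cfg$lam_bg, asym_p = cfg$asym_p,
                             iters = cfg$bg_iters)$corrected
  savgol(corr, cfg$sg_order, cfg$sg_frame)
}

#' Integrate spectral signal over a wavelength band
#'
#' Trapezoidal integral of the intensity over all channels inside the
#' (closed) band.
#'
#' @param s A spectrum.
#' @param band_nm Length-2 increasing interval in axis units.
#' @return The integral (intensity x axis units).
#' @export
integrate_signal <- function(s, band_nm) {
  stopifnot(is_spectrum(s))
  if (length(band_nm) != 2 || band_nm[1] >= band_nm[2])
    stop("band must be an increasing length-2 interval")
  keep <- s$axis >= band_nm[1] & s$axis <= band_nm[2]
  if (sum(keep) < 2) stop("band overlaps fewer than 2 channels")
  trapz_area(s$axis[keep], s$intensity[keep])
}

#' Fit a PPIX standard curve
#'
#' Ordinary least-squares line `signal = slope * amount + intercept`
#' through standards of known PPIX amount.
#'
#' @param amounts Known PPIX amounts (ng), >= 3 distinct values.
#' @param signals Integrated fluorescence signals, one per standard.
#' @return An object of class `praman_standard_curve` with `slope`
#'   (signal per ng), `intercept`, `r_squared` and the `points`.
#' @export
fit_standard_curve <- function(amounts, signals) {
  if (length(amounts) != length(signals))
    stop("amounts and signals must have equal length")
  if (length(unique(amounts)) < 3)
    stop("need at least 3 distinct standard amounts")
  fit <- stats::lm(signals ~ amounts)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((signals - mean(signals))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2,
                 points = data.frame(amount_ng = amounts, signal = signals)),
            class = "praman_standard_curve")
}

#' @export
print.praman_standard_curve <- function(x, ...) {
  cat(sprintf("<standard curve> signal = %.4g * ng + %.4g (r^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Back-calculate a tissue PPIX concentration
#'
#' Inverts the standard curve, scales by the aliquot dilution factor and
#' divides by the tumour mass. Back-calculated amounts below zero are
#' floored at zero and flagged.
#'
#' @param signal Integrated fluorescence signal of the sample aliquot.
#' @param curve A [fit_standard_curve()] object with nonzero slope.
#' @param dilution_factor Fold dilution of the aliquot (default 21: a
#'   50 uL aliquot of the tissue digest diluted into 1 mL gives
#'   (1000 + 50) / 50).
#' @param tumour_mass_g Tumour wet mass in grams.
#' @return A list with `ng_per_g`, the back-calculated cuvette
#'   `amount_ng`, and `floored` (`TRUE` when a negative amount was
#'   clipped to zero).
#' @export
quantify_ppix <- function(signal, curve, dilution_factor = 21,
                          tumour_mass_g) {
  stopifnot(inherits(curve, "praman_standard_curve"))
  if (curve$slope == 0) stop("standard curve slope is zero")
  if (tumour_mass_g <= 0) stop("tumour mass must be positive")
  if (dilution_factor <= 0) stop("dilution factor must be positive")
  amount <- (signal - curve$intercept) / curve$slope
  floored <- amount < 0
  if (floored) {
    warning("negative back-calculated amount floored at 0 ng")
    amount <- 0
  }
  list(ng_per_g = amount * dilution_factor / tumour_mass_g,
       amount_ng = amount, floored = floored)
}

#' Convert a mass concentration to molarity
#'
#' `ng/mL` divided by the molar mass in `g/mol` gives `umol/L` directly;
#' the result is reported to 3 significant figures.
#'
#' @param c_mass Mass concentration in ng/mL.
#' @param molar_mass Molar mass in g/mol.
#' @return Concentration in uM.
#' @export
mass_to_molar <- function(c_mass, molar_mass) {
  if (c_mass <= 0 || molar_mass <= 0) stop("inputs must be positive")
  signif(c_mass / molar_mass, 3)
}

#' PDT exposure time for a target fluence
#'
#' @param fluence Total optical dose in J/cm^2.
#' @param fluence_rate Delivery rate in mW/cm^2.
#' @return Exposure time in seconds: `fluence / (fluence_rate / 1000)`.
#' @export
exposure_time <- function(fluence, fluence_rate) {
  if (fluence <= 0 || fluence_rate <= 0) stop("inputs must be positive")
  fluence / (fluence_rate / 1000)
}
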