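#' Synthetic Raman generator configuration
#'
#' Parameterises a seeded generator of single-point tissue Raman spectra
#' with the structure the analysis chain assumes: Lorentzian bands at
#' the prominent tissue peaks (936, 1078, 1265, 1302, 1445, 1655 cm^-1),
#' a broad smooth fluorescence baseline, optional photosensitiser
#' background (for PPIX including a 1550 cm^-1 porphyrin band), additive
#' Gaussian noise, sporadic cosmic-ray spikes, and per-subject
#' amplitude jitter shared by a subject's replicate spectra.
#'
#' The tumour class effects lower the 1265/1302/1445/1655 cm^-1 band
#' amplitudes relative to control tissue while raising the
#' 1655-to-1445 ratio (protein up-regulation relative to the CH2
#' deformation band).
#'
#' @param axis Wavenumber grid in cm^-1.
#' @param peak_table Data frame with columns `center` (cm^-1), `width`
#'   (Lorentzian half-width at half-maximum, cm^-1) and `amplitude`.
#' @param class_effects Named list (one entry per class) of per-peak
#'   multiplicative amplitude factors, aligned with `peak_table` rows.
#' @param ps_background One of `"none"`, `"ppix"`, `"verteporfin"`,
#'   `"temoporfin"`; adds a broad fluorescence pedestal of amplitude
#'   `ps_level` and, for PPIX, a small 1550 cm^-1 band.
#' @param ps_level Amplitude of the photosensitiser fluorescence
#'   pedestal.
#' @param baseline Parameters of the smooth broad baseline: `offset`,
#'   `amplitude`, `center`, `width` (Gaussian hump plus constant).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (intensity counts).
#' @param spike_rate Per-spectrum probability of one cosmic-ray spike.
#' @param spike_amp Range (in multiples of `noise_sd`, minimum 20) of
#'   spike amplitudes.
#' @param subject_jitter_sd SD of the per-subject, per-peak log-normal
#'   amplitude jitter.
#' @param replicates_per_subject Spectra acquired per subject (default 5).
#' @param seed Default RNG seed used by the generators.
#' @return A list of class `praman_raman_gen_config`.
#' @export
raman_gen_config <- function(
    axis = seq(400, 2000, by = 1),
    peak_table = data.frame(
      center = c(936, 1078, 1265, 1302, 1445, 1655),
      width = c(12, 12, 14, 14, 16, 18),
      amplitude = c(45, 50, 60, 65, 100, 85)),
    class_effects = list(
      control = c(1, 1, 1, 1, 1, 1),
      tumour = c(1, 1, 0.80, 0.80, 0.78, 0.95)),
    ps_background = c("none", "ppix", "verteporfin", "temoporfin"),
    ps_level = 150,
    baseline = list(offset = 200, amplitude = 400, center = 1200,
                    width = 500),
    noise_sd = 4,
    spike_rate = 0.2,
    spike_amp = c(20, 60),
    subject_jitter_sd = 0.06,
    replicates_per_subject = 5,
    seed = 1L) {
  ps_background <- match.arg(ps_background)
  stopifnot(all(peak_table$width > 0), noise_sd >= 0,
            spike_rate >= 0, spike_rate <= 1,
            all(spike_amp >= 20), subject_jitter_sd >= 0,
            replicates_per_subject >= 1)
  for (cl in names(class_effects))
    if (length(class_effects[[cl]]) != nrow(peak_table))
      stop("class_effects entries must align with peak_table rows")
  structure(list(axis = axis, peak_table = peak_table,
                 class_effects = class_effects,
                 ps_background = ps_background, ps_level = ps_level,
                 baseline = baseline, noise_sd = noise_sd,
                 spike_rate = spike_rate, spike_amp = spike_amp,
                 subject_jitter_sd = subject_jitter_sd,
                 replicates_per_subject = replicates_per_subject,
                 seed = seed),
            class = "praman_raman_gen_config")
}

lorentzian <- function(x, center, hwhm, amplitude) {
  amplitude * hwhm^2 / ((x - center)^2 + hwhm^2)
}

# noiseless components for one class; jitter multiplies peak amplitudes,
# effect_mult scales the deviation of the class effect from unity
raman_template <- function(class, cfg, jitter = NULL, effect_mult = 1) {
  x <- cfg$axis
  eff <- cfg$class_effects[[class]]
  if (is.null(eff)) stop(sprintf("unknown class '%s'", class))
  eff <- 1 + effect_mult * (eff - 1)
  jitter <- jitter %||% rep(1, nrow(cfg$peak_table))
  amps <- cfg$peak_table$amplitude * eff * jitter
  peaks <- rowSums(mapply(function(c0, w, a) lorentzian(x, c0, w, a),
                          cfg$peak_table$center, cfg$peak_table$width,
                          amps))
  bl <- cfg$baseline
  baseline <- bl$offset +
    bl$amplitude * exp(-(x - bl$center)^2 / (2 * bl$width^2))
  ps <- rep(0, length(x))
  if (cfg$ps_background != "none") {
    ps <- cfg$ps_level * exp(-(x - 900)^2 / (2 * 700^2))
    if (cfg$ps_background == "ppix")
      peaks <- peaks + lorentzian(x, 1550, 15, 0.15 * mean(amps))
  }
  list(peaks = peaks, baseline = baseline + ps,
       template = peaks + baseline + ps)
}

# one noisy realisation drawn from the current RNG stream
gen_one_spectrum <- function(class, cfg, jitter = NULL, effect_mult = 1,
                             meta = list()) {
  parts <- raman_template(class, cfg, jitter, effect_mult)
  n <- length(cfg$axis)
  y <- parts$template + stats::rnorm(n, 0, cfg$noise_sd)
  spike_channels <- integer(0)
  if (stats::runif(1) < cfg$spike_rate) {
    ch <- sample.int(n, 1)
    amp <- stats::runif(1, cfg$spike_amp[1], cfg$spike_amp[2]) *
      max(cfg$noise_sd, 1)
    y[ch] <- y[ch] + amp
    spike_channels <- ch
  }
  meta$tissue_class <- class
  s <- raman_spectrum(cfg$axis, y, meta = meta)
  attr(s, "truth") <- c(parts, list(spike_channels = spike_channels))
  s
}

#' Generate a single synthetic Raman spectrum
#'
#' Draws one spectrum of the requested class. The noiseless components
#' (peaks, baseline, full template) and any injected cosmic-ray spike
#' channels are attached as the `"truth"` attribute, enabling
#' ground-truth oracle checks downstream.
#'
#' @param class Class label; must be a name of `cfg$class_effects`.
#' @param cfg A [raman_gen_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return A spectrum with a `"truth"` attribute.
#' @export
generate_spectrum <- function(class, cfg = raman_gen_config(),
                              seed = cfg$seed) {
  with_seed(seed, gen_one_spectrum(class, cfg))
}

#' Generate a labelled two-class classification dataset
#'
#' Subjects (cells or animals) contribute `cfg$replicates_per_subject`
#' adjacent replicate spectra each; subjects alternate between classes
#' so that index-interleaved (Venetian blinds) folds stay class
#' balanced. Per-subject amplitude jitter is drawn once per subject and
#' shared by its replicates.
#'
#' @param cfg A [raman_gen_config()].
#' @param n_per_class Spectra per class; must be a multiple of
#'   `cfg$replicates_per_subject`.
#' @param classes Character vector of class names (default control and
#'   tumour).
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return A list with `collection`, `labels`, and `truth` (the
#'   noiseless class templates).
#' @export
generate_classification_dataset <- function(cfg = raman_gen_config(),
                                            n_per_class = 60,
                                            classes = c("control", "tumour"),
                                            seed = cfg$seed) {
  reps <- cfg$replicates_per_subject
  if (n_per_class %% reps != 0)
    stop("n_per_class must be a multiple of replicates_per_subject")
  n_subj <- n_per_class / reps
  with_seed(seed, {
    spectra <- list(); labels <- character(0)
    for (i in seq_len(n_subj)) {
      for (cl in classes) {
        jitter <- exp(stats::rnorm(nrow(cfg$peak_table), 0,
                                   cfg$subject_jitter_sd))
        sid <- sprintf("%s_%02d", cl, i)
        for (r in seq_len(reps)) {
          s <- gen_one_spectrum(cl, cfg, jitter,
                                meta = list(subject_id = sid,
                                            replicate = r))
          spectra[[length(spectra) + 1L]] <- s
          labels <- c(labels, cl)
        }
      }
    }
    truth <- lapply(stats::setNames(classes, classes), function(cl)
      raman_template(cl, cfg))
    list(collection = spectrum_collection(spectra, labels = labels),
         labels = labels, truth = truth)
  })
}

#' Longitudinal treatment-study design
#'
#' @param n_subjects Animals per arm.
#' @param arms Character vector of arm names.
#' @param days Numeric vector of measurement days; must include 0.
#' @param response Named list (per arm) of named numeric vectors (per
#'   day, names are day numbers) giving the tumour-effect amplitude
#'   multiplier; day 0 must be 1 in every arm. A PDT-responding arm has
#'   decreasing multipliers (shrinking tumour signature), an untreated
#'   arm non-decreasing ones.
#' @param replicates Raman spectra per flank per animal per day.
#' @return A list of class `praman_study_design`.
#' @export
study_design <- function(n_subjects = 5,
                         arms = c("control", "pdt"),
                         days = c(0, 3, 6),
                         response = list(
                           control = c("0" = 1, "3" = 1.3, "6" = 1.6),
                           pdt = c("0" = 1, "3" = 0.6, "6" = 0.3)),
                         replicates = 8) {
  if (!0 %in% days) stop("days must include day 0")
  for (arm in arms) {
    r <- response[[arm]]
    if (is.null(r) || !all(as.character(days) %in% names(r)))
      stop(sprintf("response for arm '%s' must cover every day", arm))
    if (r[["0"]] != 1) stop("day 0 multiplier must be 1 in every arm")
  }
  structure(list(n_subjects = n_subjects, arms = arms, days = days,
                 response = response, replicates = replicates),
            class = "praman_study_design")
}

#' Generate a longitudinal PDT monitoring study
#'
#' For every arm, day and animal, generates replicate Raman spectra from
#' the tumour flank (tumour template, with the arm's per-day
#' tumour-effect multiplier scaling the deviation from control tissue)
#' and the contralateral control flank. Per-subject amplitude jitter is
#' drawn once per animal and flank and held fixed across days.
#'
#' @param design A [study_design()].
#' @param cfg A [raman_gen_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return Nested list `study[[arm]][[day]]` of lists with `tumour` and
#'   `control` collections (per-spectrum metadata records subject and
#'   day); the design is attached as attribute `"design"`.
#' @export
generate_longitudinal_study <- function(design = study_design(),
                                        cfg = raman_gen_config(),
                                        seed = cfg$seed) {
  with_seed(seed, {
    study <- list()
    for (arm in design$arms) {
      study[[arm]] <- list()
      jit_t <- jit_c <- list()
      for (i in seq_len(design$n_subjects)) {
        jit_t[[i]] <- exp(stats::rnorm(nrow(cfg$peak_table), 0,
                                       cfg$subject_jitter_sd))
        jit_c[[i]] <- exp(stats::rnorm(nrow(cfg$peak_table), 0,
                                       cfg$subject_jitter_sd))
      }
      for (day in design$days) {
        mult <- design$response[[arm]][[as.character(day)]]
        tum <- list(); ctl <- list(); subj <- character(0)
        for (i in seq_len(design$n_subjects)) {
          sid <- sprintf("%s_m%02d", arm, i)
          for (r in seq_len(design$replicates)) {
            tum[[length(tum) + 1L]] <- gen_one_spectrum(
              "tumour", cfg, jit_t[[i]], effect_mult = mult,
              meta = list(subject_id = sid, timepoint_days = day,
                          flank = "tumour"))
            ctl[[length(ctl) + 1L]] <- gen_one_spectrum(
              "control", cfg, jit_c[[i]],
              meta = list(subject_id = sid, timepoint_days = day,
                          flank = "control"))
            subj <- c(subj, sid)
          }
        }
        study[[arm]][[as.character(day)]] <- list(
          tumour = spectrum_collection(tum, labels = subj),
          control = spectrum_collection(ctl, labels = subj))
      }
    }
    attr(study, "design") <- design
    study
  })
}

#' Generate synthetic PPIX fluorescence standards
#'
#' Emits emission spectra (450-750 nm, 1 nm step) consisting of a broad
#' tissue autofluorescence hump, a solvent background, a Gaussian PPIX
#' emission line at 630 nm whose *total area* equals
#' `slope_truth * amount`, and additive Gaussian noise. A matching blank
#' (solvent background plus noise) is included.
#'
#' @param n_levels Number of standards (>= 3).
#' @param slope_truth True integrated signal per ng of PPIX.
#' @param noise_rel Noise SD as a fraction of the autofluorescence hump
#'   amplitude.
#' @param seed RNG seed.
#' @param amounts Optional explicit PPIX amounts (ng); default
#'   `seq(20, 120, length.out = n_levels)`. The default deliberately
#'   excludes a zero-amount standard: near the detection limit the
#'   asymmetric background subtraction responds nonlinearly, and the
#'   blank already anchors the low end of the assay.
#' @param hump_amplitude Autofluorescence hump amplitude (intensity
#'   counts).
#' @return A list with `standards` (collection, per-spectrum metadata
#'   `amount_ng`), `blank` (spectrum) and `amounts`.
#' @export
generate_fluorescence_standards <- function(n_levels = 6, slope_truth = 2,
                                            noise_rel = 0.01, seed = 1L,
                                            amounts = NULL,
                                            hump_amplitude = 50) {
  if (is.null(amounts)) {
    if (n_levels < 3) stop("need at least 3 standard levels")
    amounts <- seq(20, 120, length.out = n_levels)
  }
  if (length(amounts) < 3) stop("need at least 3 standard levels")
  wl <- seq(450, 750, by = 1)
  solvent <- 5 + 10 * exp(-(wl - 470)^2 / (2 * 40^2))
  hump <- hump_amplitude * exp(-(wl - 540)^2 / (2 * 90^2))
  sigma <- 1.5
  with_seed(seed, {
    noise_sd <- noise_rel * hump_amplitude
    spectra <- lapply(seq_along(amounts), function(i) {
      amp <- slope_truth * amounts[i] / (sigma * sqrt(2 * pi))
      y <- solvent + hump + amp * exp(-(wl - 630)^2 / (2 * sigma^2)) +
        stats::rnorm(length(wl), 0, noise_sd)
      fluorescence_spectrum(wl, y,
                            meta = list(amount_ng = amounts[i],
                                        spectrum_id = sprintf("std_%02d", i)))
    })
    blank <- fluorescence_spectrum(
      wl, solvent + stats::rnorm(length(wl), 0, noise_sd),
      meta = list(spectrum_id = "blank"))
    list(standards = spectrum_collection(spectra),
         blank = blank, amounts = amounts)
  })
}
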