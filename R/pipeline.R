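# End-to-end study workflows: diagnose, monitor, quantify. Each writes a
# plain-CSV report plus a JSON manifest so runs are fully reproducible.

write_report_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

start_manifest <- function(workflow, params) {
  list(workflow = workflow,
       tool = list(package = "praman",
                   version = as.character(utils::packageVersion("praman"))),
       params = params, stages = list())
}

add_stage <- function(manifest, name, params = list(), outputs = character(0)) {
  manifest$stages[[length(manifest$stages) + 1L]] <-
    list(name = name, params = params, outputs = as.list(outputs))
  manifest
}

finish_manifest <- function(manifest, out_dir) {
  manifest$wall_time_s <- round(as.numeric(Sys.time()) -
                                  manifest$.t0 %||% as.numeric(Sys.time()), 3)
  manifest$.t0 <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

resolve_collection <- function(x, what) {
  if (is_collection(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop(sprintf("%s file not found: %s", what, x))
    return(read_spectra(x))
  }
  stop(sprintf("%s must be a spectrum collection or a file path", what))
}

#' Run the diagnosis workflow
#'
#' Preprocesses a labelled collection of Raman spectra and classifies it
#' with cross-validated PLS-DA, writing `accuracy.csv`,
#' `confusion.csv`, `scores.csv` and `manifest.json` into `out_dir`.
#' CSV payloads are bitwise reproducible for identical inputs.
#'
#' @param spectra A [spectrum_collection()] or a file path readable by
#'   [read_spectra()].
#' @param labels Class labels, one per spectrum; defaults to the
#'   collection's labels. May also be a path to a single-column text
#'   file.
#' @param out_dir Report directory (created if needed).
#' @param pre_cfg A [preprocess_config()].
#' @param pls_cfg A [plsda_config()].
#' @return The [cross_validate()] result, invisibly; reports on disk.
#' @export
run_diagnosis <- function(spectra, labels = NULL, out_dir,
                          pre_cfg = preprocess_config(),
                          pls_cfg = plsda_config()) {
  coll <- resolve_collection(spectra, "spectra")
  if (is.character(labels) && length(labels) == 1 && file.exists(labels))
    labels <- readLines(labels)
  labels <- labels %||% coll$labels
  if (is.null(labels))
    stop("labels are required: pass a vector, a file, or a labelled collection")
  if (length(labels) != n_spectra(coll))
    stop("one label per spectrum required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- start_manifest("diagnosis",
                             list(preprocess = unclass(pre_cfg),
                                  plsda = unclass(pls_cfg)[c("n_lv", "cv_splits")]))
  manifest$.t0 <- as.numeric(Sys.time())

  proc <- preprocess_spectra(coll, pre_cfg)
  manifest <- add_stage(manifest, "preprocess",
                        list(n_spectra = n_spectra(proc)))
  cv <- cross_validate(as.matrix(proc), labels, pls_cfg)
  manifest <- add_stage(manifest, "cross_validate",
                        list(accuracy = cv$accuracy))

  write_report_csv(data.frame(n = length(labels), n_lv = pls_cfg$n_lv,
                              splits = pls_cfg$cv_splits,
                              accuracy = sprintf("%.6f", cv$accuracy)),
                   file.path(out_dir, "accuracy.csv"))
  conf <- as.data.frame.matrix(cv$confusion)
  conf <- cbind(true_class = rownames(conf), conf)
  write_report_csv(conf, file.path(out_dir, "confusion.csv"))
  sc <- data.frame(sample = seq_along(labels), label = labels,
                   predicted = cv$predicted, fold = cv$fold_of,
                   apply(cv$scores, 2, function(v) sprintf("%.8e", v)))
  write_report_csv(sc, file.path(out_dir, "scores.csv"))
  manifest <- add_stage(manifest, "report", outputs = c(
    "accuracy.csv", "confusion.csv", "scores.csv"))
  finish_manifest(manifest, out_dir)
  invisible(cv)
}

# per-subject difference spectra for one arm/day entry
subject_differences <- function(entry) {
  subj <- unique(entry$tumour$labels)
  stats::setNames(lapply(subj, function(id) {
    ta <- spectrum_collection(entry$tumour$spectra[entry$tumour$labels == id])
    ca <- spectrum_collection(entry$control$spectra[entry$control$labels == id])
    difference_spectrum(ta, ca)
  }), subj)
}

#' Run the post-treatment monitoring workflow
#'
#' For every arm and day of a longitudinal study: preprocesses tumour
#' and control-flank spectra, forms tumour-minus-control difference
#' spectra (arm-level and per animal), extracts the 1440 cm^-1 window
#' statistic normalised to day 0, Welch-tests the arms against each
#' other at each post-treatment day on the per-animal values, and, when
#' per-animal size signals are supplied, computes baseline-normalised
#' growth with 1.5 x IQR outlier exclusion (exclusions are logged, not
#' silently dropped). Writes `timecourse.csv`, `subject_values.csv`,
#' `welch.csv`, optionally `growth.csv`, and `manifest.json`.
#'
#' @param study Nested list `study[[arm]][[day]]` of lists with `tumour`
#'   and `control` collections, as produced by
#'   [generate_longitudinal_study()]; day names must include `"0"`.
#' @param out_dir Report directory.
#' @param pre_cfg A [preprocess_config()].
#' @param center,half_width Monitoring peak window in cm^-1.
#' @param sizes Optional data frame with columns `arm`, `subject_id`,
#'   `day`, `signal` (e.g. BLI total flux) for normalised-growth
#'   analysis.
#' @return A list with `timecourse`, `subject_values`, `welch` and
#'   (optionally) `growth` data frames, invisibly; reports on disk.
#' @export
run_monitoring <- function(study, out_dir, pre_cfg = preprocess_config(),
                           center = 1440, half_width = 10, sizes = NULL) {
  arms <- names(study)
  if (length(arms) < 1) stop("study has no arms")
  for (arm in arms)
    if (!"0" %in% names(study[[arm]]))
      stop(sprintf("arm '%s' is missing day 0", arm))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- start_manifest("monitoring",
                             list(center = center, half_width = half_width,
                                  preprocess = unclass(pre_cfg)))
  manifest$.t0 <- as.numeric(Sys.time())

  proc <- lapply(study, function(arm_entry)
    lapply(arm_entry, function(day_entry)
      list(tumour = preprocess_spectra(day_entry$tumour, pre_cfg),
           control = preprocess_spectra(day_entry$control, pre_cfg))))
  manifest <- add_stage(manifest, "preprocess")

  subject_rows <- list()
  timecourse_rows <- list()
  for (arm in arms) {
    days <- names(proc[[arm]])
    arm_diffs <- lapply(proc[[arm]], function(e)
      difference_spectrum(e$tumour, e$control))
    tc <- monitoring_timecourse(arm_diffs, center, half_width)
    for (d in days)
      timecourse_rows[[length(timecourse_rows) + 1L]] <-
        data.frame(arm = arm, day = as.numeric(d),
                   statistic = sprintf("%.8e", tc[[d]]))
    per_subj <- lapply(proc[[arm]], subject_differences)
    subj_ids <- names(per_subj[["0"]])
    for (id in subj_ids) {
      base <- peak_extremum(per_subj[["0"]][[id]], center, half_width)
      if (base == 0) stop("day-0 peak is zero for a subject")
      for (d in days) {
        v <- peak_extremum(per_subj[[d]][[id]], center, half_width) / base
        subject_rows[[length(subject_rows) + 1L]] <-
          data.frame(arm = arm, subject_id = id, day = as.numeric(d),
                     value = v)
      }
    }
  }
  subject_values <- do.call(rbind, subject_rows)
  timecourse <- do.call(rbind, timecourse_rows)
  manifest <- add_stage(manifest, "difference_timecourse")

  welch_rows <- list()
  if (length(arms) >= 2) {
    pairs <- utils::combn(arms, 2, simplify = FALSE)
    for (pr in pairs) {
      shared_days <- intersect(names(proc[[pr[1]]]), names(proc[[pr[2]]]))
      for (d in setdiff(shared_days, "0")) {
        va <- subject_values$value[subject_values$arm == pr[1] &
                                     subject_values$day == as.numeric(d)]
        vb <- subject_values$value[subject_values$arm == pr[2] &
                                     subject_values$day == as.numeric(d)]
        wt <- welch_t(va, vb)
        welch_rows[[length(welch_rows) + 1L]] <-
          data.frame(arm_a = pr[1], arm_b = pr[2], day = as.numeric(d),
                     t = sprintf("%.6f", wt$t), df = sprintf("%.4f", wt$df),
                     p = sprintf("%.6e", wt$p))
      }
    }
  }
  welch <- if (length(welch_rows)) do.call(rbind, welch_rows) else
    data.frame(arm_a = character(), arm_b = character(), day = numeric(),
               t = character(), df = character(), p = character())
  manifest <- add_stage(manifest, "welch_tests")

  growth <- NULL
  if (!is.null(sizes)) {
    need <- c("arm", "subject_id", "day", "signal")
    if (!all(need %in% names(sizes)))
      stop("sizes needs columns arm, subject_id, day, signal")
    rows <- list()
    for (key in unique(paste(sizes$arm, sizes$subject_id))) {
      sub <- sizes[paste(sizes$arm, sizes$subject_id) == key, ]
      g <- normalized_growth(stats::setNames(sub$signal,
                                             as.character(sub$day)), 0)
      for (j in seq_len(nrow(sub)))
        rows[[length(rows) + 1L]] <- data.frame(
          arm = sub$arm[j], subject_id = sub$subject_id[j],
          day = sub$day[j], growth = g[[as.character(sub$day[j])]])
    }
    growth <- do.call(rbind, rows)
    growth$excluded <- FALSE
    for (d in setdiff(unique(growth$day), 0)) {
      idx <- which(growth$day == d)
      if (length(idx) >= 4)
        growth$excluded[idx] <- iqr_outliers(growth$growth[idx])
    }
    manifest <- add_stage(manifest, "normalized_growth",
                          list(n_excluded = sum(growth$excluded)))
    gout <- growth
    gout$growth <- sprintf("%.8e", gout$growth)
    write_report_csv(gout, file.path(out_dir, "growth.csv"))
  }

  write_report_csv(timecourse, file.path(out_dir, "timecourse.csv"))
  sv <- subject_values
  sv$value <- sprintf("%.8e", sv$value)
  write_report_csv(sv, file.path(out_dir, "subject_values.csv"))
  write_report_csv(welch, file.path(out_dir, "welch.csv"))
  manifest <- add_stage(manifest, "report", outputs = c(
    "timecourse.csv", "subject_values.csv", "welch.csv",
    if (!is.null(growth)) "growth.csv"))
  finish_manifest(manifest, out_dir)
  invisible(list(timecourse = timecourse, subject_values = subject_values,
                 welch = welch, growth = growth))
}

#' Run the PPIX quantification workflow
#'
#' Processes standard and sample fluorescence spectra against a blank,
#' fits the standard curve, and back-calculates per-tumour PPIX
#' concentrations (ng per g tissue). Writes `standard_curve.csv`,
#' `quantities.csv` and `manifest.json`.
#'
#' @param samples Collection (or file path) of sample emission spectra.
#' @param blank Blank (solvent-only) spectrum, or a single-spectrum
#'   collection/file.
#' @param standards Collection (or file path) of standard spectra whose
#'   per-spectrum metadata carries `amount_ng`, or a list with elements
#'   `collection` and `amounts`.
#' @param masses_g Numeric vector of tumour masses (g), one per sample.
#' @param out_dir Report directory.
#' @param cfg A [fluor_quant_config()].
#' @param dilution_factor Aliquot dilution factor (default 21).
#' @return A list with `curve` and the `quantities` data frame,
#'   invisibly; reports on disk.
#' @export
run_quantification <- function(samples, blank, standards, masses_g,
                               out_dir, cfg = fluor_quant_config(),
                               dilution_factor = 21) {
  samples <- resolve_collection(samples, "samples")
  if (is.character(blank) || is_collection(blank)) {
    bc <- resolve_collection(blank, "blank")
    if (n_spectra(bc) != 1) stop("blank must contain exactly one spectrum")
    blank <- bc$spectra[[1]]
  }
  if (is.list(standards) && !is_collection(standards) &&
      !is.null(standards$collection)) {
    std_coll <- standards$collection
    amounts <- standards$amounts
  } else {
    std_coll <- resolve_collection(standards, "standards")
    amounts <- vapply(std_coll$spectra, function(s)
      as.numeric(s$meta$amount_ng %||% NA_real_), numeric(1))
  }
  if (anyNA(amounts)) stop("every standard needs an amount_ng metadata entry")
  if (length(unique(amounts)) < 3) stop("need at least 3 distinct standards")
  if (length(masses_g) != n_spectra(samples))
    stop("one tumour mass per sample spectrum required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- start_manifest("quantification",
                             list(config = unclass(cfg),
                                  dilution_factor = dilution_factor))
  manifest$.t0 <- as.numeric(Sys.time())

  std_sig <- vapply(std_coll$spectra, function(s)
    integrate_signal(process_fluorescence(s, blank, cfg),
                     cfg$signal_band_nm), numeric(1))
  curve <- fit_standard_curve(amounts, std_sig)
  manifest <- add_stage(manifest, "standard_curve",
                        list(slope = curve$slope,
                             intercept = curve$intercept,
                             r_squared = curve$r_squared))

  rows <- lapply(seq_len(n_spectra(samples)), function(i) {
    s <- samples$spectra[[i]]
    sig <- integrate_signal(process_fluorescence(s, blank, cfg),
                            cfg$signal_band_nm)
    q <- quantify_ppix(sig, curve, dilution_factor, masses_g[i])
    data.frame(sample = as.character(s$meta$spectrum_id %||% paste0("s", i)),
               signal = sprintf("%.8e", sig),
               amount_ng = sprintf("%.8e", q$amount_ng),
               mass_g = masses_g[i],
               ng_per_g = sprintf("%.8e", q$ng_per_g),
               floored = q$floored)
  })
  quantities <- do.call(rbind, rows)
  manifest <- add_stage(manifest, "quantify")

  write_report_csv(data.frame(slope = sprintf("%.8e", curve$slope),
                              intercept = sprintf("%.8e", curve$intercept),
                              r_squared = sprintf("%.8f", curve$r_squared),
                              n_standards = nrow(curve$points)),
                   file.path(out_dir, "standard_curve.csv"))
  write_report_csv(quantities, file.path(out_dir, "quantities.csv"))
  manifest <- add_stage(manifest, "report",
                        outputs = c("standard_curve.csv", "quantities.csv"))
  finish_manifest(manifest, out_dir)
  invisible(list(curve = curve, quantities = quantities))
}
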