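#' Construct a single spectrum
#'
#' A spectrum is the atomic data unit of the package: a strictly increasing
#' axis (Raman shift in cm^-1 or emission wavelength in nm), an intensity
#' vector of the same length, and free-form string metadata (subject id,
#' tissue class, photosensitiser, timepoint, acquisition settings, ...).
#'
#' @param axis Numeric vector, strictly increasing, length >= 8.
#' @param intensity Numeric vector of the same length; all values finite.
#' @param axis_kind `"raman_shift"` (cm^-1) or `"wavelength"` (nm).
#' @param meta Named list of scalar metadata values (coerced to character
#'   on file output).
#' @return An object of class `praman_spectrum` with fields `axis`,
#'   `intensity`, `axis_kind` and `meta`.
#' @seealso [raman_spectrum()], [fluorescence_spectrum()],
#'   [spectrum_collection()]
#' @export
new_spectrum <- function(axis, intensity,
                         axis_kind = c("raman_shift", "wavelength"),
                         meta = list()) {
  axis_kind <- match.arg(axis_kind)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("axis and intensity must have the same length")
  if (length(axis) < 8)
    stop("a spectrum needs at least 8 channels")
  if (any(!is.finite(axis)))
    stop("axis contains non-finite values")
  if (any(!is.finite(intensity)))
    stop("intensity contains non-finite values")
  if (any(diff(axis) <= 0))
    stop("axis must be strictly increasing")
  if (!is.list(meta)) stop("meta must be a list")
  structure(list(axis = axis, intensity = intensity,
                 axis_kind = axis_kind, meta = meta),
            class = "praman_spectrum")
}

#' @rdname new_spectrum
#' @param wavenumber Raman shift axis in cm^-1.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  new_spectrum(wavenumber, intensity, "raman_shift", meta)
}

#' @rdname new_spectrum
#' @param wavelength Emission wavelength axis in nm.
#' @export
fluorescence_spectrum <- function(wavelength, intensity, meta = list()) {
  new_spectrum(wavelength, intensity, "wavelength", meta)
}

is_spectrum <- function(x) inherits(x, "praman_spectrum")

# clone a spectrum with new data but the same kind/metadata
respectrum <- function(s, axis = s$axis, intensity = s$intensity,
                       meta = s$meta) {
  new_spectrum(axis, intensity, s$axis_kind, meta)
}

#' @export
print.praman_spectrum <- function(x, ...) {
  unit <- if (x$axis_kind == "raman_shift") "cm^-1" else "nm"
  cat(sprintf("<praman_spectrum> %d channels, %s %.6g..%.6g %s\n",
              length(x$axis), x$axis_kind, min(x$axis), max(x$axis), unit))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Construct an ordered collection of spectra
#'
#' A collection is an ordered list of spectra, usually replicate
#' acquisitions sharing one axis grid, with optional per-spectrum class
#' labels (e.g. `"tumour"` / `"control"`).
#'
#' @param spectra List of [new_spectrum()] objects (may be empty).
#' @param labels Optional character vector of class labels, one per
#'   spectrum.
#' @return An object of class `praman_collection`.
#' @export
spectrum_collection <- function(spectra, labels = NULL) {
  if (!is.list(spectra)) stop("spectra must be a list")
  ok <- vapply(spectra, is_spectrum, logical(1))
  if (length(ok) && !all(ok))
    stop("all elements must be praman_spectrum objects")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(spectra))
      stop("labels length must equal the number of spectra")
  }
  structure(list(spectra = spectra, labels = labels),
            class = "praman_collection")
}

is_collection <- function(x) inherits(x, "praman_collection")

#' Number of spectra in a collection
#' @param coll A [spectrum_collection()].
#' @return Integer count.
#' @export
n_spectra <- function(coll) {
  stopifnot(is_collection(coll))
  length(coll$spectra)
}

#' Shared axis of a collection
#'
#' @param coll A [spectrum_collection()].
#' @return The common axis vector if every member spectrum has an
#'   elementwise-identical axis, otherwise `NULL`.
#' @export
shared_axis <- function(coll) {
  stopifnot(is_collection(coll))
  if (n_spectra(coll) == 0) return(NULL)
  a <- coll$spectra[[1]]$axis
  for (s in coll$spectra[-1]) {
    if (length(s$axis) != length(a) || any(s$axis != a)) return(NULL)
  }
  a
}

require_shared_axis <- function(coll, what = "operation") {
  a <- shared_axis(coll)
  if (is.null(a))
    stop(sprintf("%s requires all spectra to share one axis", what))
  a
}

#' Intensity matrix of a collection
#'
#' @param x A [spectrum_collection()] whose members share an axis.
#' @param ... Unused.
#' @return A numeric matrix, one row per spectrum, one column per channel;
#'   column names carry the axis values.
#' @export
as.matrix.praman_collection <- function(x, ...) {
  a <- require_shared_axis(x, "as.matrix")
  m <- do.call(rbind, lapply(x$spectra, function(s) s$intensity))
  colnames(m) <- format(a, trim = TRUE)
  rownames(m) <- vapply(seq_along(x$spectra), function(i)
    as.character(x$spectra[[i]]$meta$spectrum_id %||% paste0("s", i)),
    character(1))
  m
}

# apply a per-spectrum transformation, preserving labels
collection_map <- function(coll, f, ...) {
  spectrum_collection(lapply(coll$spectra, f, ...), labels = coll$labels)
}

#' @export
print.praman_collection <- function(x, ...) {
  cat(sprintf("<praman_collection> %d spectra", n_spectra(x)))
  a <- shared_axis(x)
  if (!is.null(a)) cat(sprintf(", shared axis of %d channels", length(a)))
  cat("\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Channelwise mean spectrum of a collection
#' @param coll A [spectrum_collection()] with a shared axis and >= 1
#'   spectrum.
#' @return A spectrum holding the per-channel mean intensity.
#' @export
mean_spectrum <- function(coll) {
  a <- require_shared_axis(coll, "mean_spectrum")
  if (n_spectra(coll) < 1) stop("empty collection")
  m <- as.matrix(coll)
  new_spectrum(a, colMeans(m), coll$spectra[[1]]$axis_kind,
               meta = list(n_spectra = n_spectra(coll)))
}
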