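#' Read spectra from a delimited text file
#'
#' Two plain-text layouts common in spectroscopy exports are supported:
#' * `long_csv`: columns `spectrum_id`, `axis`, `intensity`; one row per
#'   channel per spectrum.
#' * `wide_csv`: first column the axis, then one intensity column per
#'   spectrum (column headers become spectrum ids; all spectra share the
#'   axis).
#'
#' The field separator (comma or tab) is auto-detected from the header
#' line. If a metadata sidecar (`<stem>.meta.tsv`, written by
#' [write_spectra()]) sits next to the file it is loaded: it stores the
#' axis kind, the class labels and all per-spectrum metadata.
#'
#' @param path Path to the data file.
#' @param format `"wide_csv"`, `"long_csv"` or `"auto"` (detect from the
#'   header).
#' @return A [spectrum_collection()] in file order.
#' @export
read_spectra <- function(path, format = c("auto", "wide_csv", "long_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      fill = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("parse error in %s: %s",
                                     path, conditionMessage(e)),
                             call. = FALSE))
  if (format == "auto") {
    format <- if (identical(tolower(names(df)[1]), "spectrum_id"))
      "long_csv" else "wide_csv"
  }
  side <- read_meta_sidecar(meta_sidecar_path(path))
  axis_kind <- side$axis_kind %||% "raman_shift"

  if (format == "long_csv") {
    need <- c("spectrum_id", "axis", "intensity")
    if (!all(need %in% names(df)))
      stop("long format requires columns spectrum_id, axis, intensity")
    ids <- unique(as.character(df$spectrum_id))
    spectra <- lapply(ids, function(id) {
      sub <- df[as.character(df$spectrum_id) == id, , drop = FALSE]
      build_spectrum_checked(as.numeric(sub$axis), as.numeric(sub$intensity),
                             axis_kind, id, side$meta[[id]])
    })
  } else {
    if (ncol(df) < 2) stop("wide format requires an axis column plus at least one spectrum column")
    axis <- as.numeric(df[[1]])
    ids <- names(df)[-1]
    spectra <- lapply(ids, function(id) {
      build_spectrum_checked(axis, as.numeric(df[[id]]), axis_kind, id,
                             side$meta[[id]])
    })
  }
  labels <- if (!is.null(side$labels)) unname(side$labels[ids]) else NULL
  spectrum_collection(spectra, labels = labels)
}

build_spectrum_checked <- function(axis, intensity, axis_kind, id, meta) {
  if (any(!is.finite(axis)) || any(diff(axis) <= 0))
    stop(sprintf("spectrum '%s': axis is not strictly increasing", id),
         call. = FALSE)
  meta <- meta %||% list()
  meta$spectrum_id <- id
  new_spectrum(axis, intensity, axis_kind, meta)
}

#' Write a collection of spectra to a delimited text file
#'
#' Values are written with 17 significant digits so that a
#' read-back reproduces the collection exactly. A tab-separated metadata
#' sidecar `<stem>.meta.tsv` is always written alongside, holding the
#' axis kind, the class labels, and every per-spectrum metadata entry as
#' `(spectrum_id, key, value)` rows.
#'
#' @param coll A [spectrum_collection()].
#' @param path Output file path.
#' @param format `"wide_csv"` (requires a shared axis) or `"long_csv"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(coll, path, format = c("wide_csv", "long_csv")) {
  format <- match.arg(format)
  stopifnot(is_collection(coll))
  ids <- spectrum_ids(coll)
  num <- function(x) sprintf("%.17g", x)

  if (format == "wide_csv") {
    a <- shared_axis(coll)
    if (n_spectra(coll) > 0 && is.null(a))
      stop("spectra have heterogeneous axes; use format = 'long_csv'")
    if (n_spectra(coll) == 0) {
      writeLines("axis", path)
    } else {
      m <- cbind(axis = num(a),
                 do.call(cbind, lapply(coll$spectra,
                                       function(s) num(s$intensity))))
      colnames(m) <- c("axis", ids)
      utils::write.table(m, path, sep = ",", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    }
  } else {
    rows <- lapply(seq_len(n_spectra(coll)), function(i) {
      s <- coll$spectra[[i]]
      data.frame(spectrum_id = ids[i], axis = num(s$axis),
                 intensity = num(s$intensity), stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(spectrum_id = character(), axis = character(),
                 intensity = character())
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  write_meta_sidecar(coll, ids, meta_sidecar_path(path))
  invisible(path)
}

spectrum_ids <- function(coll) {
  ids <- vapply(seq_len(n_spectra(coll)), function(i)
    as.character(coll$spectra[[i]]$meta$spectrum_id %||% paste0("s", i)),
    character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  ids
}

meta_sidecar_path <- function(path) {
  paste0(sub("\\.[^./\\\\]*$", "", path), ".meta.tsv")
}

write_meta_sidecar <- function(coll, ids, side_path) {
  rows <- list(c(".collection", "axis_kind",
                 if (n_spectra(coll)) coll$spectra[[1]]$axis_kind
                 else "raman_shift"))
  if (!is.null(coll$labels)) {
    for (i in seq_along(ids))
      rows[[length(rows) + 1L]] <- c(ids[i], ".label", coll$labels[i])
  }
  for (i in seq_len(n_spectra(coll))) {
    meta <- coll$spectra[[i]]$meta
    for (k in setdiff(names(meta), "spectrum_id"))
      rows[[length(rows) + 1L]] <- c(ids[i], k, as.character(meta[[k]]))
  }
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), side_path)
}

read_meta_sidecar <- function(side_path) {
  out <- list(axis_kind = NULL, labels = NULL, meta = list())
  if (!file.exists(side_path)) return(out)
  lines <- readLines(side_path)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) next
    id <- f[1]; key <- f[2]; val <- paste(f[-(1:2)], collapse = "\t")
    if (id == ".collection" && key == "axis_kind") {
      out$axis_kind <- val
    } else if (key == ".label") {
      out$labels[id] <- val
    } else {
      out$meta[[id]] <- c(out$meta[[id]], stats::setNames(list(val), key))
    }
  }
  out
}
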