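# Long-form CSV dialect shared by point spectra and maps: one row per
# (spectrum, wavenumber); UTF-8, comma separator, "." decimal. Standard
# columns below; any extra scalar metadata travels as additional columns.
.std_cols <- c("sample_id", "genotype", "treatment", "replicate", "plant",
               "day_or_min", "tissue", "axis", "x_um", "y_um", "z_um",
               "wavenumber_cm1", "intensity")

spectrum_rows <- function(s, sample_id) {
  m <- s$meta
  n <- length(s$wavenumbers)
  df <- data.frame(
    sample_id = m$sample_id %||% sample_id,
    genotype = m$genotype %||% NA_character_,
    treatment = m$treatment %||% NA_character_,
    replicate = m$replicate %||% NA,
    plant = m$plant %||% NA,
    day_or_min = m$day %||% m$minute %||% NA,
    tissue = m$tissue %||% NA_character_,
    axis = NA_character_, x_um = NA_real_, y_um = NA_real_, z_um = NA_real_,
    wavenumber_cm1 = s$wavenumbers, intensity = s$intensities,
    stringsAsFactors = FALSE)
  extra <- m[setdiff(names(m), c("sample_id", "genotype", "treatment", "replicate",
                                 "plant", "day", "minute", "tissue"))]
  extra <- extra[vapply(extra, function(v) is.atomic(v) && length(v) == 1L, TRUE)]
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

#' Write spectra, a study or a map to long-form CSV
#'
#' One row per (spectrum, wavenumber). Numbers are serialized at full double
#' precision, so [read_spectra()] round-trips losslessly. An empty list yields
#' a header-only file.
#'
#' @param x A `raman_spectrum`, a list of them, a `raman_study` (format
#'   `"csv"`) or a single `raman_map` (format `"map_csv"`).
#' @param path Output file.
#' @param format `"csv"` for point spectra/studies, `"map_csv"` for maps;
#'   inferred from `x` by default.
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(x, path, format = NULL) {
  if (inherits(x, "raman_map")) {
    format <- format %||% "map_csv"
    if (format != "map_csv") stop_validation("maps are written with format 'map_csv'")
    m <- x$meta
    second <- if (x$axis == "XY") "y_um" else "z_um"
    rows <- lapply(seq_len(ncol(x$intensities)), function(i) {
      df <- spectrum_rows(raman_spectrum(x$wavenumbers, x$intensities[, i], m),
                          sprintf("point%03d", i))
      df$axis <- x$axis
      df$x_um <- x$positions$x_um[i]
      df[[second]] <- x$positions[[second]][i]
      df$day_or_min <- m$timepoint_min %||% NA_real_
      df
    })
    df <- do.call(rbind, rows)
    df$timepoint_min <- NULL
  } else {
    format <- format %||% "csv"
    if (format != "csv") stop_validation("point spectra are written with format 'csv'")
    if (inherits(x, "raman_study"))
      x <- lapply(seq_len(ncol(x$intensities)), get_spectrum, x = x)
    if (inherits(x, "raman_spectrum")) x <- list(x)
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "raman_spectrum")))
    df <- if (length(x))
      do.call(rbind, lapply(seq_along(x), function(i)
        spectrum_rows(x[[i]], sprintf("spectrum%03d", i))))
    else
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(.std_cols))), .std_cols)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

row_meta <- function(df_first, extra_cols) {
  meta <- list()
  for (nm in c("genotype", "treatment", "tissue")) {
    v <- df_first[[nm]]
    if (!is.null(v) && !is.na(v) && nzchar(v)) meta[[nm]] <- v
  }
  for (nm in c("replicate", "plant")) {
    v <- df_first[[nm]]
    if (!is.null(v) && !is.na(v)) meta[[nm]] <- v
  }
  for (nm in extra_cols) {
    v <- df_first[[nm]]
    if (!is.null(v) && !(is.character(v) && !nzchar(v))) meta[[nm]] <- v
  }
  meta
}

#' Read spectra or a map from long-form CSV
#'
#' @param path CSV file written in the package's long-form dialect (see
#'   [write_spectra()]).
#' @param format `"csv"` (point spectra: returns a list of `raman_spectrum`)
#'   or `"map_csv"` (returns one `raman_map`).
#' @return List of `raman_spectrum` objects, or a `raman_map`.
#' @export
read_spectra <- function(path, format = c("csv", "map_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "wavenumber_cm1", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("format error: missing columns ", paste(miss, collapse = ", "))
  extra_cols <- setdiff(names(df), .std_cols)
  if (format == "csv") {
    if (!nrow(df)) return(list())
    groups <- split(seq_len(nrow(df)), factor(df$sample_id, levels = unique(df$sample_id)))
    lapply(groups, function(idx) {
      wn <- df$wavenumber_cm1[idx]
      bad <- which(diff(wn) <= 0)
      if (length(bad))
        stop_validation("format error: non-monotonic wavenumber at file row ",
                        idx[bad[1L] + 1L], " (sample ", df$sample_id[idx[1L]], ")")
      meta <- row_meta(df[idx[1L], ], extra_cols)
      meta$sample_id <- df$sample_id[idx[1L]]
      d <- df$day_or_min[idx[1L]]
      if (!is.null(d) && !is.na(d)) meta$day <- d
      raman_spectrum(wn, df$intensity[idx], meta)
    })
  } else {
    if (!nrow(df)) stop_validation("format error: empty map file")
    axis <- unique(df$axis[!is.na(df$axis) & nzchar(df$axis)])
    if (length(axis) != 1L || !axis %in% c("XY", "XZ"))
      stop_validation("format error: map file must declare one axis (XY or XZ)")
    second <- if (axis == "XY") "y_um" else "z_um"
    groups <- split(seq_len(nrow(df)), factor(df$sample_id, levels = unique(df$sample_id)))
    wn <- df$wavenumber_cm1[groups[[1L]]]
    bad <- which(diff(wn) <= 0)
    if (length(bad))
      stop_validation("format error: non-monotonic wavenumber at file row ", bad[1L] + 1L)
    Y <- matrix(0, length(wn), length(groups))
    pos <- data.frame(x_um = numeric(length(groups)))
    pos[[second]] <- numeric(length(groups))
    for (i in seq_along(groups)) {
      idx <- groups[[i]]
      if (!isTRUE(all.equal(df$wavenumber_cm1[idx], wn, tolerance = 0)))
        stop_validation("format error: all map points must share one wavenumber grid")
      Y[, i] <- df$intensity[idx]
      pos$x_um[i] <- df$x_um[idx[1L]]
      pos[[second]][i] <- df[[second]][idx[1L]]
    }
    meta <- row_meta(df[1L, ], extra_cols)
    d <- df$day_or_min[1L]
    meta$timepoint_min <- if (is.null(d) || is.na(d)) NA_real_ else d
    raman_map(wn, Y, pos, axis = axis, meta = meta)
  }
}

#' Assemble a study from a list of spectra
#'
#' @param spectra List of `raman_spectrum` objects on one grid whose metadata
#'   carry `genotype`, `treatment`, `replicate`, `plant` and `day`.
#' @return A `raman_study`.
#' @export
as_study <- function(spectra) {
  if (!length(spectra)) stop_validation("cannot build a study from no spectra")
  wn <- spectra[[1L]]$wavenumbers
  Y <- vapply(spectra, function(s) {
    if (!isTRUE(all.equal(s$wavenumbers, wn, tolerance = 0)))
      stop_validation("all spectra must share one wavenumber grid")
    s$intensities
  }, numeric(length(wn)))
  meta <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    m <- spectra[[i]]$meta
    data.frame(sample_id = m$sample_id %||% sprintf("spectrum%03d", i),
               genotype = m$genotype %||% NA_character_,
               treatment = m$treatment %||% NA_character_,
               replicate = m$replicate %||% NA,
               plant = m$plant %||% NA,
               day = m$day %||% NA,
               tissue = m$tissue %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  raman_study(wn, Y, meta)
}

#' Write a study manifest (JSON)
#'
#' A manifest lists the data files of a study plus its design; paths are
#' stored relative to the manifest's directory.
#'
#' @param manifest List with elements `files` (data frame or list with `path`
#'   and `format` per file) and optionally `design` and `description`.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  if (is.null(manifest$files)) stop_validation("manifest must list files")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a study manifest (JSON)
#'
#' @param path Manifest file.
#' @param resolve If `TRUE` (default), file paths are resolved relative to the
#'   manifest's directory.
#' @return The manifest list; `files` as a data frame.
#' @export
read_manifest <- function(path, resolve = TRUE) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$files)) stop_validation("manifest must list files")
  m$files <- as.data.frame(m$files, stringsAsFactors = FALSE)
  if (resolve)
    m$files$path <- file.path(dirname(normalizePath(path, mustWork = FALSE)), m$files$path)
  m
}
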