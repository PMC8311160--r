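#' Construct a single Raman spectrum
#'
#' A spectrum is one wavenumber-indexed intensity trace plus sample metadata.
#' Wavenumbers must be strictly increasing and intensities finite.
#'
#' @param wavenumbers Numeric vector of Raman shifts (cm^-1), strictly increasing.
#' @param intensities Numeric vector of detector counts (arbitrary units), same
#'   length as `wavenumbers`.
#' @param meta Named list of sample metadata. Recognised fields: `sample_id`,
#'   `genotype`, `treatment` (`"control"`, `"drought"` or `"mannitol:<mM>"`),
#'   `day` (integer >= 0) or `minute` (map series), `tissue` (`"green"` or
#'   `"white"`), `replicate`, `plant`, `leaf`. Extra fields are carried along.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumbers`, `intensities`, `meta`.
#' @examples
#' s <- raman_spectrum(1000:1002, c(1, 2, 3))
#' s$intensities
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop_validation("wavenumbers and intensities differ in length (",
                    length(wavenumbers), " vs ", length(intensities), ")")
  if (length(wavenumbers) < 2L)
    stop_validation("a spectrum needs at least 2 points")
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop_validation("wavenumbers must be finite")
  d <- diff(wavenumbers)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop_validation("wavenumbers must be strictly increasing; first violation at point ", bad)
  }
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop_validation("intensities must be finite")
  check_meta(meta)
  structure(list(wavenumbers = wavenumbers, intensities = intensities, meta = meta),
            class = "raman_spectrum")
}

valid_treatment <- function(x) {
  grepl("^(control|drought|mannitol:[0-9]+(\\.[0-9]+)?)$", x)
}

check_meta <- function(meta) {
  if (!is.list(meta)) stop_validation("meta must be a list")
  tr <- meta$treatment
  if (!is.null(tr) && !all(valid_treatment(tr)))
    stop_validation("unknown treatment label: ", paste(tr[!valid_treatment(tr)], collapse = ", "),
                    " (expected control, drought or mannitol:<mM>)")
  if (!is.null(meta$day) && any(meta$day < 0 | meta$day != floor(meta$day)))
    stop_validation("day must be an integer >= 0")
  ti <- meta$tissue
  if (!is.null(ti) && !all(ti %in% c("green", "white")))
    stop_validation("tissue must be 'green' or 'white'")
  invisible(TRUE)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm-1\n",
              length(x$wavenumbers), rng[1], rng[2]))
  if (length(x$meta)) {
    flat <- vapply(x$meta, function(v) paste(format(v), collapse = ","), "")
    cat("  ", paste(names(flat), flat, sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Construct a spatial spectrum map
#'
#' A map is a set of spectra sampled on micron coordinates of a leaf disk,
#' either in the focal plane (XY) or as a depth section (XZ). All member
#' spectra share one wavenumber grid.
#'
#' @param wavenumbers Shared wavenumber grid (cm^-1), strictly increasing.
#' @param intensities Numeric matrix, `length(wavenumbers)` rows, one column
#'   per sampled point.
#' @param positions Data frame of micron coordinates with columns `x_um` and
#'   `y_um` (XY maps) or `z_um` (XZ maps); one row per point, rows unique.
#' @param axis `"XY"` or `"XZ"`.
#' @param meta Named list of acquisition metadata (e.g. `spot_um`, `power_mw`,
#'   `integration_s`, `timepoint_min` (`NA` for the pre-treatment map),
#'   `mannitol_mm`, `tissue`, `treatment`, `replicate`).
#' @return An object of class `raman_map`.
#' @export
raman_map <- function(wavenumbers, intensities, positions, axis = c("XY", "XZ"),
                      meta = list()) {
  axis <- match.arg(axis)
  wavenumbers <- as.numeric(wavenumbers)
  if (any(diff(wavenumbers) <= 0))
    stop_validation("wavenumbers must be strictly increasing")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(wavenumbers))
    stop_validation("intensity matrix must have one row per wavenumber")
  if (ncol(intensities) < 1L) stop_validation("a map needs at least one point")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop_validation("intensities must be finite")
  positions <- as.data.frame(positions)
  second <- if (axis == "XY") "y_um" else "z_um"
  if (!all(c("x_um", second) %in% names(positions)))
    stop_validation("positions must have columns x_um and ", second)
  if (nrow(positions) != ncol(intensities))
    stop_validation("one position row per spectrum required")
  if (anyDuplicated(positions[, c("x_um", second)]))
    stop_validation("positions must be unique")
  check_meta(meta)
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 positions = positions, axis = axis, meta = meta),
            class = "raman_map")
}

#' @export
print.raman_map <- function(x, ...) {
  cat(sprintf("<raman_map> %s, %d points, %d wavenumbers\n",
              x$axis, ncol(x$intensities), length(x$wavenumbers)))
  invisible(x)
}

#' Number of sampled points in a map
#' @param map A `raman_map`.
#' @return Integer point count.
#' @export
n_points <- function(map) {
  stopifnot(inherits(map, "raman_map"))
  ncol(map$intensities)
}

#' Construct an in vivo study dataset
#'
#' Holds every spectrum of a genotype x treatment x replicate x plant x day
#' design in one intensity matrix plus a metadata table, the compact R
#' equivalent of a keyed spectrum collection.
#'
#' @param wavenumbers Shared wavenumber grid (cm^-1).
#' @param intensities Matrix with `length(wavenumbers)` rows and one column per
#'   spectrum.
#' @param meta Data frame with one row per spectrum and columns `sample_id`,
#'   `genotype`, `treatment`, `replicate`, `plant`, `day`, `tissue`.
#' @return An object of class `raman_study`.
#' @export
raman_study <- function(wavenumbers, intensities, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  if (any(diff(wavenumbers) <= 0))
    stop_validation("wavenumbers must be strictly increasing")
  intensities <- as.matrix(intensities)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "treatment", "replicate", "plant", "day")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_validation("study meta lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(meta) != ncol(intensities))
    stop_validation("one meta row per spectrum required")
  if (!all(valid_treatment(meta$treatment)))
    stop_validation("unknown treatment label in study meta")
  # days must form a contiguous 0..D range within each genotype x treatment series
  for (key in split(meta$day, paste(meta$genotype, meta$treatment))) {
    days <- sort(unique(as.numeric(key)))
    if (days[1L] != 0 || !all(days == seq_along(days) - 1))
      stop_validation("days must form a contiguous 0..D range starting at 0")
  }
  structure(list(wavenumbers = wavenumbers, intensities = intensities, meta = meta),
            class = "raman_study")
}

#' @export
print.raman_study <- function(x, ...) {
  cat(sprintf("<raman_study> %d spectra | genotypes: %s | treatments: %s | days %d-%d\n",
              ncol(x$intensities),
              paste(unique(x$meta$genotype), collapse = ", "),
              paste(unique(x$meta$treatment), collapse = ", "),
              min(x$meta$day), max(x$meta$day)))
  invisible(x)
}

#' Extract one spectrum from a study or map
#' @param x A `raman_study` or `raman_map`.
#' @param i Column index of the spectrum.
#' @return A `raman_spectrum`.
#' @export
get_spectrum <- function(x, i) {
  stopifnot(inherits(x, c("raman_study", "raman_map")))
  i <- as.integer(i)
  if (i < 1L || i > ncol(x$intensities)) stop_validation("spectrum index out of range")
  meta <- if (inherits(x, "raman_study")) as.list(x$meta[i, , drop = FALSE]) else x$meta
  raman_spectrum(x$wavenumbers, x$intensities[, i], meta)
}
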