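#' Define a quantification band
#'
#' @param name Band name, e.g. `"carotenoid_1157"`.
#' @param center Band center (cm^-1).
#' @param half_window Half-width of the search window (cm^-1, default 10): the
#'   amplitude is the maximum intensity within `center +/- half_window`, which
#'   is robust to a few cm^-1 of center jitter.
#' @return A `band_def` object.
#' @export
band_def <- function(name, center, half_window = 10) {
  if (!is.numeric(center) || length(center) != 1L) stop_validation("center must be a number")
  if (!is.numeric(half_window) || half_window <= 0)
    stop_validation("half_window must be > 0")
  structure(list(name = name, center = center, half_window = half_window),
            class = "band_def")
}

#' Packaged carotenoid band table
#'
#' The three carotenoid bands (1007, 1157, 1524 cm^-1) read from the packaged
#' `bands.yaml`. 1524 cm^-1 is the strongest carotenoid band but overlaps the
#' anthocyanin band, so degradation statistics default to 1157 cm^-1; the
#' table's `"default"` attribute names that band.
#'
#' @return Named list of [band_def()] objects with attribute `default`.
#' @export
default_bands <- function() {
  path <- system.file("extdata", "bands.yaml", package = "ramandrought", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  out <- lapply(raw$bands, function(b) band_def(b$name, b$center, b$half_window))
  names(out) <- vapply(out, `[[`, "", "name")
  attr(out, "default") <- raw$default
  out
}

band_window_idx <- function(wn, band) {
  if (band$center < min(wn) || band$center > max(wn))
    stop_validation("band ", band$name, " (", band$center,
                    " cm-1) lies outside the wavenumber grid")
  idx <- which(wn >= band$center - band$half_window & wn <= band$center + band$half_window)
  if (!length(idx)) stop_validation("band window contains no grid points")
  idx
}

#' Band amplitude of a preprocessed spectrum
#'
#' Maximum intensity within `center +/- half_window`.
#'
#' @param spectrum A preprocessed `raman_spectrum`.
#' @param band A [band_def()].
#' @return Numeric amplitude (normalized units).
#' @export
band_amplitude <- function(spectrum, band = default_bands()[["carotenoid_1157"]]) {
  stopifnot(inherits(spectrum, "raman_spectrum"), inherits(band, "band_def"))
  idx <- band_window_idx(spectrum$wavenumbers, band)
  max(spectrum$intensities[idx])
}

# vectorised version over a spectrum matrix
band_amplitude_matrix <- function(Y, wn, band) {
  idx <- band_window_idx(wn, band)
  colwise_max(Y[idx, , drop = FALSE])
}

#' Strongest band among candidates
#'
#' Returns the candidate with the largest [band_amplitude()]; exact ties are
#' broken toward the lowest center wavenumber.
#'
#' @param spectrum A preprocessed `raman_spectrum`.
#' @param candidates Non-empty list of [band_def()] objects.
#' @return The name of the winning band.
#' @export
strongest_band <- function(spectrum, candidates = default_bands()) {
  if (!length(candidates)) stop_validation("candidate list must be non-empty")
  amps <- vapply(candidates, band_amplitude, 0, spectrum = spectrum)
  centers <- vapply(candidates, `[[`, 0, "center")
  win <- order(-amps, centers)[1L]
  candidates[[win]]$name
}

#' Pointwise mean spectrum
#'
#' Arithmetic mean of spectra sharing one wavenumber grid; used to average the
#' spectra collected over different leaf regions of a plant.
#'
#' @param spectra Non-empty list of `raman_spectrum` objects on a common grid.
#' @return A `raman_spectrum`; `meta$n` records the number averaged.
#' @export
mean_spectrum <- function(spectra) {
  if (!length(spectra)) stop_validation("cannot average an empty list of spectra")
  stopifnot(all(vapply(spectra, inherits, TRUE, "raman_spectrum")))
  wn <- spectra[[1L]]$wavenumbers
  for (s in spectra[-1L])
    if (!isTRUE(all.equal(wn, s$wavenumbers, tolerance = 0)))
      stop_validation("all spectra must share one wavenumber grid")
  m <- rowMeans(vapply(spectra, `[[`, numeric(length(wn)), "intensities"))
  raman_spectrum(wn, m, meta = list(n = length(spectra), mean_spectrum = TRUE))
}
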