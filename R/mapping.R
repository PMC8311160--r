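#' Band-intensity image of a spectrum map
#'
#' Preprocesses every pixel spectrum (baseline removal + smoothing; unit-vector
#' normalization is deliberately omitted so absolute band heights remain
#' comparable across pixels and timepoints — normalizing each pixel would erase
#' the degradation signal the images track) and evaluates the band amplitude at
#' each sampled position.
#'
#' @param map A `raman_map`.
#' @param band A [band_def()] (default the 1157 cm^-1 carotenoid band, the
#'   basis of all the Raman images).
#' @param params [preprocess_params()].
#' @param baseline If `FALSE`, raw (uncorrected) peak heights are used instead
#'   of per-pixel baseline correction.
#' @return An object of class `intensity_map`: positions, one amplitude per
#'   point, band name and the map's acquisition metadata.
#' @export
band_intensity_map <- function(map, band = default_bands()[["carotenoid_1157"]],
                               params = preprocess_params(), baseline = TRUE) {
  stopifnot(inherits(map, "raman_map"), inherits(band, "band_def"))
  if (baseline) {
    out <- preprocess_matrix(map$intensities, map$wavenumbers, params, normalize = FALSE)
    Y <- out$Y
  } else {
    Y <- savgol_matrix(map$intensities, params)
  }
  vals <- band_amplitude_matrix(Y, map$wavenumbers, band)
  structure(list(axis = map$axis, positions = map$positions,
                 values = as.numeric(vals), band = band$name,
                 timepoint_min = map$meta$timepoint_min %||% NA_real_,
                 treatment = map$meta$treatment %||% NA_character_,
                 meta = map$meta),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("<intensity_map> %s, %d points, band %s, mean %.4g\n",
              x$axis, length(x$values), x$band, mean(x$values)))
  invisible(x)
}

#' Pooled summary of intensity maps
#'
#' Pools the per-point band amplitudes of several maps (e.g. the replicate
#' series behind one histogram bar) into a mean, sample SD and total point
#' count n.
#'
#' @param maps Non-empty list of `intensity_map` objects sharing one band.
#' @return List with `mean`, `sd`, `n`.
#' @export
map_summary <- function(maps) {
  if (inherits(maps, "intensity_map")) maps <- list(maps)
  if (!length(maps)) stop_validation("need at least one intensity map")
  stopifnot(all(vapply(maps, inherits, TRUE, "intensity_map")))
  bands <- unique(vapply(maps, `[[`, "", "band"))
  if (length(bands) != 1L)
    stop_validation("maps quantify different bands: ", paste(bands, collapse = ", "))
  v <- unlist(lapply(maps, `[[`, "values"), use.names = FALSE)
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0, n = length(v))
}

map_palette <- function(n = 256L) {
  ramp <- grDevices::colorRamp(c("#000000", "#5e0b8b", "#c23b22", "#ff9a00", "#ffe97f"))
  ramp(seq(0, 1, length.out = n)) / 255
}

#' Render an intensity map to a false-color PNG
#'
#' Writes one image pixel per sampled point (nearest-neighbor placement on the
#' unique coordinate grid; the sparse sampling is not interpolated) with an
#' optional color scale bar appended on the right. Deterministic for fixed
#' input.
#'
#' @param x An `intensity_map`.
#' @param path Output PNG path.
#' @param zlim Intensity range mapped onto the palette; pass a common range to
#'   make a time series comparable frame to frame. Default the map's own range.
#' @param scale_bar Append a vertical color scale bar (default `TRUE`); the
#'   image then gains `4 + 1` columns.
#' @return Invisibly, `path`.
#' @export
render_map <- function(x, path, zlim = NULL, scale_bar = TRUE) {
  stopifnot(inherits(x, "intensity_map"))
  second <- if (x$axis == "XY") "y_um" else "z_um"
  xs <- sort(unique(x$positions$x_um))
  ys <- sort(unique(x$positions[[second]]))
  img <- matrix(NA_real_, length(ys), length(xs))
  ri <- match(x$positions[[second]], ys)
  ci <- match(x$positions$x_um, xs)
  img[cbind(ri, ci)] <- x$values
  # nearest-neighbor fill for positions absent from the rectangular hull
  if (anyNA(img)) {
    filled <- which(!is.na(img), arr.ind = TRUE)
    for (cell in which(is.na(img))) {
      r <- (cell - 1L) %% nrow(img) + 1L
      c <- (cell - 1L) %/% nrow(img) + 1L
      d <- (filled[, 1L] - r)^2 + (filled[, 2L] - c)^2
      img[cell] <- img[filled[which.min(d), , drop = FALSE]]
    }
  }
  zlim <- zlim %||% range(x$values)
  z <- (img - zlim[1L]) / max(zlim[2L] - zlim[1L], .Machine$double.eps)
  z <- pmin(pmax(z, 0), 1)
  pal <- map_palette()
  idx <- matrix(pmin(1L + as.integer(z * 255), 256L), nrow(z), ncol(z))
  rgb <- array(0, c(nrow(z), ncol(z), 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[idx, ch], nrow(z), ncol(z))
  if (isTRUE(scale_bar)) {
    bar_idx <- pmin(1L + as.integer(seq(1, 0, length.out = nrow(z)) * 255), 256L)
    bar <- array(0, c(nrow(z), 4L, 3L))
    for (ch in 1:3) bar[, , ch] <- matrix(pal[bar_idx, ch], nrow(z), 4L)
    sep <- array(1, c(nrow(z), 1L, 3L))
    out <- array(0, c(nrow(z), ncol(z) + 5L, 3L))
    out[, seq_len(ncol(z)), ] <- rgb
    out[, ncol(z) + 1L, ] <- sep
    out[, ncol(z) + 2:5, ] <- bar
    rgb <- out
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}
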