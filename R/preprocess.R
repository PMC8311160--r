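#' Preprocessing parameters
#'
#' Bundles the tunables of the three-stage preprocessing chain: iterative
#' polynomial (modified-polyfit) baseline removal, Savitzky-Golay smoothing and
#' unit-vector normalization.
#'
#' @param baseline_order Polynomial order of the baseline fit (default 7;
#'   allowed 1-11, with 3-11 the conventional range for leaf autofluorescence).
#' @param max_iter Maximum clamp-and-refit iterations (default 100).
#' @param tol_rel Convergence tolerance as a fraction of the raw intensity
#'   range: iteration stops when the fitted baseline changes by less than
#'   `tol_rel * (max - min)` everywhere (default 1e-6).
#' @param sg_window Savitzky-Golay window length in points; odd, larger than
#'   `sg_order` (default 15).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param norm_range Length-2 wavenumber range (cm^-1) over which the Euclidean
#'   norm is computed, or `NULL` for the full grid (default).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(baseline_order = 7, max_iter = 100, tol_rel = 1e-6,
                              sg_window = 15, sg_order = 3, norm_range = NULL) {
  if (!is_count(baseline_order) || baseline_order < 1 || baseline_order > 11)
    stop_validation("baseline_order must be an integer in 1..11")
  if (!is_count(max_iter)) stop_validation("max_iter must be a positive integer")
  if (!is.numeric(tol_rel) || tol_rel <= 0) stop_validation("tol_rel must be > 0")
  if (!is_count(sg_window) || sg_window %% 2 == 0)
    stop_validation("sg_window must be an odd positive integer")
  if (!is_count(sg_order) || sg_order >= sg_window)
    stop_validation("sg_order must be a positive integer smaller than sg_window")
  if (!is.null(norm_range) && (length(norm_range) != 2L || diff(norm_range) <= 0))
    stop_validation("norm_range must be c(lo, hi) with lo < hi")
  structure(list(baseline_order = as.integer(baseline_order),
                 max_iter = as.integer(max_iter), tol_rel = tol_rel,
                 sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
                 norm_range = norm_range),
            class = "preprocess_params")
}

# Orthonormal polynomial basis for a grid, cached (QR of a scaled Vandermonde).
poly_basis <- function(wn, order) {
  key <- paste0("pb_", order, "_", length(wn), "_",
                format(wn[1L], digits = 17), "_", format(wn[length(wn)], digits = 17))
  q <- .rd_cache[[key]]
  if (!is.null(q)) return(q)
  t <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  v <- outer(t, 0:order, `^`)
  q <- qr.Q(qr(v))
  .rd_cache[[key]] <- q
  q
}

# Modified-polyfit baseline on an npts x nspec matrix. Fits a polynomial to the
# working trace, clamps every point above the fit down to it, and repeats until
# the fit stabilises; the limit is the lower envelope of the spectrum, i.e. the
# fluorescence background beneath the Raman bands.
baseline_fit_matrix <- function(Y, wn, params) {
  npts <- nrow(Y)
  if (npts < params$baseline_order + 2L)
    stop_validation("baseline fit needs at least order+2 = ",
                    params$baseline_order + 2L, " points")
  Q <- poly_basis(wn, params$baseline_order)
  rng <- colwise_max(Y) - (-colwise_max(-Y))
  tol <- params$tol_rel * rng
  inv_tol <- 1 / pmax(tol, .Machine$double.xmin)
  W <- Y
  fit_old <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(params$max_iter)) {
    Fit <- Q %*% crossprod(Q, W)
    if (!is.null(fit_old)) {
      rel <- abs(Fit - fit_old) * rep(inv_tol, each = npts)
      if (max(rel) <= 1) { converged <- TRUE; fit_old <- Fit; break }
    }
    W <- pmin(W, Fit)
    fit_old <- Fit
  }
  list(baseline = fit_old, converged = converged, iterations = iter)
}

#' Iterative polynomial baseline correction (modified polyfit)
#'
#' Removes the broad tissue-autofluorescence background by repeatedly fitting a
#' polynomial to the spectrum and clamping points above the fit down to it, so
#' the fit converges onto the lower envelope under the Raman bands.
#'
#' @param spectrum A `raman_spectrum`.
#' @param params A [preprocess_params()] object.
#' @return A list with elements `corrected` and `baseline` (both
#'   `raman_spectrum`), `converged` (logical; `FALSE` means the iteration cap
#'   was reached, flagged but not an error) and `iterations`.
#' @examples
#' wn <- 400:1800
#' s <- raman_spectrum(wn, 2 + 0.001 * wn)  # pure polynomial, no peaks
#' out <- baseline_correct(s, preprocess_params())
#' max(abs(out$corrected$intensities))  # ~0
#' @export
baseline_correct <- function(spectrum, params = preprocess_params()) {
  stopifnot(inherits(spectrum, "raman_spectrum"), inherits(params, "preprocess_params"))
  y <- matrix(spectrum$intensities, ncol = 1L)
  fit <- baseline_fit_matrix(y, spectrum$wavenumbers, params)
  bl <- drop(fit$baseline)
  meta <- spectrum$meta
  meta$baseline_corrected <- TRUE
  list(corrected = raman_spectrum(spectrum$wavenumbers, spectrum$intensities - bl, meta),
       baseline = raman_spectrum(spectrum$wavenumbers, bl, spectrum$meta),
       converged = fit$converged, iterations = fit$iterations)
}

sg_kernel <- function(window, order) {
  m <- signal::sgolay(p = order, n = window)
  as.numeric(m[(window + 1L) %/% 2L, ])
}

check_uniform_grid <- function(wn) {
  d <- diff(wn)
  if (max(d) - min(d) > 1e-8 * mean(d))
    stop_validation("Savitzky-Golay smoothing requires a uniform wavenumber grid; ",
                    "resample the spectrum first")
  invisible(TRUE)
}

# Savitzky-Golay convolution with mirror-padded edges on an npts x nspec matrix.
savgol_matrix <- function(Y, params) {
  npts <- nrow(Y)
  w <- params$sg_window
  if (w > npts) stop_validation("sg_window exceeds the number of points")
  k <- (w - 1L) %/% 2L
  kern <- sg_kernel(w, params$sg_order)
  if (k > 0L) {
    top <- Y[seq(k + 1L, 2L), , drop = FALSE]
    bot <- Y[seq(npts - 1L, npts - k), , drop = FALSE]
    Yp <- rbind(top, Y, bot)
  } else Yp <- Y
  out <- stats::filter(Yp, kern, method = "convolution", sides = 2)
  out <- as.matrix(out)[seq(k + 1L, k + npts), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (default: 15-point window, cubic),
#' which suppresses detector noise while preserving band shapes up to the
#' polynomial order. Edges are handled by mirror padding.
#'
#' @inheritParams baseline_correct
#' @return The smoothed `raman_spectrum` on the unchanged grid.
#' @export
savgol_smooth <- function(spectrum, params = preprocess_params()) {
  stopifnot(inherits(spectrum, "raman_spectrum"), inherits(params, "preprocess_params"))
  check_uniform_grid(spectrum$wavenumbers)
  sm <- savgol_matrix(matrix(spectrum$intensities, ncol = 1L), params)
  raman_spectrum(spectrum$wavenumbers, drop(sm), spectrum$meta)
}

norm_index <- function(wn, norm_range) {
  if (is.null(norm_range)) return(seq_along(wn))
  idx <- which(wn >= norm_range[1L] & wn <= norm_range[2L])
  if (!length(idx)) stop_validation("norm_range does not overlap the grid")
  idx
}

#' Unit-vector normalization
#'
#' Divides the whole trace by its Euclidean norm over the normalization range,
#' removing acquisition-to-acquisition intensity differences (laser power,
#' focus). The norm of the output over that range is 1.
#'
#' @inheritParams baseline_correct
#' @param norm_range Optional wavenumber range over which the norm is taken;
#'   default the full grid.
#' @return The normalized `raman_spectrum`.
#' @examples
#' unit_vector_normalize(raman_spectrum(c(1000, 1001), c(3, 4)))$intensities
#' @export
unit_vector_normalize <- function(spectrum, norm_range = NULL) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  idx <- norm_index(spectrum$wavenumbers, norm_range)
  nrm <- sqrt(sum(spectrum$intensities[idx]^2))
  if (nrm <= 0) stop_validation("cannot normalize a zero-norm spectrum")
  raman_spectrum(spectrum$wavenumbers, spectrum$intensities / nrm, spectrum$meta)
}

# Full chain on a matrix; normalize = FALSE is the map-imaging mode, which
# keeps absolute band heights comparable across pixels and timepoints.
preprocess_matrix <- function(Y, wn, params, normalize = TRUE) {
  fit <- baseline_fit_matrix(Y, wn, params)
  Yc <- Y - fit$baseline
  Yc <- savgol_matrix(Yc, params)
  if (normalize) {
    idx <- norm_index(wn, params$norm_range)
    nrm <- sqrt(colSums(Yc[idx, , drop = FALSE]^2))
    if (any(nrm <= 0)) stop_validation("cannot normalize a zero-norm spectrum")
    Yc <- Yc * rep(1 / nrm, each = nrow(Yc))
  }
  list(Y = Yc, converged = fit$converged, iterations = fit$iterations)
}

#' Full spectral preprocessing chain
#'
#' Baseline correction, then Savitzky-Golay smoothing, then unit-vector
#' normalization, in that order. The result is invariant to multiplying the raw
#' trace by any positive constant.
#'
#' @inheritParams baseline_correct
#' @return The preprocessed `raman_spectrum`; `meta$preprocess` records the
#'   parameters used and the baseline convergence flag.
#' @export
preprocess_spectrum <- function(spectrum, params = preprocess_params()) {
  stopifnot(inherits(spectrum, "raman_spectrum"), inherits(params, "preprocess_params"))
  check_uniform_grid(spectrum$wavenumbers)
  out <- preprocess_matrix(matrix(spectrum$intensities, ncol = 1L),
                           spectrum$wavenumbers, params, normalize = TRUE)
  meta <- spectrum$meta
  meta$preprocess <- list(baseline_order = params$baseline_order,
                          sg_window = params$sg_window, sg_order = params$sg_order,
                          normalized = TRUE, baseline_converged = out$converged)
  raman_spectrum(spectrum$wavenumbers, drop(out$Y), meta)
}

#' Preprocess every spectrum of a study
#'
#' Applies [preprocess_spectrum()]'s chain to all spectra of a study in one
#' vectorised pass (chunked to bound memory).
#'
#' @param study A `raman_study`.
#' @param params A [preprocess_params()] object.
#' @param chunk Maximum number of spectra processed per pass.
#' @return The study with preprocessed intensities; attribute `"preprocessed"`
#'   set to `TRUE`.
#' @export
preprocess_study <- function(study, params = preprocess_params(), chunk = 3000L) {
  stopifnot(inherits(study, "raman_study"))
  check_uniform_grid(study$wavenumbers)
  n <- ncol(study$intensities)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n)
    out <- preprocess_matrix(study$intensities[, idx, drop = FALSE],
                             study$wavenumbers, params, normalize = TRUE)
    study$intensities[, idx] <- out$Y
  }
  attr(study, "preprocessed") <- TRUE
  study
}
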