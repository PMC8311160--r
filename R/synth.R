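#' Default wavenumber grid
#'
#' 400-1800 cm^-1 at 1 cm^-1 spacing: spans every band the analysis uses
#' (1007-1524 cm^-1) at adequate resolution.
#'
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(400, 1800, by = 1)

lorentz <- function(wn, center, hwhm) 1 / (1 + ((wn - center) / hwhm)^2)

#' A single Lorentzian band component
#'
#' @param center Band center (cm^-1).
#' @param hwhm Half width at half maximum (cm^-1), > 0.
#' @param amplitude Peak height (arbitrary units), >= 0.
#' @param label Assignment: `"carotenoid"`, `"chlorophyll"`, `"anthocyanin"` or
#'   `"other"`.
#' @return A `band_component` list.
#' @export
band_component <- function(center, hwhm, amplitude,
                           label = c("carotenoid", "chlorophyll", "anthocyanin", "other")) {
  label <- match.arg(label)
  if (!is.numeric(hwhm) || hwhm <= 0) stop_validation("hwhm must be > 0")
  if (!is.numeric(amplitude) || amplitude < 0) stop_validation("amplitude must be >= 0")
  structure(list(center = center, hwhm = hwhm, amplitude = amplitude, label = label),
            class = "band_component")
}

#' Generative profile of one genotype/tissue
#'
#' Holds everything the generator needs for one genotype: the carotenoid band
#' amplitudes at day 0, the non-carotenoid (constant) leaf-matrix bands, the
#' autofluorescence background, the per-treatment 7-day degradation fraction
#' and the noise levels.
#'
#' @param genotype Genotype label.
#' @param tissue `"green"` (light-grown, chloroplast-containing) or `"white"`
#'   (dark-grown, chlorophyll-less).
#' @param amp0 Initial (day-0) height of the carotenoid 1157 cm^-1 band
#'   (detector counts). The 1007 and 1524 cm^-1 bands scale with it.
#' @param degradation Named list of 7-day degradation fractions in `[0, 1]` per
#'   treatment, e.g. `list(control = 0, drought = 0.22)`. White tissue must
#'   have 0 everywhere (carotenoids in etioplasts do not degrade under osmotic
#'   stress).
#' @param carotenoid_bands Data frame (`center`, `hwhm`, `rel_amp`) of the
#'   carotenoid bands relative to `amp0`.
#' @param constant_bands Data frame (`label`, `center`, `hwhm`, `amp`) of
#'   non-degrading leaf-matrix bands in absolute counts.
#' @param background List with polynomial coefficients `c0..c3` (on the grid
#'   rescaled to `[-1, 1]`) and broad-Gaussian fluorescence `gauss_amp`,
#'   `gauss_center`, `gauss_sd`.
#' @param amp_cv Per-spectrum multiplicative lognormal amplitude noise CV
#'   (default 0.05).
#' @param add_sd_frac Additive spectral noise SD as a fraction of the tallest
#'   band height (default 0.01).
#' @return An object of class `genotype_profile`.
#' @export
genotype_profile <- function(genotype, tissue = c("green", "white"), amp0,
                             degradation = list(control = 0, drought = 0),
                             carotenoid_bands = NULL, constant_bands = NULL,
                             background = NULL, amp_cv = 0.05, add_sd_frac = 0.01) {
  tissue <- match.arg(tissue)
  if (!is.numeric(amp0) || amp0 <= 0) stop_validation("amp0 must be > 0")
  r <- unlist(degradation)
  if (any(r < 0 | r > 1)) stop_validation("degradation fractions must lie in [0, 1]")
  if (tissue == "white" && any(r != 0))
    stop_validation("white tissue must have zero degradation under osmotic stress")
  if (amp_cv < 0 || add_sd_frac < 0) stop_validation("noise parameters must be >= 0")
  defs <- synth_defaults()
  carotenoid_bands <- carotenoid_bands %||% defs$carotenoid_bands
  constant_bands <- constant_bands %||% defs$constant_bands[[tissue]]
  background <- background %||% defs$background[[tissue]]
  if (any(carotenoid_bands$hwhm <= 0) || any(constant_bands$hwhm <= 0))
    stop_validation("band widths must be > 0")
  structure(list(genotype = genotype, tissue = tissue, amp0 = amp0,
                 degradation = as.list(r), carotenoid_bands = carotenoid_bands,
                 constant_bands = constant_bands, background = background,
                 amp_cv = amp_cv, add_sd_frac = add_sd_frac),
            class = "genotype_profile")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat(sprintf("<genotype_profile> %s (%s tissue), 1157 amp0 = %g, r = {%s}\n",
              x$genotype, x$tissue, x$amp0,
              paste(names(x$degradation), unlist(x$degradation), sep = "=", collapse = ", ")))
  invisible(x)
}

synth_defaults <- function() {
  d <- .rd_cache$synth_defaults
  if (is.null(d)) {
    path <- system.file("extdata", "genotypes.yaml", package = "ramandrought", mustWork = TRUE)
    raw <- yaml::read_yaml(path)
    d <- list(
      carotenoid_bands = do.call(rbind, lapply(raw$carotenoid_bands, as.data.frame)),
      constant_bands = lapply(raw$constant_bands,
                              function(b) do.call(rbind, lapply(b, as.data.frame))),
      background = raw$background,
      profiles = raw$profiles
    )
    .rd_cache$synth_defaults <- d
  }
  d
}

#' Packaged genotype profiles
#'
#' The six fixture profiles the in vivo experiments use: the three inbreds
#' (CML176, OH28, B73) with distinct initial carotenoid levels, the two
#' near-isogenic lipoxygenase mutants (lox2, lox4) sharing B73's initial level,
#' and the dark-grown chlorophyll-less B73 tissue (`"B73_white"`) with lower
#' carotenoid content and no degradation. Stressed 7-day degradation fractions:
#' CML176 0.22, OH28 0.20, B73 0.06, lox2 0.10, lox4 0.03.
#'
#' @return Named list of [genotype_profile()] objects.
#' @export
default_profiles <- function() {
  raw <- synth_defaults()$profiles
  out <- lapply(raw, function(p)
    genotype_profile(p$genotype, p$tissue, p$amp0,
                     degradation = list(control = 0, drought = p$r_drought)))
  names(out) <- vapply(raw, function(p)
    if (p$tissue == "white") paste0(p$genotype, "_white") else p$genotype, "")
  out
}

# Fixed spectral shapes of a profile: the carotenoid shape scales with the
# per-spectrum carotenoid amplitude, the rest is constant.
profile_shapes <- function(profile, wn) {
  car <- rowSums(vapply(seq_len(nrow(profile$carotenoid_bands)), function(i) {
    b <- profile$carotenoid_bands[i, ]
    b$rel_amp * lorentz(wn, b$center, b$hwhm)
  }, numeric(length(wn))))
  const <- rowSums(vapply(seq_len(nrow(profile$constant_bands)), function(i) {
    b <- profile$constant_bands[i, ]
    b$amp * lorentz(wn, b$center, b$hwhm)
  }, numeric(length(wn))))
  bg <- profile$background
  t <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  background <- bg$c0 + bg$c1 * t + bg$c2 * t^2 + bg$c3 * t^3 +
    bg$gauss_amp * exp(-(wn - bg$gauss_center)^2 / (2 * bg$gauss_sd^2))
  peak_height <- max(car * profile$amp0 + const)
  list(car = car, const = const, background = background, peak_height = peak_height)
}

#' Synthesize one leaf Raman spectrum
#'
#' Intensities are background(nu) + sum of Lorentzian bands x `scale` +
#' additive Gaussian noise; deterministic given `seed`.
#'
#' @param profile A [genotype_profile()].
#' @param scale Positive factor applied to all bands (laser power / focus).
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @param noise If `FALSE`, the noiseless expectation is returned.
#' @param wavenumbers Wavenumber grid (default [default_grid()]).
#' @return A `raman_spectrum` with genotype/tissue metadata.
#' @export
synth_spectrum <- function(profile, scale = 1, seed = NULL, noise = TRUE,
                           wavenumbers = default_grid()) {
  stopifnot(inherits(profile, "genotype_profile"))
  if (!is.numeric(scale) || scale <= 0) stop_validation("scale must be > 0")
  sh <- profile_shapes(profile, wavenumbers)
  y <- sh$background + scale * (profile$amp0 * sh$car + sh$const)
  if (noise && profile$add_sd_frac > 0) {
    eps <- with_seed(seed, stats::rnorm(length(y), 0, profile$add_sd_frac * sh$peak_height))
    y <- y + eps
  }
  raman_spectrum(wavenumbers, y,
                 meta = list(genotype = profile$genotype, tissue = profile$tissue,
                             synthetic = TRUE))
}

# --- day-scale decay calibration -------------------------------------------
#
# The degradation fraction r is defined on the pipeline observable: the
# preprocessed (baseline-removed, smoothed, unit-normalized) 1157 cm-1 peak
# height declines linearly from its day-0 value to (1 - r) of it at day 7.
# Because unit-vector normalization couples the observable to the whole
# spectrum, the raw Lorentzian amplitude schedule that realises this law is
# obtained by inverting the deterministic preprocessing map numerically.

observable_1157 <- function(profile, car_amp, wn, params) {
  sh <- profile_shapes(profile, wn)
  y <- sh$background + car_amp * sh$car + sh$const
  out <- preprocess_matrix(matrix(y, ncol = 1L), wn, params, normalize = TRUE)
  idx <- which(wn >= 1157 - 10 & wn <= 1157 + 10)
  max(out$Y[idx, 1L])
}

# Additive detector noise distorts the measured (normalized, windowed-max)
# amplitude by a smooth amplitude-dependent relative factor delta(a): noise
# power inflates the Euclidean norm while the windowed maximum rides noise
# peaks. delta is estimated once per profile from a fixed-seed Monte Carlo
# batch at a few amplitude anchors and spline-interpolated, so the calibrated
# schedule is linear in the *expected measured* amplitude under the profile's
# own noise model. Deterministic, and independent of the user's seed.
.noise_bias_seed <- 104729L

noise_bias_spline <- function(profile, wn, params, anchors, draws = 192L) {
  sh <- profile_shapes(profile, wn)
  idx <- which(wn >= 1157 - 10 & wn <= 1157 + 10)
  noise <- with_seed(.noise_bias_seed,
    matrix(stats::rnorm(length(wn) * draws, 0, profile$add_sd_frac * sh$peak_height),
           length(wn), draws))
  delta <- vapply(anchors, function(a) {
    y <- sh$background + a * sh$car + sh$const
    out <- preprocess_matrix(cbind(y, y + noise), wn, params, normalize = TRUE)
    m <- colwise_max(out$Y[idx, , drop = FALSE])
    mean(m[-1L]) / m[1L] - 1
  }, 0)
  stats::splinefun(anchors, delta, method = "natural")
}

calibrate_car_schedule <- function(profile, r, days, wn, params) {
  if (r == 0) return(rep(profile$amp0, length(days)))
  key <- paste0("cal_", profile$genotype, "_", profile$tissue, "_",
                format(profile$amp0, digits = 17), "_", format(r, digits = 17), "_",
                format(profile$add_sd_frac, digits = 17), "_",
                paste(days, collapse = ","), "_", length(wn), "_",
                params$baseline_order, "_", params$sg_window, "_", params$sg_order)
  got <- .rd_cache[[key]]
  if (!is.null(got)) return(got)
  delta <- if (profile$add_sd_frac > 0)
    noise_bias_spline(profile, wn, params,
                      anchors = profile$amp0 * seq(1, max(0.35, 1 - 1.3 * r), length.out = 5))
  else function(a) 0
  mbar <- function(a) observable_1157(profile, a, wn, params) * (1 + delta(a))
  m0 <- mbar(profile$amp0)
  amps <- vapply(days, function(d) {
    if (d == 0) return(profile$amp0)
    target <- m0 * (1 - r * d / 7)
    stats::uniroot(function(a) mbar(a) - target,
                   interval = c(profile$amp0 * 0.005, profile$amp0 * 1.0001),
                   tol = profile$amp0 * 1e-12)$root
  }, 0)
  .rd_cache[[key]] <- amps
  amps
}

#' Study design of the in vivo experiment
#'
#' @param treatments Character vector of treatments, subset of
#'   `c("control", "drought")`.
#' @param replicates Independent replicate experiments (default 3).
#' @param plants Plants per replicate per treatment (default 5).
#' @param spectra_per_day Spectra collected per plant per day (default 12).
#' @param days Measurement days, a contiguous integer range starting at 0
#'   (default `0:7`).
#' @return A validated design list.
#' @export
study_design <- function(treatments = c("control", "drought"), replicates = 3,
                         plants = 5, spectra_per_day = 12, days = 0:7) {
  if (!all(treatments %in% c("control", "drought")) || !length(treatments))
    stop_validation("treatments must be a non-empty subset of control/drought")
  days <- as.integer(unlist(days))
  if (days[1L] != 0 || !identical(days, seq(0L, max(days))))
    stop_validation("days must form a contiguous range starting at 0")
  for (v in c(replicates, plants, spectra_per_day))
    if (!is_count(v)) stop_validation("design counts must be positive integers")
  list(treatments = treatments, replicates = as.integer(replicates),
       plants = as.integer(plants), spectra_per_day = as.integer(spectra_per_day),
       days = days)
}

#' Simulate a full in vivo drought study
#'
#' Generates every spectrum of a genotype x treatment x replicate x plant x day
#' design. The expected preprocessed 1157 cm^-1 band amplitude of stressed
#' groups declines linearly from its day-0 value A0 to A0(1 - r) at day 7
#' (r from each profile); controls have r = 0. Per-spectrum multiplicative
#' lognormal amplitude noise (profile `amp_cv`) and additive spectral noise are
#' applied; output is reproducible given `seed`.
#'
#' @param profiles List of [genotype_profile()] objects (one per genotype).
#' @param design A [study_design()] list.
#' @param seed Integer seed.
#' @param params [preprocess_params()] used to define the calibrated
#'   observable; keep in step with the parameters used downstream.
#' @param wavenumbers Wavenumber grid.
#' @return A `raman_study`; attribute `"schedule"` holds the per
#'   genotype/treatment/day expected observable and raw amplitude.
#' @export
synth_study <- function(profiles, design = study_design(), seed = NULL,
                        params = preprocess_params(), wavenumbers = default_grid()) {
  if (inherits(profiles, "genotype_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, TRUE, "genotype_profile")))
  days <- design$days
  n_per_gt <- length(design$treatments) * design$replicates * design$plants *
    length(days) * design$spectra_per_day
  npts <- length(wavenumbers)
  total <- n_per_gt * length(profiles)
  intens <- matrix(0, npts, total)
  meta <- vector("list", length(profiles))
  sched <- list()
  with_seed(seed, {
    col <- 0L
    for (gi in seq_along(profiles)) {
      pr <- profiles[[gi]]
      sh <- profile_shapes(pr, wavenumbers)
      base <- sh$background + sh$const
      grid <- expand.grid(spectrum = seq_len(design$spectra_per_day), day = days,
                          plant = seq_len(design$plants),
                          replicate = seq_len(design$replicates),
                          treatment = design$treatments,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      amp_by <- lapply(design$treatments, function(tr) {
        r <- pr$degradation[[tr]] %||% 0
        calibrate_car_schedule(pr, r, days, wavenumbers, params)
      })
      names(amp_by) <- design$treatments
      sched[[length(sched) + 1L]] <- do.call(rbind, lapply(design$treatments, function(tr)
        data.frame(genotype = pr$genotype, tissue = pr$tissue, treatment = tr,
                   day = days, car_amp = amp_by[[tr]],
                   stringsAsFactors = FALSE)))
      n <- nrow(grid)
      car_amp <- mapply(function(tr, d) amp_by[[tr]][match(d, days)],
                        grid$treatment, grid$day)
      car_amp <- car_amp * lognorm_mult(n, pr$amp_cv)
      const_mult <- lognorm_mult(n, pr$amp_cv)
      block <- base %o% rep(1, n) +
        sh$car %o% car_amp +
        sh$const %o% (const_mult - 1)
      if (pr$add_sd_frac > 0)
        block <- block + matrix(stats::rnorm(npts * n, 0, pr$add_sd_frac * sh$peak_height),
                                npts, n)
      intens[, col + seq_len(n)] <- block
      grid$genotype <- pr$genotype
      grid$tissue <- pr$tissue
      grid$sample_id <- sprintf("%s_%s_r%d_p%d_d%d_s%02d", pr$genotype,
                                substr(grid$treatment, 1, 2), grid$replicate,
                                grid$plant, grid$day, grid$spectrum)
      meta[[gi]] <- grid
      col <- col + n
    }
  })
  meta <- do.call(rbind, meta)
  study <- raman_study(wavenumbers, intens,
                       meta[, c("sample_id", "genotype", "treatment", "replicate",
                                "plant", "day", "tissue")])
  attr(study, "schedule") <- do.call(rbind, sched)
  study
}

#' Osmotic-stress kinetics of the mannitol map experiment
#'
#' Minute-scale carotenoid decay under mannitol is exponential towards a floor:
#' the expected 1157 cm^-1 amplitude at t minutes after treatment is
#' `A0 * (floor + (1 - floor) * 2^(-t / half_life(conc)))`, where `half_life`
#' is the half-life of the degradable carotenoid pool.
#'
#' @param half_life_min Named numeric vector mapping mannitol concentration
#'   (mM, as names) to degradable-pool half-life (min); must be strictly
#'   decreasing in concentration.
#' @param floor Non-degradable amplitude fraction in `[0, 1)`.
#' @param spatial_cv Lognormal CV of the persistent pixel-to-pixel carotenoid
#'   heterogeneity across the mapped area.
#' @return An `osmotic_kinetics` object.
#' @export
osmotic_kinetics <- function(half_life_min = c("100" = 9, "150" = 5, "250" = 3),
                             floor = 0.1, spatial_cv = 0.12) {
  conc <- as.numeric(names(half_life_min))
  if (anyNA(conc)) stop_validation("half_life_min must be named by concentration (mM)")
  o <- order(conc)
  if (any(diff(half_life_min[o]) >= 0))
    stop_validation("half-life must be strictly decreasing in concentration")
  if (floor < 0 || floor >= 1) stop_validation("floor must lie in [0, 1)")
  if (spatial_cv < 0) stop_validation("spatial_cv must be >= 0")
  structure(list(half_life_min = half_life_min[o], floor = floor,
                 spatial_cv = spatial_cv),
            class = "osmotic_kinetics")
}

#' Packaged mannitol kinetics
#'
#' Half-lives of the degradable carotenoid pool chosen so the mean mapped
#' 1157 cm^-1 intensity first falls below 50% of pre-treatment at the 5-min
#' timepoint under 250 mM and the 15-min timepoint under 100 mM.
#'
#' @return An [osmotic_kinetics()] object read from the packaged
#'   `kinetics.yaml`.
#' @export
default_kinetics <- function() {
  path <- system.file("extdata", "kinetics.yaml", package = "ramandrought", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  hl <- unlist(raw$half_life_min)
  osmotic_kinetics(hl, floor = raw$floor, spatial_cv = raw$spatial_cv)
}

map_grid_positions <- function(grid) {
  switch(grid,
    XY80 = {
      pos <- expand.grid(x_um = seq(0, 180, length.out = 10),
                         y_um = seq(0, 140, length.out = 8))
      list(positions = pos[, c("x_um", "y_um")], axis = "XY")
    },
    XZ30 = {
      pos <- expand.grid(x_um = seq(0, 160, length.out = 10),
                         z_um = seq(0, 15, length.out = 3))
      list(positions = pos[, c("x_um", "z_um")], axis = "XZ")
    },
    stop_validation("unknown map grid: ", grid))
}

#' Simulate a mannitol osmotic-stress map series
#'
#' Generates Raman maps of one leaf disk before treatment and at fixed minutes
#' after mannitol is introduced. Per-pixel expected 1157 cm^-1 amplitude
#' follows `A0 * (floor + (1 - floor) * 2^(-t / half_life(conc)))`;
#' concentration 0 (deionized-water control) and white tissue do not decay.
#' Pixel-to-pixel heterogeneity persists across timepoints.
#'
#' @param kinetics An [osmotic_kinetics()] object.
#' @param conc Mannitol concentration in mM: one of the kinetics table entries
#'   or 0 for the water control.
#' @param grid `"XY80"` (180 x 140 um, 80 points) or `"XZ30"` (160 x 15 um,
#'   30 points).
#' @param timepoints Minutes after treatment; `NA` denotes the pre-treatment
#'   map. Default `c(NA, 0, 5, 15, 30, 45)`.
#' @param profile Tissue profile; default the packaged green B73 profile.
#' @param seed Integer seed.
#' @param noise If `FALSE`, heterogeneity and noise are switched off (the maps
#'   are the exact expectation).
#' @param wavenumbers Wavenumber grid.
#' @return List of `raman_map` objects named `"pre"`, `"0"`, `"5"`, ...
#' @export
synth_map_series <- function(kinetics = default_kinetics(), conc = 150,
                             grid = c("XY80", "XZ30"),
                             timepoints = c(NA, 0, 5, 15, 30, 45),
                             profile = NULL, seed = NULL, noise = TRUE,
                             wavenumbers = default_grid()) {
  grid <- match.arg(grid)
  stopifnot(inherits(kinetics, "osmotic_kinetics"))
  profile <- profile %||% default_profiles()[["B73"]]
  known <- as.numeric(names(kinetics$half_life_min))
  if (!(conc == 0 || conc %in% known))
    stop_validation("unknown mannitol concentration: ", conc,
                    " (kinetics table has ", paste(known, collapse = ", "), " mM)")
  g <- map_grid_positions(grid)
  npix <- nrow(g$positions)
  sh <- profile_shapes(profile, wavenumbers)
  decays <- vapply(timepoints, function(t) {
    if (is.na(t) || conc == 0 || profile$tissue == "white") 1
    else {
      hl <- kinetics$half_life_min[[as.character(conc)]]
      kinetics$floor + (1 - kinetics$floor) * 2^(-t / hl)
    }
  }, 0)
  with_seed(seed, {
    hetero <- if (noise) lognorm_mult(npix, kinetics$spatial_cv) else rep(1, npix)
    maps <- lapply(seq_along(timepoints), function(k) {
      t <- timepoints[k]
      acq <- if (noise) lognorm_mult(npix, profile$amp_cv) else rep(1, npix)
      cmult <- if (noise) lognorm_mult(npix, profile$amp_cv) else rep(1, npix)
      car_amp <- profile$amp0 * decays[k] * hetero * acq
      Y <- (sh$background + sh$const) %o% rep(1, npix) +
        sh$car %o% car_amp + sh$const %o% (cmult - 1)
      if (noise && profile$add_sd_frac > 0)
        Y <- Y + matrix(stats::rnorm(npix * length(wavenumbers), 0,
                                     profile$add_sd_frac * sh$peak_height),
                        length(wavenumbers), npix)
      raman_map(wavenumbers, Y, g$positions, axis = g$axis,
                meta = list(spot_um = 2,
                            power_mw = if (grid == "XY80") 2 else 2,
                            integration_s = 0.5,
                            timepoint_min = if (is.na(t)) NA_real_ else t,
                            mannitol_mm = conc,
                            treatment = if (conc > 0) paste0("mannitol:", conc) else "control",
                            tissue = profile$tissue,
                            expected_ratio = decays[k]))
    })
    names(maps) <- ifelse(is.na(timepoints), "pre", as.character(timepoints))
    maps
  })
}
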