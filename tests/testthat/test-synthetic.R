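wn <- default_grid()

test_that("band components and profiles validate their parameters", {
  expect_error(band_component(1157, hwhm = 0, amplitude = 1), "hwhm")
  expect_error(band_component(1157, hwhm = 8, amplitude = -1), "amplitude")
  expect_error(genotype_profile("x", "green", amp0 = 0), "amp0")
  expect_error(genotype_profile("x", "green", amp0 = 1,
                                degradation = list(drought = 1.2)), "\\[0, 1\\]")
  expect_error(genotype_profile("x", "white", amp0 = 1,
                                degradation = list(drought = 0.1)), "white")
  expect_error(genotype_profile("x", "green", amp0 = 1, amp_cv = -0.1), "noise")
})

test_that("a single zero-noise band peaks exactly at its center", {
  s <- synth_spectrum(bare_profile(centers = 1157), noise = FALSE)
  expect_equal(s$wavenumbers[which.max(s$intensities)], 1157)
})

test_that("the default green spectrum has its strongest carotenoid band at 1524", {
  p <- preprocess_spectrum(synth_spectrum(profile_with("B73"), noise = FALSE))
  expect_gt(p$intensities[wn == 1524], p$intensities[wn == 1157])
  expect_gt(p$intensities[wn == 1157], p$intensities[wn == 1007])
})

test_that("white tissue carries less carotenoid than green and does not degrade", {
  profs <- default_profiles()
  white <- profs[["B73_white"]]; green <- profs[["B73"]]
  expect_lt(white$amp0, green$amp0)
  expect_true(all(unlist(white$degradation) == 0))
  # measured: baseline-corrected 1157 peak height (imaging mode), same seed
  amp_of <- function(pr) {
    m <- synth_map_series(conc = 0, grid = "XZ30", timepoints = NA,
                          profile = pr, seed = 4)[["pre"]]
    mean(band_intensity_map(m)$values)
  }
  expect_lt(amp_of(white), amp_of(green))
})

test_that("synth_spectrum validates scale and is seed-deterministic", {
  pr <- profile_with("B73")
  expect_error(synth_spectrum(pr, scale = -1), "scale")
  a <- synth_spectrum(pr, seed = 5)
  b <- synth_spectrum(pr, seed = 5)
  c <- synth_spectrum(pr, seed = 6)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
  # scale multiplies the bands, not the background
  s1 <- synth_spectrum(bare_profile(), scale = 1, noise = FALSE)
  s2 <- synth_spectrum(bare_profile(), scale = 3, noise = FALSE)
  expect_equal(max(s2$intensities), 3 * max(s1$intensities), tolerance = 1e-12)
})

test_that("the full design multiplies out to 2880 spectra per genotype", {
  st <- synth_study(profile_with("B73", amp_cv = 0, add_sd_frac = 0),
                    study_design(), seed = 1)
  expect_equal(ncol(st$intensities), 2L * 3L * 5L * 8L * 12L)
  m <- st$meta
  expect_setequal(unique(m$treatment), c("control", "drought"))
  expect_equal(sort(unique(m$day)), 0:7)
  expect_equal(max(m$plant), 5L)
})

test_that("r = 0 with zero noise yields identical spectra on every day", {
  pr <- profile_with("B73", r = 0, amp_cv = 0, add_sd_frac = 0)
  st <- synth_study(pr, small_design(), seed = 1)
  day0 <- st$intensities[, st$meta$day == 0]
  day7 <- st$intensities[, st$meta$day == 7]
  expect_equal(day7, day0, tolerance = 0)
})

test_that("zero-noise decay follows the linear law: day-7/day-0 ratio 0.78 at r = 0.22", {
  pr <- profile_with("CML176", r = 0.22, amp_cv = 0, add_sd_frac = 0)
  st <- preprocess_study(synth_study(pr, small_design(), seed = 1))
  amp <- vapply(0:7, function(d)
    band_amplitude(get_spectrum(st, which(st$meta$day == d & st$meta$treatment == "drought")[1])),
    0)
  expect_equal(amp[8] / amp[1], 0.78, tolerance = 1e-6)
  # whole schedule is linear in the measured observable
  expect_lt(max(abs(amp / amp[1] - (1 - 0.22 * (0:7) / 7))), 1e-8)
})

test_that("designs not starting at day 0 are rejected", {
  expect_error(study_design(days = 1:7), "starting at 0")
  expect_error(study_design(days = c(0, 2, 3)), "contiguous")
  expect_error(study_design(treatments = "mannitol"), "subset")
})

test_that("same seed reproduces a study bit for bit; different seeds differ", {
  pr <- profile_with("lox4")
  a <- synth_study(pr, small_design(days = 0:1), seed = 9)
  b <- synth_study(pr, small_design(days = 0:1), seed = 9)
  c <- synth_study(pr, small_design(days = 0:1), seed = 10)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("packaged profiles encode the printed degradation rates and amplitudes", {
  profs <- default_profiles()
  expect_equal(profs[["CML176"]]$degradation$drought, 0.22)
  expect_equal(profs[["OH28"]]$degradation$drought, 0.20)
  expect_equal(profs[["B73"]]$degradation$drought, 0.06)
  expect_equal(profs[["lox2"]]$degradation$drought, 0.10)
  expect_equal(profs[["lox4"]]$degradation$drought, 0.03)
  expect_true(all(vapply(profs, function(p) p$degradation$control, 0) == 0))
  # near-isogenic lines start at the same signal strength as B73
  expect_equal(profs[["lox2"]]$amp0, profs[["B73"]]$amp0)
  expect_equal(profs[["lox4"]]$amp0, profs[["B73"]]$amp0)
  # inbreds have pairwise distinct initial amplitudes
  inbred <- c(profs[["CML176"]]$amp0, profs[["OH28"]]$amp0, profs[["B73"]]$amp0)
  expect_equal(anyDuplicated(inbred), 0L)
})

test_that("osmotic kinetics validate their table and floor", {
  expect_error(osmotic_kinetics(c("100" = 5, "250" = 9)), "decreasing")
  expect_error(osmotic_kinetics(floor = 1), "floor")
  kin <- default_kinetics()
  expect_true(all(diff(kin$half_life_min) < 0))
  expect_gte(kin$floor, 0)
})

test_that("map series follow the exponential-floor law exactly when noiseless", {
  kin <- osmotic_kinetics(c("100" = 9, "150" = 5.5, "250" = 5), floor = 0,
                          spatial_cv = 0)
  ser <- synth_map_series(kin, 250, "XY80", timepoints = c(NA, 5),
                          profile = profile_with("B73", amp_cv = 0, add_sd_frac = 0),
                          seed = 1, noise = FALSE)
  sh <- ramandrought:::profile_shapes(profile_with("B73"), wn)
  base <- sh$background + sh$const
  i <- which(wn == 1157)
  ratio <- (ser[["5"]]$intensities[i, ] - base[i]) / (ser[["pre"]]$intensities[i, ] - base[i])
  # half-life 5 min, t = 5, floor 0 -> exactly one half
  expect_equal(ratio, rep(0.5, 80), tolerance = 1e-12)
  expect_equal(ser[["5"]]$meta$expected_ratio, 0.5, tolerance = 1e-15)
})

test_that("map grids have the documented point counts and reject unknown concentrations", {
  expect_equal(n_points(synth_map_series(conc = 150, grid = "XY80",
                                         timepoints = NA, seed = 1)[["pre"]]), 80L)
  expect_equal(n_points(synth_map_series(conc = 150, grid = "XZ30",
                                         timepoints = NA, seed = 1)[["pre"]]), 30L)
  expect_error(synth_map_series(conc = 42, timepoints = NA, seed = 1),
               "unknown mannitol concentration")
})

test_that("the water control does not decay: every timepoint matches pre within noise", {
  ser <- synth_map_series(conc = 0, grid = "XY80", seed = 8)
  imaps <- lapply(ser, band_intensity_map)
  pre <- mean(imaps[["pre"]]$values)
  for (nm in setdiff(names(imaps), "pre")) {
    v <- imaps[[nm]]$values
    expect_lt(abs(mean(v) - pre), 3 * sd(v) / sqrt(length(v)) + 0.02 * pre)
  }
})

test_that("expected decay is monotone: later timepoints and higher concentrations lower", {
  kin <- default_kinetics()
  for (conc in c(100, 150, 250)) {
    ser <- synth_map_series(kin, conc, "XZ30", seed = 2)
    r <- vapply(ser, function(m) m$meta$expected_ratio, 0)
    expect_true(all(diff(r[c("0", "5", "15", "30", "45")]) < 0))
  }
  r5 <- vapply(c(100, 150, 250), function(conc) {
    hl <- kin$half_life_min[[as.character(conc)]]
    kin$floor + (1 - kin$floor) * 2^(-5 / hl)
  }, 0)
  expect_true(all(diff(r5) < 0))
})
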