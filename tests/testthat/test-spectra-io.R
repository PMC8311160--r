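test_that("spectrum construction enforces the type invariants", {
  expect_s3_class(raman_spectrum(1000:1002, c(1, 2, 3)), "raman_spectrum")
  expect_error(raman_spectrum(1:3, 1:4), "length")
  expect_error(raman_spectrum(c(1000, 1002, 1001), 1:3), "strictly increasing")
  expect_error(raman_spectrum(c(1000, 1000, 1001), 1:3), "strictly increasing")
  expect_error(raman_spectrum(1:3, c(1, NA, 3)), "finite")
  expect_error(raman_spectrum(1:3, c(1, Inf, 3)), "finite")
  expect_error(raman_spectrum(1:3, 1:3, meta = list(treatment = "flooded")),
               "unknown treatment")
  expect_error(raman_spectrum(1:3, 1:3, meta = list(day = -1)), "day")
  expect_error(raman_spectrum(1:3, 1:3, meta = list(tissue = "blue")), "tissue")
  # mannitol labels are valid treatments
  expect_silent(raman_spectrum(1:3, 1:3, meta = list(treatment = "mannitol:250")))
})

test_that("map construction requires a shared grid, unique positions and matching counts", {
  wn <- 1000:1004
  Y <- matrix(1, 5, 3)
  pos <- data.frame(x_um = c(0, 10, 20), y_um = 0)
  expect_s3_class(raman_map(wn, Y, pos, "XY"), "raman_map")
  expect_error(raman_map(wn, Y[1:4, ], pos, "XY"), "row per wavenumber")
  expect_error(raman_map(wn, Y, pos[1:2, ], "XY"), "position row per spectrum")
  pos_dup <- data.frame(x_um = c(0, 10, 10), y_um = 0)
  expect_error(raman_map(wn, Y, pos_dup, "XY"), "unique")
  expect_error(raman_map(wn, Y, data.frame(x_um = 1:3, y_um = 0), "XZ"), "z_um")
})

test_that("study construction demands contiguous day ranges starting at 0", {
  wn <- 1000:1004
  meta <- data.frame(sample_id = c("a", "b"), genotype = "B73",
                     treatment = "drought", replicate = 1, plant = 1, day = c(0, 1))
  expect_s3_class(raman_study(wn, matrix(1, 5, 2), meta), "raman_study")
  meta$day <- c(1, 2)
  expect_error(raman_study(wn, matrix(1, 5, 2), meta), "contiguous")
  meta$day <- c(0, 2)
  expect_error(raman_study(wn, matrix(1, 5, 2), meta), "contiguous")
})

test_that("a 3-point CSV parses into the expected spectrum", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,wavenumber_cm1,intensity",
               "s1,1000,1", "s1,1001,2", "s1,1002,3"), f)
  sp <- read_spectra(f)
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$wavenumbers, c(1000, 1001, 1002))
  expect_equal(sp[[1]]$intensities, c(1, 2, 3))
})

test_that("write then read is the identity on point spectra", {
  s <- synth_spectrum(profile_with("B73"), seed = 7)
  s$meta$treatment <- "drought"; s$meta$day <- 3; s$meta$replicate <- 2
  f <- tempfile(fileext = ".csv")
  write_spectra(s, f)
  s2 <- read_spectra(f)[[1]]
  expect_lt(max(abs(s2$intensities - s$intensities)) / max(abs(s$intensities)), 1e-9)
  expect_identical(s2$wavenumbers, s$wavenumbers)
  expect_identical(s2$meta$treatment, "drought")
  expect_identical(s2$meta$day, 3L)
  expect_identical(s2$meta$replicate, 2L)
  expect_identical(s2$meta$genotype, "B73")
})

test_that("write then read is the identity on maps, including the axis field", {
  m <- synth_map_series(conc = 250, grid = "XZ30", timepoints = c(NA, 5), seed = 3)[["5"]]
  f <- tempfile(fileext = ".csv")
  write_spectra(m, f)
  expect_match(paste(readLines(f, n = 2), collapse = ""), "XZ")
  m2 <- read_spectra(f, "map_csv")
  expect_identical(m2$axis, "XZ")
  expect_equal(n_points(m2), 30L)
  expect_lt(max(abs(m2$intensities - m$intensities)) / max(abs(m$intensities)), 1e-9)
  expect_equal(m2$positions$x_um, m$positions$x_um)
  expect_equal(m2$positions$z_um, m$positions$z_um)
  expect_equal(m2$meta$timepoint_min, 5)
  expect_identical(m2$meta$treatment, "mannitol:250")
})

test_that("a map CSV with 80 position rows on one grid yields an 80-point map", {
  m <- synth_map_series(conc = 100, grid = "XY80", timepoints = c(NA, 0), seed = 1)[["pre"]]
  f <- tempfile(fileext = ".csv")
  write_spectra(m, f)
  expect_equal(n_points(read_spectra(f, "map_csv")), 80L)
})

test_that("an empty list writes a header-only file that reads back empty", {
  f <- tempfile(fileext = ".csv")
  write_spectra(list(), f)
  expect_length(readLines(f), 1L)
  expect_length(read_spectra(f), 0L)
})

test_that("format errors name the offending row", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,wavenumber_cm1,intensity",
               "s1,1000,1", "s1,1001,2", "s1,999,3"), f)
  expect_error(read_spectra(f), "row 3")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,intensity", "s1,1"), f2)
  expect_error(read_spectra(f2), "missing columns")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,wavenumber_cm1,intensity,treatment",
               "s1,1000,1,flooded", "s1,1001,2,flooded"), f3)
  expect_error(read_spectra(f3), "unknown treatment")
})

test_that("a study round-trips through CSV and as_study", {
  pr <- profile_with("B73", amp_cv = 0, add_sd_frac = 0)
  st <- synth_study(pr, small_design(days = 0:1), seed = 1)
  f <- tempfile(fileext = ".csv")
  write_spectra(st, f)
  st2 <- as_study(read_spectra(f))
  expect_equal(dim(st2$intensities), dim(st$intensities))
  expect_lt(max(abs(st2$intensities - st$intensities)) / max(abs(st$intensities)), 1e-9)
  expect_equal(st2$meta$day, st$meta$day)
  expect_equal(st2$meta$genotype, st$meta$genotype)
})

test_that("manifests round-trip and resolve paths relative to their directory", {
  dir <- tempfile(); dir.create(dir)
  man <- list(files = data.frame(path = "spectra.csv", format = "csv"),
              design = list(replicates = 3, plants = 5),
              description = "demo")
  p <- file.path(dir, "manifest.json")
  write_manifest(man, p)
  m2 <- read_manifest(p)
  expect_equal(basename(m2$files$path), "spectra.csv")
  expect_equal(dirname(m2$files$path), normalizePath(dir))
  expect_equal(m2$design$replicates, 3L)
  expect_error(write_manifest(list(design = list()), p), "files")
})
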