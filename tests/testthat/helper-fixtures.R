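# shared fixtures: profiles with adjusted noise knobs and a bare-bones profile
# with no background and a single carotenoid band

profile_with <- function(name = "CML176", r = NULL, amp_cv = NULL, add_sd_frac = NULL) {
  pr <- default_profiles()[[name]]
  if (!is.null(r)) pr$degradation$drought <- r
  if (!is.null(amp_cv)) pr$amp_cv <- amp_cv
  if (!is.null(add_sd_frac)) pr$add_sd_frac <- add_sd_frac
  pr
}

bare_profile <- function(amp0 = 100, centers = 1157, hwhms = 8, rels = 1) {
  genotype_profile(
    "bare", "green", amp0 = amp0,
    degradation = list(control = 0, drought = 0),
    carotenoid_bands = data.frame(center = centers, hwhm = hwhms, rel_amp = rels),
    constant_bands = data.frame(label = character(), center = numeric(),
                                hwhm = numeric(), amp = numeric()),
    background = list(c0 = 0, c1 = 0, c2 = 0, c3 = 0,
                      gauss_amp = 0, gauss_center = 1050, gauss_sd = 300),
    amp_cv = 0, add_sd_frac = 0)
}

small_design <- function(...) {
  args <- utils::modifyList(
    list(replicates = 2, plants = 2, spectra_per_day = 2, days = 0:7), list(...))
  do.call(study_design, args)
}

band_1157 <- function() default_bands()[["carotenoid_1157"]]
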