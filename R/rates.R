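#' Relative degradation rate between two days
#'
#' The drought-phenotyping statistic: the percent decline of the carotenoid
#' band amplitude between the start and end of the water-withholding period,
#' `100 * (A(d_start) - A(d_end)) / A(d_start)`. Negative values mean the
#' amplitude rose.
#'
#' @param amplitudes Named numeric vector of mean band amplitudes; names are
#'   days.
#' @param d_start,d_end Days delimiting the interval (defaults 0 and 7).
#' @return Rate in percent.
#' @examples
#' degradation_rate(c("0" = 0.050, "7" = 0.039))  # 22
#' @export
degradation_rate <- function(amplitudes, d_start = 0, d_end = 7) {
  nm <- names(amplitudes)
  if (is.null(nm)) stop_validation("amplitudes must be named by day")
  if (!as.character(d_start) %in% nm)
    stop_validation("day ", d_start, " amplitude is missing")
  if (!as.character(d_end) %in% nm)
    stop_validation("day ", d_end, " amplitude is missing")
  a0 <- amplitudes[[as.character(d_start)]]
  a1 <- amplitudes[[as.character(d_end)]]
  if (is.na(a0) || is.na(a1))
    stop_validation("amplitudes must not be missing")
  if (a0 <= 0) stop_validation("amplitude at day ", d_start, " must be > 0")
  100 * (a0 - a1) / a0
}

#' Fit per-genotype carotenoid degradation rates
#'
#' The central estimator of the package. For every genotype x treatment group
#' it climbs the aggregation ladder of the in vivo design: mean band amplitude
#' of the 12 spectra per plant per day, mean over the plants of a replicate,
#' [degradation_rate()] per replicate from day `d_start` to `d_end`, then mean
#' and standard error over the replicate experiments (SE across replicates, not
#' plants).
#'
#' @param study A `raman_study`. Preprocessed automatically unless its
#'   `"preprocessed"` attribute is already set.
#' @param band [band_def()] to quantify (default the 1157 cm^-1 carotenoid
#'   band; 1524 cm^-1 is excluded from rate statistics because of the
#'   anthocyanin overlap).
#' @param d_start,d_end Days delimiting the rate interval (defaults 0 and 7,
#'   clipped to the study's last day if shorter).
#' @param params [preprocess_params()] used if preprocessing is needed.
#' @return An object of class `raman_rates` with components `rates` (one row
#'   per genotype x treatment: mean rate %, SE %, n replicates), `replicates`
#'   (per-replicate rates), `trajectories` (replicate-day mean amplitudes),
#'   `plant_amplitudes`, `band`, `d_start`, `d_end`.
#' @seealso [coef.raman_rates()], [summary.raman_rates()], [plot.raman_rates()]
#' @export
fit_rates <- function(study, band = default_bands()[["carotenoid_1157"]],
                      d_start = 0, d_end = 7, params = preprocess_params()) {
  stopifnot(inherits(study, "raman_study"), inherits(band, "band_def"))
  if (!isTRUE(attr(study, "preprocessed")))
    study <- preprocess_study(study, params)
  meta <- study$meta
  if (!nrow(meta)) stop_validation("empty study")
  if (!all(c(d_start, d_end) %in% meta$day))
    stop_validation("study lacks day ", d_start, " or day ", d_end)
  amp <- band_amplitude_matrix(study$intensities, study$wavenumbers, band)

  # plant-day means over the individual spectra
  key_pd <- interaction(meta$genotype, meta$treatment, meta$replicate,
                        meta$plant, meta$day, drop = TRUE)
  pd <- stats::aggregate(amp, by = list(key = key_pd), FUN = mean)
  info <- meta[!duplicated(key_pd),
               c("genotype", "treatment", "replicate", "plant", "day")]
  info <- info[match(pd$key, unique(key_pd)), ]
  pd <- cbind(info, amplitude = pd$x)

  # replicate-day means over plants
  rd <- stats::aggregate(pd$amplitude,
                         by = pd[, c("genotype", "treatment", "replicate", "day")],
                         FUN = mean)
  names(rd)[names(rd) == "x"] <- "amplitude"

  # per-replicate rates
  key_r <- interaction(rd$genotype, rd$treatment, rd$replicate, drop = TRUE)
  reps <- do.call(rbind, lapply(split(rd, key_r), function(g) {
    a <- stats::setNames(g$amplitude, g$day)
    data.frame(genotype = g$genotype[1L], treatment = g$treatment[1L],
               replicate = g$replicate[1L],
               rate = degradation_rate(a, d_start, d_end),
               stringsAsFactors = FALSE)
  }))
  rownames(reps) <- NULL

  key_g <- interaction(reps$genotype, reps$treatment, drop = TRUE)
  rates <- do.call(rbind, lapply(split(reps, key_g), function(g) {
    n <- nrow(g)
    data.frame(genotype = g$genotype[1L], treatment = g$treatment[1L],
               n_replicates = n, rate = mean(g$rate),
               se = if (n > 1L) stats::sd(g$rate) / sqrt(n) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL
  rates <- rates[order(rates$treatment, -rates$rate), ]

  structure(list(rates = rates, replicates = reps, trajectories = rd,
                 plant_amplitudes = pd, band = band,
                 d_start = d_start, d_end = d_end, call = match.call()),
            class = "raman_rates")
}

#' @export
print.raman_rates <- function(x, digits = 3, ...) {
  cat(sprintf("Relative carotenoid degradation rates (day %d to day %d), band %s\n",
              x$d_start, x$d_end, x$band$name))
  df <- x$rates
  df$rate <- round(df$rate, digits)
  df$se <- round(df$se, digits)
  names(df) <- c("genotype", "treatment", "n_rep", "rate_pct", "se_pct")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Mean stressed degradation rates
#'
#' @param object A `raman_rates` fit.
#' @param treatment Which treatment's rates to return (default `"drought"`).
#' @param ... Unused.
#' @return Named numeric vector of mean rates (%) per genotype, sorted
#'   decreasing (most drought-sensitive first).
#' @export
coef.raman_rates <- function(object, treatment = "drought", ...) {
  df <- object$rates[object$rates$treatment == treatment, ]
  stats::setNames(df$rate, df$genotype)
}

#' Summarise a degradation-rate fit
#'
#' Adds the one-way ANOVA comparing the per-replicate stressed rates across
#' genotypes and a Bartlett variance-homogeneity diagnostic.
#'
#' @param object A `raman_rates` fit.
#' @param treatment Treatment whose rates are compared (default `"drought"`).
#' @param ... Unused.
#' @return A `summary.raman_rates` list.
#' @export
summary.raman_rates <- function(object, treatment = "drought", ...) {
  reps <- object$replicates[object$replicates$treatment == treatment, ]
  groups <- split(reps$rate, reps$genotype)
  groups <- groups[vapply(groups, length, 0L) > 0L]
  anova <- if (length(groups) >= 2L && all(vapply(groups, length, 0L) >= 2L))
    one_way_anova(groups) else NULL
  bart <- if (length(groups) >= 2L && all(vapply(groups, length, 0L) >= 2L))
    variance_homogeneity(groups) else NULL
  structure(list(fit = object, treatment = treatment, anova = anova,
                 bartlett = bart),
            class = "summary.raman_rates")
}

#' @export
print.summary.raman_rates <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$anova)) {
    cat(sprintf("\nOne-way ANOVA of %s-group replicate rates across genotypes:\n",
                x$treatment))
    print(x$anova)
  }
  if (!is.null(x$bartlett))
    cat(sprintf("Bartlett variance-homogeneity diagnostic: K2 = %.3g, p = %.3g\n",
                x$bartlett$statistic, x$bartlett$p.value))
  invisible(x)
}

#' Plot replicate-mean amplitude trajectories
#'
#' One line per genotype x treatment x replicate; stressed groups fall from
#' day 0 to the end of the water-withholding period, controls stay level.
#'
#' @param x A `raman_rates` fit.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the wide day-by-series matrix plotted.
#' @export
plot.raman_rates <- function(x, ...) {
  tr <- x$trajectories
  series <- interaction(tr$genotype, tr$treatment, tr$replicate, drop = TRUE)
  days <- sort(unique(tr$day))
  m <- vapply(split(tr, series), function(g) g$amplitude[order(g$day)],
              numeric(length(days)))
  gt <- vapply(split(tr, series), function(g) g$genotype[1L], "")
  trt <- vapply(split(tr, series), function(g) g$treatment[1L], "")
  col <- as.integer(factor(gt))
  graphics::matplot(days, m, type = "b", pch = ifelse(trt == "control", 1, 19),
                    lty = ifelse(trt == "control", 2, 1), col = col,
                    xlab = "day", ylab = paste(x$band$name, "amplitude (normalized)"),
                    ...)
  graphics::legend("bottomleft", legend = unique(gt), col = unique(col),
                   lty = 1, bty = "n")
  invisible(m)
}

#' Classical one-way ANOVA
#'
#' Omnibus F test of equal group means, as used to compare genotype groups;
#' significance is declared at alpha = 0.05. Computed via `stats::lm`/`anova`.
#'
#' @param groups List (>= 2) of numeric vectors, each with >= 2 values.
#' @return An object of class `raman_anova`: list with `f`, `df` (between,
#'   within), `p_value`, `significant`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, df (2, 6)
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop_validation("need at least 2 groups")
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 2L)) stop_validation("every group needs at least 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  tab <- stats::anova(stats::lm(y ~ g))
  f <- tab$`F value`[1L]
  p <- tab$`Pr(>F)`[1L]
  structure(list(f = f, df = c(between = tab$Df[1L], within = tab$Df[2L]),
                 p_value = p, significant = is.finite(p) && p < 0.05),
            class = "raman_anova")
}

#' @export
print.raman_anova <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g%s\n", x$df[1L], x$df[2L], x$f,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Bartlett variance-homogeneity diagnostic
#'
#' Optional check that replicate experiments share a common variance.
#'
#' @param groups List of numeric vectors.
#' @return The `htest` result of [stats::bartlett.test()].
#' @export
variance_homogeneity <- function(groups) {
  stats::bartlett.test(groups)
}

#' Time for mapped band intensity to fall to a fraction of pre-treatment
#'
#' Scans a mannitol map series for the first sampled post-treatment timepoint
#' at which the mean mapped band amplitude is at or below `fraction` times the
#' pre-treatment mean.
#'
#' @param map_series List of `raman_map` objects including a pre-treatment map
#'   (`meta$timepoint_min` is `NA`); post-treatment timepoints must be
#'   ascending.
#' @param band [band_def()] quantified per pixel (default 1157 cm^-1).
#' @param fraction Threshold fraction of the pre-treatment mean (default 0.5).
#' @param params [preprocess_params()] for the per-pixel imaging preprocessing
#'   (baseline + smoothing, no normalization).
#' @return First crossing timepoint in minutes, or `NA_real_` if the threshold
#'   is never reached.
#' @export
time_to_fraction <- function(map_series, band = default_bands()[["carotenoid_1157"]],
                             fraction = 0.5, params = preprocess_params()) {
  stopifnot(is.list(map_series), all(vapply(map_series, inherits, TRUE, "raman_map")))
  tp <- vapply(map_series, function(m) m$meta$timepoint_min %||% NA_real_, 0)
  pre <- which(is.na(tp))
  if (!length(pre)) stop_validation("map series lacks a pre-treatment map")
  post <- which(!is.na(tp))
  post <- post[order(tp[post])]
  means <- vapply(map_series, function(m)
    mean(band_intensity_map(m, band, params)$values), 0)
  pre_mean <- mean(means[pre])
  for (i in post)
    if (means[i] <= fraction * pre_mean) return(unname(tp[i]))
  NA_real_
}
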