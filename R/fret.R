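#' Spectral parameters of the dual-channel FRET observable
#'
#' The forward model maps the mean number of acceptor-labelled drug molecules
#' per particle to donor-channel and FRET-channel intensities. In the linear
#' (weak-quench) regime each bound drug removes a fraction
#' `fret_efficiency_per_load` of donor emission and re-emits it in the FRET
#' channel; a fraction of the residual donor emission bleeds through into the
#' FRET channel.
#'
#' @param donor_brightness donor emission per particle at zero load,
#'   arbitrary intensity units.
#' @param fret_efficiency_per_load fractional donor quench per bound drug per
#'   particle (dimensionless, small).
#' @param donor_bleedthrough fraction of residual donor emission detected in
#'   the FRET channel.
#' @param gain_donor,gain_fret per-channel instrument multipliers.
#' @param max_load upper end of the calibrated loading range (drug per
#'   particle). The default keeps total quench at or below 10%, inside which
#'   the modelled ratio-load relation is linear to better than 1%.
#' @return object of class `spectral_params`.
#' @export
spectral_params <- function(donor_brightness = 1000,
                            fret_efficiency_per_load = 0.01,
                            donor_bleedthrough = 0.05,
                            gain_donor = 1, gain_fret = 1,
                            max_load = 10) {
  vals <- c(donor_brightness = donor_brightness,
            fret_efficiency_per_load = fret_efficiency_per_load,
            donor_bleedthrough = donor_bleedthrough,
            gain_donor = gain_donor, gain_fret = gain_fret,
            max_load = max_load)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all spectral parameters must be finite and >= 0", call. = FALSE)
  }
  if (fret_efficiency_per_load * max_load >= 1) {
    stop("fret_efficiency_per_load * max_load must stay below 1 (donor intensity must remain positive)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "spectral_params")
}

#' Forward model: loading to dual-channel intensities
#'
#' i_donor = gain_donor * conc * B * (1 - e*L);
#' i_fret  = gain_fret  * conc * B * (e*L + bleed * (1 - e*L)),
#' with B the donor brightness, e the per-load quench coefficient and L the
#' mean load. Donor intensity is strictly decreasing and FRET intensity
#' strictly increasing in load over the calibrated range.
#'
#' @param mean_load mean drug per particle (vectorized).
#' @param particle_conc relative particle concentration.
#' @param spectral a [spectral_params()].
#' @param time optional time stamps (s) carried into the result.
#' @return `data.frame` with columns `time_s`, `i_donor`, `i_fret`.
#' @export
predict_intensities <- function(mean_load, particle_conc = 1,
                                spectral = spectral_params(), time = 0) {
  stopifnot(inherits(spectral, "spectral_params"))
  if (any(mean_load < 0)) stop("mean_load must be >= 0", call. = FALSE)
  if (any(mean_load > spectral$max_load)) {
    stop(sprintf("mean_load exceeds the calibrated linear range [0, %g]",
                 spectral$max_load), call. = FALSE)
  }
  q <- 1 - spectral$fret_efficiency_per_load * mean_load
  base <- particle_conc * spectral$donor_brightness
  data.frame(
    time_s = rep_len(time, length(mean_load)),
    i_donor = spectral$gain_donor * base * q,
    i_fret = spectral$gain_fret * base *
      (spectral$fret_efficiency_per_load * mean_load + spectral$donor_bleedthrough * q)
  )
}

#' FRET ratio of a reading
#'
#' The FRET-channel intensity divided by the donor-channel intensity; the
#' assay's proxy for the fraction of drug still carrier-associated.
#'
#' @param reading `data.frame` with columns `i_donor` and `i_fret` (or two
#'   numeric vectors via `i_fret`).
#' @param i_fret FRET-channel intensities when `reading` is the donor vector.
#' @return dimensionless ratio(s).
#' @export
fret_ratio <- function(reading, i_fret = NULL) {
  if (is.data.frame(reading)) {
    i_donor <- reading$i_donor
    i_fret <- reading$i_fret
  } else {
    i_donor <- reading
  }
  if (any(i_donor <= 0)) stop("donor intensity must be > 0 to form a ratio", call. = FALSE)
  if (any(i_fret < 0)) stop("FRET intensity must be >= 0", call. = FALSE)
  i_fret / i_donor
}

#' Normalize a FRET-ratio series to a reference value
#'
#' @param series numeric ratio series.
#' @param reference `"first_point"` to divide by the first element, or
#'   `"pre_mix_value"` to divide by an externally measured pre-injection
#'   ratio given in `pre_mix_value`.
#' @param pre_mix_value the pre-mix reference ratio (required for
#'   `reference = "pre_mix_value"`).
#' @return series divided by the reference; equal to 1 at the reference.
#' @export
normalize_ratio_series <- function(series,
                                   reference = c("pre_mix_value", "first_point"),
                                   pre_mix_value = NULL) {
  reference <- match.arg(reference)
  ref <- if (reference == "first_point") {
    if (!length(series)) stop("empty series", call. = FALSE)
    series[1]
  } else {
    if (is.null(pre_mix_value)) stop("pre_mix_value required for reference = 'pre_mix_value'",
                                     call. = FALSE)
    pre_mix_value
  }
  if (!is.finite(ref) || ref <= 0) stop("normalization reference must be > 0", call. = FALSE)
  series / ref
}

#' Calibrate the linear FRET-ratio vs loading relation
#'
#' Ordinary least-squares line through (load, ratio) pairs, the calibration
#' used to convert measured FRET ratios into per-particle loading estimates.
#'
#' @param loads mean loads (>= 3 distinct values).
#' @param ratios measured FRET ratios, same length.
#' @return object of class `loading_calibration` with `slope`, `intercept`,
#'   `r_squared` and `valid_range` (the load interval spanned by the data).
#' @export
calibrate_loading <- function(loads, ratios) {
  if (length(loads) != length(ratios)) stop("loads and ratios differ in length", call. = FALSE)
  if (length(unique(loads)) < 3) {
    stop("calibration needs at least 3 distinct loading levels", call. = FALSE)
  }
  if (stats::var(loads) == 0) stop("loads have zero variance", call. = FALSE)
  fit <- stats::lm(ratios ~ loads)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive (ratio must increase with loading)", call. = FALSE)
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = .r_squared(ratios, stats::fitted(fit)),
                 valid_range = range(loads),
                 n = length(loads)),
            class = "loading_calibration")
}

#' @export
print.loading_calibration <- function(x, ...) {
  cat(sprintf("Loading calibration: ratio = %.6g + %.6g * load (r^2 = %.6f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  cat(sprintf("valid loading range: [%g, %g]\n", x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Predicted ratio / inverted loading on a calibration line
#'
#' `predict_ratio()` evaluates the calibration line; `invert_loading()` is its
#' exact inverse, so the round trip is the identity. Inversions landing
#' outside the calibrated loading range are returned with attribute
#' `extrapolated = TRUE` rather than refused.
#'
#' @param cal a [calibrate_loading()] result.
#' @param load,ratio values to convert (vectorized).
#' @return predicted ratio / estimated load.
#' @export
predict_ratio <- function(cal, load) {
  stopifnot(inherits(cal, "loading_calibration"))
  cal$intercept + cal$slope * load
}

#' @rdname predict_ratio
#' @export
invert_loading <- function(ratio, cal) {
  stopifnot(inherits(cal, "loading_calibration"))
  load <- (ratio - cal$intercept) / cal$slope
  extra <- load < cal$valid_range[1] | load > cal$valid_range[2]
  if (any(extra)) attr(load, "extrapolated") <- extra
  load
}
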