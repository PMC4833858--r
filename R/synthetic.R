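#' Instrument noise model for synthetic traces
#'
#' Noise stand-in for plate-reader kinetic measurements: an optional
#' common-mode photobleaching decay applied to both channels, then
#' independent multiplicative Gaussian noise per channel, then an additive
#' Gaussian floor. Identical seeds give identical traces.
#'
#' @param multiplicative_sigma fractional (CV) noise per reading.
#' @param additive_sigma additive noise, intensity units.
#' @param photobleach_rate common-mode decay rate, s^-1.
#' @param seed integer RNG seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sigma = 0.01, additive_sigma = 0,
                        photobleach_rate = 0, seed = 1L) {
  if (multiplicative_sigma < 0 || additive_sigma < 0 || photobleach_rate < 0) {
    stop("noise sigmas and photobleach rate must be >= 0", call. = FALSE)
  }
  structure(list(multiplicative_sigma = multiplicative_sigma,
                 additive_sigma = additive_sigma,
                 photobleach_rate = photobleach_rate,
                 seed = as.integer(seed)),
            class = "noise_model")
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Dual-channel kinetic trace
#'
#' Container for a time-stamped dual-channel fluorescence record with its
#' condition metadata, as produced by the generator or read from disk.
#'
#' @param times times, s, strictly increasing, first >= 0.
#' @param i_donor,i_fret channel intensities (>= 0).
#' @param condition list with `temperature_c`, `acceptor_medium`,
#'   `acceptor_fraction` (0..1), `particle_conc_mg_ml`.
#' @param label free-text label.
#' @param extra named list of additional metadata preserved on round trip.
#' @return object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, i_donor, i_fret,
                          condition = list(temperature_c = 37,
                                           acceptor_medium = "FBS",
                                           acceptor_fraction = 1,
                                           particle_conc_mg_ml = 1),
                          label = "", extra = list()) {
  if (length(times) != length(i_donor) || length(times) != length(i_fret)) {
    stop("times and intensities differ in length", call. = FALSE)
  }
  if (length(times) && times[1] < 0) stop("times must start at >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(i_donor < 0) || any(i_fret < 0)) stop("intensities must be >= 0", call. = FALSE)
  af <- condition$acceptor_fraction
  if (!is.null(af) && (af < 0 || af > 1)) {
    stop("acceptor_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(times = times, i_donor = i_donor, i_fret = i_fret,
                 condition = condition, label = label, extra = extra),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace '%s': %d points, %g-%g s\n", x$label,
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  %s at fraction %g, %g C\n",
              x$condition$acceptor_medium %||% "?",
              x$condition$acceptor_fraction %||% NA,
              x$condition$temperature_c %||% NA))
  invisible(x)
}

.apply_noise <- function(intensity, times, noise) {
  out <- intensity * exp(-noise$photobleach_rate * times)
  if (noise$multiplicative_sigma > 0) {
    out <- out * (1 + stats::rnorm(length(out), 0, noise$multiplicative_sigma))
  }
  if (noise$additive_sigma > 0) {
    out <- out + stats::rnorm(length(out), 0, noise$additive_sigma)
  }
  pmax(out, 0)
}

#' Generate a noisy kinetic trace with known ground truth
#'
#' Simulates the exchange system, maps the donor-bound fraction through the
#' FRET forward model, and applies the noise model (photobleach, then
#' multiplicative, then additive noise, independently per channel).
#'
#' @param system an [exchange_system()].
#' @param spectral a [spectral_params()].
#' @param noise a [noise_model()].
#' @param t_grid sampling times, s, from 0.
#' @param condition,label metadata stored on the trace.
#' @return a [kinetic_trace()] with attribute `truth`: the noise-free
#'   trajectory (pool amounts, intensities and FRET ratio).
#' @export
generate_trace <- function(system, spectral = spectral_params(),
                           noise = noise_model(), t_grid,
                           condition = NULL, label = "") {
  traj <- simulate_exchange(system, t_grid, spectral = spectral)
  if (is.null(condition)) {
    condition <- list(temperature_c = system$temperature_k - 273.15,
                      acceptor_medium = if (length(system$acceptors)) "FBS" else "PBS",
                      acceptor_fraction = if (length(system$acceptors)) 1 else 0,
                      particle_conc_mg_ml = 1)
  }
  noisy <- .with_seed(noise$seed, {
    list(i_donor = .apply_noise(traj$i_donor, traj$time_s, noise),
         i_fret = .apply_noise(traj$i_fret, traj$time_s, noise))
  })
  tr <- kinetic_trace(traj$time_s, noisy$i_donor, noisy$i_fret,
                      condition = condition, label = label)
  attr(tr, "truth") <- traj
  tr
}

#' Generate a loading-calibration series
#'
#' Replicated dual-channel readings of particles prepared at known mean
#' loads, with instrument noise; the noise-free columns are carried along so
#' exact recovery can be checked.
#'
#' @param loads mean loads (>= 3 values).
#' @param spectral a [spectral_params()].
#' @param noise a [noise_model()].
#' @param replicates readings per load.
#' @return `data.frame` with columns `load`, `replicate`, `i_donor`,
#'   `i_fret`, `ratio`, `i_donor_true`, `i_fret_true`, `ratio_true`.
#' @export
generate_calibration_series <- function(loads, spectral = spectral_params(),
                                        noise = noise_model(), replicates = 5) {
  if (length(loads) < 3) stop("need at least 3 loading levels", call. = FALSE)
  truth <- predict_intensities(loads, spectral = spectral)
  out <- .with_seed(noise$seed, {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      idn <- .apply_noise(truth$i_donor, 0, noise)
      ift <- .apply_noise(truth$i_fret, 0, noise)
      data.frame(load = loads, replicate = r, i_donor = idn, i_fret = ift)
    }))
  })
  out$ratio <- out$i_fret / out$i_donor
  out$i_donor_true <- rep(truth$i_donor, replicates)
  out$i_fret_true <- rep(truth$i_fret, replicates)
  out$ratio_true <- out$i_fret_true / out$i_donor_true
  out
}

#' Specification of a synthetic condition panel
#'
#' @param drugs archetype names (subset of [cy7_archetypes()]).
#' @param serum_fractions serum volume fractions in 0..1.
#' @param temperatures_c temperatures, Celsius.
#' @param duration_s trace duration, s.
#' @param interval_s sampling interval, s (plate-reader kinetic mode).
#' @param medium acceptor medium for all traces.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(drugs = c("CA", "C12", "OLA", "PLGA2k"),
                       serum_fractions = c(0.05, 0.10, 0.25, 0.50, 1.00),
                       temperatures_c = c(25, 31, 37, 41),
                       duration_s = 86400, interval_s = 120,
                       medium = "FBS") {
  if (interval_s <= 0) stop("interval_s must be > 0", call. = FALSE)
  if (duration_s < 10 * interval_s) {
    stop("duration must cover at least 10 sampling intervals", call. = FALSE)
  }
  unknown <- setdiff(drugs, cy7_archetypes()$drug)
  if (length(unknown)) {
    stop(sprintf("unknown archetype(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(drugs = drugs, serum_fractions = serum_fractions,
                 temperatures_c = temperatures_c,
                 duration_s = duration_s, interval_s = interval_s,
                 medium = medium),
            class = "panel_spec")
}

# ground-truth half-life of the noise-free observable: dense scan of the
# bound amount toward its stationary value, linear interpolation at crossing
.true_half_life <- function(system, horizon) {
  eq <- equilibrium_distribution(system)
  b_inf <- system$total_drug * (eq["surface"] + eq["core"])
  b0 <- system$state0["surface"] + system$state0["core"]
  if (b0 <= b_inf) return(NA_real_)
  target <- b_inf + (b0 - b_inf) / 2
  tg <- unique(c(0, exp(seq(log(1), log(horizon), length.out = 600))))
  traj <- simulate_exchange(system, tg)
  bound <- traj$surface + traj$core
  below <- which(bound <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(0)
  t1 <- traj$time_s[i - 1]; t2 <- traj$time_s[i]
  b1 <- bound[i - 1]; b2 <- bound[i]
  t1 + (b1 - target) / (b1 - b2) * (t2 - t1)
}

#' Generate a full synthetic condition panel
#'
#' One noisy trace per (drug x serum fraction x temperature) combination with
#' descriptor-mapped mechanism parameters, written to `out_dir` together
#' with a manifest CSV linking each file to its ground truth (true rates,
#' core fraction and half-life of the noise-free observable) and a
#' ground-truth JSON.
#'
#' @param spec a [panel_spec()].
#' @param noise a [noise_model()]; each trace gets a sub-seed derived from
#'   `noise$seed`.
#' @param out_dir output directory (created if missing).
#' @param spectral a [spectral_params()].
#' @return the manifest `data.frame`, invisibly; files on disk.
#' @export
generate_panel <- function(spec, noise = noise_model(), out_dir,
                           spectral = spectral_params()) {
  stopifnot(inherits(spec, "panel_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_grid <- seq(0, spec$duration_s, by = spec$interval_s)
  grid <- expand.grid(drug = spec$drugs,
                      serum_fraction = spec$serum_fractions,
                      temperature_c = spec$temperatures_c,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sys <- archetype_system(g$drug, medium = spec$medium,
                            acceptor_fraction = g$serum_fraction,
                            temperature_c = g$temperature_c)
    sub_noise <- noise
    sub_noise$seed <- (noise$seed * 1000L + i) %% .Machine$integer.max
    label <- sprintf("%s_f%03d_T%02d", g$drug,
                     round(100 * g$serum_fraction), round(g$temperature_c))
    cond <- list(temperature_c = g$temperature_c,
                 acceptor_medium = spec$medium,
                 acceptor_fraction = g$serum_fraction,
                 particle_conc_mg_ml = 1)
    tr <- generate_trace(sys, spectral, sub_noise, t_grid,
                         condition = cond, label = label)
    file <- file.path(out_dir, paste0(label, ".csv"))
    write_trace(tr, file)
    surf <- sys$donor$surface_pool
    core <- sys$donor$core_pool
    rows[[i]] <- data.frame(
      file = basename(file), label = label,
      drug = g$drug, serum_fraction = g$serum_fraction,
      temperature_c = g$temperature_c,
      k_off_surface = .pool_koff(surf, sys$temperature_k),
      k_off_core = .pool_koff(core, sys$temperature_k),
      core_fraction = sys$donor$core_fraction_initial,
      true_half_life_s = .true_half_life(sys, 50 * spec$duration_s),
      seed = sub_noise$seed,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(spec),
         noise = unclass(noise),
         traces = manifest),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' End-point drug distribution across pools
#'
#' Snapshot of the per-pool drug fractions after incubating the system for
#' `t_end` seconds — the simulated counterpart of an end-point
#' chromatographic analysis of a particle-serum mixture.
#'
#' @param system an [exchange_system()].
#' @param t_end incubation time, s (default 2 h).
#' @return `data.frame` with columns `pool` and `fraction` (sums to 1).
#' @export
generate_pool_snapshot <- function(system, t_end = 7200) {
  traj <- simulate_exchange(system, c(0, t_end))
  amounts <- unlist(traj[nrow(traj), setdiff(names(traj), "time_s")])
  data.frame(pool = names(amounts),
             fraction = as.numeric(amounts) / sum(amounts),
             stringsAsFactors = FALSE)
}
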