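#' Arrhenius temperature scaling of a rate constant
#'
#' k(T) = k_ref * exp(-(Ea/R) (1/T - 1/T_ref)); equal to `k_ref` at the
#' reference temperature and increasing with temperature for positive
#' activation energy.
#'
#' @param k_ref rate at the reference temperature, s^-1.
#' @param ea_kj_mol activation energy, kJ mol^-1.
#' @param temperature_k target temperature, K.
#' @param t_ref_k reference temperature, K.
#' @return rate at `temperature_k`, s^-1.
#' @examples
#' arrhenius_rate(1e-3, 60, 310.15, 298.15)  # ~2.55e-3
#' @export
arrhenius_rate <- function(k_ref, ea_kj_mol, temperature_k, t_ref_k) {
  .assert_scalar_positive(temperature_k, "temperature_k")
  .assert_scalar_positive(t_ref_k, "t_ref_k")
  if (any(k_ref < 0)) stop("k_ref must be >= 0", call. = FALSE)
  k_ref * exp(-(ea_kj_mol * 1000 / R_GAS) * (1 / temperature_k - 1 / t_ref_k))
}

#' Drug acceptor pool
#'
#' A pool of binding sites competing for free drug: a serum protein fraction
#' (albumin, gamma-globulin, HDL, LDL), another particle population, or one
#' of the donor particle's own sub-pools. Exchange is mass-action through a
#' free-drug intermediate: capture at `capture_rate * site_concentration *
#' free` and first-order release at the Arrhenius-scaled dissociation rate.
#'
#' @param name pool label.
#' @param site_concentration_um binding-site concentration, uM.
#' @param capture_rate association rate of free drug, per uM per s.
#' @param release_rate_ref dissociation rate at `t_ref_k`, s^-1.
#' @param ea_off_kj_mol dissociation activation energy, kJ mol^-1.
#' @param t_ref_k reference temperature for `release_rate_ref`, K.
#' @return object of class `acceptor_pool`.
#' @export
acceptor_pool <- function(name, site_concentration_um, capture_rate,
                          release_rate_ref, ea_off_kj_mol,
                          t_ref_k = celsius_to_kelvin(37)) {
  vals <- c(site_concentration_um = site_concentration_um,
            capture_rate = capture_rate,
            release_rate_ref = release_rate_ref,
            ea_off_kj_mol = ea_off_kj_mol)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop(sprintf("pool '%s': rates, concentrations and Ea must be finite and >= 0", name),
         call. = FALSE)
  }
  structure(list(name = name,
                 site_concentration_um = site_concentration_um,
                 capture_rate = capture_rate,
                 release_rate_ref = release_rate_ref,
                 ea_off_kj_mol = ea_off_kj_mol,
                 t_ref_k = t_ref_k),
            class = "acceptor_pool")
}

#' Donor nanoparticle sub-pools
#'
#' The donor particle carries drug in two sub-pools: an interface (surface)
#' pool of weakly held drug at the core-corona boundary, and a core pool of
#' matrix-embedded drug. The core must release no faster than the surface.
#'
#' @param surface_pool,core_pool [acceptor_pool()] records for the two
#'   sub-pools.
#' @param core_fraction_initial fraction of loaded drug starting in the core
#'   (used by the `"loaded"` initialization of [exchange_system()]).
#' @return object of class `donor_particle_pools`.
#' @export
donor_particle_pools <- function(surface_pool, core_pool,
                                 core_fraction_initial = 0.5) {
  stopifnot(inherits(surface_pool, "acceptor_pool"),
            inherits(core_pool, "acceptor_pool"))
  if (core_pool$release_rate_ref > surface_pool$release_rate_ref) {
    stop("core release rate must not exceed surface release rate", call. = FALSE)
  }
  if (core_fraction_initial < 0 || core_fraction_initial > 1) {
    stop("core_fraction_initial must lie in [0, 1]", call. = FALSE)
  }
  structure(list(surface_pool = surface_pool, core_pool = core_pool,
                 core_fraction_initial = core_fraction_initial),
            class = "donor_particle_pools")
}

#' Assemble a drug-exchange system
#'
#' Combines donor sub-pools, competing acceptor pools, temperature and total
#' drug into the mass-action system integrated by [simulate_exchange()].
#' State variables are the drug amounts in each pool plus the free
#' intermediate; binding sites are assumed far from saturation so all rates
#' are linear in the state.
#'
#' Initialization `"preequilibrated"` (default) starts from the stationary
#' state of the donor-only system — the particle stock equilibrated in buffer
#' before acceptors are introduced, which is why a system with no acceptors
#' shows no net release. `"loaded"` starts with all drug bound, split by
#' `core_fraction_initial`, and free drug zero.
#'
#' @param donor a [donor_particle_pools()].
#' @param acceptors list of [acceptor_pool()] (possibly empty = buffer only).
#' @param temperature_c temperature, Celsius.
#' @param total_drug total drug amount (conserved; arbitrary units).
#' @param mean_load0 mean drug per particle corresponding to the initially
#'   bound amount, for the FRET observable.
#' @param init `"preequilibrated"` or `"loaded"`.
#' @return object of class `exchange_system`.
#' @export
exchange_system <- function(donor, acceptors = list(),
                            temperature_c = 37, total_drug = 1,
                            mean_load0 = 5,
                            init = c("preequilibrated", "loaded")) {
  init <- match.arg(init)
  stopifnot(inherits(donor, "donor_particle_pools"))
  if (inherits(acceptors, "acceptor_pool")) acceptors <- list(acceptors)
  ok <- vapply(acceptors, inherits, logical(1), "acceptor_pool")
  if (!all(ok)) stop("`acceptors` must be a list of acceptor_pool objects", call. = FALSE)
  .assert_scalar_positive(total_drug, "total_drug")
  tk <- celsius_to_kelvin(temperature_c)
  .assert_scalar_positive(tk, "temperature (K)")
  sys <- structure(list(donor = donor, acceptors = acceptors,
                        temperature_k = tk, total_drug = total_drug,
                        mean_load0 = mean_load0, init = init),
                   class = "exchange_system")
  sys$state0 <- .initial_state(sys)
  sys
}

#' @export
print.exchange_system <- function(x, ...) {
  cat(sprintf("Exchange system at %.2f K, total drug %g\n", x$temperature_k, x$total_drug))
  cat(sprintf("  donor: surface k_off(T) = %.3g s^-1, core k_off(T) = %.3g s^-1\n",
              .pool_koff(x$donor$surface_pool, x$temperature_k),
              .pool_koff(x$donor$core_pool, x$temperature_k)))
  for (a in x$acceptors) {
    cat(sprintf("  acceptor %s: %g uM sites\n", a$name, a$site_concentration_um))
  }
  invisible(x)
}

.pool_koff <- function(pool, temperature_k) {
  arrhenius_rate(pool$release_rate_ref, pool$ea_off_kj_mol,
                 temperature_k, pool$t_ref_k)
}

.pool_kcap <- function(pool) pool$capture_rate * pool$site_concentration_um

.system_pools <- function(system) {
  c(list(surface = system$donor$surface_pool, core = system$donor$core_pool),
    stats::setNames(system$acceptors,
                    vapply(system$acceptors, `[[`, character(1), "name")))
}

#' Mass-action rate matrix of an exchange system
#'
#' Encodes the linear system dx/dt = A x with state
#' (surface, core, acceptor_1..n, free). Every column of A sums to zero, so
#' total drug is conserved by construction.
#'
#' @param system an [exchange_system()].
#' @return square matrix with named dimnames; the free intermediate is the
#'   last state.
#' @export
build_rate_matrix <- function(system) {
  stopifnot(inherits(system, "exchange_system"))
  pools <- .system_pools(system)
  np <- length(pools)
  nm <- c(names(pools), "free")
  A <- matrix(0, np + 1, np + 1, dimnames = list(nm, nm))
  for (i in seq_len(np)) {
    koff <- .pool_koff(pools[[i]], system$temperature_k)
    kcap <- .pool_kcap(pools[[i]])
    A[i, i] <- -koff          # release out of pool i
    A[np + 1, i] <- koff      # ... into the free state
    A[i, np + 1] <- kcap      # capture of free drug by pool i
  }
  A[np + 1, np + 1] <- -sum(A[seq_len(np), np + 1])
  A
}

.initial_state <- function(system) {
  pools <- .system_pools(system)
  nm <- c(names(pools), "free")
  x0 <- stats::setNames(numeric(length(nm)), nm)
  d <- system$donor
  if (system$init == "loaded") {
    x0["core"] <- system$total_drug * d$core_fraction_initial
    x0["surface"] <- system$total_drug * (1 - d$core_fraction_initial)
    return(x0)
  }
  # donor-only stationary state: pool_i : free = capture_i / k_off_i
  k <- vapply(list(d$surface_pool, d$core_pool), function(p) {
    koff <- .pool_koff(p, system$temperature_k)
    kcap <- .pool_kcap(p)
    if (koff == 0 && kcap > 0) return(Inf)
    if (kcap == 0) return(0)
    kcap / koff
  }, numeric(1))
  if (any(is.infinite(k))) {
    # a non-releasing donor pool absorbs everything it can reach
    w <- c(is.infinite(k[1]), is.infinite(k[2]))
    x0["surface"] <- system$total_drug * w[1] / sum(w)
    x0["core"] <- system$total_drug * w[2] / sum(w)
    return(x0)
  }
  denom <- 1 + sum(k)
  x0["free"] <- system$total_drug / denom
  x0["surface"] <- system$total_drug * k[1] / denom
  x0["core"] <- system$total_drug * k[2] / denom
  x0
}

#' Simulate drug exchange
#'
#' Integrates the mass-action system on a time grid with a stiff-capable
#' solver (`deSolve::lsoda`, analytic constant Jacobian, tight tolerances).
#' If spectral parameters are given, the FRET observable is attached: the
#' mean per-particle load is the initially bound load scaled by the current
#' donor-bound fraction, pushed through [predict_intensities()] and
#' [fret_ratio()].
#'
#' @param system an [exchange_system()].
#' @param t_grid output times, s, strictly increasing from 0.
#' @param spectral optional [spectral_params()] for the observable.
#' @return `data.frame` of class `exchange_trajectory`: `time_s`, one column
#'   per pool, `free`, and (with `spectral`) `fret_ratio`.
#' @export
simulate_exchange <- function(system, t_grid, spectral = NULL) {
  stopifnot(inherits(system, "exchange_system"))
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing and start at 0", call. = FALSE)
  }
  A <- build_rate_matrix(system)
  x0 <- system$state0
  sol <- deSolve::ode(
    y = x0, times = t_grid,
    func = function(t, y, parms) list(parms %*% y),
    parms = A,
    jacfunc = function(t, y, parms) parms,
    jactype = "fullusr",
    method = "lsoda",
    rtol = 1e-12, atol = 1e-14 * system$total_drug)
  if (attr(sol, "istate")[1] < 0) {
    stop("stiff integration of the exchange system failed (lsoda istate < 0)",
         call. = FALSE)
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time_s"
  if (!is.null(spectral)) {
    bound0 <- x0["surface"] + x0["core"]
    if (bound0 <= 0) stop("no drug bound to the donor at t = 0", call. = FALSE)
    load <- system$mean_load0 * (out$surface + out$core) / bound0
    inten <- predict_intensities(load, particle_conc = 1, spectral = spectral,
                                 time = out$time_s)
    out$i_donor <- inten$i_donor
    out$i_fret <- inten$i_fret
    out$fret_ratio <- fret_ratio(inten)
  }
  attr(out, "system") <- system
  class(out) <- c("exchange_trajectory", "data.frame")
  out
}

#' Stationary drug distribution of an exchange system
#'
#' The unique stationary state of the linear mass-action system, from the
#' null space of the rate matrix, scaled to total drug. Errors when the
#' stationary distribution is degenerate (all rates zero) or not unique
#' (e.g. two absorbing pools).
#'
#' @param system an [exchange_system()].
#' @return named vector of per-pool fractions summing to 1 (free included).
#' @export
equilibrium_distribution <- function(system) {
  A <- build_rate_matrix(system)
  if (all(A == 0)) stop("all rates are zero: stationary distribution undefined", call. = FALSE)
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps * 100
  null_dim <- sum(sv$d < tol)
  if (null_dim == 0) stop("no stationary state found (numerical rank deficiency missing)",
                          call. = FALSE)
  if (null_dim > 1) {
    stop("stationary distribution is not unique (disconnected or multiple absorbing pools)",
         call. = FALSE)
  }
  v <- sv$v[, ncol(A)]
  if (max(v) < 0) v <- -v
  if (min(v) < -1e-10 * max(abs(v))) {
    stop("null vector has mixed signs; system is not a valid rate system", call. = FALSE)
  }
  v[v < 0] <- 0
  stats::setNames(v / sum(v), colnames(A))
}

#' Descriptor-to-mechanism mapping for a drug
#'
#' Maps the two compatibility descriptors onto exchange-mechanism parameters:
#' the surface-pool dissociation activation energy grows linearly with
#' hydrophobicity (`ea_off = ea0 + ea_slope * logd`), and the core-loaded
#' fraction follows a falling logistic in the interaction parameter
#' (`core_fraction = 1 / (1 + exp(s * (chi - chi0)))`) — miscible drugs
#' disperse in the core, poorly miscible ones sit at the interface.
#'
#' @param logd hydrophobicity descriptor.
#' @param chi Flory-Huggins interaction parameter with the matrix polymer.
#' @param ea0 intercept of the activation-energy map, kJ mol^-1.
#' @param ea_slope slope, kJ mol^-1 per log D unit (must be >= 0).
#' @param s steepness of the core-fraction logistic (must be >= 0).
#' @param chi0 midpoint of the logistic.
#' @return object of class `drug_descriptor_map`.
#' @export
drug_descriptor_map <- function(logd, chi, ea0 = 62.5, ea_slope = 1.5,
                                s = 3, chi0 = 1.5) {
  if (ea_slope < 0) stop("ea_slope must be >= 0 (hydrophobicity raises the barrier)",
                         call. = FALSE)
  if (s < 0) stop("s must be >= 0 (core fraction decreasing in chi)", call. = FALSE)
  structure(list(logd = logd, chi = chi, ea0 = ea0, ea_slope = ea_slope,
                 s = s, chi0 = chi0),
            class = "drug_descriptor_map")
}

#' Default mechanism constants
#'
#' Calibration constants of the descriptor mapping and donor pools: an
#' attempt frequency for dissociation, the core-pool activation energy, the
#' donor binding-site concentration and capture rate, and the reference
#' temperature. These are package calibration constants chosen so the four
#' model-drug archetypes span minutes-to-hours half-lives in full serum at
#' 37 C; they are not measured values.
#'
#' @return named list.
#' @export
exchange_base_config <- function() {
  list(attempt_frequency = 1e9,   # s^-1
       ea_core_kj_mol = 80,
       donor_site_um = 10,
       donor_capture_rate = 0.01, # per uM per s
       core_capture_scale = NULL, # derived from the core fraction
       t_ref_k = celsius_to_kelvin(37))
}

#' Map drug descriptors to donor-particle pools
#'
#' Builds the donor sub-pools for a drug from its descriptors. Dissociation
#' rates follow the absolute Arrhenius form k = A exp(-Ea/(R T_ref)) with a
#' common attempt frequency, so a higher barrier always means slower release
#' at every temperature. Core capture is set so the donor-only stationary
#' bound split reproduces the descriptor-mapped core fraction (the loading
#' split is the drug's equilibrium preference).
#'
#' @param desc a [drug_descriptor_map()].
#' @param base a [exchange_base_config()] list.
#' @return a [donor_particle_pools()].
#' @export
map_descriptors_to_params <- function(desc, base = exchange_base_config()) {
  stopifnot(inherits(desc, "drug_descriptor_map"))
  ea_surf <- desc$ea0 + desc$ea_slope * desc$logd
  ea_core <- base$ea_core_kj_mol
  if (ea_surf > ea_core) {
    stop(sprintf("surface barrier (%.1f kJ/mol) exceeds the core barrier (%.1f kJ/mol); raise ea_core_kj_mol",
                 ea_surf, ea_core), call. = FALSE)
  }
  k_at <- function(ea) base$attempt_frequency * exp(-ea * 1000 / (R_GAS * base$t_ref_k))
  k_surf <- k_at(ea_surf)
  k_core <- k_at(ea_core)
  f_core <- 1 / (1 + exp(desc$s * (desc$chi - desc$chi0)))
  f_core <- min(max(f_core, 1e-6), 1 - 1e-6)
  cap_s <- base$donor_capture_rate
  # detailed balance: core-bound / surface-bound = (cap_c/k_core)/(cap_s/k_surf)
  cap_c <- cap_s * (f_core / (1 - f_core)) * (k_core / k_surf)
  surface <- acceptor_pool("surface", base$donor_site_um, cap_s,
                           k_surf, ea_surf, base$t_ref_k)
  core <- acceptor_pool("core", base$donor_site_um, cap_c,
                        k_core, ea_core, base$t_ref_k)
  donor_particle_pools(surface, core, core_fraction_initial = f_core)
}

#' Model-drug descriptor archetypes
#'
#' Stand-in descriptor values for the four dye-conjugate model drugs:
#' hydrophobicity rising with alkyl tail length (CA < C12 < OLA) and
#' miscibility with the matrix polymer best for the oligomer conjugate
#' (PLGA2k, lowest chi). Documented defaults, not measured values.
#'
#' @return `data.frame` with columns `drug`, `logd`, `chi`.
#' @export
cy7_archetypes <- function() {
  data.frame(drug = c("CA", "C12", "OLA", "PLGA2k"),
             logd = c(3, 6, 8.5, 4),
             chi = c(3.5, 3.0, 2.5, 0.3),
             stringsAsFactors = FALSE)
}

#' Default serum acceptor pools
#'
#' Illustrative acceptor-pool parameters for the media used in release
#' experiments. Site concentrations scale linearly with the serum fraction;
#' albumin carries the majority of the binding capacity (it dominates drug
#' uptake from serum). `"PBS"` has no acceptors.
#'
#' @param medium one of `"FBS"`, `"human_serum"`, `"albumin"`,
#'   `"gamma_globulin"`, `"HDL"`, `"PBS"`.
#' @param acceptor_fraction serum volume fraction in 0..1 scaling all site
#'   concentrations.
#' @return list of [acceptor_pool()] (empty for PBS).
#' @export
default_acceptor_pools <- function(medium = c("FBS", "human_serum", "albumin",
                                              "gamma_globulin", "HDL", "PBS"),
                                   acceptor_fraction = 1) {
  medium <- match.arg(medium)
  if (acceptor_fraction < 0 || acceptor_fraction > 1) {
    stop("acceptor_fraction must lie in [0, 1]", call. = FALSE)
  }
  f <- acceptor_fraction
  mk <- function(name, site, cap, koff_ea) {
    acceptor_pool(name, site * f, cap,
                  1e9 * exp(-koff_ea * 1000 / (R_GAS * celsius_to_kelvin(37))),
                  koff_ea)
  }
  # serum proteins are deep traps on assay timescales: dissociation barriers
  # well above the donor's, so captured drug is effectively sequestered
  pools <- switch(
    medium,
    PBS = list(),
    albumin = list(mk("albumin", 600, 0.01, 88)),
    gamma_globulin = list(mk("gamma_globulin", 80, 0.005, 86)),
    HDL = list(mk("HDL", 30, 0.02, 90)),
    FBS = list(mk("albumin", 600, 0.01, 88),
               mk("gamma_globulin", 80, 0.005, 86),
               mk("HDL", 30, 0.02, 90),
               mk("LDL", 10, 0.02, 90)),
    human_serum = list(mk("albumin", 640, 0.01, 88),
                       mk("gamma_globulin", 100, 0.005, 86),
                       mk("HDL", 40, 0.02, 90),
                       mk("LDL", 15, 0.02, 90)))
  pools
}

#' Build the exchange system for one archetype drug and condition
#'
#' Convenience constructor tying the descriptor mapping and default serum
#' pools together.
#'
#' @param drug archetype name (row of [cy7_archetypes()]) or a
#'   [drug_descriptor_map()].
#' @param medium,acceptor_fraction passed to [default_acceptor_pools()].
#' @param temperature_c temperature, Celsius.
#' @param ... passed to [exchange_system()].
#' @return an [exchange_system()].
#' @export
archetype_system <- function(drug, medium = "FBS", acceptor_fraction = 1,
                             temperature_c = 37, ...) {
  if (is.character(drug)) {
    arch <- cy7_archetypes()
    row <- arch[arch$drug == drug, ]
    if (nrow(row) != 1) {
      stop(sprintf("unknown archetype '%s'; use one of %s", drug,
                   paste(arch$drug, collapse = ", ")), call. = FALSE)
    }
    drug <- drug_descriptor_map(row$logd, row$chi)
  }
  stopifnot(inherits(drug, "drug_descriptor_map"))
  donor <- map_descriptors_to_params(drug)
  exchange_system(donor,
                  acceptors = default_acceptor_pools(medium, acceptor_fraction),
                  temperature_c = temperature_c, ...)
}
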