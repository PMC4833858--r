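#' Describe a molecule or polymer repeat unit by chemical-group counts
#'
#' A molecule (drug, dye conjugate or polymer repeat unit) is represented by
#' its chemical-group composition for group-contribution estimation, plus any
#' measured descriptors that should take precedence over estimates.
#'
#' @param name molecule name.
#' @param group_counts named integer vector (or list) of non-negative group
#'   counts; names must be groups of the contribution table used downstream.
#' @param supplied_logd optional measured/predicted pH 7.4 distribution
#'   coefficient (dimensionless); if present it always overrides the additive
#'   estimator.
#' @param supplied_molar_volume optional molar volume, cm^3 mol^-1.
#' @param supplied_delta optional solubility parameter, MPa^0.5.
#' @return an object of class `molecule_composition`.
#' @examples
#' decane_ish <- molecule_composition("decyl", c(CH3 = 2, CH2 = 8))
#' compute_molar_volume(decane_ish, fedors_table())
#' @export
molecule_composition <- function(name, group_counts = integer(),
                                 supplied_logd = NULL,
                                 supplied_molar_volume = NULL,
                                 supplied_delta = NULL) {
  group_counts <- unlist(group_counts)
  if (length(group_counts)) {
    if (is.null(names(group_counts)) || any(!nzchar(names(group_counts)))) {
      stop("`group_counts` must be named by chemical group", call. = FALSE)
    }
    if (any(group_counts < 0) || any(group_counts != round(group_counts))) {
      stop("group counts must be non-negative integers", call. = FALSE)
    }
  }
  has_groups <- length(group_counts) > 0 && sum(group_counts) > 0
  has_supplied <- !is.null(supplied_delta) && !is.null(supplied_molar_volume)
  if (!has_groups && !has_supplied) {
    stop(sprintf("molecule '%s' needs non-empty group counts or both supplied_delta and supplied_molar_volume",
                 name), call. = FALSE)
  }
  structure(list(name = name,
                 group_counts = group_counts,
                 supplied_logd = supplied_logd,
                 supplied_molar_volume = supplied_molar_volume,
                 supplied_delta = supplied_delta),
            class = "molecule_composition")
}

#' @export
print.molecule_composition <- function(x, ...) {
  cat(sprintf("Molecule '%s': %d group types\n", x$name, length(x$group_counts)))
  if (length(x$group_counts)) {
    cat(paste(sprintf("%s x%d", names(x$group_counts), x$group_counts), collapse = ", "), "\n")
  }
  if (!is.null(x$supplied_logd)) cat(sprintf("supplied log D = %g\n", x$supplied_logd))
  if (!is.null(x$supplied_delta)) cat(sprintf("supplied delta = %g MPa^0.5\n", x$supplied_delta))
  if (!is.null(x$supplied_molar_volume)) cat(sprintf("supplied V = %g cm^3/mol\n", x$supplied_molar_volume))
  invisible(x)
}

.lookup_contributions <- function(comp, table) {
  stopifnot(inherits(comp, "molecule_composition"), inherits(table, "group_table"))
  gc <- comp$group_counts
  idx <- match(names(gc), table$entries$group)
  if (anyNA(idx)) {
    stop(sprintf("unknown group(s) for molecule '%s': %s", comp$name,
                 paste(names(gc)[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  list(counts = as.numeric(gc),
       e = table$entries$e_coh_j_per_mol[idx],
       v = table$entries$v_cm3_per_mol[idx])
}

#' Hildebrand solubility parameter by group contribution
#'
#' delta = sqrt(sum(n_i E_coh,i) / sum(n_i V_i)) with cohesive energies in
#' J mol^-1 and volumes in cm^3 mol^-1, giving delta in (J cm^-3)^0.5 =
#' MPa^0.5. A `supplied_delta` on the composition is returned verbatim.
#'
#' @param comp a [molecule_composition()].
#' @param table a [group_table()].
#' @return solubility parameter, MPa^0.5.
#' @export
compute_solubility_parameter <- function(comp, table = fedors_table()) {
  if (!is.null(comp$supplied_delta)) return(comp$supplied_delta)
  ct <- .lookup_contributions(comp, table)
  e_total <- sum(ct$counts * ct$e)
  v_total <- sum(ct$counts * ct$v)
  if (v_total <= 0) {
    stop(sprintf("total molar volume for '%s' is not positive (%g cm^3/mol)",
                 comp$name, v_total), call. = FALSE)
  }
  if (e_total < 0) {
    stop(sprintf("total cohesive energy for '%s' is negative", comp$name), call. = FALSE)
  }
  sqrt(e_total / v_total)
}

#' Molar volume by group contribution
#'
#' V = sum(n_i V_i) in cm^3 mol^-1. A `supplied_molar_volume` on the
#' composition is returned verbatim.
#'
#' @inheritParams compute_solubility_parameter
#' @return molar volume, cm^3 mol^-1.
#' @export
compute_molar_volume <- function(comp, table = fedors_table()) {
  if (!is.null(comp$supplied_molar_volume)) return(comp$supplied_molar_volume)
  ct <- .lookup_contributions(comp, table)
  v_total <- sum(ct$counts * ct$v)
  if (v_total <= 0) {
    stop(sprintf("total molar volume for '%s' is not positive (%g cm^3/mol)",
                 comp$name, v_total), call. = FALSE)
  }
  v_total
}

#' Flory-Huggins drug-polymer interaction parameter
#'
#' chi = V (delta_drug - delta_poly)^2 / (R T). V enters in cm^3 mol^-1 and
#' the deltas in MPa^0.5; since 1 MPa = 1 J cm^-3 the numerator V*(ddelta)^2
#' is directly in J mol^-1. Smaller chi means better drug-matrix miscibility;
#' chi is symmetric in the two solubility parameters and zero iff they match.
#'
#' @param V molar volume of the drug, cm^3 mol^-1.
#' @param delta_drug,delta_poly solubility parameters, MPa^0.5.
#' @param temperature_k absolute temperature, K.
#' @return chi, dimensionless.
#' @examples
#' compute_chi(100, 22, 20, 298.15)  # ~0.161
#' @export
compute_chi <- function(V, delta_drug, delta_poly, temperature_k) {
  .assert_scalar_positive(V, "V")
  .assert_scalar_positive(temperature_k, "temperature_k")
  V * (delta_drug - delta_poly)^2 / (R_GAS * temperature_k)
}

#' Additive hydrophobicity (logP-style) estimate
#'
#' Returns `supplied_logd` when the molecule carries one (measured or
#' externally predicted values always win); otherwise sums per-group fragment
#' increments. The result carries attribute `estimated = TRUE` when it comes
#' from the additive sum, so downstream reports can label it.
#'
#' @param comp a [molecule_composition()].
#' @param fragment_table named numeric vector of per-group increments.
#' @return dimensionless hydrophobicity estimate.
#' @export
estimate_logd_additive <- function(comp, fragment_table = logp_fragment_table()) {
  if (!is.null(comp$supplied_logd)) {
    out <- comp$supplied_logd
    attr(out, "estimated") <- FALSE
    return(out)
  }
  gc <- comp$group_counts
  if (!length(gc)) {
    stop(sprintf("molecule '%s' has neither supplied_logd nor group counts", comp$name),
         call. = FALSE)
  }
  idx <- match(names(gc), names(fragment_table))
  if (anyNA(idx)) {
    stop(sprintf("fragment table lacks increment(s) for: %s (molecule '%s')",
                 paste(names(gc)[is.na(idx)], collapse = ", "), comp$name), call. = FALSE)
  }
  out <- sum(as.numeric(gc) * fragment_table[idx])
  attr(out, "estimated") <- TRUE
  out
}

#' Release-zone thresholds
#'
#' Thresholds partitioning the (chi, log D) plane into fast-release,
#' slow-release and intermediate zones. The axes of the underlying guideline
#' are qualitative, so the defaults are package conventions placed to order
#' the four model-drug archetypes correctly; override freely.
#'
#' @param chi_lo,chi_hi miscibility thresholds (chi_lo < chi_hi).
#' @param logd_lo,logd_hi hydrophobicity thresholds (logd_lo < logd_hi).
#' @return a named list of class `zone_thresholds`.
#' @export
zone_thresholds <- function(chi_lo = 1.0, chi_hi = 3.2,
                            logd_lo = 3.5, logd_hi = 8.0) {
  for (v in c(chi_lo, chi_hi, logd_lo, logd_hi)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("thresholds must be single finite numbers", call. = FALSE)
    }
  }
  if (!(chi_lo < chi_hi)) stop("need chi_lo < chi_hi", call. = FALSE)
  if (!(logd_lo < logd_hi)) stop("need logd_lo < logd_hi", call. = FALSE)
  structure(list(chi_lo = chi_lo, chi_hi = chi_hi,
                 logd_lo = logd_lo, logd_hi = logd_hi),
            class = "zone_thresholds")
}

#' Classify a drug into the release-zone guideline
#'
#' A drug is `slow_release` when it is miscible enough (chi <= chi_lo) or
#' hydrophobic enough (log D >= logd_hi) to stay carrier-associated;
#' `fast_release` when it is both poorly miscible (chi >= chi_hi) and weakly
#' hydrophobic (log D <= logd_lo); `intermediate` otherwise. The rule is
#' monotone: decreasing chi or increasing log D never moves a drug from slow
#' toward fast.
#'
#' @param chi Flory-Huggins interaction parameter.
#' @param logd pH 7.4 distribution coefficient.
#' @param thresholds a [zone_thresholds()].
#' @return one of `"slow_release"`, `"fast_release"`, `"intermediate"`
#'   (vectorized over `chi`/`logd`).
#' @export
classify_zone <- function(chi, logd, thresholds = zone_thresholds()) {
  if (!inherits(thresholds, "zone_thresholds")) {
    thresholds <- do.call(zone_thresholds, as.list(thresholds))
  }
  n <- max(length(chi), length(logd))
  chi <- rep_len(chi, n); logd <- rep_len(logd, n)
  out <- rep("intermediate", n)
  out[chi >= thresholds$chi_hi & logd <= thresholds$logd_lo] <- "fast_release"
  out[chi <= thresholds$chi_lo | logd >= thresholds$logd_hi] <- "slow_release"
  out
}

#' Full compatibility characterization of a drug-polymer pair
#'
#' Convenience wrapper combining the group-contribution descriptors, chi, the
#' hydrophobicity estimate and the release-zone label into one record.
#'
#' @param drug,polymer [molecule_composition()] objects (polymer given as its
#'   repeat unit or a composition with supplied descriptors).
#' @param temperature_k absolute temperature for chi, K.
#' @param table a [group_table()].
#' @param fragment_table fragment increments for the log D fallback.
#' @param thresholds a [zone_thresholds()].
#' @return one-row `data.frame` with columns `drug`, `polymer`,
#'   `delta_drug_mpa05`, `delta_poly_mpa05`, `molar_volume_cm3_mol`,
#'   `temperature_k`, `chi`, `logd`, `logd_estimated`, `zone`.
#' @export
characterize_compatibility <- function(drug, polymer, temperature_k,
                                       table = fedors_table(),
                                       fragment_table = logp_fragment_table(),
                                       thresholds = zone_thresholds()) {
  delta_d <- compute_solubility_parameter(drug, table)
  delta_p <- compute_solubility_parameter(polymer, table)
  V <- compute_molar_volume(drug, table)
  chi <- compute_chi(V, delta_d, delta_p, temperature_k)
  logd <- estimate_logd_additive(drug, fragment_table)
  data.frame(
    drug = drug$name,
    polymer = polymer$name,
    delta_drug_mpa05 = delta_d,
    delta_poly_mpa05 = delta_p,
    molar_volume_cm3_mol = V,
    temperature_k = temperature_k,
    chi = chi,
    logd = as.numeric(logd),
    logd_estimated = isTRUE(attr(logd, "estimated")),
    zone = classify_zone(chi, as.numeric(logd), thresholds),
    stringsAsFactors = FALSE
  )
}

#' Read molecule compositions from CSV or JSON
#'
#' CSV layout: one row per molecule, a `name` column, optional
#' `supplied_logd`, `supplied_molar_volume`, `supplied_delta` columns, and one
#' wide column per chemical group holding its count (empty/NA = 0). JSON
#' layout: an array of objects with `name`, `group_counts` (object) and the
#' optional supplied descriptors.
#'
#' @param path input file (`.csv` or `.json`).
#' @return list of [molecule_composition()] objects.
#' @export
read_compositions <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  reserved <- c("name", "supplied_logd", "supplied_molar_volume", "supplied_delta")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(recs, function(r) {
      molecule_composition(r$name,
                           unlist(r$group_counts),
                           supplied_logd = r$supplied_logd,
                           supplied_molar_volume = r$supplied_molar_volume,
                           supplied_delta = r$supplied_delta)
    }))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"name" %in% names(df)) stop(sprintf("%s lacks a 'name' column", path), call. = FALSE)
  group_cols <- setdiff(names(df), reserved)
  lapply(seq_len(nrow(df)), function(i) {
    counts <- unlist(df[i, group_cols, drop = TRUE])
    counts <- counts[!is.na(counts) & counts != 0]
    opt <- function(col) {
      if (col %in% names(df) && !is.na(df[[col]][i])) df[[col]][i] else NULL
    }
    molecule_composition(df$name[i], counts,
                         supplied_logd = opt("supplied_logd"),
                         supplied_molar_volume = opt("supplied_molar_volume"),
                         supplied_delta = opt("supplied_delta"))
  })
}
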