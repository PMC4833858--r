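#' Group-contribution table
#'
#' A read-only lookup table mapping chemical group names to per-group cohesive
#' energy (J mol^-1) and molar volume (cm^3 mol^-1) contributions, used to
#' estimate Hildebrand solubility parameters and molar volumes by summation.
#'
#' Entries flagged as corrections (e.g. branch carbons, ring closure,
#' conjugation) may legitimately carry negative molar-volume contributions;
#' all other volume contributions must be positive.
#'
#' @param groups character vector of unique group names.
#' @param e_coh_j_per_mol numeric, cohesive-energy contribution per group,
#'   J mol^-1.
#' @param v_cm3_per_mol numeric, molar-volume contribution per group,
#'   cm^3 mol^-1.
#' @param correction logical, marks correction terms exempt from the
#'   positive-volume invariant. Default all `FALSE`.
#' @param provenance free-text citation of the published table the entries
#'   come from.
#' @return an object of class `group_table`.
#' @seealso [fedors_table()] for the table shipped with the package,
#'   [read_group_table()] to load one from CSV or JSON.
#' @export
group_table <- function(groups, e_coh_j_per_mol, v_cm3_per_mol,
                        correction = rep(FALSE, length(groups)),
                        provenance = "user-supplied") {
  groups <- as.character(groups)
  if (anyDuplicated(groups)) {
    stop("group names must be unique", call. = FALSE)
  }
  if (length(e_coh_j_per_mol) != length(groups) ||
      length(v_cm3_per_mol) != length(groups) ||
      length(correction) != length(groups)) {
    stop("`groups`, `e_coh_j_per_mol`, `v_cm3_per_mol` and `correction` must have equal length",
         call. = FALSE)
  }
  bad_v <- !correction & v_cm3_per_mol <= 0
  if (any(bad_v)) {
    stop(sprintf("non-correction groups with non-positive molar volume: %s",
                 paste(groups[bad_v], collapse = ", ")), call. = FALSE)
  }
  tab <- data.frame(
    group = groups,
    e_coh_j_per_mol = as.numeric(e_coh_j_per_mol),
    v_cm3_per_mol = as.numeric(v_cm3_per_mol),
    correction = as.logical(correction),
    stringsAsFactors = FALSE
  )
  structure(list(entries = tab, provenance = provenance),
            class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat(sprintf("Group-contribution table: %d groups\n", nrow(x$entries)))
  cat(sprintf("Provenance: %s\n", x$provenance))
  print(utils::head(x$entries, 10))
  if (nrow(x$entries) > 10) cat(sprintf("... and %d more\n", nrow(x$entries) - 10))
  invisible(x)
}

#' Fedors-style group-contribution table
#'
#' The default table shipped with the package, with cohesive-energy and
#' molar-volume increments in the style of Fedors' additive scheme
#' (R. F. Fedors, Polym. Eng. Sci. 14, 147, 1974). Branch carbons and
#' structural corrections that carry negative volume increments are flagged
#' as correction terms.
#'
#' @return a [group_table()].
#' @export
fedors_table <- function() {
  group_table(
    groups = c("CH3", "CH2", "CH", "C",
               "CH2=", "CH=", "C=",
               "phenyl", "phenylene",
               "OH", "O", "CHO", "CO", "COOH", "COO",
               "NH2", "NH", "N", "CN", "NO2",
               "S", "F", "Cl", "Br",
               "ring5plus", "conjugation"),
    e_coh_j_per_mol = c(4710, 4940, 3430, 1470,
                        4310, 4310, 4310,
                        31940, 31940,
                        29800, 3350, 21350, 17370, 27630, 18000,
                        12560, 8370, 4190, 25530, 29300,
                        14150, 4190, 11550, 15490,
                        1050, 1670),
    v_cm3_per_mol = c(33.5, 16.1, -1.0, -19.2,
                      28.5, 13.5, -5.5,
                      71.4, 52.4,
                      10.0, 3.8, 22.3, 10.8, 28.5, 18.0,
                      19.2, 4.5, -9.0, 24.0, 24.0,
                      12.0, 18.0, 24.0, 30.0,
                      16.0, -2.2),
    correction = c(FALSE, FALSE, TRUE, TRUE,
                   FALSE, FALSE, TRUE,
                   FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, TRUE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE,
                   FALSE, TRUE),
    provenance = "Fedors (1974) additive cohesive energy / molar volume scheme"
  )
}

#' Additive logP fragment increments
#'
#' A small fragment table for the additive hydrophobicity estimator used by
#' self-contained synthetic studies. Crude Crippen-style increments; a
#' measured or predicted log D supplied with the molecule always takes
#' precedence (see [estimate_logd_additive()]).
#'
#' @return named numeric vector of per-group logP increments.
#' @export
logp_fragment_table <- function() {
  c(CH3 = 0.65, CH2 = 0.50, CH = 0.36, C = 0.20,
    "CH2=" = 0.40, "CH=" = 0.35, "C=" = 0.20,
    phenyl = 1.90, phenylene = 1.70,
    OH = -1.10, O = -0.40, CHO = -0.60, CO = -0.55,
    COOH = -0.70, COO = -0.45,
    NH2 = -1.20, NH = -0.90, N = -0.60, CN = -0.35, NO2 = -0.20,
    S = 0.40, F = 0.20, Cl = 0.70, Br = 0.85,
    ring5plus = 0.0, conjugation = 0.0)
}

#' Read / write group-contribution tables
#'
#' CSV files use columns `group,e_coh_j_per_mol,v_cm3_per_mol` and optionally
#' `correction`; JSON files hold the same records plus a `provenance` string.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return a [group_table()].
#' @export
read_group_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ent <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
    corr <- if ("correction" %in% names(ent)) ent$correction else rep(FALSE, nrow(ent))
    return(group_table(ent$group, ent$e_coh_j_per_mol, ent$v_cm3_per_mol,
                       correction = corr,
                       provenance = obj$provenance %||% "unspecified"))
  }
  ent <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "e_coh_j_per_mol", "v_cm3_per_mol")
  miss <- setdiff(need, names(ent))
  if (length(miss)) {
    stop(sprintf("group table %s is missing columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  corr <- if ("correction" %in% names(ent)) as.logical(ent$correction) else rep(FALSE, nrow(ent))
  group_table(ent$group, ent$e_coh_j_per_mol, ent$v_cm3_per_mol,
              correction = corr, provenance = sprintf("loaded from %s", basename(path)))
}

#' @rdname read_group_table
#' @param table a [group_table()].
#' @export
write_group_table <- function(table, path) {
  stopifnot(inherits(table, "group_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(provenance = table$provenance, entries = table$entries),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(table$entries, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
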