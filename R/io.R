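#' Write / read kinetic trace files
#'
#' The trace dialect is plain UTF-8 CSV with `#key=value` comment lines
#' carrying condition metadata (temperature_c, acceptor_medium,
#' acceptor_fraction, particle_conc_mg_ml, label, plus any extra keys, which
#' are preserved on round trip), followed by the column header
#' `time_s,i_donor,i_fret`. Numeric values are written in full precision so
#' `read_trace(write_trace(x))` reproduces `x` exactly.
#'
#' @param trace a [kinetic_trace()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  meta <- c(trace$condition, trace$extra, list(label = trace$label))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    vs <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    writeLines(sprintf("#%s=%s", k, vs), con)
  }
  writeLines("time_s,i_donor,i_fret", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", trace$times, trace$i_donor, trace$i_fret), con)
  invisible(path)
}

.known_meta <- c("temperature_c", "acceptor_medium", "acceptor_fraction",
                 "particle_conc_mg_ml")

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop(sprintf("%s is empty", path), call. = FALSE)
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1] - 1L else length(lines)
  meta <- list()
  for (ln in lines[seq_len(n_meta)]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop(sprintf("%s: malformed metadata line: %s", path, ln), call. = FALSE)
    key <- substr(kv, 1, eq - 1)
    meta[[key]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- if (n_meta > 0) lines[-seq_len(n_meta)] else lines
  if (!length(body)) stop(sprintf("%s has no column header", path), call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  need <- c("time_s", "i_donor", "i_fret")
  if (!identical(header, need)) {
    stop(sprintf("%s: expected header 'time_s,i_donor,i_fret', got '%s'",
                 path, body[1]), call. = FALSE)
  }
  rows <- body[-1]
  if (!length(rows)) stop(sprintf("%s has no data rows", path), call. = FALSE)
  parsed <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parsed) != 3)
  if (length(bad)) {
    stop(sprintf("%s: malformed row(s) at line(s) %s",
                 path, paste(n_meta + 1 + bad, collapse = ", ")), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parsed))), ncol = 3, byrow = TRUE)
  if (anyNA(m)) {
    bad <- n_meta + 1 + which(rowSums(is.na(m)) > 0)
    stop(sprintf("%s: non-numeric value(s) at line(s) %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(diff(m[, 1]) <= 0)) {
    stop(sprintf("%s: time column is not strictly increasing", path), call. = FALSE)
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  condition <- list(
    temperature_c = num(meta$temperature_c),
    acceptor_medium = meta$acceptor_medium,
    acceptor_fraction = num(meta$acceptor_fraction),
    particle_conc_mg_ml = num(meta$particle_conc_mg_ml))
  condition <- condition[!vapply(condition, is.null, logical(1))]
  extra <- meta[setdiff(names(meta), c(.known_meta, "label"))]
  kinetic_trace(m[, 1], m[, 2], m[, 3], condition = condition,
                label = meta$label %||% "", extra = extra)
}

#' Read / write run configuration
#'
#' YAML run configuration: zone thresholds, spectral parameters, descriptor
#' mapping coefficients, temperature set, seed and output options. Unknown
#' keys are preserved. `write_run_config()` is used to echo the effective
#' configuration into output directories.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default run configuration
#'
#' @return named list mirroring the package defaults.
#' @export
default_run_config <- function() {
  list(thresholds = unclass(zone_thresholds()),
       spectral = unclass(spectral_params()),
       mapping = list(ea0 = 62.5, ea_slope = 1.5, s = 3, chi0 = 1.5),
       temperatures_c = c(25, 31, 37, 41),
       serum_fractions = c(0.05, 0.10, 0.25, 0.50, 1.00),
       seed = 1L)
}

.fmt9 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.9g", x))
}

#' Write a per-trace fit report
#'
#' CSV with one row per fitted trace (label, amplitudes, rates, plateau,
#' half-life, rss, flags). Floating-point values are written at 9
#' significant digits so golden-file comparisons are stable.
#'
#' @param fits named list of [fit_two_compartment()] results.
#' @param path output CSV.
#' @param horizon passed to [half_life_of_fit()].
#' @return the report `data.frame`, invisibly.
#' @export
write_fit_report <- function(fits, path, horizon = NULL) {
  rows <- lapply(names(fits), function(lb) {
    f <- fits[[lb]]
    hl <- tryCatch(as.numeric(half_life_of_fit(f, horizon)),
                   error = function(e) NA_real_)
    data.frame(label = lb, f_fast = f$f_fast, k_fast = f$k_fast,
               f_slow = f$f_slow, k_slow = f$k_slow, plateau = f$plateau,
               half_life_s = hl, rss = f$rss,
               converged = f$converged,
               flags = paste(f$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  out <- rep_df
  for (cc in c("f_fast", "k_fast", "f_slow", "k_slow", "plateau",
               "half_life_s", "rss")) {
    out[[cc]] <- .fmt9(rep_df[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(rep_df)
}

#' Fit every trace in a directory or file list
#'
#' Reads each trace, forms the FRET ratio, normalizes it to the first point,
#' and fits the two-compartment model.
#'
#' @param paths trace files, or a single directory containing `*.csv` traces
#'   (a `manifest.csv` is ignored).
#' @param ... passed to [fit_two_compartment()].
#' @return named list of fits (names = trace labels or file stems).
#' @export
fit_trace_files <- function(paths, ...) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
    paths <- paths[basename(paths) != "manifest.csv"]
  }
  if (!length(paths)) stop("no trace files found", call. = FALSE)
  fits <- list()
  for (p in paths) {
    tr <- read_trace(p)
    ratio <- fret_ratio(data.frame(i_donor = tr$i_donor, i_fret = tr$i_fret))
    y <- normalize_ratio_series(ratio, reference = "first_point")
    nm <- if (nzchar(tr$label)) tr$label else sub("\\.csv$", "", basename(p))
    fits[[nm]] <- fit_two_compartment(tr$times, y, ...)
  }
  fits
}
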