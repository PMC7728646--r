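#' @title Delimited-text readers and writers
#' @description
#' All signals travel as two-column delimited text with `#`-prefixed header
#' lines of the form `# key=value; key=value`. The first header line
#' records the signal kind, generating preset and seed; units follow on
#' comment lines. The default dialect is tab-delimited with `.` decimal
#' marks; comma-decimal spreadsheet exports are supported via `dialect`.
#' @name cli_io
NULL

#' Delimited-text dialect
#'
#' @param delim column delimiter (default tab).
#' @param dec decimal mark, `"."` or `","`.
#' @return A list of class `text_dialect`.
#' @export
text_dialect <- function(delim = "\t", dec = ".") {
  stopifnot(dec %in% c(".", ","))
  structure(list(delim = delim, dec = dec), class = "text_dialect")
}

#' Write a time series as annotated two-column text
#'
#' @param ts a [time_series()].
#' @param path output file path.
#' @param dialect a [text_dialect()].
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, dialect = text_dialect()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s; preset=%s; seed=%s",
                     attr(ts, "kind"), attr(ts, "preset"), attr(ts, "seed")),
             con)
  writeLines(sprintf("# time_unit=%s; value_unit=%s",
                     attr(ts, "time_unit"), attr(ts, "value_unit")), con)
  lines <- paste(fmt_num(ts$time, dialect), fmt_num(ts$value, dialect),
                 sep = dialect$delim)
  writeLines(lines, con)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#'
#' Comment lines (`#`) are parsed for metadata; remaining lines must hold
#' two numeric columns. Out-of-order rows are sorted with a warning;
#' duplicate times and unparseable rows are errors (the latter reported
#' with their line numbers).
#'
#' @param path input file path.
#' @param dialect a [text_dialect()].
#' @return A [time_series()].
#' @export
read_timeseries <- function(path, dialect = text_dialect()) {
  parsed <- parse_two_columns(path, dialect)
  meta <- parsed$meta
  time_series(parsed$x, parsed$y,
              kind = meta[["kind"]] %||% "generic",
              time_unit = meta[["time_unit"]] %||% "s",
              value_unit = meta[["value_unit"]] %||% "a.u.",
              preset = meta[["preset"]] %||% NA_character_,
              seed = suppressWarnings(as.integer(meta[["seed"]] %||% NA)))
}

#' Write / read an emission spectrum (wavelength_nm, intensity)
#'
#' @param spec a [light_spectrum()].
#' @param path file path.
#' @param dialect a [text_dialect()].
#' @return `path` (writer, invisibly) or a [light_spectrum()] (reader).
#' @export
write_spectrum <- function(spec, path, dialect = text_dialect()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=spectrum; preset=%s", attr(spec, "preset")), con)
  writeLines("# wavelength_unit=nm; value_unit=a.u.", con)
  writeLines(paste(fmt_num(spec$wavelength, dialect),
                   fmt_num(spec$intensity, dialect), sep = dialect$delim),
             con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, dialect = text_dialect()) {
  parsed <- parse_two_columns(path, dialect)
  light_spectrum(parsed$x, parsed$y,
                 preset = parsed$meta[["preset"]] %||% NA_character_)
}

fmt_num <- function(x, dialect) {
  s <- vapply(x, function(xi) format(xi, digits = 17, trim = TRUE),
              character(1))
  if (dialect$dec == ",") s <- gsub(".", ",", s, fixed = TRUE)
  s
}

parse_num <- function(s, dialect) {
  if (dialect$dec == ",") s <- gsub(",", ".", s, fixed = TRUE)
  suppressWarnings(as.numeric(s))
}

parse_two_columns <- function(path, dialect = text_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  is_comment <- startsWith(trimws(lines), "#")
  meta <- list()
  for (cl in lines[is_comment]) {
    body <- sub("^\\s*#\\s*", "", cl)
    for (kv in strsplit(body, ";")[[1]]) {
      parts <- strsplit(trimws(kv), "=", fixed = TRUE)[[1]]
      if (length(parts) == 2) meta[[trimws(parts[1])]] <- trimws(parts[2])
    }
  }
  data_lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(data_lines) == 0) stop("no data rows in ", path)
  fields <- strsplit(data_lines, dialect$delim, fixed = TRUE)
  x <- vapply(fields, function(f) parse_num(f[1], dialect), numeric(1))
  y <- vapply(fields, function(f)
    parse_num(if (length(f) >= 2) f[2] else NA_character_, dialect),
    numeric(1))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0) {
    line_no <- which(!is_comment & nzchar(trimws(lines)))[bad]
    stop("unparseable data rows at line(s): ", paste(line_no, collapse = ", "))
  }
  list(x = x, y = y, meta = meta)
}

#' Reproduce all published phenotype constants from synthetic fixtures
#'
#' End-to-end determinism check of the whole pipeline: for each preset the
#' fixtures are generated, pushed through the matching analysis operators
#' (first-order fits, damage-repair fit, induction features, 77 K band
#' ratio, glow-band analysis, SOSG slopes, growth table), and the recovered
#' values are tabulated against the preset constants they should return.
#'
#' @param seed integer seed for the seeded generators (growth curves).
#' @return A data frame with columns `quantity`, `preset`, `target`,
#'   `recovered`, `rel_error`.
#' @examples
#' head(reproduce_phenotypes(seed = 1))
#' @export
reproduce_phenotypes <- function(seed = 1) {
  rows <- list()
  add <- function(quantity, preset, target, recovered) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, preset = preset, target = target,
      recovered = recovered,
      rel_error = abs(recovered - target) / abs(target))
  }
  for (pn in c("control", "EL")) {
    p <- fixture_preset(pn)
    dec <- double_normalize_decay(gen_flash_decay(p, with_dcmu = TRUE),
                                  F0_pre = 0, Fmax = 1)
    add("k_recomb (s-1)", pn, p$k_recomb,
        fit_first_order(dec, role = "recombination")$k)
    pi_ts <- gen_photoinhibition_series(p, lincomycin = TRUE)
    add("k_PI (s-1)", pn, p$k_PI,
        kpi_from_oxygen(photoinhibition_relative(pi_ts, chl = p$chl_per_od))$k)
    add("Fv/Fm", pn, 1 - p$F0_rel,
        induction_features(gen_ojip(p))$FvFm)
    add("t_Fm (s)", pn, p$t_Fm, induction_features(gen_ojip(p))$t_Fm)
    add("PSII/PSI 77K ratio", pn, p$psii_psi_ratio,
        psii_psi_ratio(normalize_spectrum_713(gen_77k_spectrum(p)))$ratio)
    add("TL Q-band peak (degC)", pn, p$tl_peak_Q,
        band_features(gen_glow_curve(p$tl_peak_Q))$T_peak)
    add("TL B-band peak (degC)", pn, p$tl_peak_B,
        band_features(gen_glow_curve(p$tl_peak_B))$T_peak)
    add("SOSG slope (a.u./min)", pn, p$sosg_slope,
        as.numeric(sosg_rate(gen_sosg_series(p))))
    drm <- fit_damage_repair(
      gen_photoinhibition_series(p, lincomycin = FALSE, duration = 7200),
      k_PI_fixed = p$k_PI)
    add("O2 equilibrium rate", pn, p$o2_eq_rate, drm$A_eq)
    tab <- acclimation_table(gen_growth_curves(p, n_cultures = 30,
                                               seed = seed))
    add("% acclimated by 96 h", pn, p$acclim_fraction_96h * 100,
        tab$pct[["pct_96h"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
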