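# Plain-text I/O: CEST profile files (ChemEx-style columns with '#' header
# metadata), results tables, and simple key = value configuration files for
# scenarios and acquisition settings.

#' Read a CEST profile from a text file
#'
#' The format is plain text with 2-3 whitespace- or comma-separated columns
#' (`offset`, `intensity`, optional `error`) and `#`-prefixed header lines
#' of the form `# key: value` (or `key = value`) carrying metadata:
#' `b0` (T), `b1` (Hz), `tex` (s), `phase` (`ap`/`ip`), and `units`
#' (`ppm`, the default, or `hz`). Offsets in Hz are converted to ppm using
#' the header `b0`; a Hz-offset file without `b0` is an error.
#'
#' @param path File path.
#' @return A [cest_profile()].
#' @export
read_cest_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z0-9_]+)\\s*[:=]\\s*(\\S+)",
                               h))[[1]]
    if (length(m) == 3) meta[[tolower(m[2])]] <- m[3]
  }
  num <- function(key) {
    if (is.null(meta[[key]])) NA_real_ else as.numeric(meta[[key]])
  }
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(trimws(body[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      stop("malformed profile row at line ",
           which(lines == body[i])[1], ": '", body[i], "'", call. = FALSE)
    }
    vals[1:2]
  })
  dat <- do.call(rbind, rows)
  units <- tolower(meta[["units"]] %||% "ppm")
  b0 <- num("b0")
  offsets <- dat[, 1]
  if (units == "hz") {
    if (is.na(b0)) {
      stop("offsets are in Hz but the header carries no b0 field",
           call. = FALSE)
    }
    offsets <- hz_to_ppm(offsets, b0)
  }
  phase <- tolower(meta[["phase"]] %||% "ap")
  cest_profile(offsets, dat[, 2], phase = phase, b0 = b0, b1 = num("b1"),
               tex = num("tex"), noise = num("noise") %||% 0,
               provenance = meta[["provenance"]] %||% "experimental")
}

#' Write a CEST profile to a text file
#'
#' Writes the `# key: value` metadata header followed by
#' `offset_ppm intensity` columns at full precision, so that
#' `read_cest_profile(write_cest_profile(x))` round-trips.
#'
#' @param profile A [cest_profile()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cest_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cest_profile"))
  m <- profile_meta(profile)
  header <- c(
    sprintf("# phase: %s", m$phase),
    sprintf("# provenance: %s", m$provenance),
    if (!is.na(m$b0)) sprintf("# b0: %.15g", m$b0),
    if (!is.na(m$b1)) sprintf("# b1: %.15g", m$b1),
    if (!is.na(m$tex)) sprintf("# tex: %.15g", m$tex),
    if (!is.na(m$noise) && m$noise > 0) sprintf("# noise: %.15g", m$noise),
    "# units: ppm"
  )
  rows <- sprintf("%.15g %.15g", profile$offset, profile$intensity)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write analysis results to CSV
#'
#' @param results A `cest_analysis` tibble (or the output of
#'   [analyze_profiles()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' Read a scenario / acquisition configuration file
#'
#' A minimal `key = value` format (one per line, `#` comments) mirroring
#' the scenario and acquisition fields: `p_g, p_e1, p_e2, kex_ge1, kex_ge2,
#' shift_g, shift_e1, shift_e2, tau_m, j_hn, r_ex, dr2_e1, dr2_e2, b0, b1,
#' offset_min, offset_span, n_offsets, tex, d1`.
#'
#' @param path File path.
#' @return A list with `scenario` and `config`.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", l))[[1]]
    if (length(m) == 3) kv[[tolower(m[2])]] <- as.numeric(m[3])
  }
  g <- function(key, default) if (is.null(kv[[key]])) default else kv[[key]]
  scenario <- exchange_scenario(
    populations = c(g("p_g", 0.95), g("p_e1", 0.05), g("p_e2", 0)),
    kex = c(g("kex_ge1", 100), g("kex_ge2", 0)),
    shifts = c(g("shift_g", 8.0), g("shift_e1", 8.8), g("shift_e2", 0)),
    tau_m = g("tau_m", 10), j_hn = g("j_hn", -93),
    r_ex = g("r_ex", 0), dr2 = c(g("dr2_e1", 0), g("dr2_e2", 0))
  )
  config <- acquisition_config(
    b0 = g("b0", 18.8), b1 = g("b1", 30),
    offset_min = g("offset_min", 6.6),
    offset_span = g("offset_span", 3.4),
    n_offsets = g("n_offsets", 90),
    tex = g("tex", 0.4), d1 = g("d1", 0.5)
  )
  list(scenario = scenario, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
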