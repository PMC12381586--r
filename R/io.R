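## ---- logging -------------------------------------------------------------

.hf_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set the package log level
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("haflex.log_level", "info")
  options(haflex.log_level = level)
  invisible(old)
}

.hf_log <- function(level, fmt, ...) {
  thr <- .hf_levels[[getOption("haflex.log_level", "info")]]
  if (.hf_levels[[level]] >= thr) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
  invisible(NULL)
}

## ---- CSV readers ----------------------------------------------------------

.read_table <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

.parse_numeric <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !is.na(df[[col]]))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value '%s' in column '%s' (line %d)",
                 path, df[[col]][bad[1L]], col, bad[1L] + 1L),
         call. = FALSE)
  }
  x
}

#' Read T1 recovery curves from CSV
#'
#' Expected dialect: comma-separated, UTF-8, mandatory header, `.` decimal;
#' columns `sample, resonance, scheme, delay_s, intensity`, one row per
#' acquired point. Rows are grouped into one [recovery_curve()] per
#' (sample, resonance); validation failures report the file line.
#'
#' @param path CSV file path.
#' @return Named list of `recovery_curve` objects
#'   (names `"sample/resonance"`).
#' @export
read_recovery_csv <- function(path) {
  req <- c("sample", "resonance", "scheme", "delay_s", "intensity")
  df <- .read_table(path, req)
  df$delay_s <- .parse_numeric(df, "delay_s", path)
  df$intensity <- .parse_numeric(df, "intensity", path)
  bad_scheme <- which(!df$scheme %in% c("saturation", "inversion"))
  if (length(bad_scheme)) {
    stop(sprintf("%s: unknown scheme '%s' (line %d)", path,
                 df$scheme[bad_scheme[1L]], bad_scheme[1L] + 1L),
         call. = FALSE)
  }
  groups <- split(df, interaction(df$sample, df$resonance, drop = TRUE,
                                  sep = "/"))
  curves <- lapply(groups, function(g) {
    scheme <- unique(g$scheme)
    if (length(scheme) != 1L) {
      stop(sprintf("%s: mixed schemes within %s/%s", path,
                   g$sample[1L], g$resonance[1L]), call. = FALSE)
    }
    recovery_curve(g$delay_s, g$intensity, scheme = scheme,
                   resonance = g$resonance[1L], sample = g$sample[1L])
  })
  .hf_log("info", "read %d curve(s) from %s", length(curves), path)
  curves
}

#' Write recovery curves to CSV
#' @param curves A `recovery_curve` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recovery_csv <- function(curves, path) {
  if (inherits(curves, "recovery_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(sample = cu$sample, resonance = cu$resonance,
               scheme = cu$scheme, delay_s = cu$delays,
               intensity = cu$intensities)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read oscillatory sweeps from CSV
#'
#' Columns `sample, omega_rad_s, g_prime_pa, g_double_prime_pa`; one
#' [oscillatory_sweep()] per sample.
#'
#' @param path CSV file path.
#' @param hz If `TRUE`, the frequency column is in Hz and is converted to
#'   rad/s on input.
#' @return Named list of `oscillatory_sweep` objects.
#' @export
read_sweep_csv <- function(path, hz = FALSE) {
  req <- c("sample", "omega_rad_s", "g_prime_pa", "g_double_prime_pa")
  df <- .read_table(path, req)
  for (col in req[-1L]) df[[col]] <- .parse_numeric(df, col, path)
  if (hz) df$omega_rad_s <- df$omega_rad_s * 2 * pi
  sweeps <- lapply(split(df, df$sample), function(g) {
    oscillatory_sweep(g$omega_rad_s, g$g_prime_pa, g$g_double_prime_pa,
                      sample = g$sample[1L])
  })
  .hf_log("info", "read %d sweep(s) from %s", length(sweeps), path)
  sweeps
}

#' Write oscillatory sweeps to CSV
#' @param sweeps An `oscillatory_sweep` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweeps, path) {
  if (inherits(sweeps, "oscillatory_sweep")) sweeps <- list(sweeps)
  rows <- do.call(rbind, lapply(sweeps, function(sw) {
    data.frame(sample = sw$sample, omega_rad_s = sw$omega,
               g_prime_pa = sw$g_prime, g_double_prime_pa = sw$g_double_prime)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a report object as JSON
#'
#' Units are explicit in key names (`t1_s`, `omega_c_rad_s`, ...); numbers
#' are written at full precision so reports are byte-reproducible under a
#' fixed seed.
#'
#' @param obj A list (report).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
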