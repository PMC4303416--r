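# Ventilator waveform sessions: container, CSV reader/writer.
#
# Units are fixed package-wide: time s, pressure cmH2O, flow L/s
# (inspiration positive), Eadi uV. No unit conversion is ever applied.

#' Construct a ventilator waveform session
#'
#' A `waveform_record` holds one ventilation session on a uniform time grid:
#' airway pressure, flow and (optionally) the electrical activity of the
#' diaphragm, plus patient and mode metadata. All estimation functions in
#' the package consume this container.
#'
#' @param time Sample times in seconds, strictly increasing from 0 on a
#'   uniform grid. The sample interval must be in (0, 0.1] s (at least
#'   10 Hz, required for breath segmentation).
#' @param paw Airway pressure per sample, cmH2O.
#' @param flow Airway flow per sample, L/s; inspiration is positive.
#' @param eadi Optional electrical diaphragm activity per sample, uV.
#' @param patient_id Patient identifier string.
#' @param mode Ventilation mode, `"PS"` or `"NAVA"`.
#'
#' @return An object of class `waveform_record` with fields `time`, `paw`,
#'   `flow`, `eadi` (possibly `NULL`), `dt`, `patient_id`, `mode`.
#' @seealso [read_waveform()], [write_waveform()], [edrs_fit()]
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' rec <- waveform_record(t, paw = rep(5, length(t)),
#'                        flow = sin(pi * t), patient_id = "p1", mode = "PS")
#' rec
waveform_record <- function(time, paw, flow, eadi = NULL,
                            patient_id = "unknown", mode = c("PS", "NAVA")) {
  mode <- match.arg(mode)
  time <- as.numeric(time); paw <- as.numeric(paw); flow <- as.numeric(flow)
  if (!is.null(eadi)) eadi <- as.numeric(eadi)
  n <- length(time)
  if (n < 2L)
    stop("waveform_record: need at least 2 samples, got ", n)
  if (length(paw) != n || length(flow) != n ||
      (!is.null(eadi) && length(eadi) != n))
    stop("waveform_record: channel lengths differ from time grid (n = ", n, ")")
  bad <- which(!is.finite(time) | !is.finite(paw) | !is.finite(flow) |
                 (if (is.null(eadi)) FALSE else !is.finite(eadi)))
  if (length(bad))
    stop("waveform_record: non-finite value at row ", bad[1L])
  if (abs(time[1L]) > 1e-9)
    stop("waveform_record: time must start at 0, got ", time[1L])
  dt <- (time[n] - time[1L]) / (n - 1L)
  dev <- abs(diff(time) - dt)
  if (any(dev > 1e-9)) {
    k <- which(dev > 1e-9)[1L] + 1L
    stop("waveform_record: non-uniform sampling at index ", k,
         " (interval ", format(time[k] - time[k - 1L]), " s, expected ",
         format(dt), " s)")
  }
  if (dt <= 0 || dt > 0.1)
    stop("waveform_record: sample interval must be in (0, 0.1] s, got ",
         format(dt), " s")
  structure(list(time = time, paw = paw, flow = flow, eadi = eadi,
                 dt = dt, patient_id = as.character(patient_id), mode = mode),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  n <- length(x$time)
  cat("Ventilator waveform session\n")
  cat(sprintf("  patient: %s   mode: %s\n", x$patient_id, x$mode))
  cat(sprintf("  %d samples at %g Hz (%.1f s)%s\n", n, 1 / x$dt,
              n * x$dt, if (is.null(x$eadi)) "" else ", Eadi present"))
  invisible(x)
}

.wf_cols <- c(time = "time_s", paw = "paw_cmH2O", flow = "flow_L_s",
              eadi = "eadi_uV")

#' Read a ventilator waveform session from CSV
#'
#' Reads the package's CSV dialect: optional leading `#` metadata lines
#' (`# patient_id: ...`, `# mode: ...`), one header line with columns
#' `time_s,paw_cmH2O,flow_L_s[,eadi_uV]`, comma separated, `.` decimal.
#' The reader validates and never alters the data: non-uniform time grids
#' are rejected, not resampled, and no filtering is applied.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector overriding column names,
#'   with names among `time`, `paw`, `flow`, `eadi`, e.g.
#'   `c(time = "t", paw = "pressure")`.
#' @return A [waveform_record()].
#' @export
read_waveform <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("read_waveform: file not found: ", path)
  cols <- .wf_cols
  if (!is.null(schema)) {
    schema <- unlist(schema)
    unknown <- setdiff(names(schema), names(cols))
    if (length(unknown))
      stop("read_waveform: unknown schema keys: ",
           paste(unknown, collapse = ", "))
    cols[names(schema)] <- schema
  }
  meta <- list(patient_id = "unknown", mode = "PS")
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("read_waveform: empty file: ", path)
    if (!startsWith(line, "#")) break
    m <- regmatches(line, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)\\s*$", line))[[1L]]
    if (length(m) == 3L && m[2L] %in% c("patient_id", "mode"))
      meta[[m[2L]]] <- m[3L]
  }
  header <- strsplit(line, ",", fixed = TRUE)[[1L]]
  dat <- read.csv(con, header = FALSE, col.names = header,
                  colClasses = "numeric", comment.char = "")
  for (key in c("time", "paw", "flow")) {
    if (!cols[[key]] %in% header)
      stop("read_waveform: missing column '", cols[[key]], "' (", key,
           ") in ", path)
  }
  eadi <- if (cols[["eadi"]] %in% header) dat[[cols[["eadi"]]]] else NULL
  waveform_record(time = dat[[cols[["time"]]]], paw = dat[[cols[["paw"]]]],
                  flow = dat[[cols[["flow"]]]], eadi = eadi,
                  patient_id = meta$patient_id, mode = meta$mode)
}

#' Write a ventilator waveform session to CSV
#'
#' Writes the dialect read by [read_waveform()], at full double precision
#' (17 significant digits) so that a write/read round trip reproduces every
#' channel bit for bit. The record is validated before anything is written.
#'
#' @param record A [waveform_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_waveform <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  # re-validate: refuses to serialise a hand-edited, broken record
  record <- waveform_record(record$time, record$paw, record$flow, record$eadi,
                            record$patient_id, record$mode)
  has_eadi <- !is.null(record$eadi)
  cols <- if (has_eadi) .wf_cols else .wf_cols[c("time", "paw", "flow")]
  num <- function(x) sprintf("%.17g", x)
  body <- if (has_eadi)
    paste(num(record$time), num(record$paw), num(record$flow),
          num(record$eadi), sep = ",")
  else paste(num(record$time), num(record$paw), num(record$flow), sep = ",")
  lines <- c(sprintf("# patient_id: %s", record$patient_id),
             sprintf("# mode: %s", record$mode),
             "# units: time s, pressure cmH2O, flow L/s, eadi uV",
             paste(cols, collapse = ","), body)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("write_waveform: cannot write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
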