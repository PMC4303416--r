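# Long-form CSV serialisation of elastance surfaces, so that surfaces can
# be computed once and summarised or compared later (and by the CLI).

#' Write an elastance surface to CSV
#'
#' Long format: one row per (breath, grid point) with columns
#' `breath_index`, `ti_s`, `tau`, `edrs_cmH2O_L`, `valid`; `#` metadata
#' lines carry the patient id, mode and estimation parameters. Values are
#' written at full double precision, so [read_surface()] inverts exactly.
#'
#' @param surface An [edrs_surface()] or [edrs_fit()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "edrs_surface"))
  nb <- nrow(surface$edrs); g <- length(surface$tau)
  num <- function(x) sprintf("%.17g", x)
  par_line <- if (length(surface$params))
    sprintf("# params: %s",
            paste(names(surface$params), unlist(surface$params),
                  sep = "=", collapse = " ")) else character(0)
  body <- paste(rep(surface$breath_index, each = g),
                num(rep(surface$ti, each = g)),
                num(rep(surface$tau, times = nb)),
                ifelse(is.na(t(surface$edrs)), "NA", num(t(surface$edrs))),
                as.integer(t(surface$valid)), sep = ",")
  writeLines(c(sprintf("# patient_id: %s", surface$patient_id),
               sprintf("# mode: %s", surface$mode),
               par_line,
               "breath_index,ti_s,tau,edrs_cmH2O_L,valid", body), path)
  invisible(path)
}

#' Read an elastance surface from CSV
#'
#' Inverse of [write_surface()].
#'
#' @param path Path to a surface CSV.
#' @return An [edrs_surface()].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("read_surface: file not found: ", path)
  lines <- readLines(path)
  meta <- list(patient_id = "unknown", mode = "PS")
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    m <- regmatches(lines[i],
                    regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)\\s*$", lines[i]))[[1L]]
    if (length(m) == 3L && m[2L] %in% c("patient_id", "mode"))
      meta[[m[2L]]] <- m[3L]
    i <- i + 1L
  }
  dat <- read.csv(text = lines[i:length(lines)], header = TRUE)
  need <- c("breath_index", "ti_s", "tau", "edrs_cmH2O_L", "valid")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("read_surface: missing column(s): ", paste(miss, collapse = ", "))
  trajs <- lapply(split(dat, dat$breath_index), function(d) {
    d <- d[order(d$tau), ]
    structure(list(tau = d$tau, edrs = d$edrs_cmH2O_L,
                   valid = as.logical(d$valid), ti = d$ti_s[1L],
                   breath_index = d$breath_index[1L]),
              class = "edrs_trajectory")
  })
  trajs <- trajs[order(vapply(trajs, `[[`, numeric(1), "breath_index"))]
  edrs_surface(trajs, patient_id = meta$patient_id, mode = meta$mode)
}
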