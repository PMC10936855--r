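# Delimited-text container for template banks: one headered file per
# template plus an index, all plain text so banks diff and version cleanly.

template_header <- function(tpl) {
  c(sprintf("# diameter_um %.17g", tpl$diameter),
    sprintf("# kind %s", tpl$kind),
    sprintf("# representation %s", tpl$representation),
    sprintf("# sampling_period_ms %.17g", tpl$sampling_period),
    sprintf("# cv_m_per_s %.17g", tpl$cv),
    sprintf("# t0_ms %.17g", tpl$t0),
    sprintf("# ref_time_ms %.17g", tpl$ref_time),
    sprintf("# ref_position_mm %.17g", tpl$ref_position),
    sprintf("# n_types %d", ncol(tpl$currents)))
}

#' Write a template to delimited text
#'
#' Header lines (`# key value`) carry the metadata; the body is one row per
#' time sample with one column per compartment type, in mA, written with 17
#' significant digits so a round trip is exact.
#'
#' @param tpl An [ap_template()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template <- function(tpl, path) {
  stopifnot(inherits(tpl, "ap_template"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(template_header(tpl), con)
  utils::write.table(format(tpl$currents, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a template written by [write_template()]
#'
#' @param path Path to a template text file.
#' @return An [ap_template()].
#' @export
read_template <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), " ", fixed = TRUE))
  meta <- stats::setNames(kv[, 2L], kv[, 1L])
  body <- lines[!grepl("^#", lines)]
  currents <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                                    as.numeric))
  ap_template(currents,
              sampling_period = as.numeric(meta[["sampling_period_ms"]]),
              cv = as.numeric(meta[["cv_m_per_s"]]),
              diameter = as.numeric(meta[["diameter_um"]]),
              kind = meta[["kind"]],
              representation = meta[["representation"]],
              t0 = as.numeric(meta[["t0_ms"]]),
              ref_time = as.numeric(meta[["ref_time_ms"]]),
              ref_position = as.numeric(meta[["ref_position_mm"]]))
}

#' Write a template bank to a directory
#'
#' One text file per template (`template_0001.txt`, ...) plus an
#' `index.csv` listing diameters and files.
#'
#' @param bank A [template_bank()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_template_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "template_bank"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("template_%04d.txt", seq_along(bank$templates))
  for (i in seq_along(bank$templates))
    write_template(bank$templates[[i]], file.path(dir, files[i]))
  idx <- data.frame(diameter_um = sprintf("%.17g", bank$diameters),
                    file = files)
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Read a template bank directory written by [write_template_bank()]
#'
#' @param dir Bank directory.
#' @return A [template_bank()].
#' @export
read_template_bank <- function(dir) {
  idx_path <- file.path(dir, "index.csv")
  if (!file.exists(idx_path))
    stop_cnap(sprintf("no index.csv in %s", dir), "cnapsim_format_error")
  idx <- utils::read.csv(idx_path)
  template_bank(lapply(file.path(dir, idx$file), read_template))
}

#' Write a CNAP signal as delimited text
#'
#' Columns `time_ms` and `amplitude_mV`, both formatted with 9 significant
#' digits so identical runs produce byte-identical files.
#'
#' @param result A [cnap_result][simulate_cnap()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cnap_csv <- function(result, path) {
  stopifnot(inherits(result, "cnap_result"))
  tab <- data.frame(time_ms = sprintf("%.9g", result$time_ms),
                    amplitude_mV = sprintf("%.9g", result$signal_mV))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
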