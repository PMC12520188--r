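# Delimited-text I/O. All traces are plain whitespace-delimited text with a
# '#'-prefixed comment header stating units (N, mm, MPa, s; relaxation times
# in ms; permeability in mm^4/(N s)) and generator settings.

write_header <- function(con, lines) {
  if (length(lines)) writeLines(paste0("# ", lines), con)
}

#' Write a numeric trace as delimited text with a comment header
#'
#' @param df data.frame of numeric columns (e.g. a load-displacement record
#'   or an indentation record's time/displacement columns).
#' @param path output file path.
#' @param header character vector of comment lines (units, seed, protocol).
#' @return `path`, invisibly.
#' @export
write_trace <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, header)
  utils::write.table(as.data.frame(df), con, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read a delimited trace written by [write_trace()]
#'
#' @param path file path; '#' lines are treated as comments.
#' @return data.frame.
#' @export
read_trace <- function(path) {
  utils::read.table(path, header = TRUE, comment.char = "#", sep = "\t")
}

#' Write a cohort table as CSV with a JSON sidecar of generator settings
#'
#' @param table cohort data.frame (e.g. from [generate_cohort()]).
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @param settings named list recorded in the sidecar (seed, design
#'   parameters, package version).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, settings = list()) {
  utils::write.csv(table, path, row.names = FALSE)
  settings$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(settings, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV path written by [write_cohort()].
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
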