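#' Fingerprint of a configuration object
#'
#' Stable MD5 over a canonical serialization; embedded in every report so a
#' result can be traced to the exact configuration that produced it.
#'
#' @param config any R object (typically a named list of parameters)
#' @return 32-character hex string
#' @export
config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, ascii = TRUE)
  unname(tools::md5sum(tmp))
}

report_header <- function(config, seed) {
  list(package = "bbscargo",
       version = as.character(utils::packageVersion("bbscargo")),
       seed = seed,
       config_hash = config_fingerprint(config))
}

#' Write a JSON report with provenance header
#'
#' Every report embeds the package version, the seed, and a configuration
#' fingerprint, so reruns are byte-identical for identical inputs.
#'
#' @param results named list of results (JSON-serializable)
#' @param path output path
#' @param config the configuration that produced the results
#' @param seed the seed used
#' @return `path`, invisibly
#' @export
write_report_json <- function(results, path, config = list(), seed = NA) {
  out <- c(report_header(config, seed), list(results = results))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write a TSV report with provenance header comments
#'
#' @param table data.frame
#' @param path output path
#' @param config the configuration that produced the table
#' @param seed the seed used
#' @return `path`, invisibly
#' @export
write_report_tsv <- function(table, path, config = list(), seed = NA) {
  hdr <- report_header(config, seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(hdr), unlist(hdr)), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
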