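#' Read and write treatment tables
#'
#' Treatment tables travel as comma-separated text with the header
#' `duration,replicate,parameter,value`; lines starting with `#` carry
#' provenance metadata (package version, seed, registry version) and are
#' ignored on read.
#'
#' @param path File path.
#' @return `read_treatment_table()` returns the validated data frame.
#' @export
read_treatment_table <- function(path) {
  as_treatment_table(utils::read.csv(path, comment.char = "#",
                                     stringsAsFactors = FALSE))
}

#' @rdname read_treatment_table
#' @param table A treatment table.
#' @param metadata Named character vector written as `# key: value`
#'   header lines.
#' @export
write_treatment_table <- function(table, path, metadata = character()) {
  table <- as_treatment_table(table)
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c("package" = paste0("cottonwl ",
                               as.character(utils::packageVersion("cottonwl"))),
            metadata)
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a registry (or batch of fits) to the registry file format
#'
#' @param registry A `curve_registry` or named list of fits/curves.
#' @param path Output path.
#' @export
write_registry <- function(registry, path) {
  tab <- registry_table(registry)
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(registry, "curve_registry")) {
    writeLines(sprintf("# registry version: %s", registry$version), con)
  }
  utils::write.csv(tab, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}
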