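# Shared file output: plain-text tables and arrays, a JSON-lines run log,
# and a content-hash manifest. All formats are text (CSV/TSV/JSON/YAML).

#' Write results to an output directory with a content-hash manifest
#'
#' Each named element of `results` is written by type: data frames as CSV,
#' matrices as TSV, numeric vectors/lists as JSON. A `log.jsonl` records the
#' package version and the result inventory (one JSON object per line), the
#' normalized configuration (when given) is echoed to `config.yaml` for
#' provenance, and `manifest.csv` lists every written file with its MD5
#' content hash. Identical runs produce identical hashes: nothing
#' time-dependent is written.
#'
#' @param results Named list of results.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` to echo.
#' @return Invisibly, the manifest data frame (columns `file`, `md5`).
#' @export
#' @examples
#' d <- file.path(tempdir(), "sfdtd-demo")
#' m <- write_outputs(list(tbl = data.frame(a = 1:3)), d)
#' m$file
write_outputs <- function(results, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(is.list(results))
  if (length(results) && is.null(names(results))) {
    stop("`results` must be a named list")
  }
  written <- character(0)

  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE)
    } else if (is.matrix(x)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", row.names = FALSE, col.names = FALSE)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
    }
    written <- c(written, f)
  }

  if (!is.null(config)) {
    f <- file.path(dir, "config.yaml")
    save_config(config, f)
    written <- c(written, f)
  }

  logf <- file.path(dir, "log.jsonl")
  con <- file(logf, open = "wt")
  writeLines(jsonlite::toJSON(
    list(package = "sfdtd",
         version = as.character(utils::packageVersion("sfdtd")),
         results = names(results)),
    auto_unbox = TRUE), con)
  for (nm in names(results)) {
    writeLines(jsonlite::toJSON(
      list(result = nm, class = class(results[[nm]])[1]),
      auto_unbox = TRUE), con)
  }
  close(con)
  written <- c(written, logf)

  manifest <- data.frame(
    file = basename(written),
    md5 = unname(tools::md5sum(written)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
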