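#' Write / read a simulation truth ledger as JSON
#'
#' The ledger is the simulator's ground truth (site classes, singleton
#' carriers, planted duplication regions, planted coding impacts, mito
#' lineages and injected errors) and is what recovery tests compare
#' against.
#'
#' @param ledger a ledger list from [simulatePopulation()] or
#'   [simulateMito()].
#' @param path file path.
#' @export
writeTruthLedger <- function(ledger, path) {
  jsonlite::write_json(ledger, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruthLedger
#' @return `readTruthLedger` returns the ledger list (data.frame elements
#'   restored).
#' @export
readTruthLedger <- function(path) {
  led <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("site_class", "singleton_carrier", "dup_truth",
               "impact_truth", "mito_lineage")) {
    if (!is.null(led[[nm]]) && !is.data.frame(led[[nm]]))
      led[[nm]] <- as.data.frame(led[[nm]], stringsAsFactors = FALSE)
  }
  led
}
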