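# Checkpointing: trained blocks are saved as an RDS blob plus a JSON sidecar
# describing the configuration, and training traces as CSV.

#' Save a trained block
#'
#' @param fit an `imputation_fit` or `ite_fit`.
#' @param path base path; writes `<path>.rds`, `<path>.json` and
#'   `<path>_trace.csv`.
#' @return base path, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, c("imputation_fit", "ite_fit")))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(fit, paste0(path, ".rds"))
  jsonlite::write_json(c(list(class = class(fit)), unclass(fit$config)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (nrow(fit$trace))
    write.csv(fit$trace, paste0(path, "_trace.csv"), row.names = FALSE)
  invisible(path)
}

#' Load a trained block saved by [save_checkpoint()]
#'
#' @param path base path used at save time.
#' @return the saved fit object.
#' @export
load_checkpoint <- function(path) {
  f <- paste0(path, ".rds")
  if (!file.exists(f)) stop("load_checkpoint: no checkpoint at ", path)
  readRDS(f)
}
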