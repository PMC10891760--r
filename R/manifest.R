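#' Write a run manifest
#'
#' Records everything needed to replay a reconstruction exactly: the full
#' configuration snapshot (including seeds), the partition plan, per-device
#' per-stage iteration counts, solver constants, any metric results, and
#' the package version.
#'
#' @param path output JSON path.
#' @param config the \code{\link{recon_config}} used.
#' @param plan the \code{partition_plan} used (or \code{NULL} for a
#'   single-device run).
#' @param device_iterations list (per device) of per-stage iteration
#'   counts.
#' @param constants named list of solver constants (e.g. \code{lambda_reg},
#'   \code{mu0}).
#' @param metrics optional named list of metric results.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, plan = NULL,
                           device_iterations = list(),
                           constants = list(), metrics = NULL) {
  obj <- list(
    package_version = as.character(utils::packageVersion("cine5d")),
    config = unclass(config),
    partition = if (is.null(plan)) NULL else
      jsonlite::fromJSON(plan_to_json(plan), simplifyVector = FALSE),
    device_iterations = lapply(device_iterations, function(it)
      list(per_stage = as.integer(it),
           formatted = format_iterations(it))),
    constants = constants,
    metrics = metrics)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", digits = NA), path)
  invisible(path)
}
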