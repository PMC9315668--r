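#' Write simulation outputs with a reproducibility manifest
#'
#' Writes the trace and event log as CSV (comma-separated, '.' decimal,
#' UTF-8, no row names; units carried in the column-name suffixes),
#' any summary tibbles/lists as JSON, and a `manifest.json` holding the
#' resolved parameter snapshot, seed, time step, protocol, package
#' version, wall-clock start and an MD5 content hash of every output
#' file.
#'
#' @param out_dir output directory (created if needed).
#' @param params the resolved [bouton_params()] object.
#' @param trace optional trace tibble.
#' @param events optional event-log tibble.
#' @param summary optional list or tibble of summary statistics.
#' @param seed,dt,protocol reproducibility metadata.
#' @return Invisibly, the manifest as a list.
#' @export
write_run_outputs <- function(out_dir, params, trace = NULL, events = NULL,
                              summary = NULL, seed = NA, dt = NA,
                              protocol = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  unit_map <- c(time = "time_ms", ca_cyt = "ca_cyt_uM", ca_iprn = "ca_iprn_uM",
                ca_az = "ca_az_uM", ca_total = "ca_total_uM",
                ca_er = "ca_er_uM", ip3 = "ip3_uM", V = "V_mV",
                j_vgcc = "j_vgcc_uM_per_ms",
                release_rate = "release_rate_per_ms")
  if (!is.null(trace)) {
    tr <- trace
    hit <- names(tr) %in% names(unit_map)
    names(tr)[hit] <- unit_map[names(tr)[hit]]
    f <- file.path(out_dir, "trace.csv")
    utils::write.csv(tr, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(events)) {
    ev <- events
    names(ev)[names(ev) == "time"] <- "time_ms"
    f <- file.path(out_dir, "events.csv")
    utils::write.csv(ev, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(summary)) {
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, f)
  }
  manifest <- list(
    package = "boutonsim",
    version = as.character(utils::packageVersion("boutonsim")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, dt_ms = dt,
    protocol = if (!is.null(protocol)) unclass(protocol) else NULL,
    condition = params$condition, coupling = params$coupling_preset,
    unit_note = params$meta$unit_note,
    parameters = unclass(params),
    outputs = if (length(files) > 0) {
      stats::setNames(as.list(unname(tools::md5sum(files))), basename(files))
    } else list()
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
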