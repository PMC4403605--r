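#' Write a machine-readable run report
#'
#' Every command-line run emits a JSON report sufficient for exact
#' re-execution: the command and arguments, md5 digests of the input files,
#' the scenario in effect, the list of output files (all of which exist on
#' success), and solver statistics or warnings.
#'
#' @param path output JSON path.
#' @param command command name.
#' @param args named list of arguments as invoked.
#' @param inputs character vector of input file paths (digested).
#' @param scenario a [Scenario-class] or NULL.
#' @param outputs character vector of output files written.
#' @param solver named list of solver statistics.
#' @param warnings character vector.
#' @return invisibly, the report list.
#' @export
writeRunReport <- function(path, command, args = list(), inputs = character(0),
                           scenario = NULL, outputs = character(0),
                           solver = list(), warnings = character(0)) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  scen <- if (!is.null(scenario)) list(
    name = scenario@name, photon_influx = scenario@photon_influx,
    maintenance_atp = scenario@maintenance_atp,
    rubisco_coupled = scenario@rubisco_coupled,
    oxygenase_fraction = scenario@oxygenase_fraction,
    respiration_fraction = scenario@respiration_fraction,
    mehler_fraction = scenario@mehler_fraction,
    ros_fraction = scenario@ros_fraction,
    nitrogen_source = scenario@nitrogen_source,
    dynamic_coupling = scenario@dynamic_coupling)
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("run report lists non-existent output(s): ",
         paste(missing, collapse = ", "))
  rep <- list(command = command, args = args, input_digests = digests,
              scenario = scen, outputs = as.list(outputs), solver = solver,
              warnings = as.list(warnings),
              package_version = as.character(utils::packageVersion("cyanoflux")))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(rep)
}
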