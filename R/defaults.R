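.ssanet_env <- new.env(parent = emptyenv())

#' Shipped model parameter defaults
#'
#' Reads the package defaults file, a YAML document holding the AdEx neuron
#' parameters, the named background-noise presets (`"high_spontaneous"`,
#' `"low_spontaneous"`, `"none"`), the synapse parameter sets keyed by
#' pathway (`AtoB`, `AtoC`, `CtoB`, `BtoD`), the input tuning-curve defaults
#' and the log-normal jitter specification. The result is cached for the
#' session.
#'
#' @param file Path to a defaults file; `NULL` (default) uses the file
#'   shipped with the package.
#' @return A named list mirroring the YAML structure.
#' @export
#' @examples
#' d <- ssanetDefaults()
#' d$adex$capacitance
ssanetDefaults <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.ssanet_env$defaults)) {
      return(.ssanet_env$defaults)
    }
    file <- system.file("extdata", "defaults.yaml", package = "ssanet",
                        mustWork = TRUE)
    d <- yaml::read_yaml(file)
    .ssanet_env$defaults <- d
    return(d)
  }
  yaml::read_yaml(file)
}

# internal: stop() with the calling function's name stripped of namespace
.check <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
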