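#' Write a pulse-number conductivity model to JSON
#'
#' Serialises a [pulse_number_model()] to a versioned JSON document with
#' explicit unit annotations, so fitted models can be archived and reloaded
#' by simulation runs.
#'
#' @param model A [pulse_number_model()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [read_conductivity_model()]
#' @export
write_conductivity_model <- function(model, path) {
  stopifnot(inherits(model, "pulse_number_model"))
  doc <- list(
    schema = "pulsecond/pulse_number_model",
    schema_version = 1L,
    units = list(
      a1 = "dimensionless", b1 = "pulses", c1 = "dimensionless",
      a2 = "V m^-1 pulses", b2 = "V/m", c2 = "1/pulse",
      E1_const = "V/m", sigma0 = "S/m", alpha = "1/degC", T0 = "degC"
    ),
    parameters = model[c("a1", "b1", "c1", "a2", "b2", "c2",
                         "E1_const", "sigma0", "alpha", "T0")],
    clamp_N = model$clamp_N
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a pulse-number conductivity model from JSON
#'
#' @param path Path to a file written by [write_conductivity_model()].
#' @return A [pulse_number_model()].
#' @export
read_conductivity_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || doc$schema != "pulsecond/pulse_number_model") {
    stop("Not a pulsecond model file: ", path, call. = FALSE)
  }
  if (!identical(as.integer(doc$schema_version), 1L)) {
    stop("Unsupported model schema version: ", doc$schema_version, call. = FALSE)
  }
  p <- lapply(doc$parameters, as.numeric)
  m <- pulse_number_model(
    a1 = p$a1, b1 = p$b1, c1 = p$c1,
    a2 = p$a2, b2 = p$b2, c2 = p$c2,
    E1_const = p$E1_const, sigma0 = p$sigma0, alpha = p$alpha, T0 = p$T0
  )
  if (!is.null(doc$clamp_N)) m$clamp_N <- doc$clamp_N
  m
}
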