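#' Read model parameters from a config file
#'
#' Parses a YAML-style `key: value` file whose keys map 1:1 onto
#' [model_params()] field names. Missing keys take the defaults; unknown keys
#' are an error (they usually indicate a typo in a sweep script).
#'
#' @param path path to the config file.
#' @return A [model_params()] object.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("current: -0.7", "noise_sd: 0.1055"), f)
#' read_model_config(f)$current
#' @export
read_model_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(model_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(model_params, vals)
}
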