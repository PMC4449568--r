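#' Read a structured run configuration
#'
#' Reads a YAML configuration with up to five sections — `synth`, `sr`,
#' `pi`, `kashif`, `ursino` — each holding overrides for the corresponding
#' parameter constructor. Unknown sections or keys are rejected by name,
#' and defaults reproduce the package's printed constants exactly, so an
#' empty file is a valid configuration.
#'
#' @param path YAML file path.
#' @return A list with elements `synth` ([synth_config()]),
#'   `sr` ([sr_params()]), `pi` ([pi_params()]), `kashif`
#'   ([kashif_params()]), `ursino` ([ursino_params()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("Config file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
    error = function(e) stop_input(sprintf("Cannot parse %s: %s", path, conditionMessage(e)))
  )
  raw <- raw %||% list()
  if (!is.list(raw)) stop_config("The configuration must be a key: value hierarchy.")
  sections <- list(
    synth = synth_config, sr = sr_params, pi = pi_params,
    kashif = kashif_params, ursino = ursino_params
  )
  unknown <- setdiff(names(raw), names(sections))
  if (length(unknown) > 0) {
    stop_config(sprintf("Unknown configuration section: `%s`.", unknown[1]))
  }
  imap(sections, function(ctor, nm) params_from_list(raw[[nm]] %||% list(), ctor, nm))
}

# Apply a named override list to a parameter constructor, rejecting unknown
# keys with the offending key named.
params_from_list <- function(overrides, constructor, section) {
  if (length(overrides) == 0) return(constructor())
  known <- names(formals(constructor))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) > 0 || is.null(names(overrides)) || any(names(overrides) == "")) {
    stop_config(sprintf(
      "Unknown key `%s` in section `%s` (known: %s).",
      if (length(unknown)) unknown[1] else "<unnamed>", section,
      paste(known, collapse = ", ")
    ))
  }
  if ("vm_window" %in% names(overrides) && !is.null(overrides$vm_window)) {
    overrides$vm_window <- as.numeric(unlist(overrides$vm_window))
  }
  do.call(constructor, overrides)
}
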