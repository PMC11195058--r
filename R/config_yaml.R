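#' Read a simulation configuration from YAML
#'
#' Top-level keys map to [simulation_config()] arguments; `hazard_specs` is
#' a mapping from endpoint name to a block with `log_hr` (organ -> per-SD
#' log hazard ratio) and optional `baseline_hazard`, `horizon`, `age_coef`,
#' `sex_coef`, `age_center`.
#'
#' @param path Path to a YAML file.
#' @return A validated `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$hazard_specs)) {
    raw$hazard_specs <- lapply(raw$hazard_specs, function(h) {
      do.call(hazard_spec, c(list(log_hr = unlist(h$log_hr)),
                             h[setdiff(names(h), "log_hr")]))
    })
  }
  if (!is.null(raw$visit_intervals))
    raw$visit_intervals <- lapply(raw$visit_intervals, unlist)
  if (!is.null(raw$age_range)) raw$age_range <- unlist(raw$age_range)
  do.call(simulation_config, raw)
}
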