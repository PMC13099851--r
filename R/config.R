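#' Read a detection configuration from YAML
#'
#' Top-level keys: `px_per_deg`, `sampling_rate`, `patch_side_deg`,
#' `min_saccade_amplitude_deg`, plus one block per detector (`ranking`,
#' `idt`, `ivt`, `moving_window`) holding that method's parameters.
#' Missing keys fall back to the package defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list with elements `cal` (a [calibration_constants()])
#'   and one parameter list per detector.
#' @export
read_gazeshift_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cal <- calibration_constants(
    px_per_deg = raw$px_per_deg %||% 13,
    patch_side_deg = raw$patch_side_deg %||% 15,
    min_saccade_amplitude_deg = raw$min_saccade_amplitude_deg %||% 1
  )
  list(
    cal = cal,
    sampling_rate = raw$sampling_rate %||% 200,
    ranking = raw$ranking %||% list(),
    idt = raw$idt %||% list(),
    ivt = raw$ivt %||% list(),
    moving_window = raw$moving_window %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
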