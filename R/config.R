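#' Read a pipeline configuration file
#'
#' YAML configuration with optional sections `design`, `effects`, `render`,
#' `nutrients` and `seed`; missing entries fall back to the package
#' defaults. Section fields are passed straight to [make_design()],
#' [treatment_effects()], [render_params()] and [nutrient_model()].
#'
#' @param path YAML file path.
#' @return A list with elements `design`, `effects`, `render`, `nutrients`
#'   and `seed`, ready for [simulate_experiment()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  design_args <- cfg$design %||% list()
  if (!is.null(design_args$ratios)) {
    design_args$ratios <- tibble::as_tibble(design_args$ratios)
  }
  list(
    design = do.call(make_design, design_args),
    effects = do.call(treatment_effects, cfg$effects %||% list()),
    render = do.call(render_params, cfg$render %||% list()),
    nutrients = do.call(nutrient_model, cfg$nutrients %||% list()),
    seed = cfg$seed %||% 1L
  )
}
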