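#' Run the quantification pipeline end to end
#'
#' Convenience wrapper chaining calibration, back-calculation,
#' pooled-reference plate normalization, and the filtering cascade.
#'
#' @param transitions transition records (from [read_transition_table()] or
#'   [simulate_dataset()]).
#' @param annotations sample annotations.
#' @param assays assay definitions.
#' @param config a [proteotype_config()].
#' @return A list with `curves`, `quant` (output of [quantify_dataset()]),
#'   `normalized` (output of [normalize_plates()]), `filtered` (output of
#'   [filter_cascade()]), and `matrix` (the final reduced
#'   `concentration_matrix`).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_design(n_strains = 2, n_proteins = 24,
#'                                           n_controls_per_sex = 3),
#'                         truth_config(n_sex_affected = 2,
#'                                      n_ko_affected_per_strain = 0),
#'                         seed = 7)
#' res <- run_pipeline(sim$transitions, sim$annotations, sim$assays)
#' res$filtered$report
run_pipeline <- function(transitions, annotations, assays,
                         config = proteotype_config()) {
  curves <- fit_calibration_curves(transitions, assays,
                                   config$weighting_exponent)
  quant <- quantify_dataset(transitions, curves, assays)
  normalized <- normalize_plates(quant$study, quant$pooled, quant$plate_map,
                                 assays)
  filtered <- filter_cascade(normalized$study, annotations, config)
  list(curves = curves, quant = quant, normalized = normalized,
       filtered = filtered, matrix = filtered$matrix)
}
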