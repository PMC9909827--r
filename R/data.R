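#' Reference volume measurements from a 7-patient CT evaluation cohort
#'
#' Per-patient ground-truth (manual) and automatically measured volumes of
#' subcutaneous fat, visceral fat and muscle over the 41-slice L3-centered
#' window, in cm³. Used as the worked example for [percent_difference()] and
#' the agreement analyses.
#'
#' @return data frame: patient_id, tissue, ground_truth_cm3, predicted_cm3.
#' @export
volume_validation_data <- function() {
  read.csv(system.file("extdata", "volume_validation.csv",
                       package = "bodycomp"),
           stringsAsFactors = FALSE)
}
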