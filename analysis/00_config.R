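# Shared configuration for the analysis scripts: one synthetic multi-site
# cohort (107 subjects ~ a 10% scale of the full-size study design,
# 100 parcels, 200 volumes) with the default planted effects, and the
# standard pipeline parameters (10% density, 10 components, alpha 0.5).
library(fcgrad)

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

analysis_config <- function(seed = 2026) {
  pipeline_config(
    cohort = cohort_config(scale = 0.1, seed = seed),
    density = 0.10, sensitivity_densities = c(0.10, 0.20),
    n_components = 10, alpha = 0.5,
    n_perm = 1000, n_receptor_types = 5, seed = seed
  )
}
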