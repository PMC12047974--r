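# small shared fixtures, built once per test session

tiny_scheme <- function(n_parcels = 28, n_networks = 7, seed = 1) {
  make_parcel_scheme(n_parcels, n_networks, seed = seed)
}

# a minimal cohort for pipeline-level tests: 2 groups x 2 sites
small_cohort_config <- function(seed = 5, effect_config = null_effect_config()) {
  cohort_config(
    n_parcels = 60, scale = NULL,
    group_sizes = c(HC = 12, ROP = 8, ROD = 8, `CHR-P` = 8),
    sites = list(A = list(amp_scale = 1, fc_offset = 0),
                 B = list(amp_scale = 1.1, fc_offset = 0.08)),
    n_timepoints = 120, effect_config = effect_config,
    missing_rate = 0.05, seed = seed
  )
}

# brute-force dispersion oracle: double loops, no shared code with
# dispersion_metrics beyond base R
brute_dispersion <- function(g1, g2, network) {
  nets <- levels(network)
  cent <- matrix(NA_real_, length(nets), 2, dimnames = list(nets, NULL))
  for (n in nets) {
    idx <- which(network == n)
    cent[n, ] <- c(median(g1[idx]), median(g2[idx]))
  }
  within <- sapply(nets, function(n) {
    idx <- which(network == n)
    tot <- 0
    for (i in idx) tot <- tot + sqrt((g1[i] - cent[n, 1])^2 + (g2[i] - cent[n, 2])^2)
    tot / length(idx)
  })
  between <- c()
  for (i in seq_along(nets)) for (j in seq_along(nets)) if (i < j) {
    between <- c(between, sqrt(sum((cent[nets[i], ] - cent[nets[j], ])^2)))
  }
  list(centroids = cent, within = within, between = between)
}
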