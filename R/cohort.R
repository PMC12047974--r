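#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the multi-site clinical study design the pipeline is
#' built for: four groups (healthy controls HC, recent-onset psychosis
#' ROP, recent-onset depression ROD, clinical high-risk CHR-P) whose
#' full-scale sizes 376/243/212/240 are scaled down by `scale`; three
#' acquisition sites with multiplicative kernel-amplitude and additive
#' FC-edge effects; 200-volume parcel time series.
#'
#' @param n_parcels,n_networks parcel scheme size.
#' @param scale group-size scale factor applied to the full-scale sizes.
#' @param group_sizes named integer vector overriding `scale`.
#' @param sites named list of per-site effects (`amp_scale`, `fc_offset`).
#' @param n_timepoints volumes per subject.
#' @param effect_config planted group effects, see [default_effect_config()].
#' @param amp,lengthscale,nugget FC kernel parameters, see [latent_kernel()].
#' @param clinical named list of clinical score definitions; each element
#'   is `list(base=, metric=, coef=, sd=)` where `metric` is one of the
#'   planted per-subject metrics (`mean_g1_<NET>`, `mean_g2_<NET>`,
#'   `within_<NET>`, `range_g1`, `range_g2`) or `NULL` for a pure-noise
#'   score.
#' @param missing_rate missing-at-random rate for clinical columns.
#' @param seed master seed; all per-subject seeds derive from it.
#' @return a named list of class `cohort_config`.
#' @export
cohort_config <- function(n_parcels = 100, n_networks = 7, scale = 0.1,
                          group_sizes = NULL,
                          sites = list(
                            MUC = list(amp_scale = 1.00, fc_offset = 0.00),
                            BSL = list(amp_scale = 1.15, fc_offset = 0.10),
                            TUR = list(amp_scale = 0.90, fc_offset = -0.08)),
                          n_timepoints = 200,
                          effect_config = default_effect_config(),
                          amp = 1, lengthscale = 0.75, nugget = 0.3,
                          clinical = list(
                            gaf = list(base = 65, metric = "mean_g1_VAN",
                                       coef = 6, sd = 5),
                            bdi = list(base = 18, metric = "within_DAN",
                                       coef = -8, sd = 5),
                            cog_total = list(base = 95, metric = "range_g1",
                                             coef = 4, sd = 4),
                            func_social = list(base = 50, metric = NULL,
                                               coef = 0, sd = 10)),
                          missing_rate = 0.05, seed = 1) {
  if (is.null(group_sizes)) {
    group_sizes <- round(c(HC = 376, ROP = 243, ROD = 212, `CHR-P` = 240) * scale)
  }
  cfg <- list(n_parcels = n_parcels, n_networks = n_networks,
              group_sizes = group_sizes, sites = sites,
              n_timepoints = n_timepoints, effect_config = effect_config,
              amp = amp, lengthscale = lengthscale, nugget = nugget,
              clinical = clinical, missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- c("cohort_config", "list")
  cfg
}

# planted per-subject metrics used as clinical-score generators
.planted_metrics <- function(lat, network) {
  net <- as.character(network)
  nets <- unique(net)
  out <- c(range_g1 = diff(range(lat[, 1])), range_g2 = diff(range(lat[, 2])))
  for (n in nets) {
    idx <- net == n
    pts <- lat[idx, , drop = FALSE]
    ctr <- .coord_median(pts)
    out[paste0("mean_g1_", n)] <- mean(pts[, 1])
    out[paste0("mean_g2_", n)] <- mean(pts[, 2])
    out[paste0("within_", n)] <- mean(sqrt((pts[, 1] - ctr[1])^2 +
                                             (pts[, 2] - ctr[2])^2))
  }
  out
}

#' Generate a full synthetic cohort
#'
#' Builds the parcel scheme, plants the ground-truth gradient geometry,
#' assigns subjects to groups and sites (round-robin within group, so
#' every site x group cell is filled), simulates per-subject time
#' series, and derives covariates and clinical scores. Clinical scores
#' are Gaussian linear readouts of each subject's planted gradient
#' metrics with missing-at-random holes.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `scheme`,
#'   `ground_truth`, `timeseries` (named list of timepoints-by-parcels
#'   matrices), `cohort` (covariate `data.frame`) and `config`.
#' @export
synthesize_cohort <- function(config = cohort_config()) {
  if (length(config$sites) < 2) stop("need >= 2 sites")
  if (length(config$group_sizes) < 2) stop("need >= 2 groups")

  scheme <- make_parcel_scheme(config$n_parcels, config$n_networks,
                               seed = config$seed)
  gt <- plant_ground_truth(scheme, config$effect_config, seed = config$seed,
                           site_effects = config$sites)

  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n <- length(groups)
  site_names <- names(config$sites)
  # round-robin site assignment within group keeps cells balanced
  site <- unlist(lapply(config$group_sizes, function(k) {
    rep_len(site_names, k)
  }), use.names = FALSE)
  cells <- table(site, groups)
  if (any(cells < 2)) {
    stop("site x group cells with < 2 subjects cannot be harmonized; ",
         "increase group sizes or drop sites")
  }

  set.seed(config$seed)
  subj_seed <- sample.int(.Machine$integer.max - 1L, n)
  age <- round(stats::rnorm(n, 25, 6), 1)
  age <- pmin(pmax(age, 15), 45)
  sex <- stats::rbinom(n, 1, 0.5)
  mean_fd <- round(pmax(stats::rnorm(n, 0.12, 0.05), 0.02), 4)
  ids <- sprintf("sub-%04d", seq_len(n))

  ts <- vector("list", n)
  names(ts) <- ids
  planted <- vector("list", n)
  for (i in seq_len(n)) {
    ts[[i]] <- synthesize_timeseries(gt, groups[i], site[i],
                                     n_timepoints = config$n_timepoints,
                                     seed = subj_seed[i], amp = config$amp,
                                     lengthscale = config$lengthscale,
                                     nugget = config$nugget)
    lat_i <- subject_latent(gt, groups[i], seed = subj_seed[i])
    planted[[i]] <- .planted_metrics(lat_i, scheme$network)
  }
  planted <- do.call(rbind, planted)

  cohort <- data.frame(subject_id = ids, group = groups, site = site,
                       age = age, sex = sex, mean_fd = mean_fd,
                       seed = subj_seed, stringsAsFactors = FALSE)

  set.seed(config$seed + 1L)
  for (sc in names(config$clinical)) {
    def <- config$clinical[[sc]]
    signal <- if (is.null(def$metric)) 0 else def$coef * planted[, def$metric]
    vals <- def$base + signal + stats::rnorm(n, 0, def$sd)
    if (config$missing_rate > 0) {
      vals[stats::runif(n) < config$missing_rate] <- NA
    }
    cohort[[sc]] <- round(vals, 2)
  }

  structure(list(scheme = scheme, ground_truth = gt, timeseries = ts,
                 cohort = cohort, config = config),
            class = "synthetic_cohort")
}

#' Names of the clinical score columns in a cohort table
#' @param cohort_or_config a `synthetic_cohort`, `cohort_config`, or a
#'   cohort `data.frame` (for which all non-covariate columns are used).
#' @export
clinical_columns <- function(cohort_or_config) {
  if (inherits(cohort_or_config, "synthetic_cohort")) {
    return(names(cohort_or_config$config$clinical))
  }
  if (inherits(cohort_or_config, "cohort_config")) {
    return(names(cohort_or_config$clinical))
  }
  setdiff(names(cohort_or_config),
          c("subject_id", "group", "site", "age", "sex", "mean_fd", "seed"))
}

#' Write a synthetic cohort to tab-separated files
#'
#' Writes the parcel scheme, one headerless time-series matrix per
#' subject, the cohort covariate table (`NA` for missing), a manifest
#' mapping subject ids to time-series files, and a provenance file with
#' every seed needed to regenerate the cohort.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_parcel_scheme(cohort$scheme, file.path(dir, "parcels.tsv"))
  utils::write.table(cohort$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  manifest <- data.frame(subject_id = names(cohort$timeseries),
                         path = file.path("timeseries",
                                          paste0(names(cohort$timeseries), ".tsv")))
  for (i in seq_along(cohort$timeseries)) {
    utils::write.table(cohort$timeseries[[i]],
                       file.path(dir, manifest$path[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prov <- c(sprintf("master_seed\t%d", cohort$config$seed),
            sprintf("%s\t%d", cohort$cohort$subject_id, cohort$cohort$seed))
  writeLines(prov, file.path(dir, "provenance.tsv"))
  invisible(dir)
}
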