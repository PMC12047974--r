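#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults follow
#' the standard gradient-analysis toolchain: 10% row density (20% as
#' the sensitivity re-run), 10 embedding components with anisotropy
#' alpha = 0.5, 10 000 spin permutations, alpha level .05.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort.
#' @param density row-threshold density.
#' @param sensitivity_densities densities for [density_sensitivity()].
#' @param n_components,alpha embedding parameters.
#' @param n_perm spin permutations for receptor associations.
#' @param alpha_level nominal significance level.
#' @param reference_group group whose mean FC anchors the reference.
#' @param contrasts named list of patient-group sets, each compared to
#'   the reference group.
#' @param harmonize_metrics run ComBat on the derived-metric table as
#'   well as on the parcel-wise gradient scores.
#' @param n_receptor_types number of synthetic receptor types.
#' @param seed master seed for spins and receptor maps.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), density = 0.10,
                            sensitivity_densities = c(0.10, 0.20),
                            n_components = 10, alpha = 0.5,
                            n_perm = 1000, alpha_level = 0.05,
                            reference_group = "HC",
                            contrasts = list(
                              ROP_vs_HC = "ROP", ROD_vs_HC = "ROD",
                              `CHR-P_vs_HC` = "CHR-P",
                              patients_vs_HC = c("ROP", "ROD", "CHR-P")),
                            harmonize_metrics = TRUE,
                            n_receptor_types = 5, seed = 1) {
  cfg <- list(cohort = cohort, density = density,
              sensitivity_densities = sensitivity_densities,
              n_components = n_components, alpha = alpha, n_perm = n_perm,
              alpha_level = alpha_level, reference_group = reference_group,
              contrasts = contrasts, harmonize_metrics = harmonize_metrics,
              n_receptor_types = n_receptor_types, seed = as.integer(seed))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# FC matrices for every subject, with the planted additive site offset
# injected at the edge level
.cohort_fc <- function(cohort) {
  site_eff <- cohort$ground_truth$site_effects
  fc <- lapply(seq_along(cohort$timeseries), function(i) {
    m <- compute_fc(cohort$timeseries[[i]])
    off <- site_eff[[cohort$cohort$site[i]]]$fc_offset
    if (!is.null(off) && off != 0) m <- apply_site_offset(m, off)
    m
  })
  names(fc) <- names(cohort$timeseries)
  fc
}

# embed + align all subjects against a reference built from ref_ids
.embed_cohort <- function(fc, ref_ids, density, n_components, alpha) {
  reference <- build_reference(fc[ref_ids], density = density,
                               n_components = n_components, alpha = alpha)
  grads <- lapply(fc, function(m) {
    g <- diffusion_embed(cosine_affinity(threshold_rows(m, density)),
                         n_components = n_components, alpha = alpha)
    procrustes_align(g, reference)
  })
  list(reference = reference, gradients = grads)
}

#' Rank-based group comparisons of differentiation metrics
#'
#' For each configured contrast, residualizes the metric table on age,
#' sex and mean framewise displacement (pooling the contrasted
#' subjects), runs Mann-Whitney tests per metric, and applies
#' Benjamini-Hochberg correction within each metric family (network
#' means per gradient; within-network dispersion; between-network
#' dispersion; range).
#'
#' @param wide subjects-by-metrics matrix from [differentiation_table()].
#' @param cohort cohort covariate `data.frame` (same subject order).
#' @param contrasts named list of patient-group sets.
#' @param reference_group control group label.
#' @return tidy `data.frame`: `contrast`, `family`, `metric`, `U`,
#'   `estimate` (median difference patient - control), `p`, `q`,
#'   `eta_sq`.
#' @export
metric_group_tests <- function(wide, cohort, contrasts,
                               reference_group = "HC") {
  fam <- ifelse(grepl("^mean_g1_", colnames(wide)), "network_mean_g1",
         ifelse(grepl("^mean_g2_", colnames(wide)), "network_mean_g2",
         ifelse(grepl("^within_", colnames(wide)), "within_dispersion",
         ifelse(grepl("^between_", colnames(wide)), "between_dispersion",
                "range"))))
  out <- list()
  for (cn in names(contrasts)) {
    pat <- cohort$group %in% contrasts[[cn]]
    ctl <- cohort$group == reference_group
    use <- pat | ctl
    covs <- cbind(age = cohort$age, sex = cohort$sex,
                  mean_fd = cohort$mean_fd)[use, , drop = FALSE]
    resid <- residualize(wide[use, , drop = FALSE], covs)
    is_pat <- pat[use]
    rows <- lapply(colnames(wide), function(m) {
      mw <- mann_whitney(resid[is_pat, m], resid[!is_pat, m])
      data.frame(contrast = cn, family = fam[match(m, colnames(wide))],
                 metric = m, U = mw$U,
                 estimate = stats::median(resid[is_pat, m]) -
                   stats::median(resid[!is_pat, m]),
                 p = mw$p, eta_sq = mw$eta_sq, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    rows$q <- stats::ave(rows$p, rows$family, FUN = fdr_bh)
    out[[cn]] <- rows
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the full gradient-analysis pipeline on a synthetic cohort
#'
#' Executes: cohort synthesis -> Fisher-z FC (with planted site-edge
#' offsets) -> row thresholding -> cosine affinity -> diffusion
#' embedding -> reference construction from controls -> Procrustes
#' alignment -> ComBat of gradient scores (and, optionally, of derived
#' metrics) -> differentiation metrics -> explained-variance F-test ->
#' regional t-maps -> rank-based metric comparisons -> clinical
#' screening/imputation and correlations -> receptor-map spin
#' associations.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-built `synthetic_cohort` (otherwise
#'   generated from `config$cohort`).
#' @param out_dir optional directory; when given, every intermediate
#'   table plus a run log are written as tab-separated text.
#' @return a results bundle (list) with elements `cohort`, `reference`,
#'   `gradients`, `scores_harmonized`, `metrics`, `ev_table`,
#'   `ev_anova`, `tmaps`, `regional`, `metric_tests`, `clinical`,
#'   `receptor`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }

  if (is.null(cohort)) cohort <- synthesize_cohort(config$cohort)
  tab <- cohort$cohort
  say("cohort: %d subjects, %d parcels, %d sites", nrow(tab),
      nrow(cohort$scheme), length(unique(tab$site)))

  fc <- .cohort_fc(cohort)
  say("stage fc: %d matrices", length(fc))

  hc_ids <- tab$subject_id[tab$group == config$reference_group]
  emb <- .embed_cohort(fc, hc_ids, config$density, config$n_components,
                       config$alpha)
  say("stage embed: reference from %d controls, density %.2f",
      length(hc_ids), config$density)

  # ComBat per gradient on the parcel-wise score tables
  design <- combat_design(tab)
  scores_h <- list()
  for (g in 1:2) {
    m <- t(vapply(emb$gradients, function(x) x$scores[, g],
                  numeric(nrow(cohort$scheme))))
    scores_h[[paste0("g", g)]] <- combat_adjust(m, tab$site, design)
  }
  say("stage combat: harmonized parcel scores for gradients 1-2")

  grads_h <- lapply(seq_along(emb$gradients), function(i) {
    g <- emb$gradients[[i]]
    g$scores[, 1] <- scores_h$g1[i, ]
    g$scores[, 2] <- scores_h$g2[i, ]
    g
  })
  names(grads_h) <- names(emb$gradients)

  mt <- differentiation_table(grads_h, cohort$scheme)
  metrics <- mt$wide
  if (config$harmonize_metrics) {
    metrics <- combat_adjust(metrics, tab$site, design)
    say("stage combat: harmonized %d derived metrics", ncol(metrics))
  }

  ev <- explained_variance_table(emb$gradients)
  ev_anova <- list(
    g1 = explained_variance_anova(ev$ev_g1, tab$group),
    g2 = explained_variance_anova(ev$ev_g2, tab$group)
  )

  covs <- cbind(age = tab$age, sex = tab$sex, mean_fd = tab$mean_fd)
  regional <- list()
  tmaps <- list()
  for (cn in names(config$contrasts)) {
    use <- tab$group %in% c(config$contrasts[[cn]], config$reference_group)
    grp <- as.numeric(tab$group[use] %in% config$contrasts[[cn]])
    for (g in 1:2) {
      key <- paste0(cn, "_g", g)
      regional[[key]] <- regional_glm(scores_h[[g]][use, , drop = FALSE],
                                      grp, covs[use, , drop = FALSE],
                                      contrast = key)
      tmaps[[key]] <- regional[[key]]$t
    }
  }
  say("stage regional: %d t-maps", length(tmaps))

  metric_tests <- metric_group_tests(metrics, tab, config$contrasts,
                                     config$reference_group)
  say("stage metric tests: %d comparisons", nrow(metric_tests))

  clin_cols <- clinical_columns(tab)
  clinical <- NULL
  if (length(clin_cols) > 0) {
    screened <- screen_and_impute_clinical(tab, clin_cols)
    keep <- match(screened$subject_id, rownames(metrics))
    resid_m <- residualize(metrics[keep, , drop = FALSE],
                           covs[keep, , drop = FALSE])
    clinical <- clinical_correlations(
      resid_m, screened[, clin_cols, drop = FALSE])
    say("stage clinical: %d subjects after screening (%d dropped, %d imputed)",
        nrow(screened), attr(screened, "n_dropped"),
        attr(screened, "n_imputed"))
  }

  spins <- spin_permutation_indices(cohort$scheme, config$n_perm,
                                    seed = config$seed)
  rec_raw <- lapply(seq_len(2 * config$n_receptor_types), function(i) {
    simulate_smooth_map(cohort$scheme, seed = config$seed + 100L + i)
  })
  names(rec_raw) <- sprintf("map%02d", seq_along(rec_raw))
  rec_types <- rep(sprintf("receptor%02d", seq_len(config$n_receptor_types)),
                   each = 2)
  receptors <- average_receptor_maps(rec_raw, rec_types)
  receptor <- receptor_association(tmaps, receptors, spins)
  say("stage receptor: %d associations with %d spins", nrow(receptor),
      config$n_perm)

  bundle <- list(cohort = cohort, reference = emb$reference,
                 gradients = grads_h, scores_harmonized = scores_h,
                 metrics = metrics, metrics_tidy = mt$tidy, ev_table = ev,
                 ev_anova = ev_anova, tmaps = tmaps,
                 regional = do.call(rbind, c(regional, make.row.names = FALSE)),
                 metric_tests = metric_tests, clinical = clinical,
                 receptor = receptor, log = log_lines, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_parcel_scheme(cohort$scheme, file.path(out_dir, "parcels.tsv"))
    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(mt$tidy, "metrics.tsv")
    wt(bundle$regional, "regional_tmaps.tsv")
    wt(metric_tests, "metric_tests.tsv")
    wt(ev, "explained_variance.tsv")
    if (!is.null(clinical)) wt(clinical, "clinical_correlations.tsv")
    wt(receptor, "receptor_associations.tsv")
    writeLines(c(sprintf("fcgrad %s; seed %d; density %.2f; n_perm %d",
                         as.character(utils::packageVersion("fcgrad")),
                         config$seed, config$density, config$n_perm),
                 log_lines),
               file.path(out_dir, "run_log.txt"))
  }
  bundle
}

#' Gradient correspondence across threshold densities
#'
#' Re-embeds the cohort at each density and matches gradients across
#' densities by maximal absolute correlation (a greedy one-to-one
#' assignment, which absorbs the order switching that different
#' densities can produce), reporting the matched correlations.
#'
#' @param config a [pipeline_config()]; `config$sensitivity_densities`
#'   supplies the densities unless `densities` is given.
#' @param cohort optional pre-built `synthetic_cohort`.
#' @param densities numeric vector of >= 2 densities.
#' @param n_gradients number of leading gradients to match (default 2).
#' @return `data.frame` with one row per matched gradient pair and per
#'   density pair: `density_a`, `density_b`, `gradient_a`,
#'   `gradient_b`, `r` (absolute correlation of mean aligned scores).
#' @export
density_sensitivity <- function(config = pipeline_config(), cohort = NULL,
                                densities = NULL, n_gradients = 2) {
  if (is.null(densities)) densities <- config$sensitivity_densities
  if (length(densities) < 2) stop("need >= 2 densities")
  if (is.null(cohort)) cohort <- synthesize_cohort(config$cohort)
  fc <- .cohort_fc(cohort)
  hc_ids <- cohort$cohort$subject_id[
    cohort$cohort$group == config$reference_group]

  mean_scores <- lapply(densities, function(d) {
    emb <- .embed_cohort(fc, hc_ids, d, config$n_components, config$alpha)
    Reduce(`+`, lapply(emb$gradients, `[[`, "scores")) /
      length(emb$gradients)
  })

  out <- list()
  for (i in seq_along(densities)[-length(densities)]) {
    for (j in (i + 1):length(densities)) {
      cmat <- abs(stats::cor(mean_scores[[i]][, seq_len(n_gradients)],
                             mean_scores[[j]][, seq_len(n_gradients)]))
      m <- cmat
      for (step in seq_len(n_gradients)) {
        best <- arrayInd(which.max(m), dim(m))
        out[[length(out) + 1]] <- data.frame(
          density_a = densities[i], density_b = densities[j],
          gradient_a = best[1], gradient_b = best[2],
          r = cmat[best[1], best[2]])
        m[best[1], ] <- -Inf
        m[, best[2]] <- -Inf
      }
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
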