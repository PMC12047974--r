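#' Confound regression of nuisance covariates
#'
#' Ordinary-least-squares residuals of each feature on the covariates
#' (with intercept), with the grand mean added back so the residualized
#' features keep interpretable units.
#'
#' @param features numeric vector or subjects-by-features matrix.
#' @param covariates subjects-by-covariates numeric matrix or
#'   `data.frame` (e.g. age, sex, mean framewise displacement); no
#'   missing values.
#' @return residualized features of the same shape.
#' @export
residualize <- function(features, covariates) {
  y <- as.matrix(features)
  x <- cbind(1, as.matrix(covariates))
  if (anyNA(x)) stop("missing covariate values")
  if (nrow(y) <= ncol(x)) stop("need n > number of covariates + 1")
  if (qr(x)$rank < ncol(x)) stop("collinear covariates")
  fit <- solve(crossprod(x), crossprod(x, y))
  res <- y - x %*% fit
  out <- sweep(res, 2, colMeans(y), `+`)
  if (is.null(dim(features))) out <- drop(out)
  out
}

#' Parcel-wise linear-model group comparison (t-map)
#'
#' For every parcel, fits a fixed-effects ordinary linear model of the
#' (aligned, harmonized) gradient score on a group indicator plus
#' covariates, and reports the group-contrast t statistic, two-sided p
#' and Benjamini-Hochberg q across all parcels of the map (one FDR
#' family per gradient x contrast).
#'
#' @param scores subjects-by-parcels matrix of one gradient's scores.
#' @param group logical or 0/1 vector (1 = the patient group of the
#'   contrast).
#' @param covariates subjects-by-covariates matrix (may be `NULL`).
#' @param contrast label stored in the output.
#' @return `data.frame` with one row per parcel: `parcel_id`, `t`,
#'   `p`, `q`, plus the contrast label.
#' @export
regional_glm <- function(scores, group, covariates = NULL,
                         contrast = "patients_vs_HC") {
  y <- as.matrix(scores)
  g <- as.numeric(group)
  if (length(unique(g)) != 2) stop("group indicator must have two levels")
  if (min(table(g)) < 2) stop("need >= 2 subjects per contrasted group")
  x <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) x <- cbind(x, as.matrix(covariates))
  n <- nrow(x)
  if (qr(x)$rank < ncol(x)) stop("degenerate design matrix")
  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, y)
  res <- y - x %*% beta
  df <- n - ncol(x)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * xtx_inv["group", "group"])
  t <- beta["group", ] / se
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(parcel_id = seq_len(ncol(y)) - 1L, t = t, p = p,
             q = fdr_bh(p), contrast = contrast, row.names = NULL)
}

#' Mann-Whitney U test with exact and tie-corrected branches
#'
#' Rank-sum test with midrank tie handling. For pooled sample sizes up
#' to `exact_max` the two-sided p-value is computed by full enumeration
#' of all group assignments (the U distribution is symmetric about
#' `n_a n_b / 2`, so the two-sided p is the probability of a U at least
#' as far from that centre). Larger samples use the normal
#' approximation with tie and continuity corrections. The effect size
#' is the common rank-biserial-style eta squared, `Z^2 / N`.
#'
#' @param a,b numeric samples.
#' @param exact_max largest pooled size for the exact branch.
#' @return list of class `mann_whitney` with `U` (for sample `a`), `p`,
#'   `eta_sq`, `z`, `method`, and `degenerate` (TRUE when all pooled
#'   values are identical, in which case p = 1).
#' @export
mann_whitney <- function(a, b, exact_max = 12) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    return(structure(list(U = na * nb / 2, p = 1, eta_sq = 0, z = 0,
                          method = "degenerate", degenerate = TRUE),
                     class = "mann_whitney"))
  }
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  # tie-corrected normal approximation (always computed; feeds eta^2)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
  cc <- min(0.5, abs(u - mu))
  z <- if (sigma == 0) 0 else (u - mu - sign(u - mu) * cc) / sigma
  p_norm <- min(1, 2 * stats::pnorm(-abs(z)))

  if (n <= exact_max) {
    idx <- utils::combn(n, na)
    u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    p <- p_norm
    method <- "normal approximation (tie/continuity corrected)"
  }
  structure(list(U = u, p = p, eta_sq = z^2 / n, z = z, method = method,
                 degenerate = FALSE),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.4g, eta^2 = %.4g (%s)\n",
              x$U, x$p, x$eta_sq, x$method))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement; order-preserving and never smaller than the input p.
#'
#' @param p vector of p-values in [0, 1] (NA allowed; excluded from the
#'   family and returned as NA).
#' @return vector of q-values, same order as `p`.
#' @export
fdr_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Screen and impute clinical scores
#'
#' Drops subjects with more than `max_missing` (strictly) of their
#' clinical entries missing, then imputes remaining missing values with
#' the group-wise median of the column.
#'
#' @param cohort cohort `data.frame` with a `group` column.
#' @param clinical character vector of clinical column names.
#' @param max_missing missingness fraction above which a subject is
#'   excluded (default 0.3; a subject at exactly 30% is retained).
#' @return the screened/imputed `data.frame`, with attributes
#'   `n_dropped` and `n_imputed`.
#' @export
screen_and_impute_clinical <- function(cohort, clinical,
                                       max_missing = 0.3) {
  if (!"group" %in% names(cohort)) stop("cohort needs a group column")
  miss_frac <- rowMeans(is.na(cohort[, clinical, drop = FALSE]))
  keep <- miss_frac <= max_missing
  out <- cohort[keep, , drop = FALSE]
  n_imputed <- 0L
  for (col in clinical) {
    na_idx <- which(is.na(out[[col]]))
    if (length(na_idx) == 0) next
    med <- tapply(out[[col]], out$group, stats::median, na.rm = TRUE)
    if (anyNA(med[unique(out$group[na_idx])])) {
      stop("clinical column '", col, "' entirely missing within a group")
    }
    out[[col]][na_idx] <- med[as.character(out$group[na_idx])]
    n_imputed <- n_imputed + length(na_idx)
  }
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Metric-by-clinical correlation screen
#'
#' Rank (Spearman, default) or Pearson correlation of every
#' (gradient metric, clinical score) pair, with Benjamini-Hochberg
#' correction across the full matrix. Constant columns yield NA and are
#' excluded from the FDR family.
#'
#' @param metrics subjects-by-metrics numeric matrix.
#' @param clinical subjects-by-scores numeric matrix or `data.frame`
#'   (already screened/imputed).
#' @param method "spearman" (default) or "pearson".
#' @return tidy `data.frame`: `metric`, `clinical`, `r`, `p`, `q`.
#' @export
clinical_correlations <- function(metrics, clinical, method = "spearman") {
  metrics <- as.matrix(metrics)
  clinical <- as.matrix(clinical)
  if (nrow(metrics) != nrow(clinical)) stop("subject mismatch")
  grid <- expand.grid(metric = colnames(metrics),
                      clinical = colnames(clinical),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- metrics[, grid$metric[i]]
    y <- clinical[, grid$clinical[i]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(grid, r = res[, "r"], p = res[, "p"], q = fdr_bh(res[, "p"]))
}

#' One-way F-test of explained-variance ratios across groups
#'
#' Ordinary fixed-effects one-way analysis of variance of per-subject
#' explained-variance ratios; a non-significant result licenses the
#' comparison of gradients between groups (the same components were
#' found in all groups).
#'
#' @param ev numeric vector of per-subject ratios.
#' @param group per-subject group labels (each group >= 2 subjects).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
explained_variance_anova <- function(ev, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("every group needs >= 2 subjects")
  a <- stats::anova(stats::lm(ev ~ group))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p = a$`Pr(>F)`[1])
}
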