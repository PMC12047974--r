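#' Empirical-Bayes (ComBat) site harmonization
#'
#' Removes additive and multiplicative site (batch) effects from a
#' subjects-by-features table while preserving specified biological
#' covariates, using the classic parametric empirical-Bayes
#' location/scale model: feature-wise linear fits with site indicators
#' and preserved covariates; standardization by the pooled residual
#' variance; site location (gamma, Normal prior) and scale (delta^2,
#' Inverse-Gamma prior) parameters shrunk by iterating the conditional
#' posterior updates to convergence; adjusted data rescaled and the
#' preserved effects restored.
#'
#' @param features numeric subjects-by-features matrix (no missing
#'   values).
#' @param site per-subject site labels (>= 2 subjects per site).
#' @param design optional subjects-by-covariates numeric matrix of
#'   biological effects to preserve (group indicators, age, sex, mean
#'   framewise displacement); no intercept column.
#' @param eb use empirical-Bayes shrinkage (TRUE, the standard model) or
#'   the unshrunk per-site estimates.
#' @param tol convergence tolerance of the EB iteration.
#' @param allow_single_site permit a single-site table (returned
#'   unchanged after the location/scale round trip); by default a
#'   single site is an error, as is any singleton site.
#' @return the harmonized matrix, with attribute `site_params` (a list
#'   with per-site `gamma_star` and `delta2_star`).
#' @export
combat_adjust <- function(features, site, design = NULL, eb = TRUE,
                          tol = 1e-4, allow_single_site = FALSE) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("feature table contains missing values")
  site <- factor(site)
  n <- nrow(features)
  if (length(site) != n) stop("site length does not match rows of features")
  tab <- table(site)
  if (any(tab < 2)) {
    stop("singleton site(s) cannot be harmonized: ",
         paste(names(tab)[tab < 2], collapse = ", "),
         " (exclude these subjects or sites)")
  }
  nbatch <- nlevels(site)
  if (nbatch < 2) {
    if (!allow_single_site) {
      stop("need >= 2 sites (set allow_single_site = TRUE to bypass)")
    }
    # nothing to remove: a single batch round-trips unchanged
    attr(features, "site_params") <- list(gamma_star = NULL,
                                          delta2_star = NULL,
                                          sites = levels(site))
    return(features)
  }

  batch_mat <- outer(as.integer(site), seq_len(nbatch), `==`) * 1
  x <- batch_mat
  if (!is.null(design)) {
    design <- as.matrix(design)
    x <- cbind(batch_mat, design)
  }
  if (qr(x)$rank < ncol(x)) {
    stop("rank-deficient design (collinear covariates or confounded site)")
  }

  beta <- solve(crossprod(x), crossprod(x, features))
  grand <- crossprod(tab / n, beta[seq_len(nbatch), , drop = FALSE])
  resid <- features - x %*% beta
  var_pooled <- colSums(resid^2) / n

  stand_mean <- matrix(grand, n, ncol(features), byrow = TRUE)
  if (!is.null(design)) {
    stand_mean <- stand_mean +
      design %*% beta[-seq_len(nbatch), , drop = FALSE]
  }
  z <- (features - stand_mean) / rep(sqrt(var_pooled), each = n)

  gamma_hat <- apply(z, 2, function(col) tapply(col, site, mean))
  delta_hat <- apply(z, 2, function(col) tapply(col, site, stats::var))
  if (nbatch == 1) {
    gamma_hat <- matrix(gamma_hat, nrow = 1)
    delta_hat <- matrix(delta_hat, nrow = 1)
  }

  if (eb && ncol(features) < 2) eb <- FALSE  # EB priors need >= 2 features
  if (eb) {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (b in seq_len(nbatch)) {
      g <- gamma_hat[b, ]
      d <- delta_hat[b, ]
      nb <- tab[b]
      g_bar <- mean(g)
      t2 <- stats::var(g)
      m <- mean(d)
      s2 <- stats::var(d)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      zb <- z[site == levels(site)[b], , drop = FALSE]
      g_new <- g
      d_new <- d
      change <- Inf
      while (change > tol) {
        g_old <- g_new
        d_old <- d_new
        g_new <- (nb * t2 * g + d_new * g_bar) / (nb * t2 + d_new)
        sum2 <- colSums((zb - matrix(g_new, nb, ncol(zb), byrow = TRUE))^2)
        d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / abs(d_old))
      }
      gamma_star[b, ] <- g_new
      delta_star[b, ] <- d_new
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  adj <- z
  for (b in seq_len(nbatch)) {
    idx <- site == levels(site)[b]
    nb <- sum(idx)
    adj[idx, ] <- (z[idx, , drop = FALSE] -
                     matrix(gamma_star[b, ], nb, ncol(z), byrow = TRUE)) /
      rep(sqrt(delta_star[b, ]), each = nb)
  }
  out <- adj * rep(sqrt(var_pooled), each = n) + stand_mean
  dimnames(out) <- dimnames(features)
  attr(out, "site_params") <- list(gamma_star = gamma_star,
                                   delta2_star = delta_star,
                                   sites = levels(site))
  out
}

#' Build a preserved-covariate design matrix from a cohort table
#'
#' Group indicators (reference level dropped), age, sex and mean
#' framewise displacement -- the biological effects ComBat must not
#' remove.
#'
#' @param cohort cohort `data.frame` with columns `group`, `age`, `sex`,
#'   `mean_fd`.
#' @param preserve_group include group indicators (default TRUE).
#' @export
combat_design <- function(cohort, preserve_group = TRUE) {
  parts <- list(age = cohort$age, sex = cohort$sex, mean_fd = cohort$mean_fd)
  m <- do.call(cbind, parts)
  if (preserve_group) {
    g <- factor(cohort$group)
    gm <- stats::model.matrix(~ g)[, -1, drop = FALSE]
    m <- cbind(gm, m)
  }
  m
}
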