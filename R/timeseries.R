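#' Squared-exponential covariance kernel over planted latent coordinates
#'
#' Population covariance of the simulated parcel time series: a
#' squared-exponential kernel in the 2-D latent gradient space plus a
#' diagonal nugget that keeps the matrix strictly positive definite.
#' Parcels close together in gradient space co-fluctuate strongly;
#' correlations decay smoothly with latent distance, which is what lets
#' the downstream affinity/embedding stage recover the planted geometry.
#'
#' @param latent parcel-by-2 latent coordinate matrix.
#' @param amp kernel amplitude (signal variance).
#' @param lengthscale kernel length scale in latent units.
#' @param nugget diagonal noise variance (> 0).
#' @return a positive-definite parcel-by-parcel covariance matrix.
#' @export
latent_kernel <- function(latent, amp = 1, lengthscale = 0.75, nugget = 0.3) {
  if (nugget <= 0) stop("nugget must be > 0 (diagonal noise variance)")
  d2 <- as.matrix(stats::dist(latent))^2
  k <- amp * exp(-d2 / (2 * lengthscale^2))
  diag(k) <- diag(k) + nugget
  k
}

#' Simulate one subject's parcel time series
#'
#' Draws `n_timepoints` i.i.d. zero-mean Gaussian vectors whose
#' population covariance is [latent_kernel()] evaluated at the subject's
#' group-specific latent coordinates, with the subject's site scaling
#' the kernel amplitude. Deterministic given `seed`.
#'
#' @param ground_truth a `ground_truth` object.
#' @param group,site subject covariates; `site` must be named in the
#'   ground truth's `site_effects` (or `NULL` for no site effect).
#' @param n_timepoints number of volumes (default 200, i.e. ~10 min at a
#'   3 s repetition time).
#' @param seed integer seed (drives both latent jitter and the series).
#' @param amp,lengthscale,nugget kernel parameters, see [latent_kernel()].
#' @return a `n_timepoints x n_parcels` numeric matrix.
#' @export
synthesize_timeseries <- function(ground_truth, group, site = NULL,
                                  n_timepoints = 200, seed = 1,
                                  amp = 1, lengthscale = 0.75, nugget = 0.3) {
  if (n_timepoints < 10) stop("n_timepoints must be >= 10")
  amp_scale <- 1
  if (!is.null(site) && !is.null(ground_truth$site_effects)) {
    se <- ground_truth$site_effects[[site]]
    if (is.null(se)) stop("unknown site: ", site)
    amp_scale <- se$amp_scale
  }
  lat <- subject_latent(ground_truth, group, seed = seed)
  k <- latent_kernel(lat, amp = amp * amp_scale,
                     lengthscale = lengthscale, nugget = nugget)
  ch <- tryCatch(chol(k), error = function(e) {
    stop("covariance kernel is not positive definite; increase the nugget ",
         "parameter (currently ", nugget, ")")
  })
  set.seed(as.integer(seed) + 1L)
  z <- matrix(stats::rnorm(n_timepoints * nrow(lat)), nrow = n_timepoints)
  z %*% ch
}
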