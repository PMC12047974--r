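#' Default effect configuration for the synthetic cohort
#'
#' Encodes the planted effect structure used throughout the package's
#' simulations, one effect family per patient group so each is
#' recoverable in its own contrast: the psychosis group carries a
#' negative ventral-attention (VAN) shift on gradient 1, the high-risk
#' group a positive somatomotor (SMN) shift, and the depression group
#' shrunken within-network dispersion in the attentional networks
#' (DAN, VAN) together with a compressed gradient-1 range (tail
#' compression). All magnitudes are in latent gradient units (the
#' planted latent columns have standard deviations `latent_scale`).
#'
#' @param van_shift gradient-1 mean shift added to VAN parcels for the
#'   ROP group.
#' @param smn_shift gradient-1 mean shift added to SMN parcels for the
#'   CHR-P group.
#' @param attn_dispersion_scale multiplicative within-network dispersion
#'   scale (< 1 shrinks) applied to DAN and VAN for the ROD group.
#' @param range_scale tail-compression slope (< 1 shrinks the range)
#'   applied to gradient 1 for the ROD group; see [subject_latent()].
#' @param noise_sd subject-level Gaussian jitter of latent coordinates.
#' @return a nested list understood by [plant_ground_truth()].
#' @export
default_effect_config <- function(van_shift = -0.15, smn_shift = 0.25,
                                  attn_dispersion_scale = 0.6,
                                  range_scale = 0.5, noise_sd = 0.05) {
  list(
    group_effects = list(
      HC = NULL,
      ROP = list(mean_shift = list(g1 = c(VAN = van_shift))),
      ROD = list(dispersion_scale = c(DAN = attn_dispersion_scale,
                                      VAN = attn_dispersion_scale),
                 range_scale = c(g1 = range_scale)),
      `CHR-P` = list(mean_shift = list(g1 = c(SMN = smn_shift)))
    ),
    noise_sd = noise_sd
  )
}

#' Null effect configuration (no planted group effects)
#' @param noise_sd subject-level latent jitter.
#' @export
null_effect_config <- function(noise_sd = 0.05) {
  list(group_effects = list(HC = NULL, ROP = NULL, ROD = NULL, `CHR-P` = NULL),
       noise_sd = noise_sd)
}

#' Plant ground-truth gradient geometry on a parcel scheme
#'
#' Constructs a two-column latent gradient geometry as smooth functions
#' of the spherical centroids: gradient 1 follows the polar axis (the
#' first-order harmonic `z`), gradient 2 the within-hemisphere
#' longitude (mirror-symmetric across the midline). Together with the
#' z-ordered golden-angle parcel placement these two coordinates tile a
#' near-uniform rectangle in latent space, which keeps the diffusion
#' eigenfunctions of the resulting connectivity approximately linear in
#' the planted axes. (Using two Cartesian harmonics of the same sphere
#' instead concentrates the latent density on an annulus, and the
#' leading eigenfunction becomes the ring angle rather than either
#' planted axis.) Optional seeded network offsets and per-parcel
#' scatter add cluster structure and regional heterogeneity. Columns
#' are centred to zero mean and scaled to `latent_scale`. Group effects
#' (network mean shifts, within-network dispersion scales, global range
#' scales) and site effects are carried along as specifications and
#' applied per subject by [subject_latent()] and downstream FC
#' construction.
#'
#' @param scheme a [make_parcel_scheme()] result.
#' @param effect_config list with `group_effects` and `noise_sd`, see
#'   [default_effect_config()].
#' @param seed integer seed controlling the network offsets.
#' @param latent_scale standard deviations of the two latent columns;
#'   gradient 1 is planted with the larger scale so that embedding
#'   recovers it as the leading component.
#' @param network_offset_sd sd of the seeded per-network offsets.
#' @param parcel_scatter_sd sd of seeded per-parcel scatter around the
#'   smooth harmonic geometry (regional heterogeneity; also breaks the
#'   exact left/right mirror degeneracy of parcel positions).
#' @param site_effects named list per site with elements `amp_scale`
#'   (multiplies the FC kernel amplitude) and `fc_offset` (added later
#'   to Fisher-z FC edges).
#' @return an object of class `ground_truth`.
#' @export
plant_ground_truth <- function(scheme, effect_config = default_effect_config(),
                               seed = 1, latent_scale = c(1, 0.8),
                               network_offset_sd = 0,
                               parcel_scatter_sd = 0.03,
                               site_effects = NULL) {
  validate_scheme(scheme)
  nets <- levels(scheme$network)
  for (g in names(effect_config$group_effects)) {
    eff <- effect_config$group_effects[[g]]
    used <- c(names(eff$mean_shift$g1), names(eff$mean_shift$g2),
              names(eff$dispersion_scale))
    bad <- setdiff(used, nets)
    if (length(bad) > 0) {
      stop("effect config names unknown network(s): ", paste(bad, collapse = ", "))
    }
    if (!is.null(eff$dispersion_scale) && any(eff$dispersion_scale <= 0)) {
      stop("dispersion scale factors must be > 0")
    }
  }

  cc <- scheme_centroids(scheme)
  # hemisphere-aware longitude (right-hemisphere x is un-mirrored), so a
  # parcel and its mirror twin share the same latent position; smooth
  # within each hemisphere's sphere except at the antimeridian seam
  sx <- ifelse(scheme$hemisphere == "R", -cc[, 1], cc[, 1])
  lon <- atan2(cc[, 2], sx)
  base <- cbind(cc[, 3], lon)

  set.seed(as.integer(seed))
  offsets <- matrix(stats::rnorm(length(nets) * 2, sd = network_offset_sd),
                    ncol = 2, dimnames = list(nets, NULL))
  latent <- base + offsets[as.character(scheme$network), ] +
    matrix(stats::rnorm(length(base), sd = parcel_scatter_sd), ncol = 2)
  latent <- scale(latent, center = TRUE, scale = FALSE)
  for (j in 1:2) latent[, j] <- latent[, j] / stats::sd(latent[, j]) * latent_scale[j]
  dimnames(latent) <- list(NULL, c("g1", "g2"))

  structure(list(
    latent = latent,
    network = scheme$network,
    group_effects = effect_config$group_effects,
    site_effects = site_effects,
    noise_sd = effect_config$noise_sd,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

# coordinate-wise median centroid of a point set (rows = points)
.coord_median <- function(pts) apply(pts, 2, stats::median)

#' Group-specific latent coordinates for one subject
#'
#' Applies, in order: within-network dispersion scaling about each
#' network's coordinate-wise median (so the planted within-network
#' dispersion scales exactly by the configured factor), gradient range
#' compression (deviations beyond the 80th percentile of |score - mean|
#' continue with the configured slope, shrinking max - min while
#' leaving the bulk geometry intact), network mean shifts (exact
#' additive construction), then optional i.i.d. Gaussian jitter.
#'
#' @param ground_truth a `ground_truth` object.
#' @param group group label (must appear in the effect config).
#' @param noise_sd jitter sd; defaults to the config's value. Use 0 for
#'   the noiseless planted geometry.
#' @param seed seed for the jitter (ignored when `noise_sd = 0`).
#' @return a parcel-by-2 latent coordinate matrix.
#' @export
subject_latent <- function(ground_truth, group, noise_sd = NULL, seed = 1) {
  if (!group %in% names(ground_truth$group_effects)) {
    stop("unknown group: ", group)
  }
  lat <- ground_truth$latent
  eff <- ground_truth$group_effects[[group]]
  net <- as.character(ground_truth$network)

  if (!is.null(eff$dispersion_scale)) {
    for (n in names(eff$dispersion_scale)) {
      idx <- which(net == n)
      ctr <- .coord_median(lat[idx, , drop = FALSE])
      lat[idx, ] <- sweep(sweep(lat[idx, , drop = FALSE], 2, ctr), 2,
                          rep(eff$dispersion_scale[[n]], 2), `*`)
      lat[idx, ] <- sweep(lat[idx, , drop = FALSE], 2, ctr, `+`)
    }
  }
  if (!is.null(eff$range_scale)) {
    # tail compression: deviations beyond the 80th percentile of |g - mean|
    # continue with slope s < 1, pulling the extremes (hence max - min)
    # toward the centre while leaving the bulk geometry -- and so the
    # affinity spectrum -- essentially unchanged
    for (g in names(eff$range_scale)) {
      j <- match(g, colnames(lat))
      s <- eff$range_scale[[g]]
      mu <- mean(lat[, j])
      dev <- lat[, j] - mu
      t <- stats::quantile(abs(dev), 0.8)
      tail <- abs(dev) > t
      dev[tail] <- sign(dev[tail]) * (t + s * (abs(dev[tail]) - t))
      lat[, j] <- mu + dev
    }
  }
  for (g in intersect(names(eff$mean_shift), colnames(lat))) {
    j <- match(g, colnames(lat))
    for (n in names(eff$mean_shift[[g]])) {
      idx <- net == n
      lat[idx, j] <- lat[idx, j] + eff$mean_shift[[g]][[n]]
    }
  }

  if (is.null(noise_sd)) noise_sd <- ground_truth$noise_sd
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    lat <- lat + matrix(stats::rnorm(length(lat), sd = noise_sd), nrow = nrow(lat))
  }
  lat
}
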