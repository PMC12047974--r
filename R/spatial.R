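#' Uniform random 3-D rotation matrix
#'
#' Drawn via QR decomposition of a Gaussian matrix with sign fixing
#' (Haar measure on SO(3); determinant forced to +1).
#' @return 3x3 rotation matrix.
#' @keywords internal
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Spin-permutation indices for a spherical parcel scheme
#'
#' For each permutation, a uniform random rotation is applied to the
#' left-hemisphere centroids and its x-mirrored counterpart to the
#' right-hemisphere centroids (so the two hemispheres rotate as mirror
#' images). Each parcel is then reassigned the value of the rotated
#' parcel nearest to it, within its own hemisphere. The default
#' nearest-neighbour variant allows duplicated sources; the one-to-one
#' variant (`method = "one_to_one"`) instead builds a greedy
#' distance-ordered matching, yielding true permutations of values.
#'
#' @param scheme a `parcel_scheme` (unit-sphere centroids).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param method "nearest" (default) or "one_to_one".
#' @param rotations optional list of 3x3 rotation matrices (test hook;
#'   overrides the random draws).
#' @return object of class `spin_null`: list with `perm` (n_perm x
#'   n_parcels integer matrix; row k maps parcel i to source `perm[k,i]`),
#'   `seed`, `method`.
#' @export
spin_permutation_indices <- function(scheme, n_perm, seed = 1,
                                     method = c("nearest", "one_to_one"),
                                     rotations = NULL) {
  method <- match.arg(method)
  validate_scheme(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  cc <- scheme_centroids(scheme)
  hemi <- scheme$hemisphere
  idx_l <- which(hemi == "L")
  idx_r <- which(hemi == "R")
  mirror <- diag(c(-1, 1, 1))

  set.seed(as.integer(seed))
  perm <- matrix(NA_integer_, n_perm, nrow(scheme))
  for (k in seq_len(n_perm)) {
    rot <- if (is.null(rotations)) random_rotation() else rotations[[k]]
    rot_r <- mirror %*% rot %*% mirror
    for (h in list(list(idx = idx_l, r = rot), list(idx = idx_r, r = rot_r))) {
      if (length(h$idx) == 0) next
      orig <- cc[h$idx, , drop = FALSE]
      rotated <- orig %*% t(h$r)
      # cross-distance via the cosine of the central angle
      cosang <- tcrossprod(orig, rotated)  # [i_orig, j_rotated]
      if (method == "nearest") {
        perm[k, h$idx] <- h$idx[apply(cosang, 1, which.max)]
      } else {
        m <- cosang
        for (step in seq_len(nrow(m))) {
          best <- arrayInd(which.max(m), dim(m))
          perm[k, h$idx[best[1]]] <- h$idx[best[2]]
          m[best[1], ] <- -Inf
          m[, best[2]] <- -Inf
        }
      }
    }
  }
  structure(list(perm = perm, seed = as.integer(seed), method = method),
            class = "spin_null")
}

#' Spin-permutation test of the spatial correlation of two parcel maps
#'
#' Pearson correlation of two parcel-level maps, with significance
#' assessed against a null built by spinning `map_a` over the sphere
#' (preserving its spatial autocorrelation). The two-sided p uses the
#' standard +1 permutation correction and can therefore never reach 0.
#'
#' @param map_a,map_b numeric parcel maps (equal length, finite).
#' @param spins a `spin_null` built on the same scheme.
#' @return list with `r`, `p_spin`, `n_perm`, `null_r`.
#' @export
spatial_correlation_test <- function(map_a, map_b, spins) {
  if (length(map_a) != length(map_b)) stop("map lengths differ")
  if (ncol(spins$perm) != length(map_a)) {
    stop("spins were built for a different parcel count")
  }
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("constant map: spatial correlation undefined")
  }
  r_obs <- stats::cor(map_a, map_b)
  spun <- matrix(map_a[t(spins$perm)], nrow = length(map_a))
  null_r <- as.vector(stats::cor(spun, map_b))
  n_perm <- nrow(spins$perm)
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (1 + n_perm)
  list(r = r_obs, p_spin = p, n_perm = n_perm, null_r = null_r)
}

#' Z-score and average receptor maps of the same receptor type
#'
#' Each map is standardized across parcels (mean 0, sd 1) and maps
#' sharing a receptor type are averaged arithmetically; singleton types
#' pass through z-scored.
#'
#' @param maps named list of numeric parcel maps.
#' @param types character vector (same length) giving each map's
#'   receptor type.
#' @return named list of averaged maps, one per distinct type.
#' @export
average_receptor_maps <- function(maps, types) {
  if (length(maps) != length(types)) stop("one type per map required")
  len <- unique(vapply(maps, length, integer(1)))
  if (length(len) != 1) stop("receptor maps have mismatched parcel counts")
  zmaps <- lapply(maps, function(m) as.vector(scale(m)))
  out <- lapply(split(zmaps, types), function(group) {
    Reduce(`+`, group) / length(group)
  })
  out[unique(types)]
}

#' Spin-tested correlation table of t-maps against receptor maps
#'
#' Correlates every (t-map, receptor map) pair across parcels, assigns
#' spin-permutation p-values (spinning the t-map by default) and
#' applies Benjamini-Hochberg correction across the whole table.
#'
#' @param tmaps named list of parcel-level t statistics (one per
#'   gradient x contrast).
#' @param receptor_maps named list of (averaged) receptor maps.
#' @param spins a `spin_null` on the same scheme.
#' @param spin_side which map is spun: `"tmap"` (default) or
#'   `"receptor"`.
#' @return `data.frame` with columns `tmap`, `receptor`, `r`, `p_spin`,
#'   `q`.
#' @export
receptor_association <- function(tmaps, receptor_maps, spins,
                                 spin_side = c("tmap", "receptor")) {
  spin_side <- match.arg(spin_side)
  if (length(tmaps) == 0 || length(receptor_maps) == 0) {
    stop("empty map lists")
  }
  grid <- expand.grid(tmap = names(tmaps), receptor = names(receptor_maps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tm <- tmaps[[grid$tmap[i]]]
    rm_ <- receptor_maps[[grid$receptor[i]]]
    st <- if (spin_side == "tmap") {
      spatial_correlation_test(tm, rm_, spins)
    } else {
      spatial_correlation_test(rm_, tm, spins)
    }
    c(r = st$r, p_spin = st$p_spin)
  })
  res <- do.call(rbind, res)
  data.frame(grid, r = res[, "r"], p_spin = res[, "p_spin"],
             q = fdr_bh(res[, "p_spin"]))
}

#' Smooth random map on a parcel scheme
#'
#' A spatially autocorrelated null map: a random linear combination of
#' low-order polynomial harmonics of the centroid coordinates plus a
#' small rough component. Used for spin-test calibration and as
#' synthetic stand-ins for receptor-density maps.
#'
#' @param scheme a `parcel_scheme`.
#' @param seed integer seed.
#' @param rough_sd sd of the parcel-level white-noise component.
#' @return numeric parcel map.
#' @export
simulate_smooth_map <- function(scheme, seed = 1, rough_sd = 0.1) {
  cc <- scheme_centroids(scheme)
  # evaluate on hemisphere-canonical coordinates (right-hemisphere x
  # un-mirrored) so the map is mirror-symmetric, matching how the spin
  # null rotates the two hemispheres as mirror images
  x <- ifelse(scheme$hemisphere == "R", -cc[, 1], cc[, 1])
  y <- cc[, 2]; z <- cc[, 3]
  # orthonormal real spherical harmonics (l = 1, 2, common factors
  # dropped) so that i.i.d. coefficients give a rotation-invariant map
  # distribution -- required for spun copies to be exchangeable
  basis <- cbind(x, y, z,
                 sqrt(3) * x * y, sqrt(3) * x * z, sqrt(3) * y * z,
                 sqrt(3) / 2 * (x^2 - y^2), (3 * z^2 - 1) / 2)
  set.seed(as.integer(seed))
  w <- stats::rnorm(ncol(basis))
  as.vector(basis %*% w) + stats::rnorm(nrow(cc), sd = rough_sd)
}
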