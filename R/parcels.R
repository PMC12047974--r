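#' Build a quasi-uniform spherical parcel scheme with network labels
#'
#' Places parcel centroids by a deterministic golden-angle (Fibonacci)
#' scheme on the unit sphere. Following the surface-analysis
#' convention, each hemisphere is represented on its own complete
#' sphere (so that spin rotations never fold): left-hemisphere
#' centroids are a Fibonacci lattice, right-hemisphere centroids their
#' mirror images across the x = 0 plane. Within each hemisphere,
#' networks are assigned as contiguous blocks of centroids ordered
#' along the z-axis, so that each network occupies a spatially coherent
#' band -- a prerequisite for spin-permutation nulls to be meaningful.
#'
#' The default seven network labels follow the canonical cortical
#' partition: visual (VN), somatomotor (SMN), dorsal attention (DAN),
#' ventral attention/salience (VAN), limbic (LN), frontoparietal control
#' (CN) and default mode (DMN).
#'
#' @param n_parcels total number of parcels (split between hemispheres;
#'   must be at least `2 * n_networks` so each network appears in both
#'   hemispheres).
#' @param n_networks number of networks (>= 2; default 7).
#' @param seed integer seed; the construction is deterministic but the
#'   seed is recorded for provenance.
#' @param network_names optional character vector of length `n_networks`.
#' @return a `data.frame` of class `parcel_scheme` with columns
#'   `parcel_id` (0-based, consecutive), `network` (factor), `hemisphere`
#'   (`"L"`/`"R"`) and unit-norm centroid coordinates `cx`, `cy`, `cz`.
#' @export
make_parcel_scheme <- function(n_parcels, n_networks = 7, seed = 1,
                               network_names = NULL) {
  if (n_networks < 2) stop("n_networks must be >= 2")
  if (n_parcels < 2 * n_networks) {
    stop("n_parcels must be >= 2 * n_networks (need every network in both hemispheres)")
  }
  if (is.null(network_names)) {
    network_names <- if (n_networks == 7) {
      c("VN", "SMN", "DAN", "VAN", "LN", "CN", "DMN")
    } else {
      paste0("N", seq_len(n_networks))
    }
  }
  stopifnot(length(network_names) == n_networks)

  n_left <- ceiling(n_parcels / 2)
  n_right <- n_parcels - n_left

  hemi_points <- function(n) {
    # full-sphere Fibonacci lattice, ordered by z
    i <- seq_len(n)
    z <- -1 + 2 * (i - 0.5) / n
    golden <- (sqrt(5) - 1) / 2
    az <- 2 * pi * ((i * golden) %% 1)
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(cx = r * cos(az), cy = r * sin(az), cz = z)
  }

  blocks <- function(n, k) {
    # contiguous block sizes as even as possible, every block nonempty
    sizes <- rep(floor(n / k), k)
    extra <- n - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    rep(seq_len(k), times = sizes)
  }

  left <- hemi_points(n_left)
  right <- hemi_points(n_right)
  right[, "cx"] <- -right[, "cx"]

  scheme <- data.frame(
    parcel_id = seq_len(n_parcels) - 1L,
    network = factor(network_names[c(blocks(n_left, n_networks),
                                     blocks(n_right, n_networks))],
                     levels = network_names),
    hemisphere = rep(c("L", "R"), c(n_left, n_right)),
    rbind(left, right),
    stringsAsFactors = FALSE
  )
  attr(scheme, "seed") <- as.integer(seed)
  class(scheme) <- c("parcel_scheme", "data.frame")
  scheme
}

#' Centroid coordinates of a parcel scheme as a matrix
#' @param scheme a `parcel_scheme`.
#' @return an `n_parcels x 3` matrix.
#' @export
scheme_centroids <- function(scheme) {
  as.matrix(scheme[, c("cx", "cy", "cz")])
}

validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "data.frame"),
            all(c("parcel_id", "network", "hemisphere", "cx", "cy", "cz") %in%
                  names(scheme)))
  if (!identical(as.integer(scheme$parcel_id), seq_len(nrow(scheme)) - 1L)) {
    stop("parcel_ids must be consecutive 0-based integers")
  }
  norms <- sqrt(rowSums(scheme_centroids(scheme)^2))
  if (any(abs(norms - 1) > 1e-9)) stop("centroids must lie on the unit sphere")
  invisible(scheme)
}

#' @export
print.parcel_scheme <- function(x, ...) {
  cat(sprintf("parcel scheme: %d parcels, %d networks (%s), hemispheres L=%d R=%d\n",
              nrow(x), nlevels(x$network),
              paste(levels(x$network), collapse = "/"),
              sum(x$hemisphere == "L"), sum(x$hemisphere == "R")))
  invisible(x)
}

#' Read / write a parcel scheme as tab-separated text
#'
#' The on-disk format has header `parcel_id network hemisphere cx cy cz`.
#' @param scheme a `parcel_scheme`.
#' @param path file path.
#' @export
write_parcel_scheme <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_scheme
#' @export
read_parcel_scheme <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$network <- factor(df$network, levels = unique(df$network))
  class(df) <- c("parcel_scheme", "data.frame")
  validate_scheme(df)
  df
}
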