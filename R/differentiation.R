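#' Mean gradient score per network
#'
#' @param gradient an aligned `gradient_set` (or a plain scores matrix).
#' @param scheme the matching `parcel_scheme`.
#' @param gradients which gradient columns to summarize (default 1:2).
#' @return `data.frame` with columns `gradient`, `network`, `value`.
#' @export
network_means <- function(gradient, scheme, gradients = 1:2) {
  scores <- if (is.list(gradient)) gradient$scores else gradient
  if (nrow(scores) != nrow(scheme)) stop("scheme does not match parcel count")
  net <- scheme$network
  if (any(table(net) == 0)) stop("empty network in scheme")
  out <- expand.grid(network = levels(net), gradient = gradients,
                     KEEP.OUT.ATTRS = FALSE)
  out$value <- mapply(function(n, g) mean(scores[net == n, g]),
                      out$network, out$gradient)
  out[, c("gradient", "network", "value")]
}

#' Gradient range (max minus min) for one subject
#'
#' A global functional-differentiation index: how far apart the two
#' extremes of the processing hierarchy sit for this subject.
#'
#' @param scores numeric vector of one gradient's parcel scores.
#' @return nonnegative scalar.
#' @export
gradient_range <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 parcels")
  max(scores) - min(scores)
}

#' Within- and between-network dispersion in 2-D gradient space
#'
#' Each network's central position is the coordinate-wise median of its
#' member parcels in the (g1, g2) plane. Within-network dispersion is
#' the mean Euclidean distance from that centre to all member parcels;
#' between-network dispersion is the Euclidean distance between the
#' centres of each unordered network pair (21 pairs for 7 networks).
#'
#' @param g1,g2 parcel score vectors for gradients 1 and 2.
#' @param scheme the matching `parcel_scheme`.
#' @return list with `centroids` (network-by-2 matrix), `within` (named
#'   vector, one per network) and `between` (`data.frame` with columns
#'   `network_a`, `network_b`, `value`).
#' @export
dispersion_metrics <- function(g1, g2, scheme) {
  if (length(g1) != nrow(scheme) || length(g2) != nrow(scheme)) {
    stop("scores do not match scheme parcel count")
  }
  net <- scheme$network
  sizes <- table(net)
  if (any(sizes == 0)) stop("empty network in scheme")
  if (any(sizes < 2)) stop("every network needs >= 2 parcels for dispersion")
  nets <- levels(net)
  pts <- cbind(g1, g2)

  centroids <- t(vapply(nets, function(n) {
    .coord_median(pts[net == n, , drop = FALSE])
  }, numeric(2)))
  colnames(centroids) <- c("g1", "g2")

  within <- vapply(nets, function(n) {
    p <- pts[net == n, , drop = FALSE]
    ctr <- centroids[n, ]
    mean(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2))
  }, 0)

  pairs <- utils::combn(nets, 2)
  between <- data.frame(
    network_a = pairs[1, ], network_b = pairs[2, ],
    value = apply(pairs, 2, function(pr) {
      sqrt(sum((centroids[pr[1], ] - centroids[pr[2], ])^2))
    }),
    stringsAsFactors = FALSE
  )
  list(centroids = centroids, within = within, between = between)
}

#' Full differentiation-metric table for a set of subjects
#'
#' Computes, per subject: network means for gradients 1 and 2, gradient
#' ranges, 7 within-network and 21 between-network dispersion scores,
#' and returns them as one tidy table and as a wide subjects-by-metrics
#' matrix (the harmonization/inference input).
#'
#' @param gradient_sets named list of aligned `gradient_set`s.
#' @param scheme the matching `parcel_scheme`.
#' @return list with `tidy` (`data.frame`: `subject_id`, `metric`,
#'   `network`, `gradient`, `value`) and `wide` (numeric matrix, rows =
#'   subjects, one column per metric).
#' @export
differentiation_table <- function(gradient_sets, scheme) {
  ids <- names(gradient_sets)
  if (is.null(ids)) ids <- sprintf("sub-%04d", seq_along(gradient_sets))
  rows <- lapply(seq_along(gradient_sets), function(i) {
    sc <- gradient_sets[[i]]$scores
    nm <- network_means(gradient_sets[[i]], scheme)
    disp <- dispersion_metrics(sc[, 1], sc[, 2], scheme)
    rbind(
      data.frame(subject_id = ids[i], metric = "network_mean",
                 network = as.character(nm$network),
                 gradient = nm$gradient, value = nm$value),
      data.frame(subject_id = ids[i], metric = "range", network = NA,
                 gradient = 1:2,
                 value = c(gradient_range(sc[, 1]), gradient_range(sc[, 2]))),
      data.frame(subject_id = ids[i], metric = "within_dispersion",
                 network = names(disp$within), gradient = NA,
                 value = unname(disp$within)),
      data.frame(subject_id = ids[i], metric = "between_dispersion",
                 network = paste(disp$between$network_a,
                                 disp$between$network_b, sep = "-"),
                 gradient = NA, value = disp$between$value)
    )
  })
  tidy <- do.call(rbind, rows)

  key <- ifelse(tidy$metric == "network_mean",
                paste0("mean_g", tidy$gradient, "_", tidy$network),
         ifelse(tidy$metric == "range", paste0("range_g", tidy$gradient),
         ifelse(tidy$metric == "within_dispersion",
                paste0("within_", tidy$network),
                paste0("between_", tidy$network))))
  cols <- unique(key)
  wide <- matrix(NA_real_, length(gradient_sets), length(cols),
                 dimnames = list(ids, cols))
  wide[cbind(match(tidy$subject_id, ids), match(key, cols))] <- tidy$value
  list(tidy = tidy, wide = wide)
}
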