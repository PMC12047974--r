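#' Diffusion-map embedding of an affinity matrix
#'
#' Standard diffusion-map construction: the affinity is shifted to be
#' nonnegative if it has negative entries (the shift is recorded),
#' density-normalized as `W' = D^-alpha W D^-alpha` (alpha = 0.5 gives
#' the anisotropic normalization that discounts sampling density),
#' row-normalized to a Markov transition matrix, and eigendecomposed via
#' the conjugate symmetric matrix. The trivial constant eigenvector is
#' dropped; the next `n_components` eigenvectors are returned scaled by
#' `lambda / (1 - lambda)` (the automatic multi-scale diffusion time) or
#' by `lambda^diffusion_time` when a finite time is given. Each
#' column's sign is fixed so its largest-magnitude entry is positive.
#'
#' @param affinity symmetric parcels-by-parcels affinity matrix.
#' @param n_components number of gradients to retain (default 10).
#' @param alpha density-normalization exponent in [0, 1] (default 0.5).
#' @param diffusion_time 0 for automatic `lambda/(1-lambda)` scaling,
#'   otherwise a positive power of the eigenvalues.
#' @return an object of class `gradient_set`: list with `scores`
#'   (parcels x n_components), `eigenvalues` (non-increasing),
#'   `explained_variance` (ratios over retained components), `aligned`
#'   (FALSE) and `shift` (the nonnegativity shift applied, 0 if none).
#' @export
diffusion_embed <- function(affinity, n_components = 10, alpha = 0.5,
                            diffusion_time = 0) {
  p <- nrow(affinity)
  if (!isTRUE(all.equal(affinity, t(affinity), tolerance = 1e-8))) {
    stop("affinity matrix must be symmetric")
  }
  if (n_components >= p) stop("n_components must be < number of parcels")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")

  w <- (affinity + t(affinity)) / 2
  shift <- 0
  mn <- min(w)
  if (mn < 0) {
    shift <- abs(mn)
    w <- w + shift
  }

  d <- rowSums(w)
  if (any(d == 0)) stop("affinity graph has an isolated parcel")
  if (alpha > 0) {
    da <- d^-alpha
    w <- w * tcrossprod(da)
    d <- rowSums(w)
  }
  # Markov matrix D^-1 W is similar to the symmetric D^-1/2 W D^-1/2
  ds <- 1 / sqrt(d)
  s <- w * tcrossprod(ds)
  es <- eigen(s, symmetric = TRUE)

  lam <- es$values
  if (sum(lam > 1 - 1e-10) > 1) {
    stop("affinity graph is disconnected (reducible Markov chain); ",
         "thresholding may be too aggressive")
  }
  # right eigenvectors of the Markov matrix, normalized so the trivial
  # one is constant: psi_k = (D^-1/2 v_k) / (D^-1/2 v_0)
  u <- es$vectors * ds
  psi <- u / u[, 1]

  idx <- 2:(n_components + 1)
  lam_k <- lam[idx]
  scale_k <- if (diffusion_time == 0) lam_k / (1 - lam_k) else lam_k^diffusion_time
  scores <- psi[, idx, drop = FALSE] * rep(scale_k, each = p)

  for (j in seq_len(ncol(scores))) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("g", seq_len(n_components))

  ev <- lam_k / sum(lam_k)
  structure(list(scores = scores, eigenvalues = lam_k,
                 explained_variance = ev, aligned = FALSE, shift = shift,
                 alpha = alpha, diffusion_time = diffusion_time),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient set: %d parcels x %d components (%saligned); EV1-2 = %.1f%%, %.1f%%\n",
              nrow(x$scores), ncol(x$scores), if (x$aligned) "" else "un",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  invisible(x)
}

#' Reference gradients from the control-group mean FC
#'
#' Averages the Fisher-z FC matrices of the control subjects
#' element-wise, then runs the standard thresholding -> cosine affinity
#' -> diffusion embedding chain. The result anchors Procrustes alignment
#' of every individual's gradients.
#'
#' @param fc_list list of symmetric Fisher-z FC matrices (same parcels).
#' @param density row-threshold density (default 0.10).
#' @param n_components,alpha passed to [diffusion_embed()].
#' @return a `gradient_set` with a `provenance` attribute recording the
#'   density, component count and number of averaged subjects.
#' @export
build_reference <- function(fc_list, density = 0.10, n_components = 10,
                            alpha = 0.5) {
  if (length(fc_list) < 1) stop("need at least one control FC matrix")
  p <- nrow(fc_list[[1]])
  if (!all(vapply(fc_list, function(m) all(dim(m) == p), logical(1)))) {
    stop("FC matrices have mismatched parcel counts")
  }
  mean_fc <- Reduce(`+`, lapply(fc_list, unclass)) / length(fc_list)
  ref <- diffusion_embed(cosine_affinity(threshold_rows(mean_fc, density)),
                         n_components = n_components, alpha = alpha)
  attr(ref, "provenance") <- list(density = density,
                                  n_components = n_components,
                                  n_subjects = length(fc_list))
  ref
}

#' Procrustes alignment of subject gradients to a reference
#'
#' Finds the orthogonal matrix `R` minimizing `||S R - Ref||_F` (no
#' scaling, no additional centering) via the SVD of `S' Ref` and returns
#' the rotated scores. Resolves sign flips, component swaps and
#' rotations between a subject's embedding and the reference.
#' Eigenvalues and explained variance are unchanged.
#'
#' @param subject a `gradient_set` (not yet aligned).
#' @param reference a `gradient_set` with identical dimensions.
#' @return the aligned `gradient_set`.
#' @export
procrustes_align <- function(subject, reference) {
  s <- subject$scores
  r <- reference$scores
  if (!all(dim(s) == dim(r))) stop("subject/reference shape mismatch")
  if (isTRUE(subject$aligned)) stop("subject gradients are already aligned")
  m <- crossprod(s, r)
  sv <- svd(m)
  if (min(sv$d) < 1e-12 * max(sv$d)) {
    stop("degenerate cross-product in Procrustes alignment; ",
         "use more embedding components")
  }
  rot <- sv$u %*% t(sv$v)
  out <- subject
  out$scores <- s %*% rot
  colnames(out$scores) <- colnames(s)
  out$aligned <- TRUE
  out$rotation <- rot
  out
}

#' Per-subject explained-variance ratios for gradients 1 and 2
#'
#' @param gradient_sets named list of `gradient_set`s embedded with the
#'   same number of components.
#' @return `data.frame` with columns `subject_id`, `ev_g1`, `ev_g2`.
#' @export
explained_variance_table <- function(gradient_sets) {
  ncomp <- vapply(gradient_sets, function(g) length(g$eigenvalues), integer(1))
  if (length(unique(ncomp)) != 1) {
    stop("gradient sets were embedded with different component counts")
  }
  ids <- names(gradient_sets)
  if (is.null(ids)) ids <- sprintf("sub-%04d", seq_along(gradient_sets))
  data.frame(
    subject_id = ids,
    ev_g1 = vapply(gradient_sets, function(g) g$explained_variance[1], 0),
    ev_g2 = vapply(gradient_sets, function(g) g$explained_variance[2], 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Convenience labels for the first two gradients
#'
#' Assigns the conventional names by correlating each gradient with
#' network-indicator contrasts: a gradient separating visual from
#' somatomotor parcels is labelled "visual-to-sensorimotor"; one
#' separating sensory (VN+SMN) from association (DMN+CN) parcels is
#' labelled "association-to-sensory". Purely a labelled convenience
#' output; the analysis itself uses gradients in computed order.
#'
#' @param gradient a `gradient_set`.
#' @param scheme the matching `parcel_scheme`.
#' @return character vector of labels for g1 and g2.
#' @export
label_gradients <- function(gradient, scheme) {
  net <- as.character(scheme$network)
  vis_smn <- (net == "VN") - (net == "SMN")
  sens_assoc <- (net %in% c("VN", "SMN")) - (net %in% c("DMN", "CN"))
  vapply(1:2, function(j) {
    g <- gradient$scores[, j]
    if (abs(stats::cor(g, vis_smn)) >= abs(stats::cor(g, sens_assoc))) {
      "visual-to-sensorimotor"
    } else {
      "association-to-sensory"
    }
  }, character(1))
}

#' Write gradient scores and eigen-spectrum to tab-separated files
#' @param gradient a `gradient_set`; @param path scores file path; a
#'   sidecar `<path>.spectrum.tsv` holds eigenvalues and ratios.
#' @export
write_gradients <- function(gradient, path) {
  df <- data.frame(parcel_id = seq_len(nrow(gradient$scores)) - 1L,
                   gradient$scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(component = seq_along(gradient$eigenvalues),
                     eigenvalue = gradient$eigenvalues,
                     explained_variance = gradient$explained_variance)
  utils::write.table(side, paste0(path, ".spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
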