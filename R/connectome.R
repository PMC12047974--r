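#' Fisher-z functional connectivity matrix
#'
#' Pearson correlation between all parcel pairs of a timepoints-by-
#' parcels matrix, Fisher z-transformed (atanh). Correlations numerically
#' at +/-1 are clipped to +/-(1 - 1e-7) before the transform; the
#' diagonal is defined as 0.
#'
#' @param ts timepoints-by-parcels numeric matrix.
#' @return symmetric parcels-by-parcels matrix of class `fc_matrix`.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  v <- apply(ts, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance time series (signal dropout) in parcel_id ",
         paste(which(v == 0) - 1L, collapse = ", "))
  }
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # enforce exact symmetry against fp noise
  class(z) <- c("fc_matrix", class(z))
  z
}

#' Inject an additive site effect into FC edges
#'
#' Adds a constant offset to every off-diagonal Fisher-z edge; used by
#' the synthetic pipeline to emulate scanner-specific connectivity
#' shifts that the harmonization stage must remove.
#'
#' @param fc an `fc_matrix`.
#' @param offset additive Fisher-z offset.
#' @export
apply_site_offset <- function(fc, offset) {
  off <- matrix(offset, nrow(fc), ncol(fc))
  diag(off) <- 0
  out <- unclass(fc) + off
  class(out) <- c("fc_matrix", class(out))
  out
}

#' Row-wise density thresholding of an FC matrix
#'
#' Independently for each row, keeps the `k = floor(density * (P - 1))`
#' largest off-diagonal entries by signed value (the strongest positive
#' connections) and zeroes the rest. Ties at the k-th value are broken
#' toward the lowest parcel id for reproducibility. The result is
#' generally asymmetric and is deliberately not symmetrized: the next
#' stage compares row profiles by cosine similarity.
#'
#' @param fc parcels-by-parcels matrix.
#' @param density fraction of connections to retain per row (0, 1).
#' @return matrix of the same shape with zeroed sub-threshold entries.
#' @export
threshold_rows <- function(fc, density = 0.10) {
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  p <- nrow(fc)
  k <- floor(density * (p - 1))
  if (k == 0) stop("density too small: floor(density * (P - 1)) = 0 connections per row")
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    row <- fc[i, ]
    row[i] <- -Inf  # diagonal excluded from selection
    keep <- order(row, seq_len(p), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(k)]
    out[i, keep] <- fc[i, keep]
  }
  attr(out, "density") <- density
  out
}

#' Cosine-similarity affinity between thresholded FC rows
#'
#' Entry (i, j) is the cosine of the angle between rows i and j of the
#' thresholded matrix. Negative similarities are passed through by
#' default; `clamp_negative = TRUE` truncates them at 0.
#'
#' @param x thresholded parcels-by-parcels matrix.
#' @param clamp_negative truncate negative similarities at zero.
#' @return symmetric parcels-by-parcels affinity matrix with unit
#'   diagonal.
#' @export
cosine_affinity <- function(x, clamp_negative = FALSE) {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    stop("all-zero thresholded row for parcel_id ",
         paste(which(nrm == 0) - 1L, collapse = ", "))
  }
  aff <- tcrossprod(x / nrm)
  aff <- (aff + t(aff)) / 2
  aff <- pmin(pmax(aff, -1), 1)
  if (clamp_negative) aff[aff < 0] <- 0
  attr(aff, "density") <- attr(x, "density")
  aff
}

#' Read / write a square matrix as tab-separated text
#'
#' Format: an optional `# key=value ...` comment line followed by a
#' headerless tab-separated square matrix.
#' @param m matrix; @param path file path.
#' @param comment named character vector written as `# k=v` metadata.
#' @export
write_matrix_tsv <- function(m, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", paste(names(comment), comment, sep = "=",
                                  collapse = " ")), con)
  }
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                              comment.char = "#"))
}
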