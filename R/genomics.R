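# Marker QC and genomic relationship matrix construction from dominant
# presence/absence markers coded 0/2.

#' Construct a marker matrix with family labels
#'
#' Markers are dominant presence/absence tags: each line carries the value 2
#' when the tag is present and 0 when absent. Rows are lines, columns are
#' markers; the family label of every line travels with the matrix as the
#' `"family"` attribute.
#'
#' @param markers numeric matrix of 0/2 values with unique rownames (line IDs)
#'   and colnames (marker IDs).
#' @param family character vector of family labels, one per line (recycled if
#'   length 1). Named vectors are matched to rownames.
#' @return A numeric matrix of class `marker_matrix` with a `family` attribute.
#' @export
marker_matrix <- function(markers, family) {
  if (!is.matrix(markers) || nrow(markers) < 1L || ncol(markers) < 1L)
    sgs_stop("markers must be a non-empty matrix", "sgs_input_error")
  if (is.null(rownames(markers)) || anyDuplicated(rownames(markers)))
    sgs_stop("marker matrix needs unique rownames (line IDs)", "sgs_input_error")
  if (is.null(colnames(markers)))
    colnames(markers) <- id_label("M", seq_len(ncol(markers)), ncol(markers))
  bad <- which(!(markers %in% c(0, 2)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(markers))
    sgs_stop(sprintf(
      "marker values must be 0 or 2; first offending cell: line '%s', marker '%s' (value %s)",
      rownames(markers)[i[1]], colnames(markers)[i[2]], markers[bad[1L]]),
      "sgs_coding_error")
  }
  if (length(family) == 1L) family <- rep(family, nrow(markers))
  if (!is.null(names(family))) family <- family[rownames(markers)]
  if (length(family) != nrow(markers) || anyNA(family))
    sgs_stop("family must supply one label per line", "sgs_input_error")
  structure(markers, family = stats::setNames(as.character(family), rownames(markers)),
            class = c("marker_matrix", class(markers)))
}

#' Family labels of a marker matrix
#' @param x a `marker_matrix`.
#' @return Named character vector of family labels.
#' @export
families <- function(x) attr(x, "family")

#' Per-marker minor allele frequency
#'
#' With the 0/2 dominant coding the frequency of the presence allele at a
#' marker is `p = mean(value) / 2`; the minor allele frequency is
#' `min(p, 1 - p)`.
#'
#' @param markers matrix of 0/2 marker values (lines x markers).
#' @return Named numeric vector of MAF values, one per marker.
#' @export
#' @examples
#' m <- matrix(c(0, 2, 2, 2), ncol = 1, dimnames = list(paste0("L", 1:4), "M1"))
#' compute_maf(m)  # p = 0.75 so MAF = 0.25
compute_maf <- function(markers) {
  if (is.null(dim(markers)) || nrow(markers) == 0L || ncol(markers) == 0L)
    sgs_stop("empty marker matrix", "sgs_input_error")
  p <- colMeans(markers) / 2
  stats::setNames(pmin(p, 1 - p), colnames(markers))
}

#' Filter markers on minor allele frequency
#'
#' Retains markers whose MAF is strictly greater than `threshold`, preserving
#' marker order.
#'
#' @param markers a `marker_matrix` (or plain 0/2 matrix).
#' @param threshold MAF threshold; markers with `MAF > threshold` are kept.
#' @return The filtered marker matrix.
#' @export
filter_markers <- function(markers, threshold = 0.05) {
  maf <- compute_maf(markers)
  keep <- maf > threshold
  if (!any(keep))
    sgs_stop(sprintf("no markers survive the MAF > %g filter", threshold),
             "sgs_filter_error")
  out <- markers[, keep, drop = FALSE]
  if (inherits(markers, "marker_matrix"))
    out <- marker_matrix(unclass(out), families(markers))
  out
}

#' Genomic relationship matrix from 0/2 dominant markers
#'
#' VanRaden method 1 treating the presence/absence code as an allele dosage:
#' columns are centered by twice the presence-allele frequency and
#' `G = W W' / sum(2 p (1 - p))`. For fully homozygous doubled-haploid lines
#' the diagonal exceeds 1 on average; for an outbred panel in
#' Hardy-Weinberg proportions it averages about 1.
#'
#' @param markers matrix of 0/2 values (lines x markers).
#' @return Symmetric relationship matrix with line IDs as dimnames.
#' @export
compute_grm <- function(markers) {
  if (is.null(dim(markers)) || nrow(markers) < 2L)
    sgs_stop("need at least 2 lines to build a relationship matrix", "sgs_input_error")
  p <- colMeans(markers) / 2
  poly <- p > 0 & p < 1
  if (!any(poly))
    sgs_stop("all markers are monomorphic; relationship matrix undefined", "sgs_input_error")
  X <- markers[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(X, 2L, 2 * p, "-")
  denom <- sum(2 * p * (1 - p))
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(markers), rownames(markers))
  G
}

#' Ridge-regularize a relationship matrix
#'
#' Adds `epsilon` to the diagonal so the matrix is numerically invertible
#' (required wherever the inverse relationship matrix enters reliability or
#' mixed-model computations). The epsilon used is recorded as an attribute.
#'
#' @param G symmetric relationship matrix.
#' @param epsilon non-negative ridge; with `epsilon > |min eigenvalue|` the
#'   result is positive definite.
#' @return `G + epsilon * I` with attribute `"epsilon"`.
#' @export
regularize_grm <- function(G, epsilon = 1e-6) {
  check_symmetric(G, name = "G")
  out <- G + diag(epsilon, nrow(G))
  dimnames(out) <- dimnames(G)
  attr(out, "epsilon") <- epsilon
  out
}
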