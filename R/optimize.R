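# Calibration-set optimization: per-individual CDmean reliabilities for
# splitting full-sib families across environments, and average-relationship
# selection of historical training individuals.

#' Family-mean contrast matrix
#'
#' Column j contrasts individual j against the family mean: entry j is
#' `(n-1)/n` and every other entry `-1/n`, so each column sums to zero
#' (`1'K = 0`).
#'
#' @param n family size (>= 2).
#' @param cols which individuals to build contrasts for (default all).
#' @return n x length(cols) contrast matrix.
#' @export
#' @examples
#' contrast_matrix(4)[, 1]  # (3/4, -1/4, -1/4, -1/4)
contrast_matrix <- function(n, cols = seq_len(n)) {
  if (n < 2) sgs_stop("contrasts need a family of at least 2", "sgs_input_error")
  K <- matrix(-1 / n, n, length(cols))
  K[cbind(cols, seq_along(cols))] <- (n - 1) / n
  K
}

#' Expected reliability (CD) of contrasts under a candidate calibration set
#'
#' Computes the coefficient of determination of each contrast column,
#' `CD(K) = diag[K' (G - lambda (Z'DZ + lambda G^-1)^-1) K] / diag[K' G K]`,
#' where `Z` is the incidence of calibration phenotypes onto family members
#' and `D` projects out the fixed effects of the calibration records.
#' `lambda` plays the role of the residual-to-genetic variance ratio.
#'
#' By default `fixed = "none"` (D is the identity): the contrasts are already
#' mean-invariant (`1'K = 0`), and projecting an intercept out of a
#' single-record calibration set would annihilate its information entirely
#' (with one record, `D = 0` and every CD is 0). `fixed = "intercept"` is
#' available for calibration sets with two or more records.
#'
#' With `lambda = 0` the penalty term vanishes and every contrast has CD 1;
#' CD decreases monotonically in `lambda` and always lies in `[0, 1]` for PSD
#' `G`.
#'
#' @param G family relationship matrix (invertible; regularize first).
#' @param calibration indices of phenotyped (calibration) individuals.
#' @param K contrast matrix (rows = family members).
#' @param lambda non-negative variance ratio (default 0.5).
#' @param fixed `"none"` or `"intercept"`.
#' @return Numeric vector, one CD value per contrast column.
#' @export
cd_reliability <- function(G, calibration, K, lambda = 0.5,
                           fixed = c("none", "intercept")) {
  fixed <- match.arg(fixed)
  if (!length(calibration)) sgs_stop("calibration set is empty", "sgs_input_error")
  if (lambda < 0) sgs_stop("lambda must be >= 0", "sgs_input_error")
  n <- nrow(G)
  denom <- colSums(K * (G %*% K))
  if (lambda == 0) return(rep(1, ncol(K)))
  nc <- length(calibration)
  Z <- matrix(0, nc, n)
  Z[cbind(seq_len(nc), calibration)] <- 1
  D <- if (fixed == "intercept") {
    diag(nc) - matrix(1 / nc, nc, nc)
  } else diag(nc)
  Ginv <- tryCatch(solve(G), error = function(e)
    sgs_stop("family G is singular; regularize_grm() it first", "sgs_numeric_error"))
  M <- crossprod(Z, D %*% Z) + lambda * Ginv
  Minv <- tryCatch(solve(M), error = function(e)
    sgs_stop("Z'DZ + lambda * G^-1 is singular; increase the ridge on G",
             "sgs_numeric_error"))
  num <- colSums(K * ((G - lambda * Minv) %*% K))
  num / denom
}

#' Per-individual CDmean scores within a full-sib family
#'
#' For each individual g of an N-member family, individual g alone serves as
#' the calibration set and the expected reliabilities of the family-mean
#' contrasts of the remaining N-1 sibs are averaged: `CDmean(g) =
#' mean(diag(CD(K)))`. High-CDmean individuals are the ones whose phenotype
#' is most informative about their sibs, which is what the sparse-testing
#' split exploits.
#'
#' `mode = "calibrate"` (default) scores individual g by the reliabilities it
#' delivers when g is phenotyped. The alternative reading, `mode =
#' "validate"`, scores g by the mean reliability of predicting g when each
#' other sib calibrates in turn.
#'
#' @param G family relationship matrix (members x members, invertible).
#' @param lambda variance ratio (default 0.5).
#' @param mode `"calibrate"` or `"validate"`.
#' @param fixed passed to [cd_reliability()].
#' @return Object of class `cd_scores`: data.frame with line_id, cdmean and
#'   rank (descending CDmean, ties broken by line ID), plus the lambda used.
#' @export
cdmean_per_individual <- function(G, lambda = 0.5,
                                  mode = c("calibrate", "validate"),
                                  fixed = c("none", "intercept")) {
  mode <- match.arg(mode); fixed <- match.arg(fixed)
  n <- nrow(G)
  if (n < 3) sgs_stop("CDmean scoring needs a family of at least 3", "sgs_input_error")
  ids <- rownames(G) %||% as.character(seq_len(n))
  # cd[h, j]: reliability of contrast j when h alone calibrates
  cd <- matrix(NA_real_, n, n)
  for (h in seq_len(n)) {
    others <- setdiff(seq_len(n), h)
    cd[h, others] <- tryCatch(
      cd_reliability(G, h, contrast_matrix(n, others), lambda, fixed),
      error = function(e) sgs_stop(sprintf(
        "CD computation failed for calibration individual '%s': %s",
        ids[h], conditionMessage(e)), "sgs_numeric_error"))
  }
  score <- if (mode == "calibrate") rowMeans(cd, na.rm = TRUE) else
    colMeans(cd, na.rm = TRUE)
  ord <- order(-score, ids)
  out <- data.frame(line_id = ids, cdmean = score, stringsAsFactors = FALSE)
  out$rank <- match(seq_len(n), ord)
  structure(out, lambda = lambda, mode = mode, class = c("cd_scores", "data.frame"))
}

#' Split a full-sib family across environments by CDmean (CV2 design)
#'
#' The half of the family with the highest CDmean is phenotyped in the first
#' well-watered environment (and masked in the second); the lower half is
#' phenotyped in the second. The water-stress calibration set takes the
#' higher-CDmean half of each WW-observed subset (ceiling from the first,
#' floor from the second), so WS contains lines originating from both WW
#' environments while half of the WW-phenotyped lines stay masked in WS. Odd
#' family sizes put the extra line in the first WW environment. Ties are
#' broken by line ID, so the split is deterministic given the scores.
#'
#' @param scores a [cdmean_per_individual()] result.
#' @param ww_envs character vector of the two WW environment labels.
#' @return data.frame of class `calibration_split` with columns line_id,
#'   ww_observed (which WW environment the line is phenotyped in) and
#'   ws_observed (logical).
#' @export
split_family_cv2 <- function(scores, ww_envs) {
  if (length(ww_envs) != 2) sgs_stop("exactly two WW environments required", "sgs_input_error")
  ord <- order(-scores$cdmean, scores$line_id)
  n <- nrow(scores)
  n_top <- ceiling(n / 2)
  top <- scores$line_id[ord[seq_len(n_top)]]
  bottom <- scores$line_id[ord[-seq_len(n_top)]]
  ws_top <- top[seq_len(ceiling(length(top) / 2))]
  ws_bottom <- if (length(bottom)) bottom[seq_len(floor(length(bottom) / 2))] else character(0)
  out <- data.frame(line_id = scores$line_id, stringsAsFactors = FALSE)
  out$ww_observed <- ifelse(out$line_id %in% top, ww_envs[1], ww_envs[2])
  out$ws_observed <- out$line_id %in% c(ws_top, ws_bottom)
  structure(out, ww_envs = ww_envs, class = c("calibration_split", "data.frame"))
}

#' Select historical training individuals by average genomic relationship
#'
#' Scores each historical candidate j by its mean relationship to the target
#' family, `Avg_GRM_j = mean(G[members, j])`, and returns the `n_select`
#' highest-scoring candidates (descending score, ties broken by line ID).
#'
#' @param G_cross relationship block, historical candidates (rows) x target
#'   family members (columns), with candidate IDs as rownames.
#' @param n_select number of historical lines to select (default 300); the
#'   whole pool is returned with a warning when the pool is smaller.
#' @return data.frame with line_id and avg_grm for the selected candidates,
#'   ordered by descending score.
#' @export
avg_grm_select <- function(G_cross, n_select = 300) {
  if (is.null(dim(G_cross)) || nrow(G_cross) < 1L)
    sgs_stop("empty historical pool", "sgs_input_error")
  ids <- rownames(G_cross) %||% as.character(seq_len(nrow(G_cross)))
  score <- rowMeans(G_cross)
  if (n_select >= length(score)) {
    if (n_select > length(score))
      warning(sprintf("requested %d historical lines but pool has only %d; returning all",
                      n_select, length(score)))
    n_select <- length(score)
  }
  ord <- order(-score, ids)[seq_len(n_select)]
  data.frame(line_id = ids[ord], avg_grm = unname(score[ord]),
             stringsAsFactors = FALSE)
}
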