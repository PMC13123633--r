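# Reference-based leukocyte deconvolution: a deliberately simple pipeline of
# specificity-scored signature genes, per-gene max scaling, and non-negative
# least squares, with proportions renormalised to sum to one.

#' Select cell-type signature genes
#'
#' Scores each gene's specificity for a cell type as that type's share of
#' the gene's row sum, and takes the `n_per_type` most specific genes per
#' type (union over types). A gene expressed in exactly one type has
#' specificity 1; a uniformly expressed gene scores 1/K.
#'
#' @param ref genes x cell-types matrix of non-negative reference expression
#'   (CPM scale), with row and column names.
#' @param n_per_type signature genes per cell type (default 50).
#' @return character vector of signature gene names.
#' @export
select_signature_genes <- function(ref, n_per_type = 50) {
  ref <- as.matrix(ref)
  if (n_per_type < 1) stop("n_per_type must be >= 1")
  if (ncol(ref) < 2) stop("need at least 2 cell types")
  rs <- rowSums(ref)
  ref <- ref[rs > 0, , drop = FALSE]
  rs <- rs[rs > 0]
  spec <- ref / rs
  if (nrow(ref) <= n_per_type) {
    warning("fewer genes than requested per type; returning all genes")
    return(rownames(ref))
  }
  sel <- unlist(lapply(seq_len(ncol(ref)), function(k) {
    rownames(ref)[order(spec[, k], decreasing = TRUE)[seq_len(min(n_per_type, nrow(ref)))]]
  }))
  unique(sel)
}

#' Estimate cell-type proportions for one mixture
#'
#' Restricts mixture and reference to shared signature genes, scales each
#' gene row by its reference row maximum (applied to both sides, so
#' noiseless mixtures of reference columns are recovered exactly), solves
#' non-negative least squares, and renormalises the weights to fractions.
#' A rank-deficient reference triggers a warning and a pseudo-inverse
#' fallback with negative weights clipped at zero.
#'
#' @param mixture named numeric vector of CPM expression for one sample.
#' @param ref genes x cell-types reference matrix.
#' @param signature_genes genes to use (default: [select_signature_genes()]).
#' @return list: `proportions` (named, in `[0,1]`, summing to 1),
#'   `residual` (Euclidean norm of the scaled-space fit residual).
#' @export
estimate_proportions <- function(mixture, ref,
                                 signature_genes = select_signature_genes(ref)) {
  ref <- as.matrix(ref)
  genes <- intersect(signature_genes, intersect(names(mixture), rownames(ref)))
  if (length(genes) < ncol(ref)) {
    stop("fewer shared signature genes than cell types")
  }
  a <- ref[genes, , drop = FALSE]
  b <- mixture[genes]
  scale_f <- apply(a, 1, max)
  keep <- scale_f > 0
  a <- a[keep, , drop = FALSE] / scale_f[keep]
  b <- b[keep] / scale_f[keep]
  if (qr(a)$rank < ncol(a)) {
    warning("reference columns are collinear; using pseudo-inverse fallback")
    w <- pmax(as.vector(pracma::pinv(a) %*% b), 0)
  } else {
    w <- pracma::lsqnonneg(a, as.vector(b))$x
  }
  if (sum(w) == 0) stop("degenerate fit: all weights zero")
  prop <- w / sum(w)
  names(prop) <- colnames(ref)
  list(proportions = prop,
       residual = sqrt(sum((a %*% w - b)^2)))
}

#' Estimate proportions for every sample of a CPM matrix
#'
#' @param cpm genes x samples matrix on the CPM scale (pre-log).
#' @param ref genes x cell-types reference matrix.
#' @param n_per_type signature genes per type.
#' @return data.frame: one row per sample with per-type fractions and
#'   `residual`.
#' @export
deconvolve_samples <- function(cpm, ref, n_per_type = 50) {
  cpm <- as.matrix(cpm)
  sig <- select_signature_genes(ref, n_per_type)
  rows <- lapply(colnames(cpm) %||% seq_len(ncol(cpm)), function(s) {
    est <- estimate_proportions(cpm[, s], ref, sig)
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          as.data.frame(t(est$proportions)),
          data.frame(residual = est$residual))
  })
  do.call(rbind, rows)
}

#' Compare cell-type proportions between two groups
#'
#' Welch's t-test per cell type on the estimated fractions.
#'
#' @param group_a,group_b data.frames of per-sample fractions (as returned
#'   by [deconvolve_samples()], or plain fraction columns).
#' @param types cell-type columns to compare (default: shared numeric
#'   columns except `residual`).
#' @return data.frame: one row per type with `t`, `df`, `p`.
#' @export
compare_celltype_proportions <- function(group_a, group_b, types = NULL) {
  if (is.null(types)) {
    shared <- intersect(names(group_a), names(group_b))
    types <- shared[vapply(group_a[shared], is.numeric, logical(1)) &
                      !shared %in% c("residual")]
  }
  rows <- lapply(types, function(ty) {
    wt <- welch_t(group_a[[ty]], group_b[[ty]])
    data.frame(cell_type = ty, t = wt$t, df = wt$df, p = wt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
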