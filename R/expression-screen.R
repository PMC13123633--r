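# Dose-correlated expression screen: CPM normalisation, low-expression and
# outlier-sample filters, per-transcript gene significance against dose rate,
# module eigengenes with trait association (correlation and nested-model
# likelihood-ratio tests), and pathway-set PCA.

#' Log2 CPM normalisation
#'
#' `log2(count / library_size * 1e6 + 1)` with the library size taken as the
#' per-sample column sum of raw counts.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return matrix of the same shape on the log2(CPM + 1) scale.
#' @export
#' @examples
#' m <- matrix(c(500, 999500), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
#' cpm_normalize(m)["g1", ] # log2(501)
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  log2(sweep(counts, 2, lib, "/") * 1e6 + 1)
}

#' Drop weakly expressed genes
#'
#' Retains genes whose cross-sample mean raw count is strictly above
#' `mean_min` (default 10).
#'
#' @param counts genes x samples count matrix.
#' @param mean_min mean-count threshold (strict).
#' @return the retained submatrix.
#' @export
filter_low_expression <- function(counts, mean_min = 10) {
  counts <- as.matrix(counts)
  counts[rowMeans(counts) > mean_min, , drop = FALSE]
}

#' Flag outlier samples by mean inter-sample correlation
#'
#' Computes each sample's mean Pearson correlation with all other samples
#' and flags those falling below `mean - k_sd * sd` of these means.
#'
#' @param normalized genes x samples normalized expression.
#' @param k_sd number of SDs below the mean that triggers flagging.
#' @return character vector of flagged sample names (possibly empty).
#' @export
flag_outlier_samples <- function(normalized, k_sd = 2.5) {
  normalized <- as.matrix(normalized)
  ns <- ncol(normalized)
  if (ns < 3) stop("need at least 3 samples")
  cc <- stats::cor(normalized)
  mean_cor <- (rowSums(cc) - 1) / (ns - 1)
  thr <- mean(mean_cor) - k_sd * stats::sd(mean_cor)
  if (!is.finite(thr)) return(character(0))
  colnames(normalized)[mean_cor < thr]
}

#' Per-gene correlation with a trait (gene significance)
#'
#' Correlates every gene's expression with a sample trait (total dose rate
#' in the screen) and attaches the student asymptotic p-value
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df, two-sided. For
#' Spearman the t approximation is applied to rho. Constant genes get NA and
#' are excluded from selection.
#'
#' @param normalized genes x samples normalized expression.
#' @param trait numeric per-sample trait (length = n samples, with variance).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame: `gene`, `r`, `p` (NA rows for constant genes).
#' @export
#' @examples
#' # r = 0.6325 at n = 10 gives t ~ 2.31, p ~ 0.0498
gene_significance <- function(normalized, trait,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  normalized <- as.matrix(normalized)
  n <- ncol(normalized)
  if (n < 4) stop("need at least 4 samples")
  if (length(trait) != n) stop("trait length must equal the sample count")
  if (stats::sd(trait) == 0) stop("trait has no variance")
  r <- suppressWarnings(apply(normalized, 1, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, trait, method = method)
  }))
  p <- cor_pvalue_student(r, n)
  data.frame(gene = rownames(normalized) %||% seq_along(r), r = r, p = p,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Student asymptotic p-value for a correlation
#'
#' @param r correlation coefficient(s) in `[-1, 1]`.
#' @param n sample size used to compute `r`.
#' @return two-sided p-value(s); `|r| = 1` returns the smallest
#'   representable double rather than 0.
#' @export
cor_pvalue_student <- function(r, n) {
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[abs(r) == 1] <- .Machine$double.xmin
  p
}

#' Select dose-correlated transcripts
#'
#' Genes in the top tail of the |r| distribution (at or above its empirical
#' `quantile`, ties included) that also pass the per-gene p-value cut.
#'
#' @param gs_rows output of [gene_significance()].
#' @param quantile |r| quantile defining the tail (default 0.95).
#' @param alpha p-value cut (strict; default 0.05).
#' @param use_abs rank by |r| (default) rather than signed r.
#' @return character vector of selected gene names.
#' @export
dose_correlated_set <- function(gs_rows, quantile = 0.95, alpha = 0.05,
                                use_abs = TRUE) {
  if (nrow(gs_rows) == 0) stop("empty gene-significance table")
  ok <- !is.na(gs_rows$r)
  score <- if (use_abs) abs(gs_rows$r) else gs_rows$r
  thr <- stats::quantile(score[ok], probs = quantile, names = FALSE)
  sel <- ok & score >= thr & gs_rows$p < alpha
  gs_rows$gene[sel]
}

#' Module eigengenes
#'
#' The first principal component of each module's per-gene standardized
#' expression, as a unit-norm samples-length vector, sign-oriented so that
#' its mean correlation with the member genes is positive. Modules with
#' fewer than 2 genes present are skipped with a warning.
#'
#' @param normalized genes x samples normalized expression.
#' @param modules data.frame (`gene`, `module`) or named vector
#'   (names = genes, values = module labels).
#' @return samples x modules matrix of eigengene values.
#' @export
module_eigengene <- function(normalized, modules) {
  normalized <- as.matrix(normalized)
  if (is.data.frame(modules)) {
    mod <- stats::setNames(as.character(modules$module), modules$gene)
  } else {
    mod <- modules
  }
  labels <- unique(mod)
  cols <- list()
  for (ml in labels) {
    genes <- intersect(names(mod)[mod == ml], rownames(normalized))
    x <- normalized[genes, , drop = FALSE]
    x <- x[apply(x, 1, stats::sd) > 0, , drop = FALSE]
    if (nrow(x) < 2) {
      warning("module '", ml, "' has fewer than 2 usable genes; skipped")
      next
    }
    xs <- t(scale(t(x))) # per-gene z-score
    sv <- svd(xs)
    eig <- sv$v[, 1]
    eig <- eig / sqrt(sum(eig^2))
    if (mean(apply(x, 1, function(g) stats::cor(g, eig))) < 0) eig <- -eig
    cols[[ml]] <- eig
  }
  if (length(cols) == 0) stop("no module had >= 2 usable genes")
  out <- do.call(cbind, cols)
  rownames(out) <- colnames(normalized)
  out
}

#' Module eigengene vs. trait: correlation and nested-model LRT
#'
#' Two complementary tests of a module's association with dose: (a) the
#' eigengene-dose correlation with its student asymptotic p-value; (b)
#' likelihood-ratio tests between nested Gaussian linear models fit by
#' maximum likelihood. The full model is
#' `eigengene ~ dose_rate * age + monocyte + granulocyte + sex`; the two
#' reduced models drop `{dose_rate, dose_rate:age}` ("dose" contrast) or
#' `{dose_rate, age, dose_rate:age}` ("dose_age" contrast). Sex enters as a
#' fixed covariate.
#'
#' @param eigengene numeric per-sample eigengene values.
#' @param traits data.frame with per-sample columns `dose_rate`, `age`,
#'   `monocyte`, `granulocyte`, `sex` (rows aligned with `eigengene`).
#' @return list: `cor`, `cor_p`, and a data.frame `lrt` with one row per
#'   contrast (`chi2`, `df`, `p`).
#' @export
module_trait_tests <- function(eigengene, traits) {
  need <- c("dose_rate", "age", "monocyte", "granulocyte", "sex")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("traits missing columns: ", paste(miss, collapse = ", "))
  if (length(eigengene) != nrow(traits)) stop("eigengene/traits length mismatch")
  if (anyNA(traits[need]) || anyNA(eigengene)) stop("complete trait rows required")
  d <- data.frame(eig = eigengene, traits[need])
  d$sex <- factor(d$sex)

  full_form <- eig ~ dose_rate * age + monocyte + granulocyte + sex
  mm <- stats::model.matrix(full_form, data = d)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[setdiff(seq_len(ncol(mm)), qr_mm$pivot[seq_len(qr_mm$rank)])]
    stop("collinear design; rank-deficient columns: ",
         paste(dropped, collapse = ", "))
  }
  full <- stats::lm(full_form, data = d)
  red_dose <- stats::lm(eig ~ age + monocyte + granulocyte + sex, data = d)
  red_dose_age <- stats::lm(eig ~ monocyte + granulocyte + sex, data = d)
  lrt_one <- function(reduced, label) {
    chi2 <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                          as.numeric(stats::logLik(reduced))))
    df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
    data.frame(contrast = label, chi2 = chi2, df = df,
               p = if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  r <- stats::cor(eigengene, d$dose_rate)
  list(cor = r, cor_p = cor_pvalue_student(r, length(eigengene)),
       lrt = rbind(lrt_one(red_dose, "dose"),
                   lrt_one(red_dose_age, "dose_age")))
}

#' PCA of a pathway gene set
#'
#' Principal components of the samples x set-genes submatrix with genes
#' centered (no scaling): sample scores on PC1/PC2 plus the variance
#' fractions of all components.
#'
#' @param normalized genes x samples normalized expression.
#' @param gene_set character vector of gene names.
#' @return list: `scores` (samples x 2 matrix, PC1/PC2), `var_explained`
#'   (fractions summing to 1).
#' @export
pathway_pca <- function(normalized, gene_set) {
  normalized <- as.matrix(normalized)
  genes <- intersect(gene_set, rownames(normalized))
  if (length(genes) < 2) stop("fewer than 2 set genes present in the matrix")
  pr <- stats::prcomp(t(normalized[genes, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  k <- min(2, ncol(pr$x))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  list(scores = scores, var_explained = ve)
}
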