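# Genotype and site quality control: per-call DP/GQ masking, site-level
# filters (biallelic autosomal SNPs, missingness, polymorphism) and greedy
# windowed LD pruning. The stages must run in order (mask -> site filters ->
# optional annotation subset -> pruning); state flags on the matrix enforce
# this.

#' Mask low-quality genotype calls
#'
#' Sets calls to missing unless depth and genotype quality are strictly above
#' the thresholds (DP > 8, GQ > 20 by default). Masked calls keep their
#' depth/quality values; only the dosage becomes NA.
#'
#' @param gm a `genotype_matrix`.
#' @param dp_min depth threshold; calls with DP <= `dp_min` are masked.
#' @param gq_min quality threshold; calls with GQ <= `gq_min` are masked.
#' @return the masked `genotype_matrix` (flagged so [site_filters()] accepts it).
#' @export
mask_low_quality <- function(gm, dp_min = 8, gq_min = 20) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (dp_min < 0 || gq_min < 0) stop("thresholds must be >= 0")
  bad <- is.na(gm$depth) | is.na(gm$quality) |
    gm$depth <= dp_min | gm$quality <= gq_min
  gm$dosage[bad] <- NA_integer_
  attr(gm, "masked") <- TRUE
  gm
}

#' Site-level filters
#'
#' Retains sites that are biallelic SNPs (single one-base ALT allele and
#' one-base REF), lie on a listed autosome, have a missing-call fraction
#' strictly below `max_missing`, and remain polymorphic after masking.
#' Requires [mask_low_quality()] to have been applied first.
#'
#' @param gm a masked `genotype_matrix`.
#' @param max_missing maximum missing fraction (strict; default 0.20).
#' @param autosomes character vector of autosomal chromosome names.
#' @return the filtered `genotype_matrix`.
#' @export
site_filters <- function(gm, max_missing = 0.20, autosomes) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!isTRUE(attr(gm, "masked"))) {
    stop("site_filters requires mask_low_quality to be applied first")
  }
  if (missing(autosomes) || length(autosomes) == 0) {
    stop("autosomes must be a non-empty chromosome list")
  }
  snp <- !gm$sites$multiallelic &
    nchar(gm$sites$ref) == 1L & nchar(gm$sites$alt) == 1L &
    gm$sites$ref %in% c("A", "C", "G", "T") & gm$sites$alt %in% c("A", "C", "G", "T")
  autosomal <- gm$sites$chrom %in% autosomes
  missing_frac <- rowMeans(is.na(gm$dosage))
  poly <- apply(gm$dosage, 1, function(d) {
    d <- d[!is.na(d)]
    length(d) > 0 && length(unique(d)) > 1
  })
  keep <- snp & autosomal & (missing_frac < max_missing) & poly
  out <- subset_sites(gm, keep)
  attr(out, "site_filtered") <- TRUE
  out
}

#' Subset sites by annotation tag
#'
#' Keeps sites whose annotation equals the requested label (e.g.
#' `"synonymous"` to restrict to putatively neutral variants).
#'
#' @param gm a site-filtered `genotype_matrix`.
#' @param tag annotation label.
#' @return the restricted `genotype_matrix` (empty, with a warning, if no
#'   site carries the tag).
#' @export
annotation_subset <- function(gm, tag) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!isTRUE(attr(gm, "site_filtered"))) {
    stop("annotation_subset requires site_filters to be applied first")
  }
  if (is.null(gm$sites$annotation)) stop("sites carry no annotation column")
  keep <- !is.na(gm$sites$annotation) & gm$sites$annotation == tag
  if (!any(keep)) warning("no sites tagged '", tag, "'; returning empty matrix")
  subset_sites(gm, keep)
}

# squared Pearson correlation of two dosage vectors over pairwise-complete
# samples; fewer than 2 complete pairs, or a constant vector, counts as
# uncorrelated.
.pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Windowed LD pruning
#'
#' Greedy pruning in sliding windows of `window` consecutive sites advancing
#' by `step` sites (the indep-pairwise scheme). Within each window, while any
#' retained pair of sites has squared dosage correlation above `r2_max`, the
#' later-positioned site of the offending pair is dropped. After the pass, no
#' retained pair within any window placement exceeds `r2_max`.
#'
#' @param gm a site-filtered `genotype_matrix`.
#' @param window window size in sites (default 50).
#' @param step window advance in sites (default 10).
#' @param r2_max maximum tolerated pairwise r-squared (default 0.1).
#' @return sorted integer vector of retained site indices (into `gm$sites`).
#' @export
ld_prune <- function(gm, window = 50, step = 10, r2_max = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!isTRUE(attr(gm, "site_filtered"))) {
    stop("ld_prune requires site_filters to be applied first")
  }
  if (window < 2) stop("window must cover at least 2 sites")
  if (!(window > step && step > 0)) stop("need window > step > 0")
  if (!(r2_max > 0 && r2_max < 1)) stop("r2_max must be in (0, 1)")
  n <- n_sites(gm)
  keep <- rep(TRUE, n)
  if (n < 2) return(which(keep))
  starts <- seq(1L, n, by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1L, n)
    repeat {
      live <- idx[keep[idx]]
      if (length(live) < 2) break
      dropped <- FALSE
      for (a in seq_len(length(live) - 1L)) {
        i <- live[a]
        if (!keep[i]) next
        for (b in (a + 1L):length(live)) {
          j <- live[b]
          if (!keep[j]) next
          if (.pair_r2(gm$dosage[i, ], gm$dosage[j, ]) > r2_max) {
            keep[j] <- FALSE # drop the later-positioned site
            dropped <- TRUE
          }
        }
      }
      if (!dropped) break
    }
  }
  which(keep)
}
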