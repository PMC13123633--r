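# Lineage-specific selection scan: per-site Weir-Cockerham (1984) FST for
# the three population pairs, Cavalli-Sforza branch lengths, the population
# branch statistic (PBS) for the focal lineage, and population branch excess
# (PBE) -- PBS minus a locus-specific expectation built from the
# sister-outgroup branch scaled by genome-wide medians. Outliers are called
# from z-scores of the zero-truncated PBE with BH-adjusted normal tail
# p-values.

#' Per-population allele summaries at each site
#'
#' For every site and population: the number of genotyped diploids `n`, the
#' alt-allele frequency `p`, and the observed heterozygote fraction `h`.
#'
#' @param gm a `genotype_matrix`.
#' @return named list (one element per population) of data.frames with
#'   columns `n`, `p`, `h` (rows = sites).
#' @export
allele_summaries <- function(gm) {
  pops <- unique(gm$samples$population)
  out <- lapply(pops, function(pp) {
    d <- gm$dosage[, gm$samples$population == pp, drop = FALSE]
    n <- rowSums(!is.na(d))
    p <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums(d == 1L, na.rm = TRUE) / n, NA_real_)
    data.frame(n = n, p = p, h = h)
  })
  names(out) <- pops
  out
}

#' Per-site Weir-Cockerham FST (two populations)
#'
#' The 1984 variance-components estimator theta-hat = a / (a + b + c) for two
#' populations of diploids, computed from sample sizes, alt-allele
#' frequencies and observed heterozygote fractions. Vectorised over sites.
#' Slightly negative estimates are legitimate; sites monomorphic in the
#' pooled sample (or with a zero total variance component) return NA and are
#' excluded downstream.
#'
#' @param n1,p1,h1 population 1 sample sizes (diploids), alt-allele
#'   frequencies and heterozygote fractions.
#' @param n2,p2,h2 the same for population 2.
#' @return numeric vector of theta-hat per site (NA where undefined).
#' @export
wc_fst <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  bad <- !is.finite(denom) | denom == 0 |
    (pbar %in% c(0, 1) & hbar == 0) | # pooled monomorphic
    n1 < 1 | n2 < 1 | nbar <= 1 | nc <= 0
  theta <- a / denom
  theta[bad] <- NA_real_
  theta
}

#' Cavalli-Sforza branch-length transform
#'
#' `T = -log(1 - FST)`, the additive divergence approximation. FST is
#' clamped to `[0, cap]` first, so negative estimates map to 0 and fixed
#' differences stay finite.
#'
#' @param fst numeric vector of FST estimates.
#' @param cap upper clamp (default `1 - 1e-9`).
#' @return branch lengths T >= 0 (NA preserved).
#' @export
#' @examples
#' cs_transform(0.5) # log(2)
cs_transform <- function(fst, cap = 1 - 1e-9) {
  -log(1 - pmin(pmax(fst, 0), cap))
}

#' Population branch statistic
#'
#' Length of the focal branch at a locus:
#' `(T_focal,sister + T_focal,outgroup - T_sister,outgroup) / 2`.
#'
#' @param t_fs,t_fo,t_so Cavalli-Sforza branch lengths for the
#'   focal-sister, focal-outgroup and sister-outgroup pairs.
#' @return PBS per site (may be negative).
#' @export
pbs <- function(t_fs, t_fo, t_so) {
  (t_fs + t_fo - t_so) / 2
}

#' Population branch excess (raw)
#'
#' PBS minus its locus-specific expectation: the sister-outgroup branch
#' scaled by the genome-wide ratio `median(PBS) / median(T_so)`. Positive
#' values mark loci where focal-lineage divergence exceeds what the shared
#' sister-outgroup divergence predicts.
#'
#' @param pbs_vec PBS values over the analyzed sites.
#' @param t_so_vec sister-outgroup branch lengths over the same sites.
#' @return raw PBE per site.
#' @export
pbe <- function(pbs_vec, t_so_vec) {
  if (length(pbs_vec) != length(t_so_vec) || length(pbs_vec) < 1) {
    stop("pbs_vec and t_so_vec must have equal length >= 1")
  }
  med_so <- stats::median(t_so_vec)
  if (med_so <= 0) {
    stop("median sister-outgroup branch length is 0; ",
         "drop invariant sites before computing PBE")
  }
  pbs_vec - t_so_vec * stats::median(pbs_vec) / med_so
}

#' Zero-truncate, z-score and attach p-values to PBE
#'
#' Negative raw PBE values are set to 0; the zeroed vector is z-scored
#' (mean/sd over all analyzed sites), upper-tail standard-normal p-values
#' are attached, and Benjamini-Hochberg adjustment is applied across sites.
#' The normal tail on the zero-inflated z distribution is the procedure as
#' practised in PBE scans; [empirical_pbe_pvalues()] offers a rank-based
#' alternative.
#'
#' @param pbe_raw_vec raw PBE values (length >= 2).
#' @return data.frame with columns `pbe`, `z`, `p`, `p_adj`.
#' @export
pbe_pvalues <- function(pbe_raw_vec) {
  if (length(pbe_raw_vec) < 2) stop("need at least 2 sites")
  pz <- pmax(pbe_raw_vec, 0)
  s <- stats::sd(pz)
  if (s == 0) stop("zero variance after zero-truncation: z-scores undefined")
  z <- (pz - mean(pz)) / s
  p <- stats::pnorm(z, lower.tail = FALSE)
  data.frame(pbe = pz, z = z, p = p, p_adj = stats::p.adjust(p, method = "BH"))
}

#' Rank-based empirical PBE p-values
#'
#' Non-default alternative to the normal-tail device: the empirical upper
#' rank `p_i = rank of site i from the top / m`.
#'
#' @param pbe_raw_vec raw PBE values.
#' @return upper-tail empirical p per site, in (0, 1].
#' @export
empirical_pbe_pvalues <- function(pbe_raw_vec) {
  pz <- pmax(pbe_raw_vec, 0)
  (length(pz) + 1 - rank(pz, ties.method = "min")) / length(pz)
}

#' Call outlier tiers from adjusted p-values
#'
#' Tiers sites by `-log10(p_adj)` against two strict thresholds: `outlier`
#' above `thr_outlier`, `extreme` above `thr_extreme` (defaults 8 and 15).
#'
#' @param p_adj_vec BH-adjusted p-values.
#' @param thr_outlier,thr_extreme thresholds on `-log10(p_adj)`.
#' @return character vector of tiers in `none`, `outlier`, `extreme`.
#' @export
call_outliers <- function(p_adj_vec, thr_outlier = 8, thr_extreme = 15) {
  if (thr_outlier <= 0 || thr_extreme < thr_outlier) {
    stop("need thr_extreme >= thr_outlier > 0")
  }
  nlp <- -log10(p_adj_vec)
  ifelse(nlp > thr_extreme, "extreme", ifelse(nlp > thr_outlier, "outlier", "none"))
}

#' Full PBE scan over a genotype matrix
#'
#' Computes the three pairwise per-site FSTs, branch lengths, PBS, PBE,
#' z-scores, normal-tail p, BH-adjusted p and outlier tiers for the focal
#' lineage. Sites with an undefined FST in any pair are excluded from the
#' scan (they contribute neither to the medians nor to the multiple-testing
#' family); the number excluded is recorded as an attribute.
#'
#' @param gm a `genotype_matrix` whose samples span the three populations.
#' @param focal,sister,outgroup population labels in `gm$samples$population`.
#' @param thr_outlier,thr_extreme outlier thresholds (see [call_outliers()]).
#' @param cap FST clamp for the branch-length transform.
#' @return data.frame (one row per analyzed site): `chrom`, `pos`, `fst_fs`,
#'   `fst_fo`, `fst_so`, `t_fs`, `t_fo`, `t_so`, `pbs`, `pbe_raw`, `pbe`,
#'   `z`, `p`, `p_adj`, `tier`; attribute `n_excluded` counts dropped sites.
#' @export
pbe_scan <- function(gm, focal = "focal", sister = "sister",
                     outgroup = "outgroup", thr_outlier = 8,
                     thr_extreme = 15, cap = 1 - 1e-9) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$samples$population)
  for (pp in c(focal, sister, outgroup)) {
    if (!pp %in% pops) stop("population '", pp, "' absent from the matrix")
  }
  s <- allele_summaries(gm)
  f <- s[[focal]]; si <- s[[sister]]; o <- s[[outgroup]]
  fst_fs <- wc_fst(f$n, f$p, f$h, si$n, si$p, si$h)
  fst_fo <- wc_fst(f$n, f$p, f$h, o$n, o$p, o$h)
  fst_so <- wc_fst(si$n, si$p, si$h, o$n, o$p, o$h)
  ok <- !is.na(fst_fs) & !is.na(fst_fo) & !is.na(fst_so)
  t_fs <- cs_transform(fst_fs[ok], cap)
  t_fo <- cs_transform(fst_fo[ok], cap)
  t_so <- cs_transform(fst_so[ok], cap)
  pbs_v <- pbs(t_fs, t_fo, t_so)
  raw <- pbe(pbs_v, t_so)
  pv <- pbe_pvalues(raw)
  out <- data.frame(chrom = gm$sites$chrom[ok], pos = gm$sites$pos[ok],
                    site_index = which(ok),
                    fst_fs = fst_fs[ok], fst_fo = fst_fo[ok], fst_so = fst_so[ok],
                    t_fs = t_fs, t_fo = t_fo, t_so = t_so,
                    pbs = pbs_v, pbe_raw = raw,
                    pbe = pv$pbe, z = pv$z, p = pv$p, p_adj = pv$p_adj,
                    tier = call_outliers(pv$p_adj, thr_outlier, thr_extreme),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Nearest-gene annotation of sites
#'
#' Annotates each site with its most proximate gene. A site inside a gene
#' interval gets distance 0 and relation `exonic` (if it falls inside an
#' exon sub-interval of that gene, when exon rows are provided) or
#' `intronic`; otherwise the nearest gene is reported with the bp gap and a
#' strand-aware `upstream`/`downstream` relation. Equidistant genes resolve
#' to the lower-coordinate gene. Sites on chromosomes without annotation get
#' relation `none` and NA distance.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based).
#' @param annotations data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `gene`, `feature`
#'   (`gene` rows required; `exon` rows optional).
#' @return data.frame: `chrom`, `pos`, `gene`, `relation`, `distance`.
#' @export
nearest_gene <- function(sites, annotations) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)),
            all(c("chrom", "start", "end", "strand", "gene", "feature") %in%
                  names(annotations)))
  genes <- annotations[annotations$feature == "gene", , drop = FALSE]
  exons <- annotations[annotations$feature == "exon", , drop = FALSE]
  res <- lapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]; pos <- sites$pos[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) {
      return(data.frame(chrom = ch, pos = pos, gene = NA_character_,
                        relation = "none", distance = NA_real_,
                        stringsAsFactors = FALSE))
    }
    # 1-based gene span is [start + 1, end]
    inside <- pos > g$start & pos <= g$end
    if (any(inside)) {
      hit <- g[inside, , drop = FALSE]
      hit <- hit[which.min(hit$start), , drop = FALSE] # lower-coordinate tie rule
      ex <- exons[exons$chrom == ch & exons$gene == hit$gene, , drop = FALSE]
      rel <- if (nrow(ex) > 0 && any(pos > ex$start & pos <= ex$end)) "exonic"
             else if (nrow(ex) > 0) "intronic"
             else "exonic" # no exon structure given: whole gene counts as exonic
      return(data.frame(chrom = ch, pos = pos, gene = hit$gene, relation = rel,
                        distance = 0, stringsAsFactors = FALSE))
    }
    d <- ifelse(pos <= g$start, g$start + 1L - pos, pos - g$end)
    j <- which(d == min(d))
    if (length(j) > 1) j <- j[which.min(g$start[j])]
    before <- pos <= g$start[j] # site precedes the gene in coordinates
    rel <- if (g$strand[j] == "+") {
      if (before) "upstream" else "downstream"
    } else {
      if (before) "downstream" else "upstream"
    }
    data.frame(chrom = ch, pos = pos, gene = g$gene[j], relation = rel,
               distance = d[j], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read a gene/exon annotation table
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `strand`, `gene`,
#'   `feature`; coordinates 0-based half-open.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
}
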