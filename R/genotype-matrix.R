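# Sites x samples genotype container used by the QC filters and the
# selection scan. Dosages are alt-allele counts (0/1/2) with NA for missing
# calls; per-call depth and genotype quality matrices travel alongside so the
# quality mask can be applied after load.

#' Construct a genotype matrix
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based, strictly
#'   increasing within chromosome), `ref`, `alt` (comma-separated when
#'   multi-allelic) and optionally `annotation` (e.g. "synonymous").
#' @param dosage integer matrix sites x samples, values 0/1/2 or NA.
#' @param depth,quality integer matrices of the same shape (per-call DP, GQ).
#' @param samples data.frame with columns `id`, `population` (levels among
#'   focal / sister / outgroup for the three-population scan).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, dosage, depth, quality, samples) {
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  stopifnot(all(c("id", "population") %in% names(samples)))
  dosage <- as.matrix(dosage); depth <- as.matrix(depth); quality <- as.matrix(quality)
  if (!all(dim(dosage) == c(nrow(sites), nrow(samples)))) {
    stop("dosage must be n_sites x n_samples")
  }
  if (!all(dim(depth) == dim(dosage)) || !all(dim(quality) == dim(dosage))) {
    stop("depth and quality must match the dosage dimensions")
  }
  if (any(!(dosage %in% c(0L, 1L, 2L, NA)))) stop("dosages must be 0, 1, 2 or NA")
  # calls require supporting depth/quality
  called <- !is.na(dosage)
  if (any(is.na(depth[called])) || any(is.na(quality[called]))) {
    stop("every called genotype must have depth and quality")
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) stop("pos must be strictly increasing within chrom ", ch)
  }
  if (is.null(sites$multiallelic)) sites$multiallelic <- grepl(",", sites$alt)
  rownames(dosage) <- rownames(depth) <- rownames(quality) <- NULL
  colnames(dosage) <- colnames(depth) <- colnames(quality) <- samples$id
  structure(list(sites = sites, dosage = dosage, depth = depth,
                 quality = quality, samples = samples),
            class = "genotype_matrix",
            masked = FALSE, site_filtered = FALSE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", nrow(x$samples), "samples\n")
  cat("  populations:", paste(sprintf("%s=%d", names(table(x$samples$population)),
                                      table(x$samples$population)), collapse = ", "), "\n")
  cat("  masked:", attr(x, "masked"), " site_filtered:", attr(x, "site_filtered"), "\n")
  invisible(x)
}

#' Number of sites / samples
#' @param gm a `genotype_matrix`.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) nrow(gm$samples)

#' Subset a genotype matrix by site index
#'
#' Keeps processing-state flags, so filters can be chained.
#'
#' @param gm a `genotype_matrix`.
#' @param idx integer or logical index over sites.
#' @return a `genotype_matrix` restricted to the chosen sites.
#' @export
subset_sites <- function(gm, idx) {
  out <- gm
  out$sites <- gm$sites[idx, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$dosage <- gm$dosage[idx, , drop = FALSE]
  out$depth <- gm$depth[idx, , drop = FALSE]
  out$quality <- gm$quality[idx, , drop = FALSE]
  attr(out, "masked") <- attr(gm, "masked")
  attr(out, "site_filtered") <- attr(gm, "site_filtered")
  class(out) <- "genotype_matrix"
  out
}

#' Read a VCF into a genotype matrix
#'
#' Parses CHROM/POS/REF/ALT and the GT:DP:GQ FORMAT fields of a VCF v4.2
#' file (via vcfR). Multi-allelic records are retained and flagged, to be
#' removed by [site_filters()]. Missing or half-called genotypes become NA
#' dosages.
#'
#' @param path VCF file.
#' @param populations optional data.frame (`sample_id`, `population`)
#'   assigning samples to populations; defaults to "unknown".
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path, populations = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  # dosage = number of non-reference alleles; half calls / missing -> NA
  alleles <- function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (length(a) != 2 || any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }
  dosage <- matrix(vapply(gt, alleles, integer(1)), nrow = nrow(gt))
  ann <- rep(NA_character_, nrow(fix))
  if (!is.null(fix$INFO)) {
    m <- regmatches(fix$INFO, regexpr("ANN=[^;]+", fix$INFO))
    ann[grepl("ANN=", fix$INFO)] <- sub("ANN=", "", m)
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, annotation = ann,
                      stringsAsFactors = FALSE)
  ids <- colnames(gt)
  if (is.null(populations)) {
    samples <- data.frame(id = ids, population = "unknown", stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("sample_id", "population") %in% names(populations)))
    pop <- populations$population[match(ids, populations$sample_id)]
    if (any(is.na(pop))) stop("samples missing from population map: ",
                              paste(ids[is.na(pop)], collapse = ", "))
    samples <- data.frame(id = ids, population = pop, stringsAsFactors = FALSE)
  }
  ord <- order(sites$chrom, sites$pos)
  genotype_matrix(sites[ord, , drop = FALSE], dosage[ord, , drop = FALSE],
                  dp[ord, , drop = FALSE], gq[ord, , drop = FALSE], samples)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal VCF with GT:DP:GQ per call; NA dosages become `./.`.
#' Round-trips losslessly through [read_vcf()].
#'
#' @param gm a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gtcode <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples$id), collapse = "\t")), con)
  info <- ifelse(is.na(gm$sites$annotation), ".",
                 paste0("ANN=", gm$sites$annotation))
  for (i in seq_len(n_sites(gm))) {
    d <- gm$dosage[i, ]
    gt <- ifelse(is.na(d), "./.", gtcode[d + 1L])
    dp <- ifelse(is.na(gm$depth[i, ]), ".", gm$depth[i, ])
    gq <- ifelse(is.na(gm$quality[i, ]), ".", gm$quality[i, ])
    writeLines(paste(c(gm$sites$chrom[i], gm$sites$pos[i], ".",
                       gm$sites$ref[i], gm$sites$alt[i], ".", "PASS", info[i],
                       "GT:DP:GQ", paste(gt, dp, gq, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample-to-population map
#' @param path TSV with columns `sample_id`, `population`.
#' @return data.frame.
#' @export
read_population_map <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
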