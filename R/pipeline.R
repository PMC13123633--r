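# End-to-end orchestration: a validated configuration object and a driver
# that runs the genomic branch (mask -> site filters -> optional annotation
# subset / LD pruning -> PBE scan -> nearest-gene annotation) and the
# expression branch (low-expression filter -> CPM -> outlier samples ->
# gene-significance screen -> deconvolution), writing stage TSVs, a resolved
# configuration copy and a JSON summary.

#' Write a TSV with the package conventions
#'
#' Tab separators, `.` for missing values, a mandatory header row.
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Pipeline configuration
#'
#' Builds the stage-parameter list with the package defaults; unknown keys
#' are rejected. Every [run_pipeline()] call writes the resolved
#' configuration next to its outputs.
#'
#' @param ... overrides for any of: `dp_min`, `gq_min`, `max_missing`,
#'   `autosomes`, `annotation_tag`, `ld_prune`, `ld_window`, `ld_step`,
#'   `ld_r2_max`, `focal`, `sister`, `outgroup`, `thr_outlier`,
#'   `thr_extreme`, `mean_min`, `outlier_k_sd`, `gs_method`, `gs_quantile`,
#'   `gs_alpha`, `deconv_n_per_type`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    dp_min = 8, gq_min = 20, max_missing = 0.20,
    autosomes = paste0("chr", 1:38),
    annotation_tag = NULL,
    ld_prune = FALSE, ld_window = 50, ld_step = 10, ld_r2_max = 0.1,
    focal = "focal", sister = "sister", outgroup = "outgroup",
    thr_outlier = 8, thr_extreme = 15,
    mean_min = 10, outlier_k_sd = 2.5,
    gs_method = "spearman", gs_quantile = 0.95, gs_alpha = 0.05,
    deconv_n_per_type = 50)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  defaults[names(override)] <- override
  structure(defaults, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the genomic branch on a genotype matrix and, when expression
#' inputs are supplied, the expression/deconvolution branch. All stage
#' outputs are written as TSVs under `out_dir`, together with
#' `config.json` (the resolved configuration) and `summary.json` (per-stage
#' row counts and tallies). Inputs are never modified.
#'
#' @param gm a `genotype_matrix` (raw; masking is applied here).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param counts optional genes x samples raw count matrix.
#' @param traits optional per-sample trait data.frame (needs `sample_id`,
#'   `dose_rate`; module tests additionally need `age`, `sex`, `monocyte`,
#'   `granulocyte`).
#' @param annotations optional gene/exon annotation data.frame (see
#'   [nearest_gene()]).
#' @param ref optional reference profile matrix for deconvolution.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(gm, config = pipeline_config(), out_dir,
                         counts = NULL, traits = NULL, annotations = NULL,
                         ref = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(n_sites_input = n_sites(gm))

  masked <- .stage("mask_low_quality",
                   mask_low_quality(gm, config$dp_min, config$gq_min))
  filtered <- .stage("site_filters",
                     site_filters(masked, config$max_missing, config$autosomes))
  if (n_sites(filtered) == 0) {
    stop("pipeline stage 'site_filters' left no sites; nothing to scan",
         call. = FALSE)
  }
  summary$n_sites_after_filters <- n_sites(filtered)
  if (!is.null(config$annotation_tag)) {
    filtered <- .stage("annotation_subset",
                       annotation_subset(filtered, config$annotation_tag))
    summary$n_sites_after_annotation <- n_sites(filtered)
  }
  if (isTRUE(config$ld_prune)) {
    kept <- .stage("ld_prune",
                   ld_prune(filtered, config$ld_window, config$ld_step,
                            config$ld_r2_max))
    filtered <- subset_sites(filtered, kept)
    summary$n_sites_after_pruning <- n_sites(filtered)
    write_tsv(filtered$sites[, c("chrom", "pos")],
              file.path(out_dir, "kept_sites.tsv"))
  }

  scan <- .stage("pbe_scan",
                 pbe_scan(filtered, config$focal, config$sister,
                          config$outgroup, config$thr_outlier,
                          config$thr_extreme))
  summary$n_sites_analyzed <- nrow(scan)
  summary$n_sites_fst_undefined <- attr(scan, "n_excluded")
  summary$n_outliers <- sum(scan$tier != "none")
  summary$n_extreme <- sum(scan$tier == "extreme")
  write_tsv(scan, file.path(out_dir, "pbe.tsv"))

  if (!is.null(annotations)) {
    hits <- .stage("nearest_gene", {
      outl <- scan[scan$tier != "none", c("chrom", "pos")]
      if (nrow(outl) > 0) nearest_gene(outl, annotations) else NULL
    })
    if (!is.null(hits)) write_tsv(hits, file.path(out_dir, "outlier_genes.tsv"))
  }

  if (!is.null(counts)) {
    if (is.null(traits)) stop("expression branch needs traits", call. = FALSE)
    kept_counts <- .stage("filter_low_expression",
                          filter_low_expression(counts, config$mean_min))
    summary$n_genes_input <- nrow(counts)
    summary$n_genes_expressed <- nrow(kept_counts)
    norm <- .stage("cpm_normalize", cpm_normalize(kept_counts))
    flagged <- .stage("flag_outlier_samples",
                      flag_outlier_samples(norm, config$outlier_k_sd))
    summary$outlier_samples <- as.list(flagged)
    keep_s <- !colnames(norm) %in% flagged
    norm <- norm[, keep_s, drop = FALSE]
    tr <- traits[match(colnames(norm), traits$sample_id), , drop = FALSE]
    gs <- .stage("gene_significance",
                 gene_significance(norm, tr$dose_rate, config$gs_method))
    selected <- .stage("dose_correlated_set",
                       dose_correlated_set(gs, config$gs_quantile,
                                           config$gs_alpha))
    summary$n_dose_correlated <- length(selected)
    gs$selected <- gs$gene %in% selected
    write_tsv(gs, file.path(out_dir, "gene_significance.tsv"))

    if (!is.null(ref)) {
      cpm <- sweep(kept_counts[, keep_s, drop = FALSE], 2,
                   colSums(kept_counts[, keep_s, drop = FALSE]), "/") * 1e6
      props <- .stage("deconvolution",
                      deconvolve_samples(cpm, ref, config$deconv_n_per_type))
      summary$n_deconvolved <- nrow(props)
      write_tsv(props, file.path(out_dir, "cell_proportions.tsv"))
    }
  }

  cfg_out <- config
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
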