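# Seeded synthetic datasets with known ground truth for every pipeline
# stage. The genotype generator draws three hierarchically related
# populations under the Balding-Nichols model (beta-distributed population
# frequencies around an ancestral frequency, drift parameter F); selection
# on the focal branch is a deterministic post-drift frequency shift.
# Defaults reproduce the study conditions: drift 0.01 on each in-group
# branch and 0.2 to the outgroup, 50 selected loci shifted by +0.4 among
# 20,000, cohorts of 10/10/25 diploids; dose-rate cohorts are lognormal with
# group means/SDs of 5.4 +/- 3.1 (exposed) and 0.02 +/- 0.01 (reference)
# uGy/h, n = 9 each.

#' Simulation configuration
#'
#' Validated parameter bundle for the synthetic generators. Defaults are the
#' study conditions used throughout the package tests.
#'
#' @param n_loci number of simulated loci.
#' @param n_focal,n_sister,n_outgroup diploid sample sizes.
#' @param f_split drift parameter from the ancestral population to the
#'   outgroup and to the in-group ancestor.
#' @param f_focal,f_sister drift on the focal / sister terminal branches.
#' @param n_selected_focal,n_selected_sister loci receiving a selection
#'   shift on the respective branch.
#' @param selection_shift post-drift allele-frequency shift at selected loci
#'   (truncated at 0.99).
#' @param missing_rate per-call missingness probability.
#' @param depth_mean,depth_size negative-binomial per-call depth parameters.
#' @param n_genes,n_dose_genes,beta,dispersion expression generator: total
#'   genes, dose-responsive genes, log2-fold effect per SD of dose, NB
#'   dispersion (variance = mu + dispersion * mu^2).
#' @param dose_groups data.frame (`population`, `mean`, `sd`, `n`) of
#'   per-group lognormal total dose-rate targets in uGy/h.
#' @param age_range uniform age range in years.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 20000,
                       n_focal = 10, n_sister = 10, n_outgroup = 25,
                       f_split = 0.2, f_focal = 0.01, f_sister = 0.01,
                       n_selected_focal = 50, n_selected_sister = 0,
                       selection_shift = 0.4,
                       missing_rate = 0.02,
                       depth_mean = 30, depth_size = 10,
                       n_genes = 1000, n_dose_genes = 20, beta = 1,
                       dispersion = 0.1,
                       dose_groups = data.frame(
                         population = c("focal", "reference"),
                         mean = c(5.4, 0.02), sd = c(3.1, 0.01),
                         n = c(9, 9), stringsAsFactors = FALSE),
                       age_range = c(1, 8)) {
  for (f in c(f_split, f_focal, f_sister)) {
    if (!(f > 0 && f < 1)) stop("drift parameters F must lie in (0, 1)")
  }
  if (!(selection_shift >= 0 && selection_shift < 1)) {
    stop("selection_shift must lie in [0, 1)")
  }
  if (!(missing_rate >= 0 && missing_rate <= 1)) {
    stop("missing_rate must lie in [0, 1]")
  }
  if (n_selected_focal + n_selected_sister > n_loci) {
    stop("more selected loci than loci")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Balding-Nichols draw: beta around ancestral frequency p with drift F
.bn_draw <- function(p, f) {
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate three-population genotypes with focal-branch selection
#'
#' Ancestral frequencies are Uniform(0.05, 0.95). The outgroup and an
#' in-group ancestor drift from the ancestral population with `f_split`;
#' focal and sister drift from the in-group ancestor with `f_focal` /
#' `f_sister`. Selected loci get an additional `selection_shift` added to
#' the focal (or sister) frequency, truncated at 0.99. Genotypes are
#' Hardy-Weinberg draws; depth is negative-binomial with genotype quality
#' coupled as `GQ = min(99, round(4 * DP))`; missingness is applied at the
#' configured rate.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (full determinism: same cfg + seed, same output).
#' @return list: `genotypes` (a `genotype_matrix`), `truth` (list with
#'   `selected_focal`, `selected_sister` locus indices and the per-population
#'   true allele frequencies).
#' @export
simulate_three_pop_genotypes <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  anc <- stats::runif(cfg$n_loci, 0.05, 0.95)
  p_out <- .bn_draw(anc, cfg$f_split)
  p_eur <- .bn_draw(anc, cfg$f_split)
  p_foc <- .bn_draw(p_eur, cfg$f_focal)
  p_sis <- .bn_draw(p_eur, cfg$f_sister)
  sel_all <- sample.int(cfg$n_loci, cfg$n_selected_focal + cfg$n_selected_sister)
  sel_foc <- sort(sel_all[seq_len(cfg$n_selected_focal)])
  sel_sis <- sort(setdiff(sel_all, sel_foc))
  p_foc[sel_foc] <- pmin(p_foc[sel_foc] + cfg$selection_shift, 0.99)
  p_sis[sel_sis] <- pmin(p_sis[sel_sis] + cfg$selection_shift, 0.99)

  draw_pop <- function(p, n) {
    matrix(stats::rbinom(length(p) * n, 2, rep(p, n)), ncol = n)
  }
  dosage <- cbind(draw_pop(p_foc, cfg$n_focal),
                  draw_pop(p_sis, cfg$n_sister),
                  draw_pop(p_out, cfg$n_outgroup))
  ntot <- ncol(dosage)
  depth <- matrix(stats::rnbinom(cfg$n_loci * ntot, mu = cfg$depth_mean,
                                 size = cfg$depth_size), ncol = ntot)
  quality <- matrix(pmin(99L, as.integer(round(4 * depth))), ncol = ntot)
  dosage[matrix(stats::runif(cfg$n_loci * ntot) < cfg$missing_rate,
                ncol = ntot)] <- NA_integer_
  samples <- data.frame(
    id = c(sprintf("foc%02d", seq_len(cfg$n_focal)),
           sprintf("sis%02d", seq_len(cfg$n_sister)),
           sprintf("out%02d", seq_len(cfg$n_outgroup))),
    population = rep(c("focal", "sister", "outgroup"),
                     c(cfg$n_focal, cfg$n_sister, cfg$n_outgroup)),
    stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = 100L * seq_len(cfg$n_loci),
                      ref = "A", alt = "C", annotation = "synonymous",
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, dosage, depth, quality, samples)
  list(genotypes = gm,
       truth = list(selected_focal = sel_foc, selected_sister = sel_sis,
                    p_focal = p_foc, p_sister = p_sis, p_outgroup = p_out))
}

#' Simulate expression counts with dose-dependent genes
#'
#' Gene baseline means are lognormal; the first `n_dose_genes` genes get a
#' log2-mean shift of `beta` per standard deviation of dose. Optional
#' co-expression modules add a latent factor `a * z(dose) + noise` with
#' per-gene loadings. Counts are negative-binomial with the configured
#' dispersion; library sizes vary uniformly by +/- 30%.
#'
#' @param cfg a [sim_config()].
#' @param doses per-sample total dose rates (uGy/h).
#' @param seed integer seed.
#' @param modules optional list of module specs, each a list with elements
#'   `size` (genes), `dose_effect` (a), `label`; module genes are drawn from
#'   the non-dose-responsive pool.
#' @return list: `counts` (genes x samples), `traits` (per-sample
#'   data.frame), `truth` (dose gene ids with slopes, module memberships and
#'   loadings).
#' @export
simulate_expression <- function(cfg = sim_config(), doses, seed = 1,
                                modules = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  ns <- length(doses)
  zdose <- if (stats::sd(doses) > 0) (doses - mean(doses)) / stats::sd(doses)
           else rep(0, ns)
  mu0 <- stats::rlnorm(cfg$n_genes, meanlog = 5, sdlog = 1)
  beta_g <- numeric(cfg$n_genes)
  dose_idx <- seq_len(cfg$n_dose_genes)
  beta_g[dose_idx] <- cfg$beta
  log2mu <- outer(log2(mu0), rep(1, ns)) + outer(beta_g, zdose)

  truth_modules <- NULL
  if (!is.null(modules)) {
    pool <- setdiff(seq_len(cfg$n_genes), dose_idx)
    assigned <- list()
    for (m in modules) {
      genes <- pool[seq_len(m$size)]
      pool <- setdiff(pool, genes)
      factor_m <- m$dose_effect * zdose + stats::rnorm(ns)
      loading <- stats::runif(m$size, 0.5, 1)
      log2mu[genes, ] <- log2mu[genes, ] + outer(loading, factor_m)
      assigned[[m$label]] <- data.frame(gene = sprintf("gene%04d", genes),
                                        module = m$label, loading = loading,
                                        stringsAsFactors = FALSE)
    }
    truth_modules <- do.call(rbind, assigned)
  }

  libf <- stats::runif(ns, 0.7, 1.3)
  mu <- sweep(2^log2mu, 2, libf, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                   nrow = cfg$n_genes)
  rownames(counts) <- sprintf("gene%04d", seq_len(cfg$n_genes))
  colnames(counts) <- sprintf("s%02d", seq_len(ns))
  traits <- data.frame(sample_id = colnames(counts), population = "focal",
                       dose_rate = doses,
                       age = stats::runif(ns, cfg$age_range[1], cfg$age_range[2]),
                       sex = sample(c("F", "M"), ns, replace = TRUE),
                       monocyte = stats::runif(ns, 0.05, 0.20),
                       granulocyte = stats::runif(ns, 0.40, 0.70),
                       stringsAsFactors = FALSE)
  list(counts = counts, traits = traits,
       truth = list(dose_genes = rownames(counts)[dose_idx],
                    slopes = beta_g[dose_idx], modules = truth_modules))
}

#' Simulate per-animal dose records
#'
#' Draws lognormal total dose rates matching each group's requested mean and
#' SD, then back-allocates the total into internal 137Cs activity, home-range
#' soil 90Sr and a measured external rate with fixed pathway fractions, so
#' that [dose_rates()] on the emitted records reproduces the drawn totals
#' exactly. Ages are Uniform over `cfg$age_range`.
#'
#' @param cfg a [sim_config()] (uses `dose_groups` and `age_range`).
#' @param seed integer seed.
#' @param coeffs the [dose_coefficients()] used for back-allocation.
#' @param fractions length-3 pathway fractions (internal 137Cs, internal
#'   90Sr, external) summing to 1.
#' @return list: `records` (data.frame for [dose_rates()]), `truth`
#'   (data.frame with the drawn total rates).
#' @export
simulate_doses <- function(cfg = sim_config(), seed = 1,
                           coeffs = dose_coefficients(),
                           fractions = c(0.5, 0.3, 0.2)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (abs(sum(fractions) - 1) > 1e-12 || any(fractions < 0)) {
    stop("fractions must be non-negative and sum to 1")
  }
  set.seed(seed)
  g <- cfg$dose_groups
  rows <- lapply(seq_len(nrow(g)), function(i) {
    m <- g$mean[i]; s <- g$sd[i]; n <- g$n[i]
    rate <- if (s == 0) rep(m, n) else {
      sdlog <- sqrt(log(1 + s^2 / m^2))
      meanlog <- log(m) - sdlog^2 / 2
      stats::rlnorm(n, meanlog, sdlog)
    }
    data.frame(animal_id = sprintf("%s%02d", substr(g$population[i], 1, 3),
                                   seq_len(n)),
               population = g$population[i],
               age_years = stats::runif(n, cfg$age_range[1], cfg$age_range[2]),
               activity_bqkg_wet = fractions[1] * rate / coeffs$dc_internal_cs137,
               activity_bqg_dry = NA_real_, wet_dry_ratio = NA_real_,
               soil_cs137_kbqm2 = NA_real_,
               soil_sr90_kbqm2 = fractions[2] * rate /
                 (coeffs$cr_sr90 * coeffs$dc_internal_sr90),
               ext_rate_ugyh = fractions[3] * rate,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  truth <- data.frame(animal_id = records$animal_id,
                      population = records$population,
                      total_rate = records$ext_rate_ugyh / fractions[3],
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Simulate reference profiles and noisy mixtures for deconvolution
#'
#' Builds a synthetic reference with `n_types` cell types, each with a block
#' of marker genes, draws mixing proportions from a Dirichlet, and produces
#' mixtures with multiplicative Gaussian noise of coefficient of variation
#' `cv`.
#'
#' @param n_genes,n_types reference dimensions.
#' @param n_samples number of mixtures.
#' @param cv multiplicative noise coefficient of variation (default 0.1).
#' @param seed integer seed.
#' @return list: `ref`, `mixtures` (genes x samples), `truth` (samples x
#'   types true proportions).
#' @export
simulate_mixtures <- function(n_genes = 200, n_types = 4, n_samples = 10,
                              cv = 0.1, seed = 1) {
  set.seed(seed)
  ref <- matrix(stats::rlnorm(n_genes * n_types, 2, 1), n_genes, n_types)
  block <- split(seq_len(n_genes),
                 rep(seq_len(n_types), length.out = n_genes))
  for (k in seq_len(n_types)) ref[block[[k]], k] <- ref[block[[k]], k] * 50
  rownames(ref) <- sprintf("gene%03d", seq_len(n_genes))
  colnames(ref) <- sprintf("type%d", seq_len(n_types))
  w <- matrix(stats::rgamma(n_samples * n_types, 2, 1), n_samples, n_types)
  w <- w / rowSums(w)
  mixtures <- ref %*% t(w)
  noise <- matrix(stats::rnorm(length(mixtures), 1, cv), nrow(mixtures))
  mixtures <- mixtures * pmax(noise, 0.01)
  colnames(mixtures) <- sprintf("s%02d", seq_len(n_samples))
  rownames(w) <- colnames(mixtures)
  colnames(w) <- colnames(ref)
  list(ref = ref, mixtures = mixtures, truth = w)
}
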