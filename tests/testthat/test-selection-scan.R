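test_that("Weir-Cockerham FST handles fixed, mixed and monomorphic sites", {
  # fixed difference between populations of 10 diploids
  expect_equal(wc_fst(10, 0, 0, 10, 1, 0), 1)
  # pooled monomorphic site is undefined
  expect_true(is.na(wc_fst(10, 0, 0, 10, 0, 0)))
  expect_true(is.na(wc_fst(10, 1, 0, 12, 1, 0)))
  # genotype-count example: pop1 (5 AA, 3 Aa, 2 aa), pop2 (1 AA, 4 Aa, 5 aa)
  p1 <- (3 + 2 * 2) / 20; h1 <- 3 / 10
  p2 <- (4 + 2 * 5) / 20; h2 <- 4 / 10
  expect_equal(wc_fst(10, p1, h1, 10, p2, h2),
               wc84_oracle(c(10, 10), c(p1, p2), c(h1, h2)))
})

test_that("vectorised FST agrees with the literal WC84 transcription on 1000 random configurations", {
  set.seed(84)
  for (i in 1:1000) {
    cfg <- random_site_config()
    got <- wc_fst(cfg$n1, cfg$p1, cfg$h1, cfg$n2, cfg$p2, cfg$h2)
    want <- wc84_oracle(c(cfg$n1, cfg$n2), c(cfg$p1, cfg$p2), c(cfg$h1, cfg$h2))
    if (is.na(want) || (cfg$p1 == cfg$p2 && cfg$p1 %in% c(0, 1) &&
                        cfg$h1 == 0 && cfg$h2 == 0)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("branch-length transform is the clamped Cavalli-Sforza form", {
  expect_equal(cs_transform(0), 0)
  expect_equal(cs_transform(0.5), log(2))
  expect_equal(cs_transform(1), -log(1e-9))
  expect_equal(cs_transform(-0.3), 0) # negative estimates clamp to 0
  # strictly increasing on [0, cap]
  x <- seq(0, 1 - 1e-9, length.out = 200)
  expect_true(all(diff(cs_transform(x)) > 0))
})

test_that("PBS is the half-sum branch combination and linear in each argument", {
  expect_equal(pbs(0.4, 0.4, 0.4), 0.2)
  expect_equal(pbs(0.2, 0.3, 0.1), 0.2)
  expect_equal(pbs(0.05, 0.05, 0.3), -0.10)
  expect_equal(pbs(2 * 0.2, 0.3, 0.1), pbs(0.2, 0.3, 0.1) + 0.1)
})

test_that("PBE subtracts the median-scaled sister-outgroup expectation", {
  expect_equal(pbe(0.7, 0.3), 0) # single locus equals its own expectation
  expect_equal(pbe(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1)),
               c(-0.1, 0, 0.1))
  # proportionality null: pbs = c * t_so for random c gives all-zero PBE
  set.seed(9)
  for (i in 1:20) {
    t_so <- runif(50, 0.01, 2)
    c0 <- runif(1, 0.1, 5)
    expect_equal(pbe(c0 * t_so, t_so), rep(0, 50), tolerance = 1e-12)
  }
  expect_error(pbe(c(0.1, 0.2), c(0, 0)), "invariant")
})

test_that("PBE p-values follow the zero-truncated z construction and BH", {
  v <- c(1, 1, 1, 1, 3)
  pv <- pbe_pvalues(v)
  expect_equal(pv$z, (v - mean(v)) / sd(v))
  expect_equal(pv$p, pnorm(pv$z, lower.tail = FALSE))
  # the p attached to a z of exactly 2 is the closed form 1 - pnorm(2)
  expect_equal(pnorm(2, lower.tail = FALSE), 0.02275, tolerance = 1e-4)
  v5 <- c(0, 0, 1, 1, 4)
  pv5 <- pbe_pvalues(v5)
  expect_equal(pv5$p, pnorm((v5 - mean(v5)) / sd(v5), lower.tail = FALSE))
  # negatives zeroed before z-scoring
  pv2 <- pbe_pvalues(c(-5, -1, 0, 1, 2))
  expect_equal(pv2$pbe, c(0, 0, 0, 1, 2))
  expect_equal(pv2$z, (c(0, 0, 0, 1, 2) - 0.6) / sd(c(0, 0, 0, 1, 2)))
  expect_error(pbe_pvalues(c(1, 1, 1)), "zero variance")
  expect_error(pbe_pvalues(c(-2, -1)), "zero variance")
  # BH step-up matches textbook arithmetic and is monotone, >= p, <= 1
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(4)
  for (i in 1:20) {
    pr <- runif(30)
    adj <- p.adjust(pr, "BH")
    # literal step-up: min over j >= rank of m * p_(j) / j
    m <- length(pr)
    o <- order(pr)
    stepup <- numeric(m)
    for (k in seq_len(m)) {
      stepup[o[k]] <- min(1, min(m * pr[o[k:m]] / match(o[k:m], o)))
    }
    expect_equal(adj, stepup, tolerance = 1e-12)
    expect_true(all(adj >= pr & adj <= 1))
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("outlier tiers respect the strict -log10 thresholds", {
  expect_equal(call_outliers(c(1, 1e-9, 1e-16)),
               c("none", "outlier", "extreme"))
  expect_equal(call_outliers(1e-8), "none") # exactly 8 is not > 8
  expect_equal(call_outliers(1e-9, thr_outlier = 6, thr_extreme = 12), "outlier")
  expect_error(call_outliers(0.5, thr_outlier = 8, thr_extreme = 7))
})

test_that("nearest-gene annotation resolves containment, strand and ties", {
  ann <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    start = c(1000L, 1000L, 5000L, 9000L),
    end = c(2000L, 1400L, 6000L, 9500L),
    strand = c("+", "+", "+", "-"),
    gene = c("gA", "gA", "gB", "gC"),
    feature = c("gene", "exon", "gene", "gene"),
    stringsAsFactors = FALSE)
  # inside gA's exon
  h1 <- nearest_gene(data.frame(chrom = "chr1", pos = 1200L), ann)
  expect_equal(h1$gene, "gA"); expect_equal(h1$relation, "exonic")
  expect_equal(h1$distance, 0)
  # inside gA but outside its exon
  h2 <- nearest_gene(data.frame(chrom = "chr1", pos = 1600L), ann)
  expect_equal(h2$relation, "intronic")
  # 64 bp past gB's 3' end on + strand
  h3 <- nearest_gene(data.frame(chrom = "chr1", pos = 6064L), ann)
  expect_equal(h3$gene, "gB"); expect_equal(h3$relation, "downstream")
  expect_equal(h3$distance, 64)
  # before gB on + strand is upstream; after gC on - strand is upstream
  h4 <- nearest_gene(data.frame(chrom = "chr1", pos = 4900L), ann)
  expect_equal(h4$relation, "upstream")
  h5 <- nearest_gene(data.frame(chrom = "chr1", pos = 9600L), ann)
  expect_equal(h5$gene, "gC"); expect_equal(h5$relation, "upstream")
  expect_equal(h5$distance, 100)
  # equidistant between gB (end 6000) and gC (1-based start 9001): pos 7500
  h6 <- nearest_gene(data.frame(chrom = "chr1", pos = 7500L), ann)
  expect_equal(h6$distance, 1500)
  expect_equal(h6$gene, "gB") # lower-coordinate gene wins the tie
  # chromosome with no annotation
  h7 <- nearest_gene(data.frame(chrom = "chr9", pos = 100L), ann)
  expect_equal(h7$relation, "none")
  expect_true(is.na(h7$distance))
})

test_that("selected loci show strongly elevated focal-sister FST and sister selection does not leak", {
  cfg <- sim_config(n_loci = 4000, n_selected_focal = 25,
                    n_selected_sister = 25)
  sim <- simulate_three_pop_genotypes(cfg, seed = 101)
  gm <- site_filters(mask_low_quality(sim$genotypes), autosomes = "chr1")
  scan <- pbe_scan(gm)
  locus <- scan$pos / 100
  foc_sel <- locus %in% sim$truth$selected_focal
  sis_sel <- locus %in% sim$truth$selected_sister
  neut <- !foc_sel & !sis_sel
  expect_gte(mean(scan$fst_fs[foc_sel]) / mean(scan$fst_fs[neut]), 5)
  # focal-selected loci rank far higher in focal PBE than sister-selected:
  # sister selection inflates both T_fs and T_so and cancels in PBS
  expect_gt(mean(scan$pbe_raw[foc_sel]), mean(scan$pbe_raw[sis_sel]) + 0.1)
  top50 <- order(-scan$pbe_raw)[1:50]
  expect_gt(sum(foc_sel[top50]), 3 * sum(sis_sel[top50]))
})

test_that("neutral scans keep the normal-tail fraction low and the rank alternative calibrated", {
  # the zero-inflated z construction does not produce a nominal-uniform p
  # distribution: the heavy upper tail of zero-truncated PBE keeps the
  # p < 0.05 fraction below nominal while allowing occasional extreme z
  # under the null (see the methods vignette); the rank-based empirical
  # alternative is uniform by construction
  for (s in c(301, 302)) {
    sim <- simulate_three_pop_genotypes(
      sim_config(n_loci = 5000, n_selected_focal = 0), seed = s)
    gm <- site_filters(mask_low_quality(sim$genotypes), autosomes = "chr1")
    scan <- pbe_scan(gm)
    expect_lt(mean(scan$p < 0.05), 0.10)
    expect_lt(sum(scan$tier != "none") / nrow(scan), 0.005)
    emp <- empirical_pbe_pvalues(scan$pbe_raw)
    expect_true(all(emp > 0 & emp <= 1))
    # uniform in the non-tied upper tail: about 5% of sites below 0.05
    expect_equal(mean(emp <= 0.05), 0.05, tolerance = 0.3)
  }
})
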