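test_that("CPM normalisation is the documented log2 column transform", {
  m <- matrix(c(500, 999500,
                0, 1000), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- cpm_normalize(m)
  expect_equal(norm["g1", "s1"], log2(501))
  expect_equal(norm["g1", "s2"], 0) # zero count maps to 0
  one <- matrix(c(7, 0), 2, 1, dimnames = list(c("g1", "g2"), "s"))
  expect_equal(cpm_normalize(one)["g1", 1], log2(1e6 + 1))
  # column operation: scaling one sample leaves others untouched, and
  # pre-log CPM columns sum to 1e6
  set.seed(21)
  counts <- matrix(rpois(60, 50), 10, 6)
  n1 <- cpm_normalize(counts)
  counts2 <- counts; counts2[, 3] <- counts2[, 3] * 5
  n2 <- cpm_normalize(counts2)
  expect_equal(n1[, -3], n2[, -3])
  expect_equal(n1[, 3], n2[, 3]) # CPM is scale-free within a column
  expect_equal(colSums(2^n1 - 1), rep(1e6, 6))
  expect_error(cpm_normalize(matrix(0, 2, 1)), "library")
})

test_that("low-expression filter uses a strict mean threshold", {
  counts <- rbind(exactly10 = rep(10, 4), zero = rep(0, 4),
                  high = c(100, 200, 50, 70), low = c(1, 2, 3, 4))
  kept <- filter_low_expression(counts)
  expect_equal(rownames(kept), "high")
  expect_equal(rownames(filter_low_expression(counts, mean_min = 2)),
               c("exactly10", "high", "low"))
})

test_that("outlier samples are flagged by depressed mean correlation", {
  set.seed(33)
  base <- matrix(rnorm(200), 50, 4)
  clones <- base[, c(1, 1, 1, 1)] + matrix(rnorm(200, sd = 0.01), 50, 4)
  colnames(clones) <- paste0("s", 1:4)
  # identical-ish samples: none flagged
  expect_length(flag_outlier_samples(clones), 0)
  # permuting one sample's values forces minimal mean correlation
  bad <- cbind(clones, s5 = sample(clones[, 1]))
  expect_equal(flag_outlier_samples(bad, k_sd = 1.5), "s5")
  expect_length(flag_outlier_samples(bad, k_sd = Inf), 0)
  expect_error(flag_outlier_samples(clones[, 1:2]), "3 samples")
})

test_that("gene significance reproduces the student asymptotic p-value", {
  # r = 0.6325 at n = 10: t ~ 2.3094, p ~ 0.0498
  r <- 0.6325
  t_hand <- r * sqrt(8) / sqrt(1 - r^2)
  expect_equal(t_hand, 2.3094, tolerance = 1e-3)
  expect_equal(cor_pvalue_student(r, 10), 2 * pt(-t_hand, 8))
  expect_equal(cor_pvalue_student(r, 10), 0.0498, tolerance = 5e-3)
  expect_equal(cor_pvalue_student(0, 10), 1)
  expect_equal(cor_pvalue_student(1, 10), .Machine$double.xmin)

  set.seed(5)
  trait <- rnorm(10)
  mat <- rbind(up = trait + rnorm(10, sd = 0.2),
               flat = rnorm(10),
               const = rep(1, 10))
  gs <- gene_significance(mat, trait, method = "pearson")
  expect_equal(gs$r[1], cor(mat[1, ], trait))
  expect_true(is.na(gs$r[3])) # constant gene excluded
  expect_error(gene_significance(mat, rep(1, 10)), "variance")
})

test_that("Spearman gene significance is invariant under monotone trait transforms", {
  set.seed(6)
  trait <- rlnorm(12)
  mat <- matrix(rnorm(120), 10, 12)
  g1 <- gene_significance(mat, trait, "spearman")
  g2 <- gene_significance(mat, log(trait), "spearman")
  g3 <- gene_significance(mat, rank(trait), "spearman")
  expect_equal(g1$r, g2$r)
  expect_equal(g1$r, g3$r)
})

test_that("dose-correlated selection takes the top |r| tail gated by p", {
  set.seed(7)
  r <- seq(0.005, 0.995, length.out = 100) * rep(c(-1, 1), 50)
  gs <- data.frame(gene = paste0("g", 1:100), r = r,
                   p = rep(0.001, 100), stringsAsFactors = FALSE)
  sel <- dose_correlated_set(gs)
  # exactly the top 5 by |r| (all |r| distinct here)
  expect_setequal(sel, gs$gene[order(-abs(gs$r))[1:5]])
  # genes tied at the threshold are all included
  gs_tie <- data.frame(gene = paste0("t", 1:10),
                       r = c(rep(0.9, 3), rep(0.2, 7)),
                       p = rep(0.001, 10), stringsAsFactors = FALSE)
  expect_setequal(dose_correlated_set(gs_tie, quantile = 0.8),
                  paste0("t", 1:3))
  # all p above alpha gives the empty set
  gs$p <- 0.5
  expect_length(dose_correlated_set(gs), 0)
  # size tracks (1 - quantile) when all p pass
  gs$p <- 0.001
  expect_equal(length(dose_correlated_set(gs, quantile = 0.9)), 10)
})

test_that("module eigengene is the oriented first principal component", {
  set.seed(8)
  prof <- rnorm(12)
  # identical genes: eigengene correlates perfectly with the shared profile
  mod <- rbind(g1 = prof, g2 = prof, g3 = prof) +
    matrix(rnorm(36, sd = 1e-6), 3, 12)
  colnames(mod) <- paste0("s", 1:12)
  eig <- module_eigengene(mod, data.frame(gene = rownames(mod), module = "m1"))
  expect_equal(abs(cor(eig[, "m1"], prof)), 1, tolerance = 1e-6)
  expect_gt(cor(eig[, "m1"], prof), 0) # orientation rule
  expect_equal(sum(eig[, "m1"]^2), 1)  # unit norm
  # flipping all member genes flips the eigengene
  eig_fl <- module_eigengene(-mod, data.frame(gene = rownames(mod), module = "m1"))
  expect_equal(eig_fl[, "m1"], -eig[, "m1"], tolerance = 1e-5)
  # gene reordering leaves it unchanged
  eig_perm <- module_eigengene(mod[c(3, 1, 2), ],
                               data.frame(gene = rownames(mod)[c(3, 1, 2)],
                                          module = "m1"))
  expect_equal(eig_perm[, "m1"], eig[, "m1"])
  # two-gene module matches a direct eigen-decomposition of the 2x2 covariance
  two <- rbind(a = rnorm(12), b = rnorm(12))
  colnames(two) <- paste0("s", 1:12)
  eig2 <- module_eigengene(two, data.frame(gene = c("a", "b"), module = "m"))
  zs <- t(scale(t(two)))
  ev <- eigen(crossprod(zs))$vectors[, 1]
  ev <- ev / sqrt(sum(ev^2))
  if (mean(apply(two, 1, function(g) cor(g, ev))) < 0) ev <- -ev
  expect_equal(as.numeric(eig2[, "m"]), as.numeric(ev), tolerance = 1e-8)
  # undersized module warns and is skipped
  expect_warning(
    module_eigengene(rbind(mod, solo = rnorm(12)),
                     data.frame(gene = c(rownames(mod), "solo"),
                                module = c("m1", "m1", "m1", "m2"))),
    "fewer than 2")
})

test_that("module trait tests: degenerate and exact cases", {
  set.seed(9)
  n <- 40
  traits <- data.frame(dose_rate = rlnorm(n, 1, 0.6), age = runif(n, 1, 8),
                       monocyte = runif(n, 0.05, 0.2),
                       granulocyte = runif(n, 0.4, 0.7),
                       sex = sample(c("F", "M"), n, TRUE))
  # eigengene an exact linear function of dose: enormous chi2, p ~ 0
  res <- module_trait_tests(2 * traits$dose_rate + 1e-8 * rnorm(n), traits)
  expect_gt(res$lrt$chi2[res$lrt$contrast == "dose"], 100)
  expect_lt(res$lrt$p[res$lrt$contrast == "dose"], 1e-10)
  expect_equal(res$cor, cor(2 * traits$dose_rate + 1e-8 * rnorm(n),
                            traits$dose_rate), tolerance = 1e-3)
  # dropping dose and age removes 3 parameters, dropping dose-only removes 2
  expect_equal(res$lrt$df, c(2, 3))
  # collinear design is reported with the offending column
  tr_bad <- traits
  tr_bad$granulocyte <- tr_bad$monocyte * 2
  expect_error(module_trait_tests(rnorm(n), tr_bad), "collinear")
})

test_that("null LRT p-values are uniform at calibration sample size", {
  # chi-square asymptotics hold at n = 100 (at the study's n = 18 the ML
  # ratio test is anticonservative; see the methods vignette)
  set.seed(10)
  n <- 100
  pvals <- replicate(500, {
    traits <- data.frame(dose_rate = rlnorm(n, 1, 0.6), age = runif(n, 1, 8),
                         monocyte = runif(n, 0.05, 0.2),
                         granulocyte = runif(n, 0.4, 0.7),
                         sex = sample(c("F", "M"), n, TRUE))
    res <- module_trait_tests(rnorm(n), traits)
    res$lrt$p[res$lrt$contrast == "dose"]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("dose-driven module recovers a significant LRT at the study size", {
  # latent factor = 1 * z(dose) + noise, module of 40 genes, n = 18
  set.seed(12)
  hits <- replicate(50, {
    doses <- rlnorm(18, 1.2, 0.6)
    cfg <- sim_config(n_genes = 300, n_dose_genes = 0)
    ex <- simulate_expression(cfg, doses, seed = sample.int(1e6, 1),
                              modules = list(list(size = 40, dose_effect = 1,
                                                  label = "mod1")))
    norm <- cpm_normalize(ex$counts)
    eig <- module_eigengene(norm, ex$truth$modules[, c("gene", "module")])
    res <- module_trait_tests(eig[, "mod1"], ex$traits)
    res$lrt$p[res$lrt$contrast == "dose_age"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("pathway PCA separates constructed group shifts", {
  set.seed(13)
  # two perfectly correlated genes: PC1 carries all variance
  g <- rnorm(10)
  mat <- rbind(a = g, b = 2 * g + 3)
  colnames(mat) <- paste0("s", 1:10)
  pp <- pathway_pca(mat, c("a", "b"))
  expect_equal(pp$var_explained[1], 1)
  # orthogonal equal-variance genes: equal fractions
  o <- rbind(a = rep(c(-1, 1), 8), b = rep(c(-1, 1, 1, -1), 4))
  colnames(o) <- paste0("s", 1:16)
  po <- pathway_pca(o, c("a", "b"))
  expect_equal(po$var_explained, c(0.5, 0.5))
  # a two-group mean shift on set genes separates centroids on PC1
  grp <- rep(c(0, 4), each = 10)
  sh <- matrix(rnorm(20 * 20), 20, 20) + matrix(grp, 20, 20, byrow = TRUE)
  rownames(sh) <- paste0("g", 1:20); colnames(sh) <- paste0("s", 1:20)
  ps <- pathway_pca(sh, rownames(sh))
  pc1 <- ps$scores[, 1]
  centd <- abs(mean(pc1[1:10]) - mean(pc1[11:20]))
  within_sd <- mean(c(sd(pc1[1:10]), sd(pc1[11:20])))
  expect_gt(centd, 2 * within_sd)
  expect_error(pathway_pca(sh, "g1"), "fewer than 2")
})
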