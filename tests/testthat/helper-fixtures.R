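# Shared fixture builders: everything is generated in code at test time.

# small genotype matrix with explicit dosage/depth/quality values
toy_gm <- function(dosage, depth = NULL, quality = NULL,
                   chrom = rep("chr1", nrow(dosage)),
                   pos = 100L * seq_len(nrow(dosage)),
                   ref = rep("A", nrow(dosage)),
                   alt = rep("C", nrow(dosage)),
                   annotation = rep("synonymous", nrow(dosage)),
                   population = rep("focal", ncol(dosage))) {
  dosage <- as.matrix(dosage)
  if (is.null(depth)) depth <- matrix(30L, nrow(dosage), ncol(dosage))
  if (is.null(quality)) quality <- matrix(99L, nrow(dosage), ncol(dosage))
  genotype_matrix(
    sites = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       annotation = annotation, stringsAsFactors = FALSE),
    dosage = dosage, depth = depth, quality = quality,
    samples = data.frame(id = sprintf("s%02d", seq_len(ncol(dosage))),
                         population = population, stringsAsFactors = FALSE))
}

# mark a matrix as already masked/filtered (for unit tests that start
# mid-pipeline)
force_flags <- function(gm, masked = TRUE, site_filtered = TRUE) {
  attr(gm, "masked") <- masked
  attr(gm, "site_filtered") <- site_filtered
  gm
}

# independent literal transcription of the Weir & Cockerham (1984)
# variance-component estimator for r populations of diploids, used as the
# oracle against the vectorised two-population implementation
wc84_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# plain-loop LD pruning oracle: same greedy rule, written independently
ld_prune_oracle <- function(dosage, window, step, r2_max) {
  r2 <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 2) return(0)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
    stats::cor(x[ok], y[ok])^2
  }
  n <- nrow(dosage)
  keep <- rep(TRUE, n)
  for (s in seq(1, n, by = step)) {
    win <- s:min(s + window - 1, n)
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      live <- win[keep[win]]
      if (length(live) < 2) break
      for (ii in seq_along(live)) {
        for (jj in seq_along(live)) {
          if (jj <= ii) next
          if (keep[live[ii]] && keep[live[jj]] &&
              r2(dosage[live[ii], ], dosage[live[jj], ]) > r2_max) {
            keep[live[jj]] <- FALSE
            changed <- TRUE
          }
        }
      }
    }
  }
  which(keep)
}

# random allele-configuration generator for the FST oracle comparison
random_site_config <- function() {
  n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
  g1 <- stats::rmultinom(1, n1, prob = stats::runif(3))[, 1]
  g2 <- stats::rmultinom(1, n2, prob = stats::runif(3))[, 1]
  list(n1 = n1, p1 = (g1[2] + 2 * g1[3]) / (2 * n1), h1 = g1[2] / n1,
       n2 = n2, p2 = (g2[2] + 2 * g2[3]) / (2 * n2), h2 = g2[2] / n2)
}
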