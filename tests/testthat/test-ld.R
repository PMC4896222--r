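biallelic_pair <- function(nAB, nAb, naB, nab) {
  geno_matrix(L1 = c(rep(100, nAB + nAb), rep(102, naB + nab)),
              L2 = c(rep(200, nAB), rep(202, nAb),
                     rep(200, naB), rep(202, nab)))
}

test_that("multi-allelic D' matches the hand-worked 2x2 case and its limits", {
  g <- biallelic_pair(40, 10, 10, 40)   # D = 0.15, Dmax = 0.25
  expect_equal(pairwise_dprime(g, "L1", "L2"), 0.6)

  coupled <- biallelic_pair(50, 0, 0, 50)
  expect_equal(pairwise_dprime(coupled, "L1", "L2"), 1)

  indep <- biallelic_pair(25, 25, 25, 25)
  expect_equal(pairwise_dprime(indep, "L1", "L2"), 0)

  mono <- geno_matrix(L1 = rep(100, 10), L2 = rep(c(200, 202), 5))
  expect_error(pairwise_dprime(mono, "L1", "L2"), "monomorphic")
})

test_that("D' is symmetric in loci, invariant to allele relabeling, in [0,1]", {
  set.seed(31)
  cfg <- sim_config(n_accessions = 80, n_loci = 6, n_subpops = 2,
                    null_rate = 0.05, seed = 31)
  g <- simulate_genotypes(cfg)$genotypes
  for (pair in list(c(1, 2), c(3, 4), c(5, 6))) {
    a <- colnames(g)[pair[1]]; b <- colnames(g)[pair[2]]
    d1 <- pairwise_dprime(g, a, b)
    expect_equal(d1, pairwise_dprime(g, b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
    # relabel alleles of locus a (order-preserving bijection of sizes)
    g2 <- g
    g2[, a] <- g[, a] * 3L + 7L
    expect_equal(pairwise_dprime(g2, a, b), d1)
  }
})

test_that("multi-allelic D' reduces to the classical |D'| for biallelic loci", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = rgamma(4, 1)))
    if (min(counts[1] + counts[2], counts[3] + counts[4]) == 0 ||
        min(counts[1] + counts[3], counts[2] + counts[4]) == 0) next
    g <- biallelic_pair(counts[1], counts[2], counts[3], counts[4])
    x11 <- counts[1] / n
    pA <- (counts[1] + counts[2]) / n
    qB <- (counts[1] + counts[3]) / n
    D <- x11 - pA * qB
    dmax <- if (D < 0) min(pA * qB, (1 - pA) * (1 - qB)) else
      min(pA * (1 - qB), (1 - pA) * qB)
    classical <- if (abs(D) < 1e-15) 0 else abs(D) / dmax
    expect_equal(pairwise_dprime(g, "L1", "L2"), classical,
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values behave at the extremes and under the null", {
  coupled <- biallelic_pair(30, 0, 0, 30)
  pp <- permutation_pvalue(coupled, "L1", "L2", n_perm = 99, seed = 1)
  expect_equal(pp$p, 1 / 100)   # observed D' = 1 beaten by no permutation?
  # self-LD is maximal
  g <- geno_matrix(L1 = rep(c(100, 102, 104), 10),
                   L2 = rep(c(100, 102, 104), 10))
  pself <- permutation_pvalue(g, "L1", "L2", n_perm = 99, seed = 1)
  expect_lt(pself$p, 0.05)

  # independent loci: p roughly uniform (coarse two-bin check, seeded)
  set.seed(33)
  ps <- replicate(60, {
    gg <- geno_matrix(L1 = sample(c(100L, 102L), 60, replace = TRUE),
                      L2 = sample(c(200L, 202L), 60, replace = TRUE))
    permutation_pvalue(gg, "L1", "L2", n_perm = 99,
                       seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps > 0.5), 0.25)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("ld_scan summary partitions significant pairs and ratios sum to 100", {
  ds <- small_qtl_panel(seed = 34, n = 90, n_loci = 8, null_rate = 0.02)
  scan <- suppressWarnings(
    ld_scan(ds$genotypes, ds$map, ds$true_Q, n_perm = 49, seed = 2))
  s <- scan$summary
  bins <- as.matrix(s[, grep("^d", names(s))])
  expect_equal(rowSums(bins), s$n_significant, ignore_attr = TRUE)
  if (sum(s$n_significant) > 0)
    expect_equal(sum(s$ratio_pct), 100, tolerance = 1)
  # ratio definition: per-subpop share of the total significant pairs
  expect_equal(s$ratio_pct,
               round(100 * s$n_significant / sum(s$n_significant), 1))
  # small subpopulations are skipped with a warning
  tiny_q <- ds$true_Q; tiny_q[, 1] <- 0; tiny_q[1, ] <- c(1, 0, 0)
  tiny_q <- tiny_q / rowSums(tiny_q)
  w <- testthat::capture_warnings(
    ld_scan(ds$genotypes[1:12, ], ds$map, tiny_q[1:12, ], n_perm = 9,
            seed = 1))
  expect_true(any(grepl("skipped", w)))
})

test_that("decay regression is exact on noiseless points and inverts correctly", {
  x <- c(1, 5, 20, 50, 100)
  pairs <- data.frame(subpop = "P1", locusA = "a", locusB = "b",
                      dprime = -0.1 * log(x) + 0.9, p = 0.001,
                      syntenic = TRUE, distance_cM = x)
  fit <- fit_decay(pairs)
  expect_equal(fit$b, -0.1, tolerance = 1e-12)
  expect_equal(fit$c, 0.9, tolerance = 1e-12)
  expect_equal(decay_distance(fit, 0.4), exp(5), tolerance = 1e-9)
  expect_equal(decay_distance(fit, fit$c), 1, tolerance = 1e-9)
  expect_warning(decay_distance(fit, 0.95), "below 1 cM")

  same_x <- transform(pairs, distance_cM = 10)
  expect_error(fit_decay(same_x), "identical")
  rising <- transform(pairs, dprime = rev(dprime))
  expect_error(decay_distance(fit_decay(rising), 0.4), "no decay")
})

test_that("simulated structured panels show decaying LD with distance", {
  ds <- small_qtl_panel(seed = 35, n = 120, n_loci = 12, null_rate = 0)
  # put all loci on one chromosome so every pair is syntenic
  map <- ds$map; map$chromosome <- 1L
  map$cM <- sort(stats::runif(nrow(map), 0, 150))
  scan <- suppressWarnings(
    ld_scan(ds$genotypes, map, ds$true_Q, n_perm = 29, seed = 3, alpha = 1))
  fit <- fit_decay(scan$pairs, alpha = 1)
  expect_true(is.finite(fit$b))
})
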