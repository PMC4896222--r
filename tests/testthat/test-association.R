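make_assoc_toy <- function(seed = 51, n = 80, n_loci = 10) {
  cfg <- sim_config(n_accessions = n, n_loci = n_loci, n_subpops = 2,
                    fst = 0.2, admixture_alpha = 0.3, null_rate = 0,
                    qtl_spec = list(list(trait = "GL", locus = "SSR002",
                                         effects = c(top1 = 2))),
                    target_h2 = c(GL = 0.9), seed = seed)
  simulate_dataset(cfg)
}

test_that("REML with identity kinship matches the OLS variance split and scales", {
  set.seed(52)
  n <- 60
  X <- cbind(1, stats::rnorm(n))
  y <- X %*% c(2, 0.5) + stats::rnorm(n)
  K <- diag(n)
  vc <- reml_variance_components(y, X, K)
  ols <- sum(stats::lm.fit(X, y)$residuals^2) / (n - 2)
  expect_equal(vc$sigma_g2 + vc$sigma_e2, ols, tolerance = 1e-6)

  vc2 <- reml_variance_components(2 * y, X, K)
  expect_equal(vc2$sigma_g2 + vc2$sigma_e2, 4 * ols, tolerance = 1e-6)

  Xbad <- cbind(X, X[, 2])
  expect_error(reml_variance_components(y, Xbad, K), "rank deficient")
})

test_that("REML recovers a planted variance ratio on a known kinship", {
  set.seed(53)
  n <- 300
  Z <- matrix(stats::rnorm(n * 40), n)
  K <- tcrossprod(Z) / 40
  ratios <- replicate(8, {
    L <- chol(K + diag(1e-8, n))
    u <- sqrt(2) * drop(crossprod(L, stats::rnorm(n)))
    y <- 3 + u + stats::rnorm(n)
    vc <- reml_variance_components(y, cbind(rep(1, n)), K)
    vc$sigma_g2 / vc$sigma_e2
  })
  expect_gt(mean(ratios), 2 * 0.7)
  expect_lt(mean(ratios), 2 * 1.3)
})

test_that("with K = I and intercept-only Q the marker test equals one-way ANOVA", {
  ds <- make_assoc_toy()
  means <- tapply(ds$phenotypes$value[ds$phenotypes$year == 2013 &
                                        ds$phenotypes$trait == "GL"],
                  ds$phenotypes$accession[ds$phenotypes$year == 2013 &
                                            ds$phenotypes$trait == "GL"],
                  mean)
  y <- as.numeric(means[rownames(ds$genotypes)])
  n <- length(y)
  K <- diag(n); dimnames(K) <- list(rownames(ds$genotypes),
                                    rownames(ds$genotypes))
  X0 <- cbind(rep(1, n))
  vc <- reml_variance_components(y, X0, K)
  for (loc in colnames(ds$genotypes)[1:5]) {
    res <- mlm_marker_test(y, NULL, K, ds$genotypes[, loc], vc,
                           rare_min = 5)
    cls <- ssrmine:::marker_classes(ds$genotypes[, loc], rare_min = 5)
    if (is.null(res) || nlevels(cls) < 2) next
    p_aov <- stats::anova(stats::lm(y ~ cls))[["Pr(>F)"]][1]
    expect_equal(res$p, p_aov, tolerance = 1e-8)
  }
})

test_that("monomorphic and near-monomorphic markers are skipped, not zeroed", {
  y <- stats::rnorm(30)
  K <- diag(30)
  vc <- list(sigma_g2 = 0, sigma_e2 = 1)
  mono <- rep(100L, 30)
  expect_null(mlm_marker_test(y, NULL, K, mono, vc))
  nearly <- c(rep(100L, 29), 102L)   # singleton class collapses away
  expect_null(mlm_marker_test(y, NULL, K, nearly, vc))
})

test_that("genome scan finds the planted QTL, is complete, and ignores accession order", {
  ds <- make_assoc_toy(seed = 54, n = 100)
  fitK <- kinship_matrix(ds$genotypes)
  q <- ds$true_Q
  scan <- genome_scan(ds$phenotypes, ds$genotypes, ds$map, q, fitK)
  y13 <- scan[scan$year == 2013, ]
  expect_identical(y13$locus[which.min(y13$p)], "SSR002")
  # completeness: each testable locus appears once per trait-year
  expect_true(all(table(scan$locus, scan$year) <= 1))
  expect_true(all(scan$pve >= 0 & scan$pve <= 100))
  expect_true(all(scan$p > 0 & scan$p <= 1))

  perm <- sample(nrow(ds$genotypes))
  scan2 <- genome_scan(ds$phenotypes, ds$genotypes[perm, ], ds$map,
                       q[perm, ], kinship_matrix(ds$genotypes[perm, ]))
  m <- merge(scan, scan2, by = c("trait", "year", "locus"))
  expect_equal(m$p.x, m$p.y, tolerance = 1e-8)
})

test_that("significance filter applies strict p and per-row PVE thresholds", {
  res <- data.frame(trait = "GL", year = c(2013, 2014, 2013, 2014),
                    locus = rep(c("L1", "L2"), each = 2),
                    chromosome = 1, position_cM = 1:4,
                    p = c(0.01, 0.01, 0.01, 0.05),
                    pve = c(4.9, 5.03, 8, 9))
  out <- filter_significant(res)
  # L1 significant both years but only its 5.03 row passes the PVE bar;
  # L2 hits p = 0.05 exactly in 2014 and is excluded (strict inequality)
  expect_identical(nrow(out), 1L)
  expect_equal(out$pve, 5.03)

  expect_identical(nrow(filter_significant(res[0, ])), 0L)

  out2 <- filter_significant(res, both_years = FALSE)
  expect_identical(nrow(out2), 2L)   # the 5.03 and the 8 rows
})
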