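test_that("K = 1 reduces to the pooled-frequency likelihood", {
  cfg <- sim_config(n_accessions = 60, n_loci = 12, n_subpops = 2,
                    null_rate = 0.05, seed = 8)
  g <- simulate_genotypes(cfg)$genotypes
  fit <- admixture_em(g, K = 1)
  expect_true(all(fit$Q == 1))
  pooled_ll <- sum(vapply(seq_len(ncol(g)), function(l) {
    calls <- g[, l][!is.na(g[, l])]
    f <- table(calls) / length(calls)
    sum(log(f[as.character(calls)]))
  }, 0))
  expect_equal(fit$loglik, pooled_ll, tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone and Q rows stay on the simplex", {
  cfg <- sim_config(n_accessions = 90, n_loci = 20, n_subpops = 3,
                    admixture_alpha = 0.1, null_rate = 0.03, seed = 9)
  g <- simulate_genotypes(cfg)$genotypes
  fit <- suppressWarnings(admixture_em(g, K = 3, seed = 2, max_iter = 80))
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_equal(rowSums(fit$Q), rep(1, nrow(g)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(fit$Q >= 0 & fit$Q <= 1))
  expect_error(admixture_em(g, K = 1000), "exceeds")
})

test_that("two well-separated clusters are recovered with confident memberships", {
  cfg <- sim_config(n_accessions = 120, n_loci = 30, n_subpops = 2,
                    fst = 0.3, admixture_alpha = 0.05, null_rate = 0,
                    seed = 7)
  sim <- simulate_genotypes(cfg)
  fit <- suppressWarnings(admixture_em(sim$genotypes, K = 2, seed = 3,
                                       max_iter = 300, tol = 1e-6))
  expect_gt(mean(apply(fit$Q, 1, max)), 0.9)
  true_lab <- max.col(sim$true_Q)
  est_lab <- max.col(fit$Q)
  agreement <- max(mean(true_lab == est_lab), mean(true_lab != est_lab))
  expect_gt(agreement, 0.9)
})

test_that("Evanno delta-K reproduces the hand-worked second difference", {
  fits <- list(`1` = c(-1000, -1000), `2` = c(-800.5, -799.5),
               `3` = c(-790, -790), `4` = c(-788, -788))
  sel <- select_k_delta_k(fits)
  # sd(L(2)) = sqrt(0.5); |L(3) - 2 L(2) + L(1)| = 190
  expect_equal(sel$table$delta_k[2], 190 / stats::sd(c(-800.5, -799.5)))
  expect_error(select_k_delta_k(fits[c(1, 3, 4)]), "consecutive")
  expect_error(select_k_delta_k(fits[1:2]), "at least 3")

  flat <- list(`1` = c(-5, -5), `2` = c(-5, -5), `3` = c(-5, -5),
               `4` = c(-5, -5))
  expect_warning(sel2 <- select_k_delta_k(flat), "flat")
  expect_identical(sel2$chosen_k, 2L)   # tie resolved to the smaller K
})

test_that("kinship identities: self = 1, background pair = 0, order invariance", {
  cfg <- sim_config(n_accessions = 50, n_loci = 25, n_subpops = 3,
                    admixture_alpha = 0.2, null_rate = 0.02, seed = 12)
  g <- simulate_genotypes(cfg)$genotypes
  kin <- kinship_matrix(g)
  expect_equal(diag(kin$raw), rep(1, 50), ignore_attr = TRUE)
  # background rescaling: k_ij = (s_ij - s_bar) / (1 - s_bar)
  s_bar <- mean(kin$sharing[upper.tri(kin$sharing)])
  expect_equal(kin$raw[1, 2],
               (kin$sharing[1, 2] - s_bar) / (1 - s_bar))
  expect_equal(kin$model, t(kin$model))
  expect_true(all(eigen(kin$model, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  # permutation invariance
  perm <- sample(50)
  kin2 <- kinship_matrix(g[perm, ])
  expect_equal(kin2$model[rownames(kin$model), colnames(kin$model)],
               kin$model, tolerance = 1e-12)
  expect_identical(sum(kin$histogram), as.integer(choose(50, 2)))
})

test_that("within-cluster kinship exceeds between-cluster kinship on hard assignments", {
  cfg <- sim_config(n_accessions = 80, n_loci = 30, n_subpops = 2,
                    fst = 0.3, admixture_alpha = 0.01, null_rate = 0,
                    seed = 13)
  sim <- simulate_genotypes(cfg)
  kin <- kinship_matrix(sim$genotypes)
  lab <- max.col(sim$true_Q)
  same <- outer(lab, lab, "==") & upper.tri(kin$raw)
  diff_ <- outer(lab, lab, "!=") & upper.tri(kin$raw)
  expect_gt(mean(kin$raw[same]), mean(kin$raw[diff_]))
})

test_that("weakly structured panels put nearly all pairs in the lowest kinship bin", {
  cfg <- sim_config(n_accessions = 100, n_loci = 262, n_subpops = 3,
                    fst = 1e-4, admixture_alpha = 1, null_rate = 0,
                    seed = 14)
  g <- simulate_genotypes(cfg)$genotypes
  kin <- kinship_matrix(g)
  expect_gt(kin$histogram[["<0.05"]] / sum(kin$histogram), 0.9)
})
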