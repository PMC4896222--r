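test_that("simulated panel has the requested shape and allele ranges", {
  cfg <- sim_config(n_accessions = 628, n_loci = 262,
                    alleles_per_locus_range = c(3, 25), seed = 1)
  sim <- simulate_genotypes(cfg)
  expect_identical(dim(sim$genotypes), c(628L, 262L))
  observed <- apply(sim$genotypes, 2, function(x) length(unique(stats::na.omit(x))))
  expect_true(all(observed >= 1 & observed <= 25))
  expect_identical(nrow(sim$map), 262L)
  expect_true(all(sim$map$chromosome %in% 1:12))
  # positions sorted within chromosome
  for (c in unique(sim$map$chromosome))
    expect_false(is.unsorted(sim$map$cM[sim$map$chromosome == c]))
})

test_that("fst near zero leaves subpopulation frequencies at the ancestral values", {
  cfg <- sim_config(n_accessions = 50, n_loci = 40, n_subpops = 4,
                    fst = 1e-6, seed = 3)
  sim <- simulate_genotypes(cfg)
  # with no drift all subpopulations share frequencies: row ranges collapse
  dev <- vapply(sim$subpop_freqs, function(f)
    mean(abs(sweep(f, 2, colMeans(f)))), 0)
  expect_lt(mean(dev), 0.02)
})

test_that("null sentinel honours null_rate", {
  cfg0 <- sim_config(n_accessions = 100, n_loci = 30, null_rate = 0, seed = 2)
  expect_identical(sum(is.na(simulate_genotypes(cfg0)$genotypes)), 0L)
  cfg1 <- sim_config(n_accessions = 300, n_loci = 50, null_rate = 0.05, seed = 2)
  rate <- mean(is.na(simulate_genotypes(cfg1)$genotypes))
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(fst = 0, seed = 1), "fst")
  expect_error(sim_config(fst = 1, seed = 1), "fst")
  expect_error(sim_config(alleles_per_locus_range = c(1, 5), seed = 1), ">= 2")
  expect_error(sim_config(null_rate = 0.5, seed = 1), "null_rate")
  expect_error(sim_config(), "seed")
})

test_that("near-zero admixture alpha gives one-hot memberships; rows sum to 1", {
  cfg <- sim_config(n_accessions = 80, n_loci = 10, n_subpops = 3,
                    admixture_alpha = 1e-3, seed = 4)
  q <- simulate_genotypes(cfg)$true_Q
  expect_equal(rowSums(q), rep(1, 80), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_gt(mean(apply(q, 1, max)), 0.99)
})

test_that("noiseless heritability gives identical replicates; flat QTL errors", {
  cfg <- sim_config(n_accessions = 40, n_loci = 10,
                    qtl_spec = list(list(trait = "GL", locus = 1L,
                                         effects = c(top1 = 1))),
                    target_h2 = c(GL = 1), seed = 5)
  sim <- simulate_dataset(cfg)
  ph <- sim$phenotypes
  spread <- tapply(ph$value, paste(ph$accession, ph$year), function(v)
    diff(range(v)))
  expect_equal(max(spread), 0)

  cfg2 <- sim_config(n_accessions = 40, n_loci = 10,
                     qtl_spec = list(list(trait = "GL", locus = 1L,
                                          effects = c(nonexistent = 1))),
                     target_h2 = c(GL = 0.9), seed = 5)
  expect_error(simulate_dataset(cfg2), "Var\\(g\\)")
})

test_that("written dataset round-trips losslessly", {
  ds <- small_qtl_panel(seed = 11, n = 40, n_loci = 8)
  dir <- withr::local_tempdir()
  files <- write_dataset(ds, dir)
  expect_identical(read_genotypes(files[["genotypes"]]), ds$genotypes)
  m <- read_marker_map(files[["map"]])
  expect_equal(m[order(m$locus), ]$cM, ds$map[order(ds$map$locus), ]$cM)
  ph <- read_phenotypes(files[["phenotypes"]])
  expect_equal(ph$value, ds$phenotypes$value, tolerance = 1e-12)
  expect_error(write_dataset(structure(list(), class = "ssr_dataset"), dir),
               "empty")
})

test_that("realized heritability tracks the target at moderate panel size", {
  ds <- small_qtl_panel(seed = 21, n = 300, n_loci = 10, h2 = 0.9)
  vc13 <- anova_variance_components(ds$phenotypes, "GL", 2013)
  expect_gt(vc13$H2, 0.85); expect_lt(vc13$H2, 0.95)
})

test_that("structure-driven traits carry subpopulation signal and no QTL", {
  cfg <- sim_config(n_accessions = 150, n_loci = 12, n_subpops = 3,
                    fst = 0.3, admixture_alpha = 0.1, null_rate = 0,
                    structure_shifts = list(GL = c(0, 1, 2)),
                    target_h2 = c(GL = 0.9), n_years = 1, seed = 6)
  ds <- simulate_dataset(cfg)
  m <- tapply(ds$phenotypes$value, ds$phenotypes$accession, mean)
  lab <- max.col(ds$true_Q)
  grp <- split(as.numeric(m[rownames(ds$true_Q)]), lab)
  # subpopulation means reflect the planted shifts, in order
  expect_true(all(diff(vapply(grp, mean, 0)) > 0))
  # structure_shifts without true_Q is rejected
  expect_error(simulate_phenotypes(ds$genotypes, cfg), "true_Q")
})
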