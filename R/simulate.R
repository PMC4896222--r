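#' Configuration for the synthetic SSR panel generator
#'
#' Builds and validates the parameter set for a simulated structured panel of
#' inbred accessions genotyped at multi-allelic SSR loci. Defaults emulate a
#' rice diversity panel: 628 accessions, 262 loci on 12 chromosomes with 3-25
#' alleles per locus, seven admixed subpopulations, two years x two
#' replicates, broad-sense heritabilities in the high range typical of grain
#' size traits, and a low null-allele (amplification failure) rate.
#'
#' @param n_accessions Number of inbred accessions.
#' @param n_loci Number of SSR loci.
#' @param n_chromosomes Number of chromosomes (rice: 12).
#' @param chrom_length_cM Genetic length of each chromosome, recycled to
#'   `n_chromosomes`.
#' @param alleles_per_locus_range Integer `c(min, max)` allele counts per
#'   locus; min must be >= 2.
#' @param n_subpops Number of ancestral subpopulations (the generating K).
#' @param fst Balding-Nichols drift parameter in (0, 1): subpopulation allele
#'   frequencies are drawn from a Dirichlet centred on the ancestral
#'   frequencies with concentration `(1 - fst) / fst`.
#' @param admixture_alpha Symmetric Dirichlet concentration for per-accession
#'   admixture proportions; small values give near-pure accessions.
#' @param qtl_spec List of QTL: each element a list with fields `trait`,
#'   `locus` (index or id), and `effects`, a named numeric vector mapping
#'   allele label (bp, or `"topN"` for the locus's Nth most frequent allele)
#'   to additive effect in trait units. Alleles of the locus not named get
#'   effect 0, as does the null allele.
#' @param target_h2 Named per-trait broad-sense heritability in (0, 1],
#'   on the accession-mean scale given `n_reps` replicates.
#' @param structure_shifts Optional named list mapping a trait to a numeric
#'   vector of `n_subpops` additive subpopulation effects: the accession's
#'   genetic value gains `sum(Q_i * shifts)`. Used alone it builds a purely
#'   structure-driven trait (a structured null with no QTL).
#' @param trait_base Named per-trait baseline value added to every phenotype
#'   (keeps values positive; defaults to 10 per trait).
#' @param year_effects Numeric vector of additive year shifts (length
#'   `n_years`).
#' @param n_years,n_reps Years and replicates per year.
#' @param null_rate Probability, per genotype cell, that amplification fails
#'   and the null allele is recorded; must lie in [0, 0.2].
#' @param seed Integer seed; all stochastic steps are reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 628L, n_loci = 262L,
                       n_chromosomes = 12L, chrom_length_cM = 150,
                       alleles_per_locus_range = c(3L, 25L),
                       n_subpops = 7L, fst = 0.3, admixture_alpha = 0.2,
                       qtl_spec = list(), structure_shifts = list(),
                       target_h2 = NULL,
                       trait_base = NULL, year_effects = c(0, 0.1),
                       n_years = 2L, n_reps = 2L, null_rate = 0.03,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_loci = as.integer(n_loci),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_cM = rep_len(chrom_length_cM, n_chromosomes),
              alleles_per_locus_range = as.integer(alleles_per_locus_range),
              n_subpops = as.integer(n_subpops), fst = fst,
              admixture_alpha = admixture_alpha, qtl_spec = qtl_spec,
              structure_shifts = structure_shifts,
              target_h2 = target_h2, trait_base = trait_base,
              year_effects = rep_len(year_effects, n_years),
              n_years = as.integer(n_years), n_reps = as.integer(n_reps),
              null_rate = null_rate, seed = as.integer(seed))
  if (cfg$n_accessions < 2L || cfg$n_loci < 1L) stop("degenerate panel size")
  if (cfg$alleles_per_locus_range[1L] < 2L)
    stop("alleles_per_locus_range minimum must be >= 2")
  if (!(fst > 0 && fst < 1)) stop("fst must lie strictly in (0, 1)")
  if (!(null_rate >= 0 && null_rate <= 0.2))
    stop("null_rate must lie in [0, 0.2]")
  if (!is.null(cfg$target_h2) && any(cfg$target_h2 <= 0 | cfg$target_h2 > 1))
    stop("target_h2 must lie in (0, 1]")
  for (q in cfg$qtl_spec) {
    if (!all(c("trait", "locus", "effects") %in% names(q)))
      stop("each qtl_spec entry needs trait, locus, effects")
  }
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- rowSums(x)
  zero <- sw == 0          # all-gamma underflow at tiny alpha: hard-assign
  if (any(zero)) {
    x[zero, ] <- 0
    x[cbind(which(zero), sample.int(k, sum(zero), replace = TRUE))] <- 1
    sw[zero] <- 1
  }
  x / sw
}

#' Simulate structured SSR genotypes
#'
#' Draws, per locus, ancestral allele frequencies from a symmetric Dirichlet;
#' subpopulation frequencies Balding-Nichols style around them with drift
#' `fst`; per-accession admixture proportions from `Dirichlet(alpha)`; and
#' one allele per accession and locus from its personal mixture frequency
#' (inbred haploid coding). Null alleles are overlaid independently with
#' probability `null_rate`. Allele labels are integer fragment sizes spaced
#' 2 bp apart, mimicking an SSR ladder. Map positions are uniform on each
#' chromosome and sorted.
#'
#' @param config A [sim_config()].
#' @return List with elements `genotypes` (integer matrix, NA = null allele),
#'   `map` (locus/chromosome/cM data.frame), `true_Q` (admixture matrix),
#'   `subpop_freqs` and `n_alleles` (generating frequencies, for testing).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions; L <- config$n_loci; K <- config$n_subpops
  acc <- sprintf("ACC%04d", seq_len(n))
  loci <- sprintf("SSR%03d", seq_len(L))

  n_alleles <- sample(seq(config$alleles_per_locus_range[1L],
                          config$alleles_per_locus_range[2L]),
                      L, replace = TRUE)
  true_Q <- rdirichlet(n, rep(config$admixture_alpha, K))
  dimnames(true_Q) <- list(acc, paste0("Q", seq_len(K)))

  drift <- (1 - config$fst) / config$fst
  geno <- matrix(NA_integer_, n, L, dimnames = list(acc, loci))
  subpop_freqs <- vector("list", L)
  for (l in seq_len(L)) {
    A <- n_alleles[l]
    p_anc <- as.vector(rdirichlet(1L, rep(1, A)))
    f <- rdirichlet(K, p_anc * drift)        # K x A subpopulation frequencies
    mix <- true_Q %*% f                      # n x A per-accession frequencies
    u <- stats::runif(n)
    cum <- t(apply(mix, 1L, cumsum))
    idx <- rowSums(u > cum) + 1L
    idx[idx > A] <- A
    sizes <- 80L + 2L * seq_len(A)           # fragment ladder, 2 bp spacing
    geno[, l] <- sizes[idx]
    subpop_freqs[[l]] <- f
  }
  if (config$null_rate > 0)
    geno[stats::runif(n * L) < config$null_rate] <- NA_integer_

  chrom <- sort(rep_len(seq_len(config$n_chromosomes), L))
  pos <- numeric(L)
  for (c in unique(chrom)) {
    i <- which(chrom == c)
    pos[i] <- sort(stats::runif(length(i), 0, config$chrom_length_cM[c]))
  }
  map <- data.frame(locus = loci, chromosome = chrom, cM = round(pos, 2))

  list(genotypes = geno, map = map, true_Q = true_Q,
       subpop_freqs = subpop_freqs, n_alleles = n_alleles)
}

#' Simulate replicated phenotypes from planted QTL
#'
#' Each accession's genetic value is the sum of the allelic effects of the
#' QTL alleles it carries (a null allele contributes 0), plus any
#' structure-driven term from `structure_shifts`. The environmental error
#' variance is set from the realized genetic variance so that
#' `Var(g) / (Var(g) + sigma_e^2 / n_reps)` equals the per-trait target
#' broad-sense heritability on the accession-mean scale. Replicate values are
#' `base + g + year effect + e`.
#'
#' @param genotypes Integer genotype matrix from [simulate_genotypes()].
#' @param config A [sim_config()] with `target_h2` and a non-empty
#'   `qtl_spec` and/or `structure_shifts`.
#' @param true_Q Admixture matrix from [simulate_genotypes()]; required when
#'   `structure_shifts` is non-empty.
#' @return List with `phenotypes` (long data.frame), `genetic_values`
#'   (trait x accession matrix), `sigma_e2` and `realized_h2` per trait.
#' @export
simulate_phenotypes <- function(genotypes, config, true_Q = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$qtl_spec) && !length(config$structure_shifts))
    stop("no trait architecture: qtl_spec and structure_shifts both empty")
  set.seed(config$seed + 1L)
  acc <- rownames(genotypes)
  traits <- unique(c(vapply(config$qtl_spec, `[[`, "", "trait"),
                     names(config$structure_shifts)))
  h2 <- config$target_h2
  if (is.null(h2)) stop("target_h2 required")
  if (is.null(names(h2))) h2 <- stats::setNames(rep_len(h2, length(traits)), traits)
  base <- config$trait_base
  if (is.null(base)) base <- stats::setNames(rep(10, length(traits)), traits)

  g <- matrix(0, length(traits), length(acc), dimnames = list(traits, acc))
  for (q in config$qtl_spec) {
    locus <- if (is.numeric(q$locus)) colnames(genotypes)[q$locus] else q$locus
    if (!locus %in% colnames(genotypes))
      stop("qtl locus not in genotypes: ", locus)
    calls <- genotypes[, locus]
    effects <- q$effects
    ranked <- grepl("^top[0-9]+$", names(effects))
    if (any(ranked)) {
      # "topN" names resolve to the locus's Nth most frequent observed allele
      freq_order <- names(allele_frequencies(genotypes, locus))
      rk <- as.integer(sub("^top", "", names(effects)[ranked]))
      if (any(rk > length(freq_order)))
        stop("locus ", locus, " has only ", length(freq_order), " alleles")
      names(effects)[ranked] <- freq_order[rk]
    }
    eff <- effects[as.character(calls)]
    eff[is.na(eff)] <- 0                     # unlisted alleles and nulls
    g[q$trait, ] <- g[q$trait, ] + eff
  }
  for (tr in names(config$structure_shifts)) {
    if (is.null(true_Q))
      stop("structure_shifts requires the true_Q matrix")
    shifts <- rep_len(config$structure_shifts[[tr]], ncol(true_Q))
    g[tr, ] <- g[tr, ] + as.vector(true_Q[acc, , drop = FALSE] %*% shifts)
  }

  sigma_e2 <- stats::setNames(numeric(length(traits)), traits)
  rows <- vector("list", 0L)
  for (tr in traits) {
    vg <- stats::var(g[tr, ])
    if (vg == 0 && h2[tr] < 1)
      stop("Var(g) is zero for trait ", tr,
           ": give the QTL alleles distinct nonzero effects")
    sigma_e2[tr] <- if (h2[tr] == 1) 0 else
      config$n_reps * vg * (1 - h2[tr]) / h2[tr]
    for (y in seq_len(config$n_years)) {
      for (r in seq_len(config$n_reps)) {
        noise <- if (sigma_e2[tr] == 0) 0 else
          stats::rnorm(length(acc), 0, sqrt(sigma_e2[tr]))
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc, trait = tr, year = 2012L + y, replicate = r,
          value = base[tr] + g[tr, ] + config$year_effects[y] + noise)
      }
    }
  }
  ph <- do.call(rbind, rows)
  rownames(ph) <- NULL
  realized <- vapply(traits, function(tr) {
    vg <- stats::var(g[tr, ])
    vg / (vg + sigma_e2[tr] / config$n_reps)
  }, 0)
  list(phenotypes = ph, genetic_values = g,
       sigma_e2 = sigma_e2, realized_h2 = realized)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotypes()] (when a QTL architecture is configured).
#'
#' @param config A [sim_config()].
#' @return List of class `ssr_dataset`: genotypes, map, phenotypes, true_Q,
#'   true_effects (the qtl_spec), realized_h2, genetic_values, sigma_e2.
#' @export
simulate_dataset <- function(config) {
  gsim <- simulate_genotypes(config)
  out <- list(genotypes = gsim$genotypes, map = gsim$map,
              true_Q = gsim$true_Q, true_effects = config$qtl_spec,
              phenotypes = NULL, realized_h2 = NULL)
  if (length(config$qtl_spec) || length(config$structure_shifts)) {
    psim <- simulate_phenotypes(gsim$genotypes, config, gsim$true_Q)
    out$phenotypes <- psim$phenotypes
    out$realized_h2 <- psim$realized_h2
    out$genetic_values <- psim$genetic_values
    out$sigma_e2 <- psim$sigma_e2
  }
  class(out) <- "ssr_dataset"
  out
}

#' Write a simulated dataset to disk
#'
#' Emits genotypes.tsv, map.tsv, phenotypes.tsv and true_q.tsv in the
#' package's standard dialects; the files round-trip losslessly through the
#' corresponding readers.
#'
#' @param dataset An `ssr_dataset` from [simulate_dataset()].
#' @param out_dir Writable output directory (created if absent).
#' @return Named character vector of the files written.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "ssr_dataset"))
  if (is.null(dataset$genotypes) || nrow(dataset$genotypes) == 0L)
    stop("refusing to write an empty dataset")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(genotypes = file.path(out_dir, "genotypes.tsv"),
             map = file.path(out_dir, "map.tsv"),
             true_q = file.path(out_dir, "true_q.tsv"))
  write_genotypes(dataset$genotypes, files[["genotypes"]])
  write_marker_map(dataset$map, files[["map"]])
  write_q_matrix(dataset$true_Q, files[["true_q"]])
  if (!is.null(dataset$phenotypes)) {
    files <- c(files, phenotypes = file.path(out_dir, "phenotypes.tsv"))
    write_phenotypes(dataset$phenotypes, files[["phenotypes"]])
  }
  files
}
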