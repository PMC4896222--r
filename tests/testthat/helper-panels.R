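# Small panel builders shared across tests.

# genotype matrix from a plain list of per-locus call vectors
geno_matrix <- function(..., accessions = NULL) {
  cols <- list(...)
  n <- length(cols[[1L]])
  if (is.null(accessions)) accessions <- sprintf("acc%02d", seq_len(n))
  m <- do.call(cbind, lapply(cols, as.integer))
  dimnames(m) <- list(accessions, names(cols))
  m
}

# long phenotype table from a named vector of per-accession values,
# replicated over years/reps with no noise
pheno_table <- function(values, trait = "GL", years = 2013L, reps = 1L) {
  rows <- expand.grid(accession = names(values), year = years,
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  data.frame(accession = rows$accession, trait = trait, year = rows$year,
             replicate = rows$replicate,
             value = unname(values[rows$accession]))
}

# structured panel with one planted QTL, used by several recovery tests
small_qtl_panel <- function(seed, n = 150L, n_loci = 15L, h2 = 0.9,
                            effect = 1.2, null_rate = 0.05) {
  cfg <- sim_config(n_accessions = n, n_loci = n_loci, n_subpops = 3L,
                    fst = 0.25, admixture_alpha = 0.1,
                    null_rate = null_rate,
                    qtl_spec = list(list(trait = "GL", locus = "SSR003",
                                         effects = c(top1 = effect))),
                    target_h2 = c(GL = h2), seed = seed)
  simulate_dataset(cfg)
}
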