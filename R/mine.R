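## Allele-effect estimation against the null-allele reference class.
## The null (non-amplified) allele marks accessions that carry none of the
## scorable fragments at a locus; their mean phenotype serves as the
## reference, so the effect of allele i is
##   a_i = mean(phenotype of carriers of i) - mean(phenotype of null class).
## Loci without any null-allele accession fall back to the population mean
## as reference, flagged.

accession_trait_means <- function(phenotypes, trait) {
  ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  if (!nrow(ph)) stop("no phenotype records for trait ", trait)
  tapply(ph$value, ph$accession, mean)  # cross-year, cross-replicate mean
}

#' Phenotypic effect of one allele
#'
#' @param phenotypes Long-format phenotype table.
#' @param genotypes Integer genotype matrix (NA = null allele).
#' @param trait Trait name.
#' @param locus Locus id.
#' @param allele Allele size (bp).
#' @return List of class `allele_effect`: trait, locus, allele, effect,
#'   n_carriers, n_reference, reference ("null-allele" or
#'   "population-mean"), carriers.
#' @export
allele_effect <- function(phenotypes, genotypes, trait, locus, allele) {
  means <- accession_trait_means(phenotypes, trait)
  calls <- genotypes[, locus]
  acc <- intersect(rownames(genotypes), names(means))
  calls <- calls[acc]
  carriers <- acc[!is.na(calls) & calls == allele]
  if (!length(carriers))
    stop("allele ", allele, " not observed at locus ", locus)
  null_acc <- acc[is.na(calls)]
  if (length(null_acc)) {
    ref_mean <- mean(means[null_acc]); ref <- "null-allele"
    n_ref <- length(null_acc)
  } else {
    ref_mean <- mean(means[acc]); ref <- "population-mean"
    n_ref <- length(acc)
  }
  structure(list(trait = trait, locus = locus, allele = allele,
                 effect = mean(means[carriers]) - ref_mean,
                 n_carriers = length(carriers), n_reference = n_ref,
                 reference = ref, carriers = carriers),
            class = "allele_effect")
}

#' Mine elite alleles at association-retained loci
#'
#' For every trait x locus combination in a filtered association table,
#' estimates the effect of every observed allele against the null-allele
#' reference and flags elite alleles. For the grain traits modeled here an
#' allele is elite when its effect is positive (`direction = "increase"`);
#' set `direction = "decrease"` to mine trait-reducing alleles. Alleles with
#' fewer than `min_carriers` carriers are reported but flagged as singletons
#' and never marked elite. The typical carrier is filled by
#' [typical_carriers()].
#'
#' @param assoc_filtered Output of [filter_significant()] (or any data.frame
#'   with trait and locus columns).
#' @param phenotypes Long-format phenotype table.
#' @param genotypes Integer genotype matrix.
#' @param direction Which effect sign counts as elite.
#' @param min_carriers Minimum carrier count for elite status (default 2).
#' @param top_n Size of the top phenotypic ranking for typical carriers.
#' @return data.frame of class `elite_table`: trait, locus, allele, effect,
#'   n_carriers, reference, singleton, elite, typical_carrier,
#'   carrier_in_top_n.
#' @export
mine_elite_alleles <- function(assoc_filtered, phenotypes, genotypes,
                               direction = c("increase", "decrease"),
                               min_carriers = 2L, top_n = 30L) {
  direction <- match.arg(direction)
  combos <- unique(as.data.frame(assoc_filtered)[, c("trait", "locus")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    tr <- combos$trait[i]; loc <- combos$locus[i]
    calls <- genotypes[, loc]
    alleles <- sort(unique(calls[!is.na(calls)]))
    if (!length(alleles)) {
      message("locus ", loc, " has only null calls; skipped")
      next
    }
    for (a in alleles) {
      ae <- allele_effect(phenotypes, genotypes, tr, loc, a)
      singleton <- ae$n_carriers < min_carriers
      elite <- !singleton &&
        if (direction == "increase") ae$effect > 0 else ae$effect < 0
      tc <- typical_carriers(ae, phenotypes, top_n = top_n)
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, locus = loc, allele = a, effect = ae$effect,
        n_carriers = ae$n_carriers, reference = ae$reference,
        singleton = singleton, elite = elite,
        typical_carrier = tc$typical_carrier,
        carrier_in_top_n = tc$in_top_n)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(trait = character(), locus = character(),
               allele = integer(), effect = numeric(),
               n_carriers = integer(), reference = character(),
               singleton = logical(), elite = logical(),
               typical_carrier = character(), carrier_in_top_n = logical())
  class(res) <- c("elite_table", class(res))
  res
}

#' Typical carrier of an allele among top-ranked accessions
#'
#' Intersects the allele's carriers with the `top_n` accessions by
#' cross-year trait mean; the typical carrier is the intersected accession
#' with the highest trait value. When no carrier ranks in the top `top_n`,
#' the highest-phenotype carrier overall is returned with `in_top_n =
#' FALSE`.
#'
#' @param ae An `allele_effect` object.
#' @param phenotypes Long-format phenotype table.
#' @param top_n Number of top-ranked accessions considered (default 30).
#' @return List: typical_carrier, in_top_n, top_carriers (all carriers in
#'   the top ranking).
#' @export
typical_carriers <- function(ae, phenotypes, top_n = 30L) {
  if (top_n < 1L) stop("top_n must be >= 1")
  means <- accession_trait_means(phenotypes, ae$trait)
  top <- names(sort(means, decreasing = TRUE))[seq_len(min(top_n, length(means)))]
  hits <- intersect(ae$carriers, top)
  if (length(hits)) {
    list(typical_carrier = hits[which.max(means[hits])], in_top_n = TRUE,
         top_carriers = hits)
  } else {
    carr <- ae$carriers[ae$carriers %in% names(means)]
    list(typical_carrier = carr[which.max(means[carr])], in_top_n = FALSE,
         top_carriers = character())
  }
}

#' Per-trait elite allele counts
#' @param elite_table Output of [mine_elite_alleles()].
#' @return Named integer vector of elite alleles per trait.
#' @export
elite_counts <- function(elite_table) {
  et <- as.data.frame(elite_table)
  vapply(split(et$elite, et$trait), sum, 0L)
}
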