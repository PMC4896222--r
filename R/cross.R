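## Cross design by elite-allele pyramiding. A line derived from a biparental
## cross of inbreds can fix at most one allele per locus, so at every
## association-retained locus the pooled elite alleles of the two parents
## contribute only the largest-effect one.

#' Pyramidable elite-allele set of a parent pair
#'
#' @param parentA,parentB Accession ids.
#' @param elite_table Output of [mine_elite_alleles()] (rows with
#'   `elite = TRUE` are used).
#' @param genotypes Integer genotype matrix.
#' @param trait Trait name.
#' @return data.frame: locus, allele, effect, source ("A", "B" or "both"),
#'   one row per locus where either parent carries an elite allele.
#' @export
pyramid_set <- function(parentA, parentB, elite_table, genotypes, trait) {
  for (p in c(parentA, parentB))
    if (!p %in% rownames(genotypes))
      stop("parent not genotyped: ", p)
  et <- as.data.frame(elite_table)
  et <- et[et$elite & et$trait == trait, , drop = FALSE]
  out <- list()
  for (loc in unique(et$locus)) {
    rows <- et[et$locus == loc, , drop = FALSE]
    ga <- genotypes[parentA, loc]; gb <- genotypes[parentB, loc]
    carried <- rows[(!is.na(ga) & rows$allele == ga) |
                      (!is.na(gb) & rows$allele == gb), , drop = FALSE]
    if (!nrow(carried)) next
    best <- carried[which.max(carried$effect), , drop = FALSE]
    src <- c("A", "B")[c(!is.na(ga) && ga == best$allele,
                         !is.na(gb) && gb == best$allele)]
    out[[length(out) + 1L]] <- data.frame(
      locus = loc, allele = best$allele, effect = best$effect,
      source = if (length(src) == 2L) "both" else src)
  }
  if (!length(out))
    return(data.frame(locus = character(), allele = integer(),
                      effect = numeric(), source = character()))
  res <- do.call(rbind, out)
  res[order(res$locus), , drop = FALSE]
}

#' Predict one cross
#'
#' @inheritParams pyramid_set
#' @return List of class `cross_plan`: trait, parents (sorted pair),
#'   pyramided (the [pyramid_set()] table), n_elite, predicted_effect (sum
#'   of the pyramided effects, trait units).
#' @export
predict_cross <- function(parentA, parentB, elite_table, genotypes, trait) {
  parents <- sort(c(parentA, parentB))   # canonical order: fully symmetric
  ps <- pyramid_set(parents[1L], parents[2L], elite_table, genotypes, trait)
  structure(list(trait = trait, parents = parents,
                 pyramided = ps, n_elite = nrow(ps),
                 predicted_effect = sum(ps$effect)),
            class = "cross_plan")
}

#' @export
print.cross_plan <- function(x, ...) {
  cat(sprintf("%s x %s (%s): %d elite allele(s), predicted effect %.3g\n",
              x$parents[1L], x$parents[2L], x$trait, x$n_elite,
              x$predicted_effect))
  invisible(x)
}

#' Rank all parental combinations for one trait
#'
#' Scores every unordered accession pair by exhaustive enumeration and ranks
#' by number of pyramidable elite alleles (descending), then predicted
#' effect (descending), then lexicographically by the parent ids.
#'
#' @param accessions Candidate parent ids (default: all genotyped carriers
#'   of at least one elite allele for the trait).
#' @param elite_table Output of [mine_elite_alleles()].
#' @param genotypes Integer genotype matrix.
#' @param trait Trait name.
#' @param top_m Number of top crosses to return.
#' @return data.frame: parentA, parentB, n_elite, predicted_effect, ranked.
#' @export
rank_crosses <- function(accessions = NULL, elite_table, genotypes, trait,
                         top_m = 5L) {
  if (top_m < 1L) stop("top_m must be >= 1")
  et <- as.data.frame(elite_table)
  et <- et[et$elite & et$trait == trait, , drop = FALSE]
  if (is.null(accessions)) {
    carriers <- character()
    for (i in seq_len(nrow(et))) {
      calls <- genotypes[, et$locus[i]]
      carriers <- union(carriers,
                        rownames(genotypes)[!is.na(calls) &
                                              calls == et$allele[i]])
    }
    accessions <- sort(carriers)
  }
  if (length(accessions) < 2L) stop("need at least 2 candidate parents")
  pairs <- utils::combn(sort(accessions), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    cp <- predict_cross(pairs[1L, k], pairs[2L, k], et, genotypes, trait)
    data.frame(parentA = cp$parents[1L], parentB = cp$parents[2L],
               n_elite = cp$n_elite, predicted_effect = cp$predicted_effect)
  })
  res <- do.call(rbind, rows)
  ord <- order(-res$n_elite, -res$predicted_effect, res$parentA, res$parentB)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top_m)
}
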