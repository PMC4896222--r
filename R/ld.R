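## Linkage disequilibrium for multi-allelic SSR pairs in inbred panels.
## Haplotypes need no phasing: each accession contributes its observed
## two-locus allele pair. Accessions with a null allele at either locus are
## dropped pairwise.

dprime_from_indices <- function(ia, ib, A, B) {
  joint <- tabulate(ia + A * (ib - 1L), A * B) / length(ia)
  dim(joint) <- c(A, B)
  p <- rowSums(joint); q <- colSums(joint)
  if (sum(p > 0) < 2L || sum(q > 0) < 2L)
    stop("D' undefined: monomorphic locus in the co-amplified set")
  D <- joint - outer(p, q)
  dmax <- ifelse(D < 0,
                 pmin(outer(p, q), outer(1 - p, 1 - q)),
                 pmin(outer(p, 1 - q), outer(1 - p, q)))
  dp <- abs(D) / dmax
  dp[dmax == 0 | abs(D) < 1e-15] <- 0
  sum(outer(p, q) * dp)
}

ld_pair_indices <- function(genotypes, locusA, locusB) {
  a <- genotypes[, locusA]; b <- genotypes[, locusB]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L)
    stop("fewer than 2 accessions co-amplified at ", locusA, " and ", locusB)
  a <- a[ok]; b <- b[ok]
  ua <- sort(unique(a)); ub <- sort(unique(b))
  list(ia = match(a, ua), ib = match(b, ub),
       A = length(ua), B = length(ub))
}

#' Multi-allelic standardized disequilibrium D'
#'
#' The multi-allelic D' is the allele-frequency-weighted mean of the
#' classical standardized coefficients over all allele pairs:
#' `D' = sum_ij p_i q_j |D'_ij|` with `D_ij = x_ij - p_i q_j` and the usual
#' sign-dependent `D_max`. On a biallelic pair this reduces to the classical
#' |D'|. Haplotype frequencies `x_ij` are the observed two-locus pairs of
#' the inbred accessions.
#'
#' @param genotypes Integer genotype matrix (NA = null allele).
#' @param locusA,locusB Locus ids or column indices.
#' @return D' in [0, 1].
#' @export
pairwise_dprime <- function(genotypes, locusA, locusB) {
  z <- ld_pair_indices(genotypes, locusA, locusB)
  if (z$A < 2L || z$B < 2L)
    stop("D' undefined: monomorphic locus among co-amplified accessions")
  dprime_from_indices(z$ia, z$ib, z$A, z$B)
}

#' Permutation p-value for D'
#'
#' One locus's calls are permuted across accessions `n_perm` times and the
#' p-value is `(#{D'_perm >= D'_obs} + 1) / (n_perm + 1)`.
#'
#' @inheritParams pairwise_dprime
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `dprime` and `p`.
#' @export
permutation_pvalue <- function(genotypes, locusA, locusB, n_perm = 1000L,
                               seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  z <- ld_pair_indices(genotypes, locusA, locusB)
  if (z$A < 2L || z$B < 2L)
    stop("D' undefined: monomorphic locus among co-amplified accessions")
  obs <- dprime_from_indices(z$ia, z$ib, z$A, z$B)
  set.seed(seed)
  m <- length(z$ia)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    dp <- dprime_from_indices(z$ia[sample.int(m)], z$ib, z$A, z$B)
    if (dp >= obs - 1e-12) hits <- hits + 1L
  }
  list(dprime = obs, p = (hits + 1) / (n_perm + 1))
}

#' Genome-wide LD scan per subpopulation
#'
#' Computes D' and a permutation p-value for every locus pair within each
#' subpopulation (hard assignment: argmax of the accession's Q row), plus a
#' per-subpopulation summary of the significant pairs (p < `alpha`): count,
#' ratio (%) of that count to the total significant pairs across
#' subpopulations, a D' histogram in bins 0-0.2, 0.2-0.4, 0.4-0.6, 0.6-0.8,
#' 0.8-1.0, and the mean D'. Subpopulations with fewer than `min_subpop`
#' accessions are skipped with a warning. Monomorphic-within-subpopulation
#' pairs are skipped.
#'
#' @param genotypes Integer genotype matrix.
#' @param map Marker map (locus, chromosome, cM) for syntenic distances.
#' @param Q Q matrix (or a factor/character vector of assignments).
#' @param n_perm Permutations per pair.
#' @param alpha Significance level for "pairs in LD" (unadjusted).
#' @param seed Integer seed.
#' @param min_subpop Minimum subpopulation size (default 10).
#' @return List with `pairs` (data.frame: subpop, locusA, locusB, dprime, p,
#'   syntenic, distance_cM) and `summary` (data.frame per subpopulation).
#' @export
ld_scan <- function(genotypes, map, Q, n_perm = 1000L, alpha = 0.05,
                    seed = 1L, min_subpop = 10L) {
  assign <- if (is.matrix(Q)) {
    factor(colnames(Q)[max.col(Q, ties.method = "first")],
           levels = colnames(Q))
  } else factor(Q)
  stopifnot(length(assign) == nrow(genotypes))
  chrom <- map$chromosome[match(colnames(genotypes), map$locus)]
  pos <- map$cM[match(colnames(genotypes), map$locus)]
  loci <- colnames(genotypes)
  res <- list()
  set.seed(seed)
  for (sp in levels(assign)) {
    rows <- which(assign == sp)
    if (length(rows) < min_subpop) {
      warning("subpopulation ", sp, " has ", length(rows),
              " accessions (< ", min_subpop, "); skipped")
      next
    }
    g <- genotypes[rows, , drop = FALSE]
    for (i in seq_along(loci)[-length(loci)]) {
      for (j in seq((i + 1L), length(loci))) {
        pr <- tryCatch(
          permutation_pvalue(g, loci[i], loci[j], n_perm = n_perm,
                             seed = sample.int(.Machine$integer.max, 1L)),
          error = function(e) NULL)
        if (is.null(pr)) next
        syntenic <- !is.na(chrom[i]) && !is.na(chrom[j]) &&
          chrom[i] == chrom[j]
        res[[length(res) + 1L]] <- data.frame(
          subpop = sp, locusA = loci[i], locusB = loci[j],
          dprime = pr$dprime, p = pr$p, syntenic = syntenic,
          distance_cM = if (syntenic) abs(pos[i] - pos[j]) else NA_real_)
      }
    }
  }
  pairs <- if (length(res)) do.call(rbind, res) else
    data.frame(subpop = character(), locusA = character(),
               locusB = character(), dprime = numeric(), p = numeric(),
               syntenic = logical(), distance_cM = numeric())
  list(pairs = pairs, summary = ld_summary(pairs, alpha = alpha))
}

#' Summarize an LD pair table per subpopulation
#'
#' @param pairs Pair-level table from [ld_scan()].
#' @param alpha Significance level.
#' @return data.frame: subpop, n_pairs_tested, n_significant, ratio_pct,
#'   bin columns, mean_dprime.
#' @export
ld_summary <- function(pairs, alpha = 0.05) {
  bins <- c(0, 0.2, 0.4, 0.6, 0.8, 1.0)
  bin_labels <- paste0("d", c("0.0_0.2", "0.2_0.4", "0.4_0.6",
                              "0.6_0.8", "0.8_1.0"))
  sig <- pairs[pairs$p < alpha, , drop = FALSE]
  total_sig <- nrow(sig)
  sps <- unique(pairs$subpop)
  out <- lapply(sps, function(sp) {
    s <- sig[sig$subpop == sp, , drop = FALSE]
    cut_idx <- findInterval(s$dprime, bins, rightmost.closed = TRUE,
                            all.inside = TRUE)
    counts <- tabulate(cut_idx, 5L)
    df <- data.frame(subpop = sp,
                     n_pairs_tested = sum(pairs$subpop == sp),
                     n_significant = nrow(s),
                     ratio_pct = if (total_sig > 0)
                       round(100 * nrow(s) / total_sig, 1) else NA_real_,
                     mean_dprime = if (nrow(s)) round(mean(s$dprime), 2)
                     else NA_real_)
    df[bin_labels] <- as.list(counts)
    df
  })
  do.call(rbind, out)
}

#' Fit LD decay against log genetic distance
#'
#' Least-squares fit of `D' = b * ln(distance_cM) + c` over syntenic,
#' significant locus pairs.
#'
#' @param pairs Pair-level table from [ld_scan()] (one subpopulation's rows).
#' @param alpha Significance filter on the permutation p-values.
#' @return List of class `ld_decay_fit`: `b`, `c`, `n`, `r_squared`.
#' @export
fit_decay <- function(pairs, alpha = 0.05) {
  use <- pairs[pairs$syntenic & pairs$p < alpha &
                 !is.na(pairs$distance_cM) & pairs$distance_cM > 0, ,
               drop = FALSE]
  if (nrow(use) < 3L)
    stop("need at least 3 syntenic significant pairs with positive distance")
  if (length(unique(use$distance_cM)) < 2L)
    stop("all pair distances are identical; decay slope inestimable")
  fit <- stats::lm(dprime ~ log(distance_cM), data = use)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((use$dprime - mean(use$dprime))^2)
  structure(list(b = unname(stats::coef(fit)[2L]),
                 c = unname(stats::coef(fit)[1L]),
                 n = nrow(use),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("LD decay fit: D' = %.4f ln(cM) + %.4f  (n = %d, R^2 = %.3f)\n",
              x$b, x$c, x$n, x$r_squared))
  invisible(x)
}

#' Distance at which fitted LD decays to a critical D'
#'
#' Inverts the decay fit: `x* = exp((critical - c) / b)`, defined for
#' negative slopes. The conventional critical value is the 95th percentile
#' of the inter-chromosomal (background) D' in the same subpopulation, see
#' [background_critical_dprime()].
#'
#' @param fit An `ld_decay_fit`.
#' @param critical_dprime Critical D' value.
#' @return Decay distance in cM.
#' @export
decay_distance <- function(fit, critical_dprime) {
  if (fit$b >= 0)
    stop("no decay: fitted slope is non-negative")
  x <- exp((critical_dprime - fit$c) / fit$b)
  if (x < 1)
    warning(sprintf(
      "decay distance %.3g cM is below 1 cM map resolution", x))
  x
}

#' Background-critical D' from non-syntenic pairs
#'
#' @param pairs Pair-level table (one subpopulation's rows).
#' @param probs Quantile of the inter-chromosomal D' distribution (default
#'   0.95).
#' @return Critical D' value.
#' @export
background_critical_dprime <- function(pairs, probs = 0.95) {
  bg <- pairs$dprime[!pairs$syntenic]
  if (!length(bg)) stop("no non-syntenic pairs for the background")
  unname(stats::quantile(bg, probs))
}
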