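#' Allele frequencies at one locus
#'
#' Frequencies are computed over amplified alleles only: null alleles are
#' excluded from the denominator (the null class serves as a reference
#' elsewhere, not as a diversity class).
#'
#' @param genotypes Integer genotype matrix (NA = null allele).
#' @param locus Locus id or column index.
#' @return Named numeric vector of frequencies summing to 1, names are allele
#'   sizes (bp), sorted by decreasing frequency then allele.
#' @export
allele_frequencies <- function(genotypes, locus) {
  calls <- genotypes[, locus]
  calls <- calls[!is.na(calls)]
  if (!length(calls))
    stop("locus ", locus, " has no amplified calls")
  tab <- table(calls)
  f <- as.numeric(tab) / sum(tab)
  names(f) <- names(tab)
  f[order(-f, as.integer(names(f)))]
}

#' Gene diversity (expected heterozygosity)
#'
#' `1 - sum(p^2)` over the allele frequencies of a locus.
#'
#' @param freqs Numeric frequency vector summing to 1.
#' @return Gene diversity in [0, 1).
#' @export
gene_diversity <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

#' Polymorphism information content (PIC)
#'
#' Botstein's PIC: `1 - sum(p_i^2) - 2 * sum_{i<j} p_i^2 p_j^2`. Always at
#' most the gene diversity of the same frequencies.
#'
#' @param freqs Numeric frequency vector summing to 1.
#' @return PIC in [0, 1).
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  p2 <- freqs^2
  s2 <- sum(p2)
  # 2 * sum_{i<j} p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p2^2))
}

check_freqs <- function(freqs) {
  if (!is.numeric(freqs) || !length(freqs) || any(freqs < 0) ||
      abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be non-negative and sum to 1")
  invisible(freqs)
}

pic_class <- function(p) {
  ifelse(p > 0.5, "high", ifelse(p > 0.25, "moderate", "slight"))
}

#' Per-locus diversity summary
#'
#' For every locus: number of (amplified) alleles, major allele frequency,
#' gene diversity, PIC, and an informativeness class (high: PIC > 0.5,
#' moderate: 0.25 < PIC <= 0.5, slight: PIC <= 0.25). The panel summary
#' rounds as conventionally printed: mean alleles per locus to 1 decimal,
#' diversity and PIC to 4 decimals.
#'
#' @param genotypes Integer genotype matrix (NA = null allele).
#' @return List with `per_locus` (data.frame) and `summary` (list: n_loci,
#'   total_alleles, mean_alleles_per_locus, mean_gene_diversity, mean_pic,
#'   class_counts).
#' @export
summarize_diversity <- function(genotypes) {
  loci <- colnames(genotypes)
  rows <- lapply(loci, function(l) {
    f <- allele_frequencies(genotypes, l)
    d <- gene_diversity(f)
    p <- pic(f)
    data.frame(locus = l, n_alleles = length(f), major_allele_freq = f[[1L]],
               gene_diversity = d, pic = p,
               informativeness = pic_class(p))
  })
  per_locus <- do.call(rbind, rows)
  cls <- factor(per_locus$informativeness,
                levels = c("high", "moderate", "slight"))
  summary <- list(
    n_loci = nrow(per_locus),
    total_alleles = sum(per_locus$n_alleles),
    mean_alleles_per_locus = round(mean(per_locus$n_alleles), 1),
    mean_gene_diversity = round(mean(per_locus$gene_diversity), 4),
    mean_pic = round(mean(per_locus$pic), 4),
    class_counts = table(cls))
  list(per_locus = per_locus, summary = summary)
}

#' Allele-sharing (Nei) distance between accessions
#'
#' Each inbred accession carries a single scorable allele per locus, so the
#' classical Nei distances between one-individual "populations" all reduce to
#' allele sharing: `d(i, j) = 1 - proportion of loci where i and j carry the
#' same allele`, over loci where both amplified.
#'
#' @param genotypes Integer genotype matrix (NA = null allele).
#' @return Symmetric distance matrix in [0, 1] with zero diagonal.
#' @export
nei_distance <- function(genotypes) {
  n <- nrow(genotypes)
  if (n < 2L) stop("need at least 2 accessions")
  amp <- !is.na(genotypes)
  shared <- matrix(0, n, n)
  both <- matrix(0, n, n)
  for (l in seq_len(ncol(genotypes))) {
    a <- genotypes[, l]
    ok <- amp[, l]
    eq <- outer(a, a, "==")
    eq[!ok, ] <- FALSE; eq[, !ok] <- FALSE
    shared <- shared + eq
    both <- both + outer(ok, ok, "&")
  }
  if (any(both[upper.tri(both)] == 0)) {
    idx <- which(both == 0 & upper.tri(both), arr.ind = TRUE)[1L, ]
    stop("no co-amplified loci for pair ", rownames(genotypes)[idx[1L]],
         " / ", rownames(genotypes)[idx[2L]])
  }
  d <- 1 - shared / both
  diag(d) <- 0
  dimnames(d) <- list(rownames(genotypes), rownames(genotypes))
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix. Ties in the Q criterion
#' are broken by the lowest index pair for determinism. Negative branch
#' lengths are clamped to zero with the deficit moved to the sister edge, so
#' path lengths between leaves are preserved; on additive matrices the input
#' distances are reconstructed exactly.
#'
#' @param dist Symmetric distance matrix with dimnames (or `dist` object).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")

  n_tip <- n
  next_node <- 2L * n_tip - 2L   # internal ids count down from the ape root id
  # active cluster -> node id; tips are 1..n, internals n+1..2n-2 (ape style)
  node_of <- seq_len(n_tip)
  internal_next <- n_tip + 2L    # reserve n_tip+1 for the final join (ape root)
  edges <- matrix(0L, 0L, 2L)
  lengths <- numeric(0)

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lengths <<- c(lengths, len)
  }

  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest-index pair among minima (column-major scan is deterministic)
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- min(best[1L, ]); j <- max(best[1L, ])
    li <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    # clamp, preserving li + lj
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_id <- internal_next; internal_next <- internal_next + 1L
    add_edge(new_id, node_of[i], li)
    add_edge(new_id, node_of[j], lj)
    dn <- 0.5 * (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j])
    dn <- pmax(dn, 0)
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, dn), c(dn, 0))
    node_of <- c(node_of[-c(i, j)], new_id)
  }
  # final star join of the 3 remaining clusters
  v1 <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  v2 <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  v3 <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  v <- c(v1, v2, v3)
  for (k in 1:3) if (v[k] < 0) {
    others <- setdiff(1:3, k)
    v[others] <- v[others] + v[k] / 2  # spread deficit over the two sisters
    v[k] <- 0
  }
  root <- n_tip + 1L
  for (k in 1:3) add_edge(root, node_of[k], v[k])

  tree <- list(edge = edges, edge.length = lengths,
               tip.label = labels, Nnode = n_tip - 2L)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}
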