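#' Admixture-model EM for haploid multi-allelic genotypes
#'
#' Fits the classical admixture likelihood for inbred (haploid-coded) SSR
#' data: each accession i has membership proportions q_i over K clusters,
#' each cluster k has its own allele frequencies f_kl per locus, and the
#' probability of an observed call is `sum_k q_ik f_kl(allele)`. Null alleles
#' carry no information and are skipped. The EM alternates responsibilities
#' with weighted frequency/proportion updates; the log-likelihood is
#' non-decreasing and iteration stops when its change falls below `tol`.
#' This is a deterministic-given-seed surrogate for MCMC-based structure
#' inference with the same Q-matrix contract.
#'
#' @param genotypes Integer genotype matrix (NA = null allele).
#' @param K Number of clusters, >= 1.
#' @param seed Integer seed for the random restart.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @return List of class `admixture_fit`: `Q` (n x K matrix), `freqs` (list
#'   per locus of K x alleles matrices), `loglik`, `loglik_trace`, `K`,
#'   `seed`, `iterations`, `converged`.
#' @export
admixture_em <- function(genotypes, K, seed = 1L, max_iter = 200L,
                         tol = 1e-4) {
  n <- nrow(genotypes); L <- ncol(genotypes)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of accessions")
  # per-locus integer allele indices
  alleles <- lapply(seq_len(L), function(l) {
    a <- sort(unique(genotypes[, l][!is.na(genotypes[, l])]))
    if (!length(a)) stop("locus ", colnames(genotypes)[l],
                         " has no amplified calls")
    a
  })
  gi <- vapply(seq_len(L), function(l)
    match(genotypes[, l], alleles[[l]]), integer(n))   # n x L, NA = null
  set.seed(seed)
  Q <- rdirichlet(n, rep(1, K))
  F_list <- lapply(seq_len(L), function(l) {
    A <- length(alleles[[l]])
    cnt <- tabulate(gi[, l][!is.na(gi[, l])], A)
    pooled <- cnt / sum(cnt)
    f <- matrix(rep(pooled, each = K), K, A) *
      matrix(stats::rexp(K * A) + 0.5, K, A)  # perturbed restart
    f / rowSums(f)
  })
  if (K == 1L) {
    F_list <- lapply(seq_len(L), function(l) {
      A <- length(alleles[[l]])
      cnt <- tabulate(gi[, l][!is.na(gi[, l])], A)
      matrix(cnt / sum(cnt), 1L, A)
    })
    Q <- matrix(1, n, 1L)
  }

  loglik_of <- function(Q, F_list) {
    ll <- 0
    for (l in seq_len(L)) {
      idx <- gi[, l]
      obs <- which(!is.na(idx))
      lik <- rowSums(Q[obs, , drop = FALSE] *
                       t(F_list[[l]][, idx[obs], drop = FALSE]))
      ll <- ll + sum(log(lik))
    }
    ll
  }

  trace <- loglik_of(Q, F_list)
  iter <- 0L; converged <- (K == 1L)
  eps <- 1e-12
  while (iter < max_iter && !converged) {
    iter <- iter + 1L
    q_acc <- matrix(0, n, K)
    n_obs <- numeric(n)
    F_new <- vector("list", L)
    for (l in seq_len(L)) {
      idx <- gi[, l]
      obs <- which(!is.na(idx))
      fk <- t(F_list[[l]][, idx[obs], drop = FALSE])  # |obs| x K
      r <- Q[obs, , drop = FALSE] * fk
      r <- r / rowSums(r)
      q_acc[obs, ] <- q_acc[obs, ] + r
      n_obs[obs] <- n_obs[obs] + 1
      A <- ncol(F_list[[l]])
      fnum <- matrix(eps, K, A)
      for (k in seq_len(K))
        fnum[k, ] <- fnum[k, ] + tabulate_weighted(idx[obs], r[, k], A)
      F_new[[l]] <- fnum / rowSums(fnum)
    }
    Q <- q_acc / pmax(n_obs, 1)
    Q <- Q / rowSums(Q)
    F_list <- F_new
    ll <- loglik_of(Q, F_list)
    converged <- abs(ll - trace[length(trace)]) < tol
    trace <- c(trace, ll)
  }
  if (!converged && K > 1L)
    warning(sprintf(
      "EM stopped after %d iterations; last log-likelihood change %.3g",
      iter, diff(utils::tail(trace, 2L))))
  dimnames(Q) <- list(rownames(genotypes), paste0("Q", seq_len(K)))
  structure(list(Q = Q, freqs = F_list, alleles = alleles,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 K = K, seed = seed, iterations = iter,
                 converged = converged),
            class = "admixture_fit")
}

tabulate_weighted <- function(bin, w, nbins) {
  # rowsum drops empty groups, so scatter its result into a full vector
  out <- numeric(nbins)
  s <- rowsum(w, bin)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture fit: K = %d, n = %d, loglik = %.2f (%d iterations%s)\n",
              x$K, nrow(x$Q), x$loglik, x$iterations,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Fit the admixture model over a range of K with repeated restarts
#'
#' @param genotypes Integer genotype matrix.
#' @param k_range Integer vector of consecutive K values.
#' @param n_runs Restarts per K (different seeds).
#' @param seed Base seed; run r at K uses `seed + 1000*K + r`.
#' @param ... Passed to [admixture_em()].
#' @return Named list mapping K to a list of `admixture_fit` objects.
#' @export
structure_scan <- function(genotypes, k_range = 2:10, n_runs = 5L,
                           seed = 1L, ...) {
  fits <- lapply(k_range, function(K)
    lapply(seq_len(n_runs), function(r)
      admixture_em(genotypes, K, seed = seed + 1000L * K + r, ...)))
  names(fits) <- as.character(k_range)
  fits
}

#' Evanno delta-K model selection
#'
#' `deltaK(K) = mean|L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`, computed from the
#' log-likelihoods of repeated runs at consecutive K. The run standard
#' deviation is floored at 1e-6. The chosen K is the interior argmax; ties go
#' to the smaller K (parsimony). Mean log-likelihoods are also returned so
#' the raw Pr(X|K) comparison can be made alongside.
#'
#' @param fits Named list K -> list of `admixture_fit` (or numeric vector of
#'   per-run log-likelihoods), as from [structure_scan()].
#' @return List with `table` (data.frame K, mean_loglik, sd_loglik, delta_k)
#'   and `chosen_k`.
#' @export
select_k_delta_k <- function(fits) {
  ks <- sort(as.integer(names(fits)))
  if (length(ks) < 3L) stop("need at least 3 consecutive K values")
  if (!all(diff(ks) == 1L))
    stop("K values must be consecutive; missing: ",
         paste(setdiff(seq(min(ks), max(ks)), ks), collapse = ", "))
  ll <- lapply(as.character(ks), function(k) {
    f <- fits[[k]]
    if (is.numeric(f)) f else vapply(f, `[[`, 0, "loglik")
  })
  if (any(vapply(ll, length, 0L) < 2L))
    stop("need at least 2 runs per K for the run standard deviation")
  mean_l <- vapply(ll, mean, 0)
  sd_l <- pmax(vapply(ll, stats::sd, 0), 1e-6)
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1L, length(ks))])
    dk[i] <- abs(mean_l[i + 1L] - 2 * mean_l[i] + mean_l[i - 1L]) / sd_l[i]
  tab <- data.frame(K = ks, mean_loglik = mean_l, sd_loglik = sd_l,
                    delta_k = dk)
  interior <- which(!is.na(dk))
  if (length(interior) > 1L && max(dk[interior]) - min(dk[interior]) < 1e-9)
    warning("flat delta-K profile; chosen K is not well supported")
  chosen <- ks[interior[which.max(dk[interior])]]  # which.max: first = smallest K
  list(table = tab, chosen_k = chosen)
}

#' Allele-sharing kinship with background correction
#'
#' `s_ij` is the proportion of co-amplified loci at which accessions i and j
#' carry the same allele; relatedness is rescaled against the panel
#' background as `k_ij = (s_ij - s_bar) / (1 - s_bar)` with `s_bar` the mean
#' off-diagonal sharing, so an average pair scores 0 and identical accessions
#' score 1. The model copy is clamped at 0 and repaired to positive
#' semidefiniteness by flooring eigenvalues at 0, as required for use as a
#' mixed-model covariance; the raw rescaled values are retained.
#'
#' @param genotypes Integer genotype matrix (NA = null allele).
#' @return List of class `kinship_matrix`: `model` (clamped, PSD, diagonal
#'   1), `raw` (unclamped rescaled), `sharing` (s matrix), `histogram`
#'   (counts of off-diagonal model values in bins <0.05, 0.05-0.10, >0.10).
#' @export
kinship_matrix <- function(genotypes) {
  n <- nrow(genotypes)
  if (n < 2L) stop("need at least 2 accessions")
  s <- 1 - nei_distance(genotypes)   # shares the co-amplification checks
  diag(s) <- 1
  off <- s[upper.tri(s)]
  s_bar <- mean(off)
  raw <- (s - s_bar) / (1 - s_bar)
  diag(raw) <- 1
  model <- pmin(pmax(raw, 0), 1)
  diag(model) <- 1
  e <- eigen(model, symmetric = TRUE)
  if (any(e$values < 0)) {
    v <- pmax(e$values, 0)
    model <- e$vectors %*% (v * t(e$vectors))
    model <- (model + t(model)) / 2
    dimnames(model) <- dimnames(raw)
  }
  k_off <- model[upper.tri(model)]
  histogram <- c("<0.05" = sum(k_off < 0.05),
                 "0.05-0.10" = sum(k_off >= 0.05 & k_off <= 0.10),
                 ">0.10" = sum(k_off > 0.10))
  structure(list(model = model, raw = raw, sharing = s,
                 histogram = histogram),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  n <- nrow(x$model)
  cat(sprintf("kinship matrix for %d accessions; off-diagonal bins:\n", n))
  print(x$histogram)
  invisible(x)
}
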