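## Q+K mixed-linear-model genome scan for multi-allelic markers.
## The polygenic background is a single random effect with covariance
## proportional to the kinship matrix; variance components are estimated
## once on the marker-free (Q-only) null model by REML and reused for every
## marker (P3D), which makes the scan deterministic and fast. Each marker
## enters as an allele-class factor tested by a generalized-least-squares
## F-test.

#' REML variance components for a single-kinship mixed model
#'
#' Estimates `(sigma_g2, sigma_e2)` in `y = X b + u + e`,
#' `u ~ N(0, sigma_g2 K)`, `e ~ N(0, sigma_e2 I)`, by profiling the
#' restricted likelihood over the variance ratio `lambda = sigma_g2 /
#' sigma_e2` on the eigenbasis of K (one-dimensional optimization, EMMA
#' style). Deterministic given its inputs.
#'
#' @param y Numeric response (accession means).
#' @param X Fixed-effect design matrix (must include the intercept and be
#'   full column rank).
#' @param K Symmetric PSD kinship matrix aligned with `y`.
#' @return List: sigma_g2, sigma_e2, lambda, reml_loglik, eigen (the
#'   decomposition, reusable for P3D whitening).
#' @export
reml_variance_components <- function(y, X, K) {
  n <- length(y)
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  p <- ncol(X)
  e <- eigen(K, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yr <- crossprod(e$vectors, y)
  Xr <- crossprod(e$vectors, X)

  neg_reml <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (lam * d + 1)
    fit <- stats::lm.wfit(Xr, yr, w)
    rss <- sum(w * fit$residuals^2)
    sigma_e2 <- rss / (n - p)
    xtwx <- crossprod(Xr, Xr * w)
    0.5 * ((n - p) * log(sigma_e2) + sum(log(lam * d + 1)) +
             determinant(xtwx, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(neg_reml, interval = c(-12, 12))
  lam <- exp(opt$minimum)
  w <- 1 / (lam * d + 1)
  fit <- stats::lm.wfit(Xr, yr, w)
  sigma_e2 <- sum(w * fit$residuals^2) / (n - p)
  list(sigma_g2 = lam * sigma_e2, sigma_e2 = sigma_e2, lambda = lam,
       reml_loglik = -opt$objective, eigen = e)
}

marker_classes <- function(calls, rare_min = 5L) {
  # collapse allele classes with < rare_min carriers into one "rare" class
  f <- factor(calls)
  counts <- table(f)
  rare <- names(counts)[counts < rare_min]
  lv <- levels(f)
  lv[lv %in% rare] <- "rare"
  levels(f) <- lv
  droplevels(f)
}

#' GLS F-test of one marker under the Q+K model
#'
#' Accessions with a null allele at the marker are excluded from the test.
#' Allele classes with fewer than `rare_min` carriers are collapsed into a
#' single "rare" class; markers with fewer than 2 classes afterwards are
#' skipped (NULL is returned). The variance
#' components are taken as given (P3D): the model covariance
#' `sigma_g2 K + sigma_e2 I` is restricted to the tested accessions, the
#' system is whitened by its Cholesky factor, and the marker factor is
#' tested by an F-test against the Q-only null. PVE is the marker's
#' reduction in residual sum of squares over the whitened total sum of
#' squares (about the whitened intercept fit), in percent.
#'
#' @param y Numeric response, one value per accession.
#' @param Q Q matrix (its last column is dropped to avoid collinearity with
#'   the intercept); may be NULL for intercept-only structure.
#' @param K Kinship matrix.
#' @param marker_calls Integer allele calls (NA = null allele).
#' @param vc Variance components from [reml_variance_components()].
#' @param rare_min Minimum carriers per allele class.
#' @return List(p, pve, n_classes, n_used), or NULL when the marker is
#'   skipped (monomorphic after collapsing, collinear with the structure
#'   covariates, or without residual degrees of freedom).
#' @export
mlm_marker_test <- function(y, Q, K, marker_calls, vc, rare_min = 5L) {
  ok <- !is.na(marker_calls)
  cls <- marker_classes(marker_calls[ok], rare_min = rare_min)
  if ("rare" %in% levels(cls) && sum(cls == "rare") < rare_min) {
    # pooled rare class still too small for a stable contrast: exclude it
    ok[ok] <- cls != "rare"
    cls <- droplevels(cls[cls != "rare"])
  }
  if (nlevels(cls) < 2L)
    return(NULL)  # monomorphic after collapsing: nothing to test
  yk <- y[ok]
  n <- length(yk)
  X0 <- cbind(Intercept = rep(1, n))
  if (!is.null(Q) && ncol(Q) > 1L)
    X0 <- cbind(X0, Q[ok, -ncol(Q), drop = FALSE])
  V <- vc$sigma_g2 * K[ok, ok, drop = FALSE] +
    diag(vc$sigma_e2, n)
  Ui <- backsolve(chol(V), diag(n), transpose = TRUE)  # V^{-1/2}
  yw <- Ui %*% yk
  X0w <- Ui %*% X0
  Xm <- stats::model.matrix(~cls)[, -1L, drop = FALSE]
  X1w <- cbind(X0w, Ui %*% Xm)
  rss0 <- sum(qr.resid(qr(X0w), yw)^2)
  q1 <- qr(X1w)
  if (q1$rank < ncol(X1w))
    return(NULL)  # marker collinear with structure covariates
  rss1 <- sum(qr.resid(q1, yw)^2)
  df1 <- ncol(X1w) - ncol(X0w)
  df2 <- n - ncol(X1w)
  if (df2 < 1L) return(NULL)
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  tss <- sum(qr.resid(qr(Ui %*% rep(1, n)), yw)^2)
  pve <- 100 * (rss0 - rss1) / tss
  list(p = pval, pve = pve, n_classes = nlevels(cls), n_used = n)
}

#' Q+K genome scan over all traits, years and loci
#'
#' Per-accession means over replicates are formed per trait and year; the
#' REML variance components of the Q-only model are estimated once per
#' trait-year and reused across markers (P3D). Accession sets of phenotypes,
#' genotypes, Q and K are inner-joined.
#'
#' @param phenotypes Long-format phenotype table.
#' @param genotypes Integer genotype matrix.
#' @param map Marker map.
#' @param Q Q matrix (rownames = accessions) or NULL.
#' @param K Kinship matrix (`kinship_matrix()` output or plain matrix).
#' @param rare_min Minimum carriers per allele class.
#' @return data.frame of class `association_scan`: trait, year, locus,
#'   chromosome, position_cM, p, pve, n_classes, sorted by trait,
#'   chromosome, position.
#' @export
genome_scan <- function(phenotypes, genotypes, map, Q, K, rare_min = 5L) {
  Km <- if (inherits(K, "kinship_matrix")) K$model else K
  acc <- Reduce(intersect, list(unique(phenotypes$accession),
                                rownames(genotypes), rownames(Km),
                                if (is.null(Q)) rownames(genotypes)
                                else rownames(Q)))
  if (length(acc) < 10L) stop("fewer than 10 accessions shared across inputs")
  geno <- genotypes[acc, , drop = FALSE]
  Km <- Km[acc, acc]
  Qm <- if (is.null(Q)) NULL else Q[acc, , drop = FALSE]
  chrom <- map$chromosome[match(colnames(geno), map$locus)]
  pos <- map$cM[match(colnames(geno), map$locus)]

  out <- list()
  for (tr in unique(phenotypes$trait)) {
    for (yr in sort(unique(phenotypes$year[phenotypes$trait == tr]))) {
      ph <- phenotypes[phenotypes$trait == tr & phenotypes$year == yr, ]
      means <- tapply(ph$value, ph$accession, mean)
      if (!all(acc %in% names(means))) {
        missing_acc <- setdiff(acc, names(means))
        message("trait ", tr, " year ", yr, ": ", length(missing_acc),
                " accession(s) without phenotype dropped")
      }
      use <- intersect(acc, names(means))
      y <- as.numeric(means[use])
      Ku <- Km[use, use]
      Qu <- if (is.null(Qm)) NULL else Qm[use, , drop = FALSE]
      X0 <- cbind(Intercept = rep(1, length(y)))
      if (!is.null(Qu) && ncol(Qu) > 1L)
        X0 <- cbind(X0, Qu[, -ncol(Qu), drop = FALSE])
      vc <- reml_variance_components(y, X0, Ku)
      gsub <- geno[use, , drop = FALSE]
      for (j in seq_len(ncol(gsub))) {
        res <- mlm_marker_test(y, Qu, Ku, gsub[, j], vc,
                               rare_min = rare_min)
        if (is.null(res)) next
        out[[length(out) + 1L]] <- data.frame(
          trait = tr, year = yr, locus = colnames(gsub)[j],
          chromosome = chrom[j], position_cM = pos[j],
          p = res$p, pve = res$pve, n_classes = res$n_classes)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$trait, res$chromosome, res$position_cM, res$year), ]
  rownames(res) <- NULL
  class(res) <- c("association_scan", class(res))
  res
}

#' Filter a genome scan to significant, well-explained loci
#'
#' Default rule: a row is retained if its locus is significant
#' (`p < p_max`, strict) in every scanned year for that trait and the row's
#' own PVE exceeds `pve_min` (`both_years = TRUE`); with
#' `both_years = FALSE` rows are filtered year by year on both criteria.
#'
#' @param results Scan table from [genome_scan()].
#' @param p_max Significance threshold (strict inequality), default 0.05.
#' @param pve_min Minimum percent variance explained, default 5.
#' @param both_years Require significance in all years jointly.
#' @return Filtered rows of `results`.
#' @export
filter_significant <- function(results, p_max = 0.05, pve_min = 5.0,
                               both_years = TRUE) {
  res <- as.data.frame(results)
  if (!nrow(res)) return(res)
  if (both_years) {
    keep <- rep(FALSE, nrow(res))
    key <- paste(res$trait, res$locus)
    for (k in unique(key)) {
      rows <- which(key == k)
      n_years <- length(unique(res$year[res$trait == res$trait[rows[1L]]]))
      if (length(rows) == n_years && all(res$p[rows] < p_max))
        keep[rows] <- res$pve[rows] > pve_min
    }
    out <- res[keep, , drop = FALSE]
  } else {
    out <- res[res$p < p_max & res$pve > pve_min, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
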