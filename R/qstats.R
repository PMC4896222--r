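#' Per-trait, per-year phenotype descriptives
#'
#' Accession means over replicates are formed per trait and year, then
#' summarized: mean, sample SD (n-1), range, CV% (= SD/mean * 100),
#' SAS-style adjusted skewness and excess kurtosis (type 2 of
#' [e1071::skewness()]/[e1071::kurtosis()], matching common field-trial
#' software). Kurtosis and skewness are reported as NA when too few
#' accessions make them undefined (or the trait is constant) and `moments_ok`
#' is set FALSE.
#'
#' @param phenotypes Long-format phenotype table.
#' @return data.frame: trait, year, n, mean, sd, min, max, cv_pct, kurtosis,
#'   skewness, moments_ok.
#' @export
trait_descriptives <- function(phenotypes) {
  ph <- validate_phenotypes(phenotypes)
  means <- stats::aggregate(value ~ accession + trait + year, ph, mean)
  out <- list()
  for (tr in unique(means$trait)) for (yr in sort(unique(means$year))) {
    v <- means$value[means$trait == tr & means$year == yr]
    if (!length(v)) next
    m <- mean(v); s <- stats::sd(v)
    ok <- length(v) >= 4L && s > 0
    out[[length(out) + 1L]] <- data.frame(
      trait = tr, year = yr, n = length(v), mean = m,
      sd = if (length(v) > 1L) s else 0,
      min = min(v), max = max(v),
      cv_pct = if (m != 0) 100 * (if (length(v) > 1L) s else 0) / m
      else NA_real_,
      kurtosis = if (ok) e1071::kurtosis(v, type = 2L) else NA_real_,
      skewness = if (ok) e1071::skewness(v, type = 2L) else NA_real_,
      moments_ok = ok)
  }
  do.call(rbind, out)
}

#' One-way ANOVA variance components within a year
#'
#' Replicate-level values of one trait in one year are decomposed by a
#' one-way genotype ANOVA: the error variance is the within-genotype mean
#' square and the genetic variance is `(MSG - MSE) / n_bar`, with `n_bar`
#' the harmonic mean number of replicates per accession. Negative genetic
#' variance estimates are truncated at 0 and flagged.
#'
#' @param phenotypes Long-format phenotype table.
#' @param trait Trait name.
#' @param year Year.
#' @return List of class `variance_components`: trait, year, sigma_g2,
#'   sigma_e2, n_reps (harmonic mean), ms_genotype, ms_error, truncated, H2.
#' @export
anova_variance_components <- function(phenotypes, trait, year) {
  ph <- phenotypes[phenotypes$trait == trait & phenotypes$year == year, ,
                   drop = FALSE]
  if (!nrow(ph)) stop("no records for trait ", trait, " in year ", year)
  reps <- table(ph$accession)
  if (length(reps) < 2L) stop("need at least 2 accessions")
  if (all(reps < 2L)) stop("single replicate everywhere: error variance inestimable")
  n_bar <- length(reps) / sum(1 / as.numeric(reps))
  fit <- stats::aov(value ~ accession, data = ph)
  tab <- summary(fit)[[1L]]
  msg <- tab["accession", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (is.na(mse)) mse <- 0  # identical replicates everywhere
  sigma_g2 <- (msg - mse) / n_bar
  truncated <- sigma_g2 < 0
  if (truncated) sigma_g2 <- 0
  vc <- list(trait = trait, year = year, sigma_g2 = sigma_g2,
             sigma_e2 = mse, n_reps = n_bar, ms_genotype = msg,
             ms_error = mse, truncated = truncated)
  vc$H2 <- if (sigma_g2 == 0 && mse == 0) NA_real_ else
    broad_sense_heritability(vc)
  class(vc) <- "variance_components"
  vc
}

#' Broad-sense heritability of line means
#'
#' `H2 = sigma_g^2 / (sigma_g^2 + sigma_e^2 / n)` with `n` the number of
#' replicates, i.e. the genotypic share of the variance of accession means.
#'
#' @param vc A `variance_components` object, or a list with fields
#'   `sigma_g2`, `sigma_e2`, `n_reps`.
#' @param as_percent Return as percent rounded to 2 decimals (the
#'   conventional printout) instead of a proportion.
#' @return Heritability in [0, 1] (or percent).
#' @export
broad_sense_heritability <- function(vc, as_percent = FALSE) {
  if (vc$sigma_g2 < 0 || vc$sigma_e2 < 0)
    stop("variance components must be non-negative")
  if (vc$sigma_g2 == 0 && vc$sigma_e2 == 0)
    stop("both variance components are zero: heritability undefined")
  h2 <- vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2 / vc$n_reps)
  if (as_percent) round(100 * h2, 2) else h2
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "%s (%s): sigma_g2 = %.4g, sigma_e2 = %.4g, n = %.3g, H2 = %s%s\n",
    x$trait, x$year, x$sigma_g2, x$sigma_e2, x$n_reps,
    if (is.na(x$H2)) "undefined" else sprintf("%.2f%%", 100 * x$H2),
    if (x$truncated) " [sigma_g2 truncated at 0]" else ""))
  invisible(x)
}

#' Pairwise trait correlations with significance stars
#'
#' Pearson correlations among per-accession trait means, per year, with
#' two-sided t-test p-values and stars at 0.05 (*) and 0.01 (**). Constant
#' traits yield NA correlations and are flagged.
#'
#' @param phenotypes Long-format phenotype table.
#' @return Named list per year, each with matrices `r`, `p`, `stars`.
#' @export
trait_correlations <- function(phenotypes) {
  ph <- validate_phenotypes(phenotypes)
  means <- stats::aggregate(value ~ accession + trait + year, ph, mean)
  out <- list()
  for (yr in sort(unique(means$year))) {
    w <- stats::reshape(means[means$year == yr, c("accession", "trait", "value")],
                        idvar = "accession", timevar = "trait",
                        direction = "wide")
    traits <- sub("^value\\.", "", names(w)[-1L])
    m <- as.matrix(w[, -1L, drop = FALSE])
    colnames(m) <- traits
    if (nrow(m) < 3L) stop("need at least 3 accessions for correlations")
    k <- ncol(m)
    r <- diag(1, k); p <- matrix(NA_real_, k, k)
    dimnames(r) <- dimnames(p) <- list(traits, traits)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) {
        r[i, j] <- NA_real_
        next
      }
      ct <- stats::cor.test(m[, i], m[, j])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
    stars <- matrix("", k, k, dimnames = dimnames(r))
    stars[!is.na(p) & p < 0.05] <- "*"
    stars[!is.na(p) & p < 0.01] <- "**"
    out[[as.character(yr)]] <- list(r = r, p = p, stars = stars)
  }
  out
}

#' Full descriptive + heritability report
#'
#' Runs [trait_descriptives()] and per trait-year
#' [anova_variance_components()], returning one table shaped like a
#' field-trial summary: mean, SD, range, CV, kurtosis, skewness and H2 (%).
#'
#' @param phenotypes Long-format phenotype table.
#' @return data.frame keyed by trait and year.
#' @export
phenotype_report <- function(phenotypes) {
  desc <- trait_descriptives(phenotypes)
  desc$H2_pct <- NA_real_
  for (i in seq_len(nrow(desc))) {
    vc <- tryCatch(
      anova_variance_components(phenotypes, desc$trait[i], desc$year[i]),
      error = function(e) NULL)
    if (!is.null(vc) && !is.na(vc$H2))
      desc$H2_pct[i] <- round(100 * vc$H2, 2)
  }
  desc
}
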