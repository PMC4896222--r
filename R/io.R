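#' @importFrom utils read.delim write.table head
NULL

# All tabular artifacts are tab-delimited, "." decimal, no locale handling.
# The null (non-amplified) allele is the literal token "NA" on disk and
# NA_integer_ in memory; it is a genotype class of its own, never a missing row.

#' Read an SSR genotype matrix
#'
#' Parses a tab-delimited genotype table: header row of locus ids, first
#' column `accession`, each cell an amplified fragment size in base pairs
#' (positive integer) or the token `NA` for a null (non-amplified) allele.
#' Accessions are inbred lines, so one allele is scored per locus.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix (accessions x loci) with `NA` marking null alleles;
#'   rownames are accession ids, colnames are locus ids.
#' @export
read_genotypes <- function(path) {
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = NULL)
  if (ncol(raw) < 2L)
    stop("genotype file needs an accession column plus at least one locus")
  acc <- raw[[1L]]
  loci <- colnames(raw)[-1L]
  if (anyDuplicated(acc))
    stop("duplicate accession id(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  if (anyDuplicated(loci))
    stop("duplicate locus id(s): ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  m <- matrix(NA_integer_, nrow = length(acc), ncol = length(loci),
              dimnames = list(acc, loci))
  for (j in seq_along(loci)) {
    cells <- raw[[j + 1L]]
    is_null <- cells == "NA"
    ok <- is_null | grepl("^[0-9]+$", cells)
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop(sprintf("non-integer genotype cell '%s' at row %d (accession %s), locus %s",
                   cells[bad], bad, acc[bad], loci[j]))
    }
    vals <- suppressWarnings(as.integer(cells))
    vals[is_null] <- NA_integer_
    if (any(vals[!is_null] <= 0L))
      stop("non-positive allele size at locus ", loci[j])
    m[, j] <- vals
  }
  validate_genotypes(m)
  m
}

#' Write an SSR genotype matrix
#'
#' @param genotypes Integer matrix as returned by [read_genotypes()].
#' @param path Output path.
#' @export
write_genotypes <- function(genotypes, path) {
  validate_genotypes(genotypes)
  df <- data.frame(accession = rownames(genotypes),
                   genotypes, check.names = FALSE)
  write_tsv(df, path)
}

validate_genotypes <- function(genotypes) {
  if (!is.matrix(genotypes) || !is.numeric(genotypes))
    stop("genotypes must be a numeric matrix")
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop("genotypes must carry accession rownames and locus colnames")
  if (anyDuplicated(rownames(genotypes)))
    stop("duplicate accession ids in genotype matrix")
  if (anyDuplicated(colnames(genotypes)))
    stop("duplicate locus ids in genotype matrix")
  if (any(genotypes <= 0, na.rm = TRUE))
    stop("allele sizes must be positive")
  invisible(genotypes)
}

#' Read a marker map
#'
#' Columns `locus`, `chromosome` (1-12), `cM` (non-negative absolute position
#' on the chromosome). Returned sorted by chromosome then position.
#'
#' @param path Path to the TSV file.
#' @param genotypes Optional genotype matrix to cross-check locus coverage.
#' @param n_chromosomes Number of chromosomes accepted (default 12 for rice).
#' @return data.frame with columns locus, chromosome, cM.
#' @export
read_marker_map <- function(path, genotypes = NULL, n_chromosomes = 12L) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = c("character", "integer", "numeric"))
  names(df) <- c("locus", "chromosome", "cM")
  validate_marker_map(df, genotypes = genotypes, n_chromosomes = n_chromosomes)
}

validate_marker_map <- function(map, genotypes = NULL, n_chromosomes = 12L) {
  if (anyDuplicated(map$locus))
    stop("duplicate locus id(s) in map: ",
         paste(unique(map$locus[duplicated(map$locus)]), collapse = ", "))
  if (any(is.na(map$chromosome)) ||
      any(map$chromosome < 1L | map$chromosome > n_chromosomes))
    stop("chromosome outside 1-", n_chromosomes)
  if (any(is.na(map$cM)) || any(map$cM < 0))
    stop("negative or missing cM position")
  if (!is.null(genotypes)) {
    missing_loci <- setdiff(colnames(genotypes), map$locus)
    if (length(missing_loci))
      stop("genotyped loci absent from map: ",
           paste(missing_loci, collapse = ", "))
    extra <- setdiff(map$locus, colnames(genotypes))
    if (length(extra))
      warning("map loci not in genotypes: ", paste(extra, collapse = ", "))
  }
  map <- map[order(map$chromosome, map$cM), , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' Write a marker map
#' @param map data.frame with columns locus, chromosome, cM.
#' @param path Output path.
#' @export
write_marker_map <- function(map, path) {
  write_tsv(map[, c("locus", "chromosome", "cM")], path)
}

#' Read a phenotype table
#'
#' Long format with columns `accession`, `trait`, `year`, `replicate`,
#' `value`. Values must be positive (grain dimensions in mm, ratios,
#' thousand-grain weight in g); the key (accession, trait, year, replicate)
#' must be unique.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the five columns above.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = c("character", "character", "integer",
                                  "integer", "character"))
  names(df) <- c("accession", "trait", "year", "replicate", "value")
  bad <- !grepl("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", df$value)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("non-numeric phenotype value '%s' at row %d (accession %s, trait %s)",
                 df$value[i], i, df$accession[i], df$trait[i]))
  }
  df$value <- as.numeric(df$value)
  validate_phenotypes(df)
}

validate_phenotypes <- function(phenotypes) {
  need <- c("accession", "trait", "year", "replicate", "value")
  if (!all(need %in% names(phenotypes)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  if (any(phenotypes$value <= 0))
    stop("non-positive phenotype value at row ",
         which(phenotypes$value <= 0)[1L])
  key <- with(phenotypes, paste(accession, trait, year, replicate, sep = "\r"))
  if (anyDuplicated(key)) {
    d <- phenotypes[which(duplicated(key))[1L], ]
    stop(sprintf("duplicate phenotype record: accession %s, trait %s, year %s, replicate %s",
                 d$accession, d$trait, d$year, d$replicate))
  }
  rownames(phenotypes) <- NULL
  phenotypes
}

#' Write a phenotype table
#' @param phenotypes Long-format phenotype data.frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write_tsv(validate_phenotypes(phenotypes), path)
}

#' Read / write a Q (admixture proportion) matrix
#'
#' TSV with first column `accession` and one column per cluster; each row
#' sums to 1.
#'
#' @param path File path.
#' @return Numeric matrix with accession rownames.
#' @export
read_q_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  q <- as.matrix(df[, -1L, drop = FALSE])
  rownames(q) <- df[[1L]]
  if (any(q < 0 | q > 1) || any(abs(rowSums(q) - 1) > 1e-6))
    stop("Q matrix rows must be membership proportions summing to 1")
  q
}

#' @rdname read_q_matrix
#' @param q Q matrix (accessions x clusters).
#' @export
write_q_matrix <- function(q, path) {
  df <- data.frame(accession = rownames(q), q, check.names = FALSE)
  write_tsv(df, path)
}

#' Read / write a square named matrix (kinship, distance)
#' @param path File path.
#' @return Symmetric numeric matrix with matching dimnames.
#' @export
read_square_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("expected a square matrix with identical row and column ids")
  m
}

#' @rdname read_square_matrix
#' @param m Square matrix with dimnames.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' Write a phylogenetic tree to newick
#'
#' @param tree An [ape::phylo] tree with branch lengths and named leaves.
#' @param path Output path; the file is `;`-terminated standard newick.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (length(tree$tip.label) < 2L)
    stop("refusing to write a tree with fewer than 2 leaves")
  if (any(is.na(tree$tip.label)) || any(tree$tip.label == ""))
    stop("every leaf must be named")
  ape::write.tree(tree, file = path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
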