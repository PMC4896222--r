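## One-config orchestration of the full analysis:
## simulate -> diversity -> tree -> structure -> kinship -> ld -> qstats ->
## assoc -> mine -> cross. Each stage writes TSV artifacts into out_dir and
## is skipped on rerun when its outputs exist and its input hashes are
## unchanged (recorded in manifest.json).

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Integer seed propagated to every stochastic stage.
#' @param simulate Simulation parameters (passed to [sim_config()]); set to
#'   NULL and provide `genotypes`/`map`/`phenotypes` paths to analyse an
#'   existing dataset.
#' @param k_range,n_runs Structure-scan K range and restarts per K.
#' @param em_max_iter,em_tol EM iteration cap and convergence tolerance.
#' @param n_perm LD permutations per pair.
#' @param p_max,pve_min,both_years Association filter settings.
#' @param top_n Top-ranked accessions for typical carriers.
#' @param min_carriers Minimum carriers for elite status.
#' @param top_m Crosses reported per trait.
#' @param stages Character vector of stages to run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, simulate = list(),
                            k_range = 2:6, n_runs = 3L,
                            em_max_iter = 200L, em_tol = 1e-4,
                            n_perm = 200L, p_max = 0.05, pve_min = 5.0,
                            both_years = TRUE, top_n = 30L,
                            min_carriers = 2L, top_m = 5L,
                            stages = c("simulate", "diversity", "tree",
                                       "structure", "kinship", "ld",
                                       "qstats", "assoc", "mine", "cross")) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              simulate = simulate, k_range = k_range, n_runs = n_runs,
              em_max_iter = em_max_iter, em_tol = em_tol, n_perm = n_perm,
              p_max = p_max, pve_min = pve_min, both_years = both_years,
              top_n = top_n, min_carriers = min_carriers, top_m = top_m,
              stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @param ... Overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  dots <- list(...)
  raw[names(dots)] <- dots
  if (!is.null(raw$k_range) && length(raw$k_range) == 2L)
    raw$k_range <- seq(raw$k_range[1L], raw$k_range[2L])
  do.call(pipeline_config, raw)
}

stage_log <- function(stage, msg) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), "[", stage, "] ", msg)
}

#' Run the full pipeline
#'
#' Stages run in dependency order; a stage is skipped when all its output
#' files already exist and the recorded hashes of its inputs are unchanged.
#' Two runs with the same config and seed produce byte-identical TSVs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest: per stage, its output files with MD5 hashes and the
#'   hashes of the inputs it consumed. Also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  od <- config$out_dir
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(od, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  cfg_hash <- digest_object(config[setdiff(names(config), "out_dir")])

  path <- function(...) file.path(od, ...)
  md5 <- function(files) {
    h <- tools::md5sum(files)
    stats::setNames(as.vector(h), basename(files))
  }
  fresh <- function(stage, inputs, outputs) {
    rec <- manifest[[stage]]
    if (is.null(rec)) return(FALSE)
    if (!all(file.exists(outputs))) return(FALSE)
    if (!identical(rec$config_hash, cfg_hash)) return(FALSE)
    # inputs-only check: a corrupted output does not rerun its own stage,
    # only the stages downstream of it (which see a changed input hash)
    identical(as.list(rec$input_md5), as.list(md5(inputs)))
  }
  record <- function(stage, inputs, outputs) {
    manifest[[stage]] <<- list(stage = stage, seed = config$seed,
                               config_hash = cfg_hash,
                               input_md5 = as.list(md5(inputs)),
                               output_md5 = as.list(md5(outputs)))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  run_stage <- function(stage, inputs, outputs, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    if (fresh(stage, inputs, outputs)) {
      stage_log(stage, "up to date; skipped")
      return(invisible(NULL))
    }
    stage_log(stage, "running")
    tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    record(stage, inputs, outputs)
    stage_log(stage, "done")
  }

  geno_f <- path("genotypes.tsv"); map_f <- path("map.tsv")
  pheno_f <- path("phenotypes.tsv"); trueq_f <- path("true_q.tsv")

  run_stage("simulate", character(),
            c(geno_f, map_f, pheno_f, trueq_f), function() {
    sc <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    ds <- simulate_dataset(sc)
    write_dataset(ds, od)
  })

  geno <- read_genotypes(geno_f)
  map <- read_marker_map(map_f, genotypes = geno)
  pheno <- if (file.exists(pheno_f)) read_phenotypes(pheno_f) else NULL

  run_stage("diversity", c(geno_f),
            c(path("diversity_per_locus.tsv"), path("diversity_summary.tsv")),
            function() {
    div <- summarize_diversity(geno)
    write_tsv(div$per_locus, path("diversity_per_locus.tsv"))
    s <- div$summary
    write_tsv(data.frame(statistic = c("n_loci", "total_alleles",
                                       "mean_alleles_per_locus",
                                       "mean_gene_diversity", "mean_pic",
                                       paste0("n_", names(s$class_counts))),
                         value = c(s$n_loci, s$total_alleles,
                                   s$mean_alleles_per_locus,
                                   s$mean_gene_diversity, s$mean_pic,
                                   as.integer(s$class_counts))),
              path("diversity_summary.tsv"))
  })

  run_stage("tree", c(geno_f), path("nj_tree.nwk"), function() {
    d <- nei_distance(geno)
    write_newick(neighbor_joining(d), path("nj_tree.nwk"))
  })

  run_stage("structure", c(geno_f),
            c(path("q_matrix.tsv"), path("delta_k.tsv")), function() {
    fits <- structure_scan(geno, k_range = config$k_range,
                           n_runs = config$n_runs, seed = config$seed,
                           max_iter = config$em_max_iter,
                           tol = config$em_tol)
    sel <- select_k_delta_k(fits)
    best <- fits[[as.character(sel$chosen_k)]]
    best <- best[[which.max(vapply(best, `[[`, 0, "loglik"))]]
    write_q_matrix(best$Q, path("q_matrix.tsv"))
    tab <- sel$table
    tab$chosen <- tab$K == sel$chosen_k
    write_tsv(tab, path("delta_k.tsv"))
  })

  run_stage("kinship", c(geno_f),
            c(path("kinship.tsv"), path("kinship_histogram.tsv")),
            function() {
    kin <- kinship_matrix(geno)
    write_square_matrix(round(kin$model, 6), path("kinship.tsv"))
    write_tsv(data.frame(bin = names(kin$histogram),
                         count = as.integer(kin$histogram)),
              path("kinship_histogram.tsv"))
  })

  run_stage("ld", c(geno_f, map_f, path("q_matrix.tsv")),
            c(path("ld_pairs.tsv"), path("ld_summary.tsv"),
              path("ld_decay.tsv")), function() {
    q <- read_q_matrix(path("q_matrix.tsv"))
    scan <- ld_scan(geno, map, q, n_perm = config$n_perm,
                    seed = config$seed)
    write_tsv(scan$pairs, path("ld_pairs.tsv"))
    write_tsv(scan$summary, path("ld_summary.tsv"))
    decays <- list()
    for (sp in unique(scan$pairs$subpop)) {
      rows <- scan$pairs[scan$pairs$subpop == sp, , drop = FALSE]
      fit <- tryCatch(fit_decay(rows), error = function(e) NULL)
      if (is.null(fit)) next
      crit <- tryCatch(background_critical_dprime(rows),
                       error = function(e) NA_real_)
      dd <- if (!is.na(crit) && fit$b < 0)
        suppressWarnings(decay_distance(fit, crit)) else NA_real_
      decays[[length(decays) + 1L]] <- data.frame(
        subpop = sp, b = fit$b, c = fit$c, n = fit$n,
        critical_dprime = crit, decay_cM = dd)
    }
    write_tsv(if (length(decays)) do.call(rbind, decays) else
      data.frame(subpop = character(), b = numeric(), c = numeric(),
                 n = integer(), critical_dprime = numeric(),
                 decay_cM = numeric()),
      path("ld_decay.tsv"))
  })

  if (!is.null(pheno)) {
    run_stage("qstats", c(pheno_f),
              c(path("phenotype_report.tsv"), path("correlations.tsv")),
              function() {
      write_tsv(phenotype_report(pheno), path("phenotype_report.tsv"))
      cors <- trait_correlations(pheno)
      rows <- list()
      for (yr in names(cors)) {
        r <- cors[[yr]]$r; st <- cors[[yr]]$stars
        for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r)))
          if (i < j)
            rows[[length(rows) + 1L]] <- data.frame(
              year = yr, traitA = rownames(r)[i], traitB = colnames(r)[j],
              r = round(r[i, j], 3), stars = st[i, j])
      }
      write_tsv(do.call(rbind, rows), path("correlations.tsv"))
    })

    run_stage("assoc", c(geno_f, map_f, pheno_f, path("q_matrix.tsv"),
                         path("kinship.tsv")),
              c(path("associations.tsv"), path("associations_filtered.tsv")),
              function() {
      q <- read_q_matrix(path("q_matrix.tsv"))
      kin <- read_square_matrix(path("kinship.tsv"))
      scan <- genome_scan(pheno, geno, map, q, kin)
      write_tsv(as.data.frame(scan), path("associations.tsv"))
      write_tsv(filter_significant(scan, p_max = config$p_max,
                                   pve_min = config$pve_min,
                                   both_years = config$both_years),
                path("associations_filtered.tsv"))
    })

    run_stage("mine", c(geno_f, pheno_f, path("associations_filtered.tsv")),
              path("elite_alleles.tsv"), function() {
      filt <- read.delim(path("associations_filtered.tsv"))
      et <- mine_elite_alleles(filt, pheno, geno,
                               min_carriers = config$min_carriers,
                               top_n = config$top_n)
      write_tsv(as.data.frame(et), path("elite_alleles.tsv"))
    })

    run_stage("cross", c(geno_f, path("elite_alleles.tsv")),
              path("crosses.tsv"), function() {
      et <- read.delim(path("elite_alleles.tsv"))
      rows <- list()
      for (tr in unique(et$trait[et$elite])) {
        rc <- tryCatch(rank_crosses(NULL, et, geno, tr,
                                    top_m = config$top_m),
                       error = function(e) NULL)
        if (is.null(rc)) next
        rc <- cbind(trait = tr, rc)
        rows[[length(rows) + 1L]] <- rc
      }
      write_tsv(if (length(rows)) do.call(rbind, rows) else
        data.frame(trait = character(), parentA = character(),
                   parentB = character(), n_elite = integer(),
                   predicted_effect = numeric()),
        path("crosses.tsv"))
    })
  }

  invisible(manifest)
}

digest_object <- function(x) {
  # stable hash of an R object via its deparsed canonical text form
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}
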