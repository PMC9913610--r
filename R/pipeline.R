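# Orchestration: simulate -> quantitative genetics -> index -> GWAS,
# with delimited-text outputs stamped with the configuration hash and seed.

.string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.config_hash <- function(cfg) .string_hash(paste(deparse(cfg), collapse = ""))

.write_stamped <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# config_hash: ", .config_hash(cfg)),
               paste0("# seed: ", cfg$seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML file with a mandatory \code{seed}; unknown keys are passed through
#' to [sim_config()], model options (\code{models}, \code{n_pc},
#' \code{n_top}, \code{n_negative}, QC thresholds) are picked up by the
#' stage runners.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

.sim_cfg_from_run <- function(cfg) {
  keep <- intersect(names(cfg), names(formals(sim_config)))
  do.call(sim_config, cfg[keep])
}

#' Simulate and write a full synthetic dataset
#'
#' Writes the pedigree, the record table, the truth ledger and the PLINK-1
#' genotype fileset to \code{out_dir}.
#'
#' @param cfg Run configuration list (needs \code{seed}; see
#'   [read_run_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the list of generated objects.
#' @export
run_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- .sim_cfg_from_run(cfg)
  dat <- simulate_dataset(scfg, cap = isTRUE(cfg$cap))
  gt <- simulate_genotypes(scfg)
  ped_out <- dat$pedigree[, c("animal", "sire", "dam", "birth_year", "sex")]
  ped_out$sire[is.na(ped_out$sire)] <- "0"
  ped_out$dam[is.na(ped_out$dam)] <- "0"
  .write_stamped(ped_out, file.path(out_dir, "pedigree.tsv"), cfg)
  .write_stamped(dat$records, file.path(out_dir, "records.tsv"), cfg)
  .write_stamped(
    data.frame(animal = rownames(dat$truth$egv_true), dat$truth$egv_true,
               check.names = FALSE),
    file.path(out_dir, "truth_egv.tsv"), cfg)
  write_plink1(file.path(out_dir, "genotypes"), gt$G, gt$map, gt$sample_ids)
  .write_stamped(data.frame(id = names(gt$phenotype), IpcT = gt$phenotype),
                 file.path(out_dir, "pseudo_phenotype.tsv"), cfg)
  .write_stamped(data.frame(causal = gt$truth$causal_ids,
                            effect = gt$truth$causal_effects),
                 file.path(out_dir, "truth_causal.tsv"), cfg)
  invisible(list(dataset = dat, genotypes = gt))
}

#' Run the quantitative-genetic analysis stage
#'
#' Fits the repeatability model and the requested random-regression models,
#' then writes the study's standard summary tables: descriptive statistics,
#' variance components with relative importance, model comparison
#' (logL/AIC/BIC), the parity trajectory of genetic variance and
#' heritability, the index eigen table, EGV correlations, the composite
#' index and the yearly genetic trend.
#'
#' @param cfg Run configuration (optionally \code{models}, a subset of
#'   \code{c("rep", "ra1", "ra2")}; default all three).
#' @param out_dir Output directory.
#' @param data Optional in-memory list (pedigree, records) as produced by
#'   [run_simulate()]; otherwise read from \code{cfg$pedigree_file} /
#'   \code{cfg$records_file}.
#' @return Invisibly, a list with the fits, trajectory, index and tables.
#' @export
run_quantgen <- function(cfg, out_dir, data = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(data)) {
    ped <- sort_pedigree(read_pedigree(cfg$pedigree_file,
                                       sep = cfg$sep %||% ","))
    rec <- utils::read.table(cfg$records_file, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  } else {
    ped <- data$pedigree
    rec <- data$records
  }
  models <- cfg$models %||% c("rep", "ra1", "ra2")
  desc <- rbind(
    cbind(parameter = "Re", descriptive_stats(rec$Re)),
    cbind(parameter = "F", descriptive_stats(rec$F)),
    cbind(parameter = "age_first_calving",
          descriptive_stats(rec$age_months[rec$Cn == 1])))
  .write_stamped(desc, file.path(out_dir, "descriptives.tsv"), cfg)
  Ainv <- a_inverse_sparse(ped)
  fits <- list()
  comparison <- NULL
  if ("rep" %in% models) {
    fits$rep <- fit_repeatability(rec, ped, Ainv = Ainv)
    comp <- fits$rep$components
    .write_stamped(
      data.frame(effect = names(comp), variance = comp,
                 rel_importance = relative_importance(comp)),
      file.path(out_dir, "components_rep.tsv"), cfg)
  }
  for (r in 1:2) {
    mname <- paste0("ra", r)
    if (mname %in% models) fits[[mname]] <- fit_rrm(rec, ped, r = r, Ainv = Ainv)
  }
  comparison <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    ic <- information_criteria(f$logL, f$n_params, f$n_records)
    data.frame(model = nm, n_params = f$n_params, logL = f$logL,
               AIC = ic[["AIC"]], BIC = ic[["BIC"]],
               converged = f$converged)
  }))
  .write_stamped(comparison, file.path(out_dir, "model_comparison.tsv"), cfg)
  result <- list(fits = fits, comparison = comparison)
  best_ra <- if (!is.null(fits$ra2)) fits$ra2 else fits$ra1
  if (!is.null(best_ra)) {
    tr <- rrm_trajectory(best_ra)
    .write_stamped(tr$table, file.path(out_dir, "trajectory.tsv"), cfg)
    .write_stamped(
      data.frame(calving = rownames(tr$rg), round(tr$rg, 4),
                 check.names = FALSE),
      file.path(out_dir, "genetic_correlations.tsv"), cfg)
    pi_ <- pca_index(best_ra$egv, n_pc = cfg$n_pc %||% 2)
    eig <- data.frame(component = colnames(pi_$pca$vectors),
                      eigenvalue = pi_$pca$values,
                      variance_pct = pi_$pca$variance_pct)
    .write_stamped(eig, file.path(out_dir, "index_eigen.tsv"), cfg)
    .write_stamped(
      data.frame(loading = rownames(pi_$pca$vectors),
                 pi_$pca$vectors[, 1:2, drop = FALSE]),
      file.path(out_dir, "index_eigenvectors.tsv"), cfg)
    .write_stamped(pi_$index, file.path(out_dir, "index.tsv"), cfg)
    egv_cor <- stats::cor(best_ra$egv)
    ipct_cor <- as.numeric(stats::cor(pi_$index$IpcT, best_ra$egv))
    cor_row <- function(label, v) {
      data.frame(row = label,
                 as.list(stats::setNames(v, paste0("EGV", seq_along(v)))),
                 check.names = FALSE)
    }
    .write_stamped(
      rbind(cor_row("EGV1", egv_cor[1, ]), cor_row("IpcT", ipct_cor)),
      file.path(out_dir, "egv_correlations.tsv"), cfg)
    by <- stats::setNames(ped$birth_year, ped$animal)
    trend <- genetic_trend(pi_$index$IpcT |>
                             stats::setNames(pi_$index$animal), by)
    .write_stamped(trend, file.path(out_dir, "genetic_trend.tsv"), cfg)
    result$trajectory <- tr
    result$index <- pi_
    result$trend <- trend
  }
  invisible(result)
}

#' Run the association stage
#'
#' QC, LD pruning, GRM, stratification PCs, the LMM Wald scan on the index
#' pseudo-phenotype, the hit table, candidate-gene windows and the
#' Manhattan-plot data table.
#'
#' @param cfg Run configuration (thresholds \code{call_rate_min},
#'   \code{maf_min}, \code{r2_max}, \code{n_pcs}, \code{suggestive},
#'   \code{genomewide}, \code{flank_bp} all optional).
#' @param out_dir Output directory.
#' @param data Optional in-memory list with \code{genotypes} (from
#'   [run_simulate()]); otherwise \code{cfg$plink_prefix} and
#'   \code{cfg$phenotype_file} are read.
#' @param gene_table Optional gene annotation data.frame (gene, chr, start,
#'   end).
#' @return Invisibly, list with scan, hits, genes, and the QC report.
#' @export
run_gwas <- function(cfg, out_dir, data = NULL, gene_table = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(data)) {
    pl <- read_plink1(cfg$plink_prefix)
    ph <- utils::read.table(cfg$phenotype_file, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    y <- stats::setNames(ph[[2]], ph[[1]])[pl$fam$iid]
    G <- pl$G
    map <- pl$map
  } else {
    G <- data$genotypes$G
    map <- data$genotypes$map
    y <- data$genotypes$phenotype
  }
  qc <- qc_filter(G, map, call_rate_min = cfg$call_rate_min %||% 0.95,
                  maf_min = cfg$maf_min %||% 0.05)
  .write_stamped(qc$report, file.path(out_dir, "qc_report.tsv"), cfg)
  pruned <- ld_prune(qc$G, qc$map, r2_max = cfg$r2_max %||% 0.5)
  K <- grm_centered(pruned$G)
  W <- stratification_pcs(pruned$G, n_pcs = cfg$n_pcs %||% 10)
  scan <- wald_scan(y, W, qc$G, K, map = qc$map)
  .write_stamped(scan, file.path(out_dir, "assoc.tsv"), cfg)
  hits <- significant_hits(scan, suggestive = cfg$suggestive %||% 1e-4,
                           genomewide = cfg$genomewide %||% 1e-5)
  .write_stamped(hits, file.path(out_dir, "hits.tsv"), cfg)
  genes <- candidate_genes(hits, gene_table %||%
                             data.frame(gene = character(0), chr = character(0),
                                        start = integer(0), end = integer(0)),
                           flank = cfg$flank_bp %||% 5e5)
  .write_stamped(genes, file.path(out_dir, "candidate_genes.tsv"), cfg)
  manh <- data.frame(chr = scan$chr, pos = scan$ps,
                     neg_log10_p = -log10(scan$p_wald))
  .write_stamped(manh, file.path(out_dir, "manhattan.tsv"), cfg)
  invisible(list(scan = scan, hits = hits, genes = genes,
                 qc_report = qc$report, lambda = attr(scan, "lambda"),
                 lambda_gc = gc_lambda(scan$p_wald)))
}

#' Run the full pipeline
#'
#' Simulation, quantitative-genetic stage and association stage in
#' sequence under one seed and one output directory.
#'
#' @param cfg Run configuration.
#' @param out_dir Output directory.
#' @return Invisibly, list of stage results.
#' @export
run_all <- function(cfg, out_dir) {
  sim <- run_simulate(cfg, file.path(out_dir, "simulated"))
  qg <- run_quantgen(cfg, file.path(out_dir, "quantgen"),
                     data = sim$dataset)
  gw <- run_gwas(cfg, file.path(out_dir, "gwas"), data = sim)
  invisible(list(sim = sim, quantgen = qg, gwas = gw))
}
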