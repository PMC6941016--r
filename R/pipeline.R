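#' Read a pipeline configuration
#'
#' Plain-text YAML with one block per stage (`simulate`, `qc`, `grm`,
#' `reml`, `bayes`, `gwas`, `cv`) plus top-level `seed`, `out_dir` and
#' `verbose`.  The environment is never consulted for parameters.
#'
#' @param path YAML file.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pipeline_config(cfg)
}

#' Validate a pipeline configuration list
#'
#' @param config named list; see [run_pipeline()] for recognised fields.
#' @return the validated list, classed `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  defaults <- list(
    seed = 1L, out_dir = "domgp_out", verbose = TRUE,
    simulate = list(n_individuals = 500, n_snps = 2000),
    qc = list(),
    reml = list(),
    bayes = list(n_iterations = 4000L, burn_in = 1000L, thinning = 5L),
    gwas = list(),
    cv = list(k = 5L, repeats = 2L, models = c("GBLUP", "GBLUP-D"))
  )
  cfg <- utils::modifyList(defaults, config)
  if (!is.numeric(cfg$seed)) stop("config$seed must be an integer")
  structure(cfg, class = "pipeline_config")
}

.log_msg <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> qc -> grm -> reml (GBLUP and GBLUP-D with the
#' likelihood-ratio test) -> bayes -> gwas -> cv in dependency order,
#' writing every stage's outputs under `config$out_dir` and a manifest
#' (file name, byte size, MD5 hash) at the end.  Stage seeds are derived
#' deterministically from the global seed, so changing a later stage's
#' inputs never perturbs an earlier stage.
#'
#' @param config a `pipeline_config`, a plain named list, or a path to a
#'   YAML file.
#' @return list with `manifest` (data frame), `results` (per-stage R
#'   objects), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  verbose <- isTRUE(config$verbose)
  seed <- as.integer(config$seed)
  written <- character(0)
  results <- list()

  # -- stage 1: simulate
  sim_args <- config$simulate
  sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)
  .log_msg(verbose, "[simulate] n = %d, m = %d, h2_a = %.3f, h2_d = %.3f, seed = %d",
           cfg$n_individuals, cfg$n_snps, cfg$h2_additive, cfg$h2_dominance, seed)
  ds <- simulate_dataset(cfg)
  prefix <- file.path(out_dir, "sim")
  written <- c(written, write_dataset(ds, prefix))
  results$simulate <- ds

  # -- stage 2: qc
  thr <- do.call(qc_thresholds, config$qc)
  .log_msg(verbose, "[qc] maf > %g, snp missing < %g, hwe p > %g, ind missing <= %g",
           thr$min_maf, thr$max_snp_missing, thr$min_hwe_p, thr$max_ind_missing)
  qc <- apply_qc(ds$genotypes, thr)
  qc_path <- file.path(out_dir, "qc_report.tsv")
  write_qc_report(qc$report, qc_path)
  written <- c(written, qc_path)
  results$qc <- qc$report
  geno <- qc$genotypes
  keep_ids <- geno$individual_ids
  ph <- ds$phenotypes[match(keep_ids, ds$phenotypes$id), , drop = FALSE]

  # -- stage 3: grm
  .log_msg(verbose, "[grm] building G and D for %d individuals x %d SNPs",
           n_ind(geno), n_snp(geno))
  G <- stabilize(build_G(geno), 1e-6)
  D <- stabilize(build_D(geno), 1e-6)
  g_path <- file.path(out_dir, "grm_G.tsv")
  d_path <- file.path(out_dir, "grm_D.tsv")
  write_grm_tsv(G, g_path, keep_ids)
  write_grm_tsv(D, d_path, keep_ids)
  written <- c(written, g_path, d_path)
  results$grm <- list(G = G, D = D)

  # -- stage 4: reml (GBLUP vs GBLUP-D)
  design <- trait_design(
    ph$trait, ph[, c("year", "sex", "entry_weight", "fattening_days")],
    ids = ph$id
  )
  vc_a <- reml_fit(design, list(G))
  vc_ad <- reml_fit(design, list(G, D))
  lrt <- likelihood_ratio_test(vc_a$logL, vc_ad$logL)
  h2 <- heritabilities(vc_ad)
  .log_msg(verbose, "[reml] GBLUP logL = %.3f, GBLUP-D logL = %.3f, LRT chi2 = %.3f",
           vc_a$logL, vc_ad$logL, lrt$chi2)
  vc_tab <- data.frame(
    quantity = c("sigma_a2_AD", "sigma_d2_AD", "sigma_e2_AD", "h2_narrow_AD",
                 "h2_dominance_AD", "dominance_to_genetic_AD", "sigma_a2_A",
                 "sigma_e2_A", "h2_narrow_A", "logL_A", "logL_AD",
                 "lrt_chi2", "lrt_p_mixture"),
    value = c(vc_ad$sigma_a2, vc_ad$sigma_d2, vc_ad$sigma_e2, h2$h2_narrow,
              h2$h2_dominance, h2$dominance_to_genetic, vc_a$sigma_a2,
              vc_a$sigma_e2, heritabilities(vc_a)$h2_narrow, vc_a$logL,
              vc_ad$logL, lrt$chi2, lrt$p_value)
  )
  vc_path <- file.path(out_dir, "variance_components.tsv")
  write.table(vc_tab, vc_path, quote = FALSE, sep = "\t", row.names = FALSE)
  written <- c(written, vc_path)
  blup <- blup_solve(design, list(G, D), vc_ad)
  blup_path <- file.path(out_dir, "blup.tsv")
  write.table(
    data.frame(id = keep_ids, a_hat = blup$a_hat, d_hat = blup$d_hat),
    blup_path, quote = FALSE, sep = "\t", row.names = FALSE
  )
  written <- c(written, blup_path)
  results$reml <- list(GBLUP = vc_a, `GBLUP-D` = vc_ad, lrt = lrt,
                       heritabilities = h2, blup = blup)

  # -- stage 5: bayes
  bayes_args <- config$bayes
  bayes_args$seed <- seed + 1000L
  hyper <- do.call(bayes_hyper, bayes_args)
  .log_msg(verbose, "[bayes] BayesAD chain: %d sweeps, %d burn-in, seed %d",
           hyper$n_iterations, hyper$burn_in, hyper$seed)
  designs <- build_designs(geno)
  chain <- run_chain(design, designs, hyper, model = "bayesAD")
  bayes_path <- file.path(out_dir, "bayes_effects.tsv")
  write.table(bayes_summary(chain), bayes_path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  written <- c(written, bayes_path)
  results$bayes <- chain

  # -- stage 6: gwas
  gwas_args <- config$gwas
  sc <- do.call(scan_config, gwas_args)
  hits <- mlmm_scan(design, geno, list(G, D), sc)
  .log_msg(verbose, "[gwas] %d hit(s) at threshold %.3g", nrow(hits),
           attr(hits, "threshold"))
  if (!is.null(config$genes)) {
    genes <- read.table(config$genes, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    hits <- annotate_hits(hits, genes)
  }
  gwas_path <- file.path(out_dir, "gwas_hits.tsv")
  write.table(as.data.frame(hits), gwas_path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  written <- c(written, gwas_path)
  results$gwas <- hits

  # -- stage 7: cv
  cv_args <- config$cv
  plan <- make_folds(keep_ids, k = cv_args$k, repeats = cv_args$repeats,
                     seed = seed + 2000L)
  .log_msg(verbose, "[cv] %d-fold x %d repeats, models: %s", plan$k,
           plan$repeats, paste(cv_args$models, collapse = ", "))
  cv <- cross_validate(design, geno, models = cv_args$models, plan = plan,
                       matrices = if ("GBLUP-D" %in% cv_args$models)
                         list(G, D) else list(G))
  cv_cells_path <- file.path(out_dir, "cv_cells.tsv")
  cv_summary_path <- file.path(out_dir, "cv_summary.tsv")
  write.table(cv$cells, cv_cells_path, quote = FALSE, sep = "\t", row.names = FALSE)
  write.table(cv$summary, cv_summary_path, quote = FALSE, sep = "\t", row.names = FALSE)
  written <- c(written, cv_cells_path, cv_summary_path)
  results$cv <- cv

  manifest <- data.frame(
    file = basename(written),
    bytes = file.size(written),
    md5 = unname(tools::md5sum(written)),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, manifest_path, quote = FALSE, sep = "\t", row.names = FALSE)
  .log_msg(verbose, "[done] %d files written to %s", nrow(manifest), out_dir)
  invisible(list(manifest = manifest, results = results))
}
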