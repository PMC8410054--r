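# Orchestration: a one-command end-to-end run on synthetic data, a run
# manifest for reproducibility, and a small CLI dispatcher.

#' Pipeline configuration
#'
#' Collects thresholds, sizes and the root seed for [run_all()].  All
#' randomness flows from the root seed through fixed per-stage substreams,
#' so a rerun with the same configuration is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param seed root seed.
#' @param n_genes,n_per_group simulation size (see [sim_config()]).
#' @param fdr_deg,lfc_min DEG signature thresholds.
#' @param fdr_gsea GSEA significance threshold.
#' @param n_perm GSEA permutations.
#' @param n_sets,n_enriched gene-set collection size.
#' @param cohort_n_per_sex cohort subjects per sex.
#' @param cohort_loading planted cohort effect size.
#' @param normalize_scores normalize summed Z-scores by gene count.
#' @param overlap_denominator "union" or "smaller".
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "fcglung_run", seed = 1L,
                            n_genes = 2000L, n_per_group = 3L,
                            fdr_deg = 0.05, lfc_min = 1.0, fdr_gsea = 0.25,
                            n_perm = 1000L, n_sets = 50L, n_enriched = 5L,
                            cohort_n_per_sex = 60L, cohort_loading = 2,
                            normalize_scores = FALSE,
                            overlap_denominator = "union") {
  if (fdr_deg <= 0 || fdr_deg > 1 || fdr_gsea <= 0 || fdr_gsea > 1) {
    stop("FDR thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), n_genes = n_genes,
    n_per_group = n_per_group, fdr_deg = fdr_deg, lfc_min = lfc_min,
    fdr_gsea = fdr_gsea, n_perm = n_perm, n_sets = n_sets,
    n_enriched = n_enriched, cohort_n_per_sex = cohort_n_per_sex,
    cohort_loading = cohort_loading, normalize_scores = normalize_scores,
    overlap_denominator = overlap_denominator
  ), class = "pipeline_config")
}

stage_msg <- function(stage, t0) {
  message(sprintf("[fcglung] %-12s %6.1fs", stage,
                  as.numeric(proc.time()["elapsed"]) - t0))
}

#' Run the full synthetic pipeline
#'
#' Simulates a factorial study, a cohort and a gene-set collection; runs the
#' per-genotype hyperoxia contrasts at every timepoint; decomposes the
#' responses into the gonadal/chromosomal regions; projects the signatures
#' onto the cohort (summed Z-scores, intersignature correlation, UPGMA
#' clustering); runs preranked GSEA for the last-timepoint responses and a
#' cohort BPD contrast, applies the discordant-pathway rule; and computes
#' the sex-stratified clinical associations.  All numeric outputs plus a
#' JSON run manifest (package version, seed, thresholds, input digests) are
#' written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all in-memory results.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(proc.time()["elapsed"])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  sc <- sim_config(n_genes = config$n_genes,
                   n_per_group = config$n_per_group, seed = config$seed)
  eff <- scaled_effects(sc)
  study <- simulate_murine_counts(sc, eff)
  write_counts_tsv(study$counts, out("counts.tsv"))
  write_sample_sheet(study$design, out("sample_sheet.tsv"))
  utils::write.table(study$gene_annotation, out("gene_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg("simulate", t0)

  contrasts <- list()
  decomp <- list()
  for (tp in sc$timepoints) {
    hc <- hyperoxia_contrasts(study, tp, fdr_max = config$fdr_deg,
                              lfc_min = config$lfc_min)
    contrasts[[tp]] <- hc
    for (g in names(hc)) {
      utils::write.table(hc[[g]]$table, out(sprintf("deg_%s_%s.tsv", g, tp)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_signature_tsv(hc[[g]]$signature,
                          out(sprintf("signature_%s_%s.tsv", g, tp)))
    }
    dv <- decompose_signatures(hc$XXF$signature, hc$XXM$signature,
                               hc$XYF$signature, hc$XYM$signature)
    decomp[[tp]] <- dv
    jsonlite::write_json(
      list(counts = as.data.frame(dv$counts),
           discordant = dv$discordant),
      out(sprintf("venn_%s.json", tp)), auto_unbox = TRUE, digits = NA)
  }
  stage_msg("deg+venn", t0)

  last_tp <- utils::tail(sc$timepoints, 1)
  sigs <- lapply(unlist(contrasts, recursive = FALSE),
                 function(x) x$signature)
  nonempty <- vapply(sigs, function(s) length(s$up) + length(s$down) > 0,
                     logical(1))
  sigs <- sigs[nonempty]
  if (length(sigs) == 0L) stop("pipeline stage 'project': every signature is empty",
                               call. = FALSE)
  planted_sig <- contrasts[[last_tp]]$XXF$signature
  cohort <- simulate_cohort(sc, planted_sig, loading = config$cohort_loading,
                            n_per_sex = config$cohort_n_per_sex)
  write_counts <- cohort$expression
  utils::write.table(
    data.frame(gene_id = rownames(write_counts), write_counts,
               check.names = FALSE),
    out("cohort_expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_clinical_csv(cohort$clinical, out("clinical.csv"))

  z <- zscore_matrix(cohort)
  scores <- score_all(z, sigs, normalize = config$normalize_scores)
  utils::write.table(
    data.frame(signature = rownames(scores), scores, check.names = FALSE),
    out("score_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  rr <- intersignature_correlation(scores)
  utils::write.table(
    data.frame(signature = rownames(rr), rr, check.names = FALSE),
    out("intersignature_correlation.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tree <- cluster_responses(rr, input = "correlation")
  write_newick(tree, out("signature_dendrogram.nwk"))
  assoc <- clinical_association(scores, cohort$clinical)
  utils::write.table(assoc, out("clinical_association.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_msg("project", t0)

  gene_sets <- simulate_gene_sets(sc, eff, n_sets = config$n_sets,
                                  n_enriched = config$n_enriched)
  write_gmt(gene_sets, out("gene_sets.gmt"))
  gsea_results <- list()
  for (g in GENOTYPES) {
    ranked <- rank_from_contrast(contrasts[[last_tp]][[g]]$table)
    gsea_results[[g]] <- gsea_preranked(
      ranked, gene_sets, n_perm = config$n_perm,
      seed = child_seed(config$seed, 101L + match(g, GENOTYPES)))
    utils::write.table(gsea_results[[g]],
                       out(sprintf("gsea_%s_%s.tsv", g, last_tp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # cohort-side ranked response: BPD (any grade) vs none, moderated test
  has_bpd <- cohort$clinical$bpd_status != "none"
  human_tab <- moderated_two_group_test(
    cohort$expression,
    group_a = cohort$clinical$subject_id[!has_bpd],
    group_b = cohort$clinical$subject_id[has_bpd])
  gsea_results$human <- gsea_preranked(
    rank_from_contrast(human_tab), gene_sets, n_perm = config$n_perm,
    seed = child_seed(config$seed, 106L))
  utils::write.table(gsea_results$human, out("gsea_human.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nes <- nes_matrix(gsea_results, fdr_max = config$fdr_gsea)
  utils::write.table(
    data.frame(response = rownames(nes), nes, check.names = FALSE),
    out("nes_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(nes) >= 2L) {
    write_newick(cluster_responses(nes, input = "nes"),
                 out("nes_dendrogram.nwk"))
  }
  disc <- discordant_pathways(gsea_results$human, gsea_results$XXF,
                              gsea_results$XXM, gsea_results$XYF,
                              gsea_results$XYM, fdr_max = config$fdr_gsea)
  writeLines(disc, out("discordant_pathways.txt"))
  stage_msg("gsea", t0)

  manifest <- list(
    package = "fcglung",
    version = as.character(utils::packageVersion("fcglung")),
    seed = config$seed,
    thresholds = list(fdr_deg = config$fdr_deg, lfc_min = config$lfc_min,
                      fdr_gsea = config$fdr_gsea),
    n_perm = config$n_perm,
    digests = as.list(tools::md5sum(c(out("counts.tsv"),
                                      out("sample_sheet.tsv"),
                                      out("gene_sets.gmt"))))
  )
  names(manifest$digests) <- basename(names(manifest$digests))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  stage_msg("done", t0)

  invisible(list(study = study, contrasts = contrasts, decomposition = decomp,
                 cohort = cohort, scores = scores, correlation = rr,
                 tree = tree, association = assoc, gene_sets = gene_sets,
                 gsea = gsea_results, nes = nes, discordant = disc,
                 manifest = manifest))
}

# --- minimal CLI -----------------------------------------------------------

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `deg`, `anova` and `all`; invoke
#' via `Rscript -e 'fcglung::fcg_cli()' <subcommand> --out DIR --seed N`.
#'
#' @param args character vector of arguments (defaults to the command line).
#' @return invisibly, the subcommand's result.
#' @export
fcg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: fcg_cli <simulate|deg|anova|all> [--out DIR] [--seed N] ...")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  seed <- as.integer(opts$seed %||% 1L)
  out_dir <- opts$out %||% "fcglung_run"
  res <- switch(
    cmd,
    simulate = {
      sc <- sim_config(n_genes = as.integer(opts$genes %||% 2000L),
                       seed = seed)
      study <- simulate_murine_counts(sc, scaled_effects(sc))
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_counts_tsv(study$counts, file.path(out_dir, "counts.tsv"))
      write_sample_sheet(study$design, file.path(out_dir, "sample_sheet.tsv"))
      utils::write.table(study$gene_annotation,
                         file.path(out_dir, "gene_annotation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      study
    },
    deg = {
      counts <- read_counts_tsv(opts$counts)
      design <- read_sample_sheet(opts$samples)
      study <- list(counts = counts, design = design)
      tp <- opts$timepoint %||% design$timepoint[1]
      hc <- hyperoxia_contrasts(study, tp)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (g in names(hc)) {
        utils::write.table(hc[[g]]$table,
                           file.path(out_dir, sprintf("deg_%s_%s.tsv", g, tp)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        write_signature_tsv(hc[[g]]$signature,
                            file.path(out_dir,
                                      sprintf("signature_%s_%s.tsv", g, tp)))
      }
      hc
    },
    anova = {
      df <- utils::read.csv(opts$phenotype, stringsAsFactors = FALSE)
      tab <- three_way_anova(df$value, df)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(tab, file.path(out_dir, "anova_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    },
    all = {
      cfg <- pipeline_config(out_dir = out_dir, seed = seed,
                             n_genes = as.integer(opts$genes %||% 2000L),
                             n_perm = as.integer(opts$n_perm %||% 1000L))
      run_all(cfg)
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(res)
}
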