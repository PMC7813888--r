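#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Orchestrates the stages end-to-end: simulate (or load) paired VC/SC
#' methylomes, call per-context DMRs, annotate them against gene/TE
#' features, optionally run gene-set enrichment on the associated genes,
#' and summarise allele transmission from progeny counts. All outputs
#' are tab-separated tables under `out_dir`, plus a JSON manifest
#' recording every parameter and the seed, so a rerun with the same
#' config is byte-identical.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{seed}{integer, seeds every stage.}
#'     \item{simulation}{a [simulation_config], or `NULL` to skip
#'       simulation (then `sample_A_path`/`sample_B_path` cytosine
#'       reports are required).}
#'     \item{sample_A_path,sample_B_path}{optional cytosine report
#'       paths used when `simulation` is `NULL`.}
#'     \item{gff_path}{optional GFF3 with gene/TE features (required
#'       when not simulating and annotation is wanted).}
#'     \item{dmr}{a [dmr_params]; default `dmr_params()`.}
#'     \item{annotation_window}{bp flank for gene association
#'       (default 500).}
#'     \item{gmt_path,background}{optional GMT term sets and background
#'       gene universe for enrichment of DMR-associated genes.}
#'     \item{progeny_path}{optional progeny TSV for the transmission
#'       stage.}
#'     \item{expected}{Mendelian expectation for the transmission test
#'       (default 0.5).}
#'     \item{min_seeds,max_seeds}{silique filters (default 20, NULL).}
#'   }
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results of each stage
#'   (`dmrs`, `annotated`, `enrichment`, `transmission`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- if (!is.null(config$dmr)) config$dmr else dmr_params()
  window <- if (!is.null(config$annotation_window))
    config$annotation_window else 500L
  results <- list()

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    layout <- make_genome(sim)
    truth <- plant_truth(sim, layout)
    vc <- simulate_sample(truth, layout, "VC", "functional", sim)
    sc <- simulate_sample(truth, layout, "SC", "functional", sim)
    write_genome_fasta(layout$genome, file.path(out_dir, "genome.fa"))
    write_gff(layout$genes, layout$tes, file.path(out_dir, "features.gff3"))
    utils::write.table(truth, file.path(out_dir, "truth_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_cytosine_report(vc, file.path(out_dir, "VC.cx_report.tsv"))
    write_cytosine_report(sc, file.path(out_dir, "SC.cx_report.tsv"))
    genes <- layout$genes
    tes <- layout$tes
    results$truth <- truth
  } else {
    if (is.null(config$sample_A_path) || is.null(config$sample_B_path))
      stop("pipeline stage 'input': need simulation config or two cytosine reports")
    vc <- parse_cytosine_report(config$sample_A_path, cell_type = "VC")
    sc <- parse_cytosine_report(config$sample_B_path, cell_type = "SC")
    genes <- NULL
    tes <- NULL
    if (!is.null(config$gff_path)) {
      feats <- parse_gff(config$gff_path)
      genes <- feats$genes
      tes <- feats$tes
    }
  }

  dmr_sets <- call_dmrs(vc, sc, params)
  dmrs <- dmr_table(dmr_sets)
  write_dmr_table(dmrs, file.path(out_dir, "dmrs.tsv"))
  write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
  results$dmrs <- dmrs

  counts <- as.data.frame(table(
    context = factor(dmrs$context, levels = c("CG", "CHG", "CHH")),
    direction = factor(dmrs$direction, levels = c("hypo", "hyper"))))
  names(counts)[3L] <- "n_dmrs"

  if (!is.null(genes)) {
    ann <- annotate_dmrs(dmrs, genes, tes, window)
    utils::write.table(ann, file.path(out_dir, "dmrs_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$annotated <- ann
    cat_counts <- as.data.frame(table(
      context = factor(ann$context, levels = c("CG", "CHG", "CHH")),
      direction = factor(ann$direction, levels = c("hypo", "hyper")),
      category = factor(ann$category,
                        levels = c("TE", "genic", "intergenic"))))
    names(cat_counts)[4L] <- "n_dmrs"
    utils::write.table(cat_counts,
                       file.path(out_dir, "dmr_category_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(config$gmt_path) && !is.null(config$background)) {
      gene_list <- unique(unlist(strsplit(
        ann$associated_genes[nzchar(ann$associated_genes)], ",")))
      enr <- term_enrichment(gene_list, read_gmt(config$gmt_path),
                             config$background)
      write_enrichment_tsv(enr, file.path(out_dir, "enrichment.tsv"))
      results$enrichment <- enr
    }
  }
  utils::write.table(counts, file.path(out_dir, "dmr_count_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(config$progeny_path)) {
    prog <- read_progeny_tsv(config$progeny_path)
    min_seeds <- if (!is.null(config$min_seeds)) config$min_seeds else 20L
    prog <- filter_siliques(prog, min_seeds = min_seeds,
                            max_seeds = config$max_seeds)
    expected <- if (!is.null(config$expected)) config$expected else 0.5
    ts <- transmission_summary(prog, expected)
    tdf <- data.frame(mean_frequency = ts$mean, sd = ts$sd,
                      n_replicates = ts$n_replicates,
                      pooled_frequency = ts$pooled_frequency,
                      n_total = ts$n_total, expected = ts$expected,
                      p_vs_mendelian = ts$p_vs_mendelian)
    utils::write.table(tdf, file.path(out_dir, "transmission_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$transmission <- ts
  }

  manifest <- list(
    seed = config$seed,
    dmr_params = unclass(params),
    annotation_window = window,
    simulation = if (!is.null(config$simulation))
      unclass(config$simulation) else NULL,
    n_dmrs = nrow(dmrs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  results$manifest <- manifest
  invisible(results)
}
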