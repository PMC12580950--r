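#' Run configuration
#'
#' One manifest for an end-to-end run: either a simulation block (the
#' dataset is generated) or paths to counts / sample sheet / gene lengths,
#' plus the per-stage parameter blocks and the output directory. Every run
#' echoes its effective parameters into the run summary so thresholds
#' never drift silently.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [simulation_config()], or `NULL` to read real inputs.
#' @param counts,samples,lengths Input paths (used when `sim` is `NULL`).
#' @param panels Optional path to a panel TSV; default panels otherwise.
#' @param quantify [quantify_params()].
#' @param rsg [rsg_params()].
#' @param de [de_params()].
#' @param panel_q_threshold q ceiling for the panel `variable` class.
#' @param seed Integer seed; overrides `sim$seed` when simulating.
#' @param force Overwrite existing outputs (default `FALSE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       sim = simulation_config(),
                       counts = NULL, samples = NULL, lengths = NULL,
                       panels = NULL,
                       quantify = quantify_params(),
                       rsg = rsg_params(),
                       de = de_params(),
                       panel_q_threshold = 0.05,
                       seed = 1L,
                       force = FALSE) {
  if (is.null(sim) && (is.null(counts) || is.null(samples) || is.null(lengths)))
    abort("without a simulation block, counts, samples and lengths paths are required")
  structure(list(out_dir = out_dir, sim = sim, counts = counts,
                 samples = samples, lengths = lengths, panels = panels,
                 quantify = quantify, rsg = rsg, de = de,
                 panel_q_threshold = panel_q_threshold,
                 seed = as.integer(seed), force = force),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full regional-expression pipeline
#'
#' Chains simulate (or load) -> FPKM quantification -> expressed-gene
#' accounting -> retention -> region-specific gene detection and
#' clustering -> all-pairs differential expression -> panel stability,
#' writing every stage table as TSV plus a run-summary JSON into
#' `config$out_dir`. Identical config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return The run summary list, invisibly.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) abort("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) {
    p <- file.path(config$out_dir, f)
    if (file.exists(p) && !config$force)
      abort("output '%s' exists; set force = TRUE to overwrite", p)
    p
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    ds <- stage("simulate", simulate_dataset(sim_cfg))
    counts <- ds$counts; samples <- ds$samples; gene_len <- ds$lengths
    truth <- ds$truth
    write_counts(counts, outfile("counts.tsv"))
    write_sample_sheet(samples, outfile("samples.csv"))
    write_gene_lengths(gene_len, outfile("gene_lengths.tsv"))
    write_truth(truth, outfile("truth.tsv"))
  } else {
    counts <- stage("read counts", read_counts(config$counts))
    samples <- stage("read samples", read_sample_sheet(config$samples))
    gene_len <- stage("read lengths", read_gene_lengths(config$lengths))
  }

  fpkm <- stage("quantify", compute_fpkm(counts, gene_len))
  rexpr <- stage("quantify", region_means(fpkm, samples))
  expr_sets <- stage("quantify", expressed_sets(rexpr, config$quantify))
  retained <- stage("quantify", retain_genes(rexpr, fpkm, samples, config$quantify))
  write_tsv(data.frame(gene_id = rownames(fpkm), round(fpkm, 4),
                       check.names = FALSE), outfile("fpkm.tsv"))
  write_tsv(data.frame(gene_id = rownames(rexpr), round(rexpr, 4),
                       check.names = FALSE), outfile("region_means.tsv"))
  write_tsv(expr_sets$summary, outfile("expressed_summary.tsv"))
  write_tsv(data.frame(gene_id = retained), outfile("retained_genes.tsv"))

  calls <- stage("rsg", detect_rsg(rexpr, retained, config$rsg))
  rsg_hits <- calls[calls$is_rsg, c("gene_id", "region", "mean_fpkm")]
  write_tsv(calls, outfile("rsg_calls.tsv"))
  write_tsv(rsg_hits, outfile("rsg_list.tsv"))
  if (nrow(rsg_hits) >= 2) {
    cl <- stage("rsg", cluster_rsg(rexpr[rsg_hits$gene_id, , drop = FALSE]))
    write_tsv(data.frame(gene_id = rownames(cl$zmat), round(cl$zmat, 4),
                         check.names = FALSE), outfile("rsg_heatmap_matrix.tsv"))
    jsonlite::write_json(
      list(labels = cl$labels, order = cl$order, heights = cl$heights,
           merge = cl$merge, distance = "euclidean", linkage = "complete"),
      outfile("rsg_dendrogram.json"), auto_unbox = TRUE, digits = NA)
  }

  pairs <- stage("de", enumerate_comparisons(region_levels(samples)))
  de_records <- lapply(seq_len(nrow(pairs)), function(i) {
    rec <- stage("de", pairwise_de(counts[retained, , drop = FALSE],
                                   samples, pairs[i, ], config$de))
    write_tsv(rec, outfile(paste0("de_", pairs$label[i], ".tsv")))
    rec
  })
  de_sum <- stage("de", summarize_de(de_records))
  write_tsv(de_sum, outfile("de_summary.tsv"))

  panel_defs <- if (is.null(config$panels)) default_panels() else
    stage("panels", read_panels(config$panels))
  psum <- stage("panels", panel_summary(fpkm, samples, panel_defs,
                                        config$panel_q_threshold))
  write_tsv(psum, outfile("panel_summary.tsv"))

  rsg_per_region <- table(factor(rsg_hits$region, levels = colnames(rexpr)))
  summary <- list(
    seed = config$seed,
    n_genes = nrow(counts),
    n_samples = ncol(counts),
    n_regions = ncol(rexpr),
    regions = colnames(rexpr),
    expressed = stats::setNames(as.list(expr_sets$counts),
                                names(expr_sets$counts)),
    n_shared_all_regions = length(expr_sets$shared),
    n_unique = stats::setNames(as.list(lengths(expr_sets$unique)),
                               names(expr_sets$unique)),
    n_retained = length(retained),
    n_rsg_total = nrow(rsg_hits),
    rsg_per_region = stats::setNames(as.list(as.integer(rsg_per_region)),
                                     names(rsg_per_region)),
    de_summary = de_sum,
    n_panel_variable = sum(psum$class == "variable", na.rm = TRUE),
    n_panel_stable = sum(psum$class == "stable", na.rm = TRUE),
    n_panel_missing = sum(psum$missing),
    params = list(
      quantify = unclass(config$quantify),
      rsg = unclass(config$rsg),
      de = unclass(config$de),
      panel_q_threshold = config$panel_q_threshold,
      sim = if (!is.null(config$sim)) unclass(config$sim) else NULL))
  if (!is.null(truth)) {
    ev <- truth_eval(rsg_hits, truth)
    summary$truth_eval <- list(sensitivity = ev$sensitivity, fpr = ev$fpr,
                               n_planted = ev$n_planted,
                               n_recovered = ev$n_recovered,
                               n_false = ev$n_false)
  }
  jsonlite::write_json(summary, outfile("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(summary)
}
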