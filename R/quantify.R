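#' Quantification parameters
#'
#' @param expressed_threshold FPKM floor for calling a gene expressed in a
#'   region (inclusive, `>=`); default 1.
#' @param retention_threshold FPKM floor for the retained analysis universe
#'   (strict, `>`); default 1.
#' @param retention_rule `"mean_per_region_any"` (default): retain a gene
#'   if its region-mean FPKM exceeds the threshold in at least one region.
#'   `"all_replicates_any_region"`: retain if some region has every
#'   replicate above the threshold — a much harsher literal reading, kept
#'   as an option.
#' @return A list of class `quantify_params`.
#' @export
quantify_params <- function(expressed_threshold = 1,
                            retention_threshold = 1,
                            retention_rule = c("mean_per_region_any",
                                               "all_replicates_any_region")) {
  if (expressed_threshold < 0 || retention_threshold < 0)
    abort("thresholds must be >= 0")
  structure(list(expressed_threshold = expressed_threshold,
                 retention_threshold = retention_threshold,
                 retention_rule = match.arg(retention_rule)),
            class = "quantify_params")
}

#' Compute FPKM from counts and gene lengths
#'
#' FPKM for gene g in sample j is `c_gj * 1e9 / (T_j * L_g)` where `T_j`
#' is the sample's total count over the genes present in the matrix
#' ("reads in genes", not total sequenced reads) and `L_g` the gene length
#' in bp. The value is zero exactly where the count is zero, is invariant
#' to uniform scaling of a sample's counts, and halves when a gene's
#' length doubles.
#'
#' @param counts Count matrix (genes x samples).
#' @param lengths Named vector of gene lengths in bp covering every gene
#'   in `counts`.
#' @return FPKM matrix with the same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, lengths) {
  counts <- validate_counts(counts)
  lengths <- validate_gene_lengths(lengths)
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    abort("no length for gene(s): %s", paste(miss, collapse = ", "))
  total <- colSums(counts)
  zero <- colnames(counts)[total == 0]
  if (length(zero))
    abort("sample(s) with zero total gene-assigned reads: %s",
          paste(zero, collapse = ", "))
  L <- lengths[rownames(counts)]
  counts * 1e9 / outer(L, total)
}

#' Per-region mean expression
#'
#' Arithmetic mean FPKM over each region's replicate samples, one column
#' per region in sample-sheet order.
#'
#' @param fpkm FPKM matrix from [compute_fpkm()].
#' @param samples Sample sheet covering every column of `fpkm`.
#' @return Matrix genes x regions with the per-region replicate count in
#'   attribute `"n_replicates"`.
#' @export
region_means <- function(fpkm, samples) {
  samples <- validate_sample_table(samples)
  miss <- setdiff(colnames(fpkm), samples$sample_id)
  if (length(miss))
    abort("sample(s) in matrix but not in sample sheet: %s",
          paste(miss, collapse = ", "))
  samples <- samples[samples$sample_id %in% colnames(fpkm), , drop = FALSE]
  groups <- samples_by_region(samples)
  groups <- groups[lengths(groups) > 0]
  means <- vapply(groups, function(ids)
    rowMeans(fpkm[, ids, drop = FALSE]), numeric(nrow(fpkm)))
  means <- matrix(means, nrow = nrow(fpkm),
                  dimnames = list(rownames(fpkm), names(groups)))
  attr(means, "n_replicates") <- lengths(groups)
  means
}

#' Expressed-gene sets per region
#'
#' A gene counts as expressed in a region when its region-mean FPKM is at
#' or above the threshold. Reports per-region sets and counts, the genes
#' shared by all regions, and the genes uniquely expressed in exactly one
#' region.
#'
#' @param region_expr Matrix from [region_means()].
#' @param params [quantify_params()].
#' @return List with `per_region` (named list of gene id vectors),
#'   `counts`, `shared`, `unique` (named list) and a tidy `summary`
#'   data.frame.
#' @export
expressed_sets <- function(region_expr, params = quantify_params()) {
  thr <- params$expressed_threshold
  expressed <- region_expr >= thr
  per_region <- lapply(seq_len(ncol(expressed)), function(j)
    rownames(expressed)[expressed[, j]])
  names(per_region) <- colnames(expressed)
  n_exp <- rowSums(expressed)
  shared <- rownames(expressed)[n_exp == ncol(expressed)]
  uniq <- lapply(seq_len(ncol(expressed)), function(j)
    rownames(expressed)[expressed[, j] & n_exp == 1])
  names(uniq) <- colnames(expressed)
  list(per_region = per_region,
       counts = lengths(per_region),
       shared = shared,
       unique = uniq,
       summary = data.frame(region = colnames(expressed),
                            n_expressed = unname(lengths(per_region)),
                            n_unique = unname(lengths(uniq)),
                            n_shared_all = length(shared)))
}

#' Retained analysis universe
#'
#' Applies the expression floor that defines the gene set used by the
#' region-specificity and differential-expression stages. Under the
#' default `mean_per_region_any` rule a gene is retained when its
#' region-mean FPKM is strictly above the threshold in at least one
#' region; under `all_replicates_any_region` some region must have every
#' replicate strictly above it. The returned list preserves input gene
#' order.
#'
#' @param region_expr Matrix from [region_means()].
#' @param fpkm FPKM matrix (needed for the all-replicates rule).
#' @param samples Sample sheet.
#' @param params [quantify_params()].
#' @return Character vector of retained gene ids.
#' @export
retain_genes <- function(region_expr, fpkm, samples,
                         params = quantify_params()) {
  thr <- params$retention_threshold
  keep <- switch(params$retention_rule,
    mean_per_region_any = rowSums(region_expr > thr) >= 1,
    all_replicates_any_region = {
      samples <- validate_sample_table(samples)
      samples <- samples[samples$sample_id %in% colnames(fpkm), , drop = FALSE]
      groups <- samples_by_region(samples)
      pass <- vapply(groups, function(ids)
        rowSums(fpkm[, ids, drop = FALSE] > thr) == length(ids),
        logical(nrow(fpkm)))
      rowSums(matrix(pass, nrow = nrow(fpkm))) >= 1
    })
  rownames(region_expr)[keep]
}
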