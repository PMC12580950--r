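#' Region-specific gene detection parameters
#'
#' The three specificity criteria, evaluated on region-mean FPKM of the
#' retained gene universe:
#' 1. fold dominance — the candidate region's mean is at least `fold`
#'    times the aggregate (default: maximum) of the other regions' means;
#' 2. fraction-of-others floor — the candidate mean is strictly greater
#'    than `frac_of_others` times the average of the other regions' means
#'    (implied by criterion 1 under either aggregate, kept for fidelity to
#'    the printed definition);
#' 3. top-quantile expression — the candidate mean is at or above the
#'    `top_quantile` quantile (linear-interpolation convention, inclusive
#'    boundary) of all retained genes' means within that region.
#'
#' @param fold Fold-dominance ratio (> 1), default 3.
#' @param frac_of_others Fraction for criterion 2, default 0.5.
#' @param top_quantile Quantile for criterion 3, default 0.75 (top 25%).
#' @param others_aggregate `"max"` (default, strictest) or `"mean"` for
#'   criterion 1's aggregate over the other regions.
#' @return A list of class `rsg_params`.
#' @export
rsg_params <- function(fold = 3, frac_of_others = 0.5, top_quantile = 0.75,
                       others_aggregate = c("max", "mean")) {
  if (fold <= 1) abort("fold must be > 1")
  if (top_quantile <= 0 || top_quantile >= 1)
    abort("top_quantile must be in (0, 1)")
  if (frac_of_others < 0) abort("frac_of_others must be >= 0")
  structure(list(fold = fold, frac_of_others = frac_of_others,
                 top_quantile = top_quantile,
                 others_aggregate = match.arg(others_aggregate)),
            class = "rsg_params")
}

#' Detect region-specific genes
#'
#' Evaluates the three criteria of [rsg_params()] for every retained gene
#' in every region and returns the full verdict table; the rows with
#' `is_rsg == TRUE` are the region-specific genes. With the default `max`
#' aggregate and `fold > 1` a gene can be specific to at most one region.
#' The criteria are scale-free: multiplying all region means by one
#' positive constant leaves every call unchanged.
#'
#' @param region_expr Matrix from [region_means()] (>= 2 regions).
#' @param retained Character vector of retained gene ids (non-empty subset
#'   of `rownames(region_expr)`); only these are evaluated and they define
#'   the per-region quantile universe.
#' @param params [rsg_params()].
#' @return data.frame with one row per (gene, region) candidate: gene_id,
#'   region, mean_fpkm, the three criterion verdicts and `is_rsg`, in
#'   region-major order with genes in input order.
#' @export
detect_rsg <- function(region_expr, retained, params = rsg_params()) {
  if (ncol(region_expr) < 2)
    abort("region-specificity needs >= 2 regions")
  if (length(retained) == 0) abort("retained gene list is empty")
  miss <- setdiff(retained, rownames(region_expr))
  if (length(miss))
    abort("retained gene(s) absent from region means: %s",
          paste(miss, collapse = ", "))
  E <- region_expr[retained, , drop = FALSE]
  regions <- colnames(E)
  out <- vector("list", length(regions))
  for (j in seq_along(regions)) {
    e <- E[, j]
    others <- E[, -j, drop = FALSE]
    agg <- switch(params$others_aggregate,
                  max = apply(others, 1, max),
                  mean = rowMeans(others))
    q <- stats::quantile(e, params$top_quantile, type = 7, names = FALSE)
    passes_fold <- e >= params$fold * agg
    passes_frac <- e > params$frac_of_others * rowMeans(others)
    passes_top <- e >= q
    out[[j]] <- data.frame(
      gene_id = retained, region = regions[j], mean_fpkm = unname(e),
      passes_fold = unname(passes_fold), passes_frac = unname(passes_frac),
      passes_top = unname(passes_top),
      is_rsg = unname(passes_fold & passes_frac & passes_top),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cluster region-specific genes
#'
#' Row-standardizes the expression matrix of detected RSGs (z-score across
#' regions; all-constant rows map to zeros) and clusters rows by
#' agglomerative hierarchical clustering with Euclidean distance and
#' complete linkage. `stats::hclust` resolves distance ties
#' deterministically from the input row order, so output is reproducible.
#'
#' @param expr Matrix of RSG rows (genes x regions), typically the RSG
#'   subset of [region_means()] output; >= 2 rows.
#' @return List with `order` (leaf order), `labels`, `heights` and `merge`
#'   from the linkage, the z-scored matrix `zmat`, and the `hclust`
#'   object.
#' @export
cluster_rsg <- function(expr) {
  if (is.null(dim(expr)) || nrow(expr) < 2)
    abort("clustering needs >= 2 RSG rows; skip clustering below that")
  z <- t(apply(expr, 1, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  dimnames(z) <- dimnames(expr)
  h <- stats::hclust(stats::dist(z, method = "euclidean"),
                     method = "complete")
  list(order = h$order, labels = rownames(z), heights = h$height,
       merge = h$merge, zmat = z, hclust = h)
}
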