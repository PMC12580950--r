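#' Differential-expression parameters
#'
#' @param fdr_threshold BH-adjusted q-value ceiling for significance,
#'   default 0.05.
#' @param lfc_threshold Minimum |log2 fold change|, default 1.
#' @param pseudocount Added to both group means in the fold change (and,
#'   by convention, substituted for a zero group mean inside the test
#'   statistic), default 0.5.
#' @return A list of class `de_params`.
#' @export
de_params <- function(fdr_threshold = 0.05, lfc_threshold = 1,
                      pseudocount = 0.5) {
  if (fdr_threshold <= 0 || lfc_threshold <= 0 || pseudocount <= 0)
    abort("de thresholds and pseudocount must be > 0")
  structure(list(fdr_threshold = fdr_threshold,
                 lfc_threshold = lfc_threshold,
                 pseudocount = pseudocount),
            class = "de_params")
}

# Base order reproducing the published enumeration of the six-cut design:
# pairs are emitted later-listed-first, giving BB vs GM first and
# LD vs QF last.
.default_pair_base <- c("GM", "BB", "IM", "T", "QF", "LD")

#' Enumerate pairwise region comparisons
#'
#' All C(n, 2) unordered region pairs. Within each pair the later-listed
#' region is the "A" side (numerator of the fold change). For the default
#' six-cut label set the enumeration follows the study convention,
#' starting at BB vs GM and ending at LD vs QF.
#'
#' @param regions Ordered character vector of region labels (>= 2).
#' @return data.frame with columns `region_a`, `region_b` and `label`
#'   (`"A_vs_B"`).
#' @export
enumerate_comparisons <- function(regions) {
  regions <- unique(as.character(regions))
  if (length(regions) < 2) abort("need >= 2 regions to compare")
  base <- if (setequal(regions, .default_pair_base)) .default_pair_base else regions
  n <- length(base)
  a <- character(0); b <- character(0)
  for (j in 2:n) for (i in seq_len(j - 1)) {
    a <- c(a, base[j]); b <- c(b, base[i])
  }
  data.frame(region_a = a, region_b = b,
             label = paste0(a, "_vs_", b), stringsAsFactors = FALSE)
}

#' Median-of-ratios size factors
#'
#' The reference for each gene is its geometric mean across samples,
#' computed over genes with no zero count; each sample's factor is the
#' median ratio of its counts to the reference over those genes.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of strictly positive factors.
#' @export
size_factors <- function(counts) {
  counts <- validate_counts(counts)
  usable <- rowSums(counts == 0) == 0
  if (!any(usable))
    abort(paste("no gene has positive counts in every sample;",
                "median-of-ratios is undefined (a pseudo-reference",
                "fallback would be required)"))
  ref <- exp(rowMeans(log(counts[usable, , drop = FALSE])))
  apply(counts[usable, , drop = FALSE], 2, function(col)
    stats::median(col / ref))
}

#' Pairwise differential expression (negative-binomial Wald stand-in)
#'
#' A transparent, dependency-free stand-in for a full DE engine, used to
#' exercise the comparison design and thresholds. Counts of the two
#' groups are normalized by median-of-ratios size factors computed on the
#' pair's samples; per gene, with normalized group means `mA`, `mB` and a
#' pooled method-of-moments dispersion `a = max(0, (v - m) / m^2)` (v the
#' pooled within-group variance, m the overall mean), the Wald statistic
#' is `z = (log mA - log mB) / SE` with
#' `SE^2 = (1/mA + a)/nA + (1/mB + a)/nB`, two-sided p from the standard
#' normal and BH correction within the comparison. The fold change is
#' `log2((mA + pc) / (mB + pc))`. Genes with both group means zero get
#' p = 1 and log2FC = 0; a single zero mean is replaced by the
#' pseudocount inside the statistic.
#'
#' @param counts Count matrix restricted to the analysis gene universe.
#' @param samples Sample sheet.
#' @param pair One-row data.frame (or list) with `region_a`, `region_b`.
#' @param params [de_params()].
#' @return data.frame with comparison, gene_id, log2fc (A over B),
#'   pvalue, qvalue and direction (`up`, `down`, `ns`).
#' @export
pairwise_de <- function(counts, samples, pair, params = de_params()) {
  samples <- validate_sample_table(samples)
  a_ids <- samples$sample_id[samples$region == pair$region_a]
  b_ids <- samples$sample_id[samples$region == pair$region_b]
  a_ids <- intersect(a_ids, colnames(counts))
  b_ids <- intersect(b_ids, colnames(counts))
  if (length(a_ids) < 2 || length(b_ids) < 2)
    abort("comparison %s vs %s needs >= 2 samples per group (found %d and %d)",
          pair$region_a, pair$region_b, length(a_ids), length(b_ids))
  sub <- counts[, c(a_ids, b_ids), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  A <- norm[, a_ids, drop = FALSE]
  B <- norm[, b_ids, drop = FALSE]
  nA <- length(a_ids); nB <- length(b_ids)
  muA <- rowMeans(A); muB <- rowMeans(B)
  vA <- rowSums((A - muA)^2) / (nA - 1)
  vB <- rowSums((B - muB)^2) / (nB - 1)
  v <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  m <- (nA * muA + nB * muB) / (nA + nB)
  disp <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  pc <- params$pseudocount
  log2fc <- log2((muA + pc) / (muB + pc))
  mA <- ifelse(muA == 0, pc, muA)
  mB <- ifelse(muB == 0, pc, muB)
  se <- sqrt((1 / mA + disp) / nA + (1 / mB + disp) / nB)
  z <- (log(mA) - log(mB)) / se
  p <- 2 * stats::pnorm(-abs(z))
  both_zero <- muA == 0 & muB == 0
  p[both_zero] <- 1
  log2fc[both_zero] <- 0
  q <- stats::p.adjust(p, method = "BH")
  direction <- rep("ns", length(p))
  direction[q < params$fdr_threshold & log2fc > params$lfc_threshold] <- "up"
  direction[q < params$fdr_threshold & log2fc < -params$lfc_threshold] <- "down"
  data.frame(comparison = paste0(pair$region_a, "_vs_", pair$region_b),
             gene_id = rownames(counts), log2fc = unname(log2fc),
             pvalue = unname(p), qvalue = unname(q), direction = direction,
             stringsAsFactors = FALSE)
}

#' Summarize differential-expression results per comparison
#'
#' @param records One data.frame (or list of data.frames, rbind-ed) of
#'   [pairwise_de()] rows across comparisons.
#' @return data.frame with `comparison`, `n_up`, `n_down`, `n_total`
#'   (significant genes only), one row per comparison in first-appearance
#'   order.
#' @export
summarize_de <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (is.null(records) || nrow(records) == 0)
    abort("no DE records to summarize")
  comps <- unique(records$comparison)
  out <- do.call(rbind, lapply(comps, function(cc) {
    r <- records[records$comparison == cc, , drop = FALSE]
    data.frame(comparison = cc,
               n_up = sum(r$direction == "up"),
               n_down = sum(r$direction == "down"),
               stringsAsFactors = FALSE)
  }))
  out$n_total <- out$n_up + out$n_down
  out
}
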