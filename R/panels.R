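#' Default gene panels
#'
#' Curated panels of fatty-acid biosynthesis, degradation and elongation
#' genes and of muscle-fiber structural genes, by symbol. Symbol-to-id
#' mapping for a user's own annotation is the user's responsibility; genes
#' absent from the expression matrix are reported as missing, never
#' silently dropped.
#'
#' @return data.frame with columns `panel` and `gene_id`.
#' @export
default_panels <- function() {
  panels <- list(
    fatty_acid_biosynthesis = c(
      "SAST", "OXSM", "IQCAL", "IQCA1", "FAS", "FABD", "CCD57", "ACSL1",
      "ACSL3", "ACSL4", "ACSL5", "ACSL6", "ACBG1", "ACBG2", "ACAC"),
    fatty_acid_degradation = c(
      "THIM", "THIL", "THIK", "THIC", "SPAT9", "GNB1L", "GCDH", "ECI",
      "ECHP", "ECHM", "ECHA", "ECHB", "CPT2", "CPT1A", "CPT1B", "CPT1C",
      "CP4CA", "CP4AO", "CP4AB", "AL9A1", "AL7A1", "AL3A2", "ADH",
      "ACSL1", "ACSL3", "ACSL4", "ACSL5", "ACSL6", "ACOXL", "ACOX1",
      "ACOX3", "ACDSB", "ACBG2", "ACBG1", "ACADV", "ACADS", "A16A1"),
    fatty_acid_elongation = c(
      "THIM", "TECRL", "TECR", "SLMAP", "PPT1", "PPT2", "MECR", "HSDL1",
      "HACD", "ELOV", "ECHM", "ECHB", "ECHA", "DHB12", "BACH", "ACOT1",
      "ACOT2", "ACOT4"),
    muscle_fiber_structure = c("TPM1", "MYH1", "MYL6B", "TNNI1"))
  do.call(rbind, lapply(names(panels), function(p)
    data.frame(panel = p, gene_id = unique(panels[[p]]),
               stringsAsFactors = FALSE)))
}

#' Read a panel definition table
#'
#' TSV with columns `panel` and `gene_id`; gene ids must be unique within
#' each panel.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `panel` and `gene_id`.
#' @export
read_panels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  miss <- setdiff(c("panel", "gene_id"), names(df))
  if (length(miss))
    abort("panel table is missing column(s): %s", paste(miss, collapse = ", "))
  validate_panels(df)
}

validate_panels <- function(df) {
  if (nrow(df) == 0) abort("panel table is empty")
  dup <- df[duplicated(df[c("panel", "gene_id")]), , drop = FALSE]
  if (nrow(dup))
    abort("duplicate gene(s) within a panel: %s",
          paste(unique(paste(dup$panel, dup$gene_id, sep = "/")), collapse = ", "))
  df
}

#' Panel expression stability across regions
#'
#' Quantifies whether each panel gene's expression differs among regions,
#' replacing a purely visual comparison with a stated statistic: per gene,
#' region-mean FPKM, the coefficient of variation of those region means,
#' and a Kruskal-Wallis test (midranks for ties, chi-square
#' approximation) on replicate FPKM across regions, BH-corrected within
#' the panel. A gene is classed `variable` when its q-value is below
#' `q_threshold`, otherwise `stable`.
#'
#' @param fpkm FPKM matrix.
#' @param samples Sample sheet covering the matrix columns.
#' @param panels Panel table from [default_panels()] or [read_panels()].
#' @param q_threshold BH q ceiling for the `variable` class, default 0.05.
#' @return data.frame with one row per (panel, gene): region-mean columns
#'   `mean_<region>`, `cv`, `kw_stat`, `pvalue`, `qvalue`, `class` and
#'   `missing`. Genes absent from the matrix (and the degenerate all-zero
#'   case, whose CV is set to 0) carry `missing = TRUE`.
#' @export
panel_summary <- function(fpkm, samples, panels = default_panels(),
                          q_threshold = 0.05) {
  panels <- validate_panels(panels)
  samples <- validate_sample_table(samples)
  samples <- samples[samples$sample_id %in% colnames(fpkm), , drop = FALSE]
  groups <- samples_by_region(samples)
  regions <- names(groups)
  region_f <- factor(samples$region, levels = regions)
  ord <- samples$sample_id

  rows <- lapply(seq_len(nrow(panels)), function(i) {
    g <- panels$gene_id[i]
    out <- data.frame(panel = panels$panel[i], gene_id = g,
                      stringsAsFactors = FALSE)
    if (!g %in% rownames(fpkm)) {
      means <- rep(NA_real_, length(regions))
      out$cv <- NA_real_; out$kw_stat <- NA_real_; out$pvalue <- NA_real_
      out$missing <- TRUE
    } else {
      x <- fpkm[g, ord]
      means <- vapply(groups, function(ids) mean(fpkm[g, ids]), numeric(1))
      mu <- mean(means)
      out$cv <- if (mu == 0) 0 else stats::sd(means) / mu
      if (stats::var(x) == 0) {
        # indistinguishable across regions by construction
        out$kw_stat <- 0; out$pvalue <- 1
      } else {
        kw <- stats::kruskal.test(x, region_f)
        out$kw_stat <- unname(kw$statistic)
        out$pvalue <- kw$p.value
      }
      out$missing <- mu == 0
    }
    for (k in seq_along(regions))
      out[[paste0("mean_", regions[k])]] <- unname(means[k])
    out
  })
  res <- do.call(rbind, rows)
  res$qvalue <- NA_real_
  for (p in unique(res$panel)) {
    sel <- res$panel == p & !is.na(res$pvalue)
    res$qvalue[sel] <- stats::p.adjust(res$pvalue[sel], method = "BH")
  }
  res$class <- ifelse(is.na(res$qvalue), NA_character_,
                      ifelse(res$qvalue < q_threshold, "variable", "stable"))
  front <- c("panel", "gene_id", "missing", "cv", "kw_stat", "pvalue",
             "qvalue", "class")
  res[c(front, setdiff(names(res), front))]
}
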