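#' @keywords internal
"_PACKAGE"

# Stop with a message assembled from sprintf-style parts; no call in output.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Shared validator: a counts object is an integer-valued, non-negative
# matrix with unique, non-empty row (gene) and column (sample) names.
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("counts must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts must carry gene ids as rownames and sample ids as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    abort("duplicate gene id(s) in counts: %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    abort("duplicate sample id(s) in counts: %s", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    abort("counts must be non-negative integers; offending cell gene '%s', sample '%s' (value %s)",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
          format(counts[bad[1, , drop = FALSE]]))
  storage.mode(counts) <- "double"
  counts
}

validate_sample_table <- function(samples) {
  if (!is.data.frame(samples))
    abort("sample sheet must be a data.frame")
  need <- c("sample_id", "region", "animal_id")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    abort("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$region    <- as.character(samples$region)
  samples$animal_id <- as.character(samples$animal_id)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    abort("duplicate sample_id(s) in sample sheet: %s", paste(unique(dup), collapse = ", "))
  blank <- samples$sample_id[is.na(samples$region) | samples$region == ""]
  if (length(blank))
    abort("empty region for sample(s): %s", paste(blank, collapse = ", "))
  key <- paste(samples$animal_id, samples$region, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup))
    abort("duplicated (animal_id, region) pair(s): %s",
          paste(unique(gsub("\r", "/", dup)), collapse = ", "))
  if ("sex" %in% names(samples)) {
    samples$sex <- as.character(samples$sex)
    bad <- setdiff(unique(samples$sex[!is.na(samples$sex)]), c("M", "F"))
    if (length(bad))
      abort("sex must be 'M' or 'F'; found: %s", paste(bad, collapse = ", "))
  }
  samples
}

# Region labels in order of first appearance in the sample sheet.
region_levels <- function(samples) unique(samples$region)

# Split sample ids by region, preserving sheet order of regions.
samples_by_region <- function(samples) {
  split(samples$sample_id, factor(samples$region, levels = region_levels(samples)))
}
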