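#' Read a gene-level count matrix
#'
#' Reads a tab-delimited count matrix whose header row holds sample ids and
#' whose first column holds gene ids. Cells must be non-negative integers.
#' Gene and sample order are preserved as read; every downstream result
#' reports genes in this input order.
#'
#' @param path Path to a TSV file (UTF-8, `.` decimal, header row).
#' @return A numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames.
#' @seealso [write_counts()] for the inverse; the pair round-trips
#'   byte-identically on its own output.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2)
    abort("count matrix '%s' needs a gene id column plus >=1 sample column", path)
  gene_ids <- df[[1]]
  samples <- colnames(df)[-1]
  vals <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, samples))
  na <- which(is.na(vals) & !is.na(as.matrix(df[-1])), arr.ind = TRUE)
  if (nrow(na))
    abort("non-numeric count for gene '%s', sample '%s' in '%s'",
          gene_ids[na[1, 1]], samples[na[1, 2]], path)
  validate_counts(vals)
}

#' Write a count matrix as TSV
#'
#' @param counts Matrix as returned by [read_counts()] or
#'   [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample sheet
#'
#' CSV with columns `sample_id`, `region`, `animal_id` and optionally `sex`
#' (`M`/`F`). Sample ids must be unique, regions non-empty, and each
#' (animal, region) pair may appear at most once — one biopsy per animal per
#' muscle region.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with character columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  validate_sample_table(df)
}

#' Write a sample sheet as CSV
#' @param samples Sample sheet data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  samples <- validate_sample_table(samples)
  utils::write.csv(samples, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length table
#'
#' TSV with columns `gene_id` and `length` (total gene length in base
#' pairs, a positive integer). Coverage of the count matrix is checked at
#' join time by [compute_fpkm()], which names any missing gene.
#'
#' @param path Path to the TSV file.
#' @return A named numeric vector, lengths in bp keyed by gene id.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("gene_id", "length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort("gene-length table is missing column(s): %s", paste(miss, collapse = ", "))
  len <- suppressWarnings(as.numeric(df$length))
  validate_gene_lengths(stats::setNames(len, df$gene_id))
}

validate_gene_lengths <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == ""))
    abort("gene lengths must be named by gene id")
  dup <- names(lengths)[duplicated(names(lengths))]
  if (length(dup))
    abort("duplicate gene id(s) in gene-length table: %s",
          paste(unique(dup), collapse = ", "))
  bad <- names(lengths)[!is.finite(lengths) | lengths < 1 |
                          lengths != round(lengths)]
  if (length(bad))
    abort("gene length must be a positive integer (bp); offending gene(s): %s",
          paste(bad, collapse = ", "))
  lengths
}

#' Write a gene-length table as TSV
#' @param lengths Named numeric vector of lengths in bp.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_lengths <- function(lengths, path) {
  lengths <- validate_gene_lengths(lengths)
  df <- data.frame(gene_id = names(lengths), length = unname(lengths))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Generic TSV writer for result tables (header + rows, no quoting).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
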