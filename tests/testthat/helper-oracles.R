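# Independent oracles and fixture builders shared across test files.

# Linear-interpolation quantile with inclusive boundary, written out by
# hand so the RSG oracle does not lean on the implementation's quantile().
manual_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) x[n] else x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Brute-force re-evaluation of the three region-specificity criteria,
# looping over every (gene, region) pair.
brute_rsg <- function(E, retained, fold = 3, frac = 0.5, topq = 0.75,
                      agg = c("max", "mean")) {
  agg <- match.arg(agg)
  res <- NULL
  for (r in colnames(E)) {
    q <- manual_quantile(E[retained, r], topq)
    for (g in retained) {
      others <- E[g, setdiff(colnames(E), r)]
      a <- if (agg == "max") max(others) else mean(others)
      c1 <- E[g, r] >= fold * a
      c2 <- E[g, r] > frac * mean(others)
      c3 <- E[g, r] >= q
      res <- rbind(res, data.frame(
        gene_id = g, region = r, passes_fold = c1, passes_frac = c2,
        passes_top = c3, is_rsg = c1 && c2 && c3,
        stringsAsFactors = FALSE))
    }
  }
  rownames(res) <- NULL
  res
}

# Region-mean matrix of the worked 8-gene x 3-region example.
toy_region_means <- function() {
  m <- rbind(g1 = c(90, 5, 5), g2 = c(10, 10, 10), g3 = c(5, 80, 6),
             g4 = c(1, 1, 1), g5 = c(50, 40, 45), g6 = c(0.5, 0.1, 0.1),
             g7 = c(2, 2, 60), g8 = c(7, 6, 5))
  colnames(m) <- c("A", "B", "C")
  m
}

# Minimal two-region sample sheet: n replicates per region.
tiny_samples <- function(regions = c("X", "Y"), n = 2) {
  data.frame(
    sample_id = paste0(rep(regions, each = n), seq_len(n)),
    region = rep(regions, each = n),
    animal_id = paste0("a", rep(seq_len(n), length(regions))),
    stringsAsFactors = FALSE)
}

# Small fast simulation config used by pipeline-level unit tests.
tiny_sim_config <- function(seed = 1, ...) {
  simulation_config(n_regions = 3, n_animals = 4, n_genes = 300,
                    n_rsg = 5, seed = seed, ...)
}

# Direct NB count fixture for the DE stand-in: two groups of n samples,
# per-gene means mu (optionally scaled by fold in group A).
nb_two_group <- function(mu, n = 12, alpha = 0.1, fold_a = 1) {
  G <- length(mu)
  size <- if (alpha > 0) 1 / alpha else Inf
  A <- matrix(stats::rnbinom(G * n, mu = mu * fold_a, size = size), G, n)
  B <- matrix(stats::rnbinom(G * n, mu = mu, size = size), G, n)
  counts <- cbind(A, B)
  dimnames(counts) <- list(sprintf("g%04d", seq_len(G)),
                           c(paste0("X", seq_len(n)), paste0("Y", seq_len(n))))
  samples <- data.frame(sample_id = colnames(counts),
                        region = rep(c("X", "Y"), each = n),
                        animal_id = paste0("a", seq_len(2 * n)),
                        stringsAsFactors = FALSE)
  list(counts = counts, samples = samples)
}
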