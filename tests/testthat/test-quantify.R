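test_that("FPKM matches the printed formula and its invariances", {
  # c = 100, L = 1000 bp, T = 1e6 -> FPKM = 100 * 1e9 / (1e6 * 1000) = 100
  counts <- matrix(c(100, 999900, 0, 500000), 2, 2,
                   dimnames = list(c("G1", "G2"), c("s1", "s2")))
  lens <- c(G1 = 1000, G2 = 2000)
  f <- compute_fpkm(counts, lens)
  expect_equal(f["G1", "s1"], 100)
  # zero count -> zero FPKM regardless of length and depth
  expect_equal(f["G1", "s2"], 0)
  expect_identical(f == 0, counts == 0)

  # scale invariance: multiplying one sample's counts by 7
  scaled <- counts
  scaled[, "s1"] <- scaled[, "s1"] * 7
  expect_equal(compute_fpkm(scaled, lens)[, "s1"], f[, "s1"])

  # doubling a gene's length halves its FPKM everywhere
  f2 <- compute_fpkm(counts, c(G1 = 2000, G2 = 2000))
  expect_equal(f2["G1", ], f["G1", ] / 2)

  # empty sample is an error naming the sample
  bad <- counts; bad[, "s2"] <- 0
  expect_error(compute_fpkm(bad, lens), "zero total.*s2")
})

test_that("region means average each region's replicates", {
  samples <- tiny_samples(c("X", "Y"), n = 2)
  fpkm <- matrix(c(2, 4, 3, 3, 1, 1, 5, 5), nrow = 2, byrow = FALSE,
                 dimnames = list(c("G", "H"), samples$sample_id))
  rm <- region_means(fpkm, samples)
  expect_equal(rm["G", "X"], mean(c(2, 3)))
  expect_equal(rm["G", "Y"], mean(c(1, 5)))
  expect_equal(attr(rm, "n_replicates"), c(X = 2L, Y = 2L))
  # identical replicates reproduce the common value
  const <- matrix(7, 2, 4, dimnames = dimnames(fpkm))
  expect_true(all(region_means(const, samples) == 7))
})

test_that("12-replicate region means concentrate near the planted mean", {
  # NB mean 50, dispersion 0.1, 12 replicates: mean within 20% of 50 in
  # >= 95% of 200 simulations
  set.seed(101)
  samples <- tiny_samples(c("R1", "R2"), n = 12)
  within <- vapply(seq_len(200), function(i) {
    x <- matrix(stats::rnbinom(24, mu = 50, size = 10), 1, 24,
                dimnames = list("G", samples$sample_id))
    abs(region_means(x, samples)["G", "R1"] - 50) <= 0.2 * 50
  }, logical(1))
  expect_gte(mean(within), 0.95)
})

test_that("expressed sets partition into shared and unique as enumerated", {
  E <- rbind(g1 = c(2, 0.5), g2 = c(3, 3))
  colnames(E) <- c("X", "Y")
  res <- expressed_sets(E, quantify_params(expressed_threshold = 1))
  expect_setequal(res$per_region$X, c("g1", "g2"))
  expect_identical(res$per_region$Y, "g2")
  expect_identical(res$shared, "g2")
  expect_identical(res$unique$X, "g1")
  expect_length(res$unique$Y, 0)

  const <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), c("A", "B", "C")))
  rc <- expressed_sets(const)
  expect_length(rc$shared, 4)
  expect_true(all(lengths(rc$unique) == 0))

  pos <- matrix(0.01, 2, 2, dimnames = list(c("a", "b"), c("A", "B")))
  expect_length(expressed_sets(pos, quantify_params(expressed_threshold = 0))$shared, 2)
})

test_that("retention rules implement mean and all-replicates readings", {
  samples <- tiny_samples(c("X", "Y"), n = 3)
  # gene A: best-region replicates (1.2, 0.9, 1.2) -> mean 1.1
  fpkm <- rbind(A = c(1.2, 0.9, 1.2, 0.1, 0.1, 0.1),
                B = c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8),
                C = c(1.5, 1.5, 1.5, 0.1, 0.1, 0.1))
  colnames(fpkm) <- samples$sample_id
  rm <- region_means(fpkm, samples)

  mean_rule <- retain_genes(rm, fpkm, samples, quantify_params())
  expect_true("A" %in% mean_rule)     # mean 1.1 > 1
  expect_false("B" %in% mean_rule)    # means (0.2, 0.8) both <= 1
  expect_true("C" %in% mean_rule)

  strict <- retain_genes(rm, fpkm, samples,
                         quantify_params(retention_rule = "all_replicates_any_region"))
  expect_false("A" %in% strict)       # one replicate at 0.9 fails
  expect_true("C" %in% strict)

  # retained set shrinks monotonically as the threshold rises
  sizes <- vapply(c(0, 0.5, 1, 1.4, 2), function(thr)
    length(retain_genes(rm, fpkm, samples,
                        quantify_params(retention_threshold = thr))),
    integer(1))
  expect_true(all(diff(sizes) <= 0))
  # gene order of the input is preserved
  expect_identical(mean_rule, intersect(rownames(fpkm), mean_rule))
})
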