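test_that("comparison enumeration follows the six-cut convention", {
  pairs <- enumerate_comparisons(c("LD", "IM", "T", "BB", "GM", "QF"))
  expect_equal(nrow(pairs), 15)
  expect_identical(pairs$label[1], "BB_vs_GM")
  expect_identical(pairs$label[15], "LD_vs_QF")
  # each unordered pair exactly once
  key <- apply(pairs[c("region_a", "region_b")], 1,
               function(x) paste(sort(x), collapse = "|"))
  expect_equal(anyDuplicated(key), 0)

  expect_equal(nrow(enumerate_comparisons(c("A", "B"))), 1)
  expect_equal(nrow(enumerate_comparisons(c("A", "B", "C"))), 3)
  expect_error(enumerate_comparisons("A"), ">= 2 regions")
})

test_that("median-of-ratios size factors behave like the reference method", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(size_factors(m), c(s1 = 1, s2 = 1))

  m2 <- m; m2[, "s2"] <- m[, "s1"] * 2
  sf <- size_factors(m2)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)

  # an all-zero gene is ignored, not fatal
  m3 <- rbind(m2, g4 = c(0, 0))
  expect_equal(size_factors(m3), sf)

  allz <- matrix(c(0, 1, 1, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(allz), "pseudo-reference")
})

test_that("size factors match DESeq2's median-of-ratios on a random matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(404)
  # odd gene count: the arithmetic median of ratios and DESeq2's
  # exp(median(log ratio)) coincide exactly only at odd n
  m <- matrix(stats::rnbinom(306, mu = 50, size = 5), 51, 6,
              dimnames = list(sprintf("g%02d", 1:51), paste0("s", 1:6)))
  m[m == 0] <- 1  # keep every gene usable for both routes
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(size_factors(m), ref, tolerance = 1e-12)
})

test_that("the NB-Wald stand-in is symmetric and null on identical groups", {
  set.seed(505)
  d <- nb_two_group(mu = stats::rlnorm(100, log(50), 1))
  # identical per-gene counts in the two groups: no signal at all
  same <- d$counts
  same[, 13:24] <- same[, 1:12]
  res <- pairwise_de(same, d$samples,
                     list(region_a = "X", region_b = "Y"))
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$direction == "ns"))

  # swapping the pair negates fold changes and swaps directions
  fwd <- pairwise_de(d$counts, d$samples, list(region_a = "X", region_b = "Y"))
  rev <- pairwise_de(d$counts, d$samples, list(region_a = "Y", region_b = "X"))
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$pvalue, fwd$pvalue)
  expect_identical(rev$direction == "up", fwd$direction == "down")

  # BH q is monotone in p rank and q >= p at the largest p
  o <- order(fwd$pvalue)
  expect_true(all(diff(fwd$qvalue[o]) >= 0))
  expect_gte(fwd$qvalue[o][length(o)], fwd$pvalue[o][length(o)])

  expect_error(pairwise_de(d$counts[, c(1, 13:24)], d$samples,
                           list(region_a = "X", region_b = "Y")),
               ">= 2 samples")
})

test_that("genes with all-zero counts in both groups are null by convention", {
  set.seed(606)
  d <- nb_two_group(mu = c(rep(50, 10), 0, 0))
  res <- pairwise_de(d$counts, d$samples, list(region_a = "X", region_b = "Y"))
  zero <- rowSums(d$counts) == 0
  expect_true(all(res$pvalue[zero] == 1))
  expect_true(all(res$log2fc[zero] == 0))
})

test_that("planted 4-fold effects are recovered near log2FC = 2", {
  set.seed(707)
  mu <- stats::rlnorm(220, log(100), 1)
  d <- nb_two_group(mu, fold_a = c(rep(4, 20), rep(1, 200)))
  res <- pairwise_de(d$counts, d$samples, list(region_a = "X", region_b = "Y"))
  expect_equal(median(res$log2fc[1:20]), 2, tolerance = 0.15)
  expect_lt(abs(median(res$log2fc[1:20]) - 2), 0.3)
})

test_that("per-pair summaries match an independent recount", {
  set.seed(808)
  mu <- stats::rlnorm(150, log(80), 1)
  d <- nb_two_group(mu, fold_a = c(rep(5, 10), rep(1, 140)))
  recs <- list(
    pairwise_de(d$counts, d$samples, list(region_a = "X", region_b = "Y")),
    pairwise_de(d$counts, d$samples, list(region_a = "Y", region_b = "X")))
  sm <- summarize_de(recs)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$n_total, sm$n_up + sm$n_down)
  # oracle: filter-and-count over the raw records
  all_recs <- do.call(rbind, recs)
  for (i in 1:2) {
    r <- all_recs[all_recs$comparison == sm$comparison[i], ]
    expect_equal(sm$n_up[i], sum(r$qvalue < 0.05 & r$log2fc > 1))
    expect_equal(sm$n_down[i], sum(r$qvalue < 0.05 & r$log2fc < -1))
  }
  expect_equal(summarize_de(recs[1])$n_total,
               sum(recs[[1]]$direction != "ns"))
})
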