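# venex

Regional gene-expression analysis of muscle cuts from bulk RNA-seq
read counts.

`venex` is for researchers comparing transcriptomes across anatomically
defined muscle regions — e.g. the six venison cuts longissimus dorsi
(LD), intercostal muscles (IM), trapezius (T), biceps brachii (BB),
gluteus maximus (GM) and quadriceps femoris (QF), each sampled in the
same animals. Starting from a gene × sample count matrix (e.g. HTSeq
output), a sample sheet and a gene-length table, it provides the whole
downstream analysis as tested, reusable functions:

1. **Quantification** — FPKM per the standard formula
   `FPKM_gj = c_gj · 10^9 / (T_j · L_g)`, where `c_gj` is the gene's
   read count, `T_j` the sample's total gene-assigned reads and `L_g`
   the gene length in bp; per-region expressed-gene accounting
   (FPKM ≥ 1), shared and region-unique gene sets, and the retained
   analysis universe (region-mean FPKM > 1 in at least one region, with
   a stricter all-replicates rule as an option).
2. **Region-specific genes (RSGs)** — a gene is specific to region *r*
   when (i) its mean FPKM there is ≥ 3× the maximum of the other
   regions' means, (ii) it exceeds 50% of the other regions' average,
   and (iii) it sits within the top 25% of retained-gene expression in
   that region (linear-interpolation quantile, inclusive). Detected
   RSGs are z-scored and clustered (Euclidean, complete linkage).
3. **Differential expression** — all C(n,2) pairwise region
   comparisons (15 for six regions), median-of-ratios size factors, a
   transparent negative-binomial Wald stand-in test, BH correction per
   comparison, and significance at FDR < 0.05 with |log2FC| > 1.
4. **Gene panels** — fatty-acid biosynthesis/degradation/elongation and
   muscle-fiber structural gene panels compared across regions with a
   Kruskal–Wallis stability statistic and region-mean CVs.
5. **Synthetic data** — a negative-binomial simulator
   (`variance = µ + αµ²`) reproducing the 6-region × 12-animal design
   with planted RSG effects and a truth table, so sensitivity and
   false-positive rate of the whole pipeline are measurable.

## Worked example

```r
library(venex)

sim   <- simulate_dataset(simulation_config(seed = 1))   # 5000 genes, 72 samples
fpkm  <- compute_fpkm(sim$counts, sim$lengths)
rexpr <- region_means(fpkm, sim$samples)

retained <- retain_genes(rexpr, fpkm, sim$samples)
calls    <- detect_rsg(rexpr, retained)
hits     <- calls[calls$is_rsg, ]
table(hits$region)
#> BB GM IM LD QF  T
#> 20 20 20 20 20 20

truth_eval(hits[, c("gene_id", "region")], sim$truth)[c("sensitivity", "fpr")]
#> $sensitivity [1] 1      $fpr [1] 0

pairs <- enumerate_comparisons(unique(sim$samples$region))  # 15 comparisons
de    <- pairwise_de(sim$counts[retained, ], sim$samples, pairs[15, ])
summarize_de(de)
#>   comparison n_up n_down n_total
#> 1   LD_vs_QF   20     20      40
```

With the default simulation 4923 of 5000 genes are retained and all
120 planted region-specific genes (20 per region, 8-fold) are
recovered with no false positives; the LD vs QF comparison finds
exactly the 20 LD-planted genes up and the 20 QF-planted genes down.
`run_all(run_config(out_dir = "out"))` chains every stage and writes
the per-stage TSVs plus a `run_summary.json` echoing all thresholds.

## Acceptance script

`scripts/acceptance.R` regenerates the default synthetic study under a
given seed, runs the complete pipeline (quantification, retention, RSG
detection and clustering, all 15 pairwise comparisons, panel
summaries), logs the recovery summary, and writes the result JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
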