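# scRescale

Composition-aware integration of single-cell RNA-seq datasets across
platforms, tissues and batches.

## The problem

Atlas projects profile the same organs with different chemistries — deep
plate-based full-length protocols (SMART-Seq2-like read counts) and
shallow droplet-based protocols (10X-like UMI counts) — and the standard
preprocessing (log-normalization, then scaling every gene to unit
variance per dataset) silently assumes the datasets contain the same cell
types in the same proportions. They rarely do. A gene's per-dataset mean
and variance are composition-weighted mixtures over cell types, so when
one dataset is 50/50 over two types and the other is 80/20, the *same*
expression program lands on different numerical scales and a plain
concatenation clusters by platform instead of by biology.

`scRescale` corrects exactly that composition effect, for users who need
integrated atlas data whose within-dataset structure is untouched:

1. cluster each dataset (PCA + shared-nearest-neighbor Louvain);
2. align clusters across datasets in the joint PC space — anchor cluster
   `a` (the anchor is the larger dataset) aligns to the nearest of its
   five nearest query clusters `b` satisfying the spread criterion
   `‖Z̄_a − Z̄_b‖² < Q₀.₇₅(‖Z_{b,i} − Z̄_b‖²)`, with a proportion-matched
   subsampling retry for clusters whose abundance differs;
3. build composition-matched subsets from the aligned clusters (each pair
   contributes `min(n_a, n_b)` cells per side) and standardize every gene
   of each *whole* dataset by its subset moments, `(Y − m)/s`;
4. concatenate; search clustering resolutions over `[0.1, 2]²` and keep
   the pair minimising a neighbourhood mixing metric — falling back to
   plain concatenation (the baseline) whenever re-scaling does not
   strictly improve mixing, which is what prevents overcorrection when
   datasets share few or no cell types.

The toolkit also provides kNN label transfer with per-cell match scores,
the four standard integration metrics (mixing, local-structure
preservation, silhouette width, adjusted Rand index), sequential
integration of three or more datasets ordered by shared highly variable
genes, and a synthetic multi-platform generator for validation.

## Worked example

```r
library(scRescale)

# two synthetic platforms, same two cell types, 50/50 vs 80/20
sim <- simulate_pair(scenario("skewed_composition", seed = 0))
cfg <- rescale_config(resolution_step = 0.3, n_hvg = 1000, seed = 0)
res <- integrate_pair(sim$datasets[[1]], sim$datasets[[2]], cfg)
res
#> integration_result: 865 genes x 4000 cells, mixing 12.46, re-scaled at resolutions (1.0, 1.0)

res$baseline_mixing
#> [1] 130.5998

truth <- sim$truth$type[match(res$integrated$cell_ids, sim$truth$cell_id)]
evaluate_integration(res, truth, cfg)
#> integration metrics: mixing 12.46 | local structure 0.310 | ASW 0.572 | ARI 1.000
```

Reading: plain concatenation leaves the two platforms essentially
unmixed (mixing ≈ 131 on a scale that saturates at 153 for fully
separated batches and reaches ≈ 9–10 for perfectly interleaved ones);
after composition-matched re-scaling the platforms interleave (mixing
≈ 12) while a granularity-matched clustering of the integrated embedding
reproduces the true cell types exactly (ARI 1.0). With
`scenario("disjoint_types")` — no shared types at all — no cluster pair
passes the alignment criterion and the result is the untouched baseline
(`res$baseline_used` is `TRUE`).

A thin command-line wrapper covers the same pipeline
(`inst/cli/screscale simulate | integrate | transfer | evaluate`); run it
with no arguments for usage.

## Layout

| path | contents |
| --- | --- |
| `R/` | implementation (ingest/preprocess, embedding + clustering, alignment, re-scaling + resolution search, metrics, transfer, multi-dataset, simulator, CLI) |
| `tests/testthat/` | unit, property and end-to-end scenario tests with brute-force oracles |
| `vignettes/composition-aware-integration.Rmd` | the model, its assumptions, parameter choices and limits |
| `scripts/acceptance.R` | scenario-level reproduction script |
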