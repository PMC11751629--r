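---
title: "Two-stage text and transcriptome retrieval: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage text and transcriptome retrieval: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txscout)
```

# The retrieval problem

Public RNA-seq repositories hold hundreds of thousands of samples whose
usefulness is gated by two different notions of relatedness. Two experiments
can be *semantically* related -- their descriptions concern the same tissue,
disease or perturbation -- or *transcriptionally* related -- their expression
profiles look alike -- and the two do not always coincide. txscout treats a
corpus as two parallel embedding databases and searches them in sequence:

1. **Metadata space.** Each study's assembled text (title, summary, overall
   design) is embedded into a fixed-length vector; a free-text query is
   embedded the same way and the `n_search` closest studies by cosine
   similarity are retrieved.
2. **Transcriptome space.** Counts are averaged per experimental condition
   within each study, and each condition profile is projected to `k`
   dimensions with a seeded Gaussian Johnson--Lindenstrauss (JL) map. Each
   stage-1 study's condition vectors then act as queries of their own, and
   the `n_expand` closest other studies join the candidate list.

The six strategies in `retrieval_strategies()` are the crossings of the two
spaces (each alone, or one followed by expansion in either). `S_PLUS_T` --
text first, transcriptome expansion -- is the default: it anchors the result
set to the query's meaning, then pulls in studies whose molecular profiles
match the anchors even when their descriptions differ. Gene-set queries
enter transcriptome space as indicator pseudo-profiles over the gene
universe (`geneset_to_pseudoprofile()`): a deliberate, simple choice that
scores co-elevation of the set without any model fitting.

Retrieved samples can finally be screened for actual enrichment of a query
gene set (`filter_enriched()`): a single-sample GSEA score per sample, a
gene-permutation p-value, Benjamini--Hochberg adjustment, and an FDR cut.

# Models and scores

## Text embedding

All retrieval code depends only on the `text_embedder()` contract:
deterministic, length-`dim`, L2-normalized output (zero vector for empty
text). The built-in embedder is signed feature hashing: tokens are
lowercased alphanumeric runs, each token's bucket is its FNV-1a hash modulo
`dim`, its sign comes from the parity of a second FNV-1a pass with a
different offset basis, and signed token counts are accumulated and
normalized. This captures lexical overlap only -- synonyms do not match --
but it needs no model download, is bit-reproducible across platforms, and
makes the full pipeline testable. A pretrained sentence embedder can be
wrapped in `text_embedder()` without touching any other interface. The
default `dim = 384` mirrors the output width of compact sentence
transformers, so an adapter swap changes nothing structurally.

## Transcriptome embedding

Condition profiles are arithmetic means of member samples' count columns
(`aggregate_conditions()`). The default grouping key is the sample's
condition label, falling back to its source-name text and finally to the
sample id; corpora rarely state conditions in one canonical field, so the
rule is replaceable by any `function(samples_df) -> labels`.

The JL projector (`fit_jl_projector()`) is a dense `k x n_genes` matrix of
i.i.d. N(0, 1/k) draws, fully determined by `(n_genes, k, seed)`. Dense
Gaussian is the simplest construction satisfying the JL lemma and a single
seed reproduces it exactly, which the query path relies on: the projector is
never stored, only its parameters, and is refit at load time. The default
`k = 1000` keeps relative distance distortion tight (the suite checks that
at least 95% of pairwise distances among random count profiles are
preserved within 20%; the concentration at this width is in fact much
tighter).

Profiles are projected raw by default (`preprocess = "raw_mean"`), keeping
the map linear in counts; `"log1p_cpm"` is available when library-size or
dynamic-range robustness matters more than linearity. We do not guess any
further normalization.

## ssGSEA and the enrichment filter

For one sample, genes are ranked by expression (descending, ties broken by
gene id). With `r_j = n - position_j + 1` the descending rank weight, the
in-set running sum at position `i` is
`P_in(i) = sum_{j <= i, g_j in S} r_j^alpha / sum_{g in S} r_g^alpha`, the
out-of-set sum is `P_out(i) = #{j <= i, g_j not in S} / (n - |S|)`, and the
enrichment score is `ES = sum_i (P_in(i) - P_out(i))` -- the area between
the two running curves. `alpha = 0.25` is the conventional ssGSEA weighting
and the package default.

Significance uses a gene-label permutation null: each sample's ranking is
kept fixed and the set membership is redrawn uniformly (`n_perm` times,
shared across samples so p-values are comparable), with
`p = (1 + #{ES_perm >= ES_obs}) / (1 + n_perm)`. Adjustment is standard
Benjamini--Hochberg; the filter retains samples with `q <` the FDR
threshold (0.05 by default; a threshold of 1 disables the filter).

**Choosing `n_perm`.** The smallest attainable p-value is
`1 / (n_perm + 1)`. If a retrieval run returns `m` samples of which `k` are
truly enriched, BH keeps them only when `m * p_min / k < FDR`, i.e.
`n_perm + 1 > m / (k * FDR)`. At the pipeline's typical scale (one to two
hundred returned samples, a ~10% enriched fraction, FDR 0.05) this requires
several hundred permutations, so `run_config()` defaults to
`n_perm = 499`. The lower-level functions default to 199, which suits
smaller sample sets and the calibration analyses.

## Evaluation metrics and comparisons

`compare_strategies()` scores each query x strategy run with: returned and
enriched sample counts; the mean cosine between the query vector and
returned studies' metadata vectors (does the result stay on topic); and the
mean pairwise interpoint distance of returned studies in each space (L1
over JL vectors, L2 over metadata vectors -- how tight the retrieved set
is). Normalized Jaccard distance compares sample sets between strategies.
"Better" is strictly greater for counts and query cosine and strictly
smaller for interpoint distances; ties are reported separately, since an
outperformance proportion without a tie rule is ambiguous. Paired per-query
metrics get an exact Wilcoxon signed-rank test (full sign-assignment
enumeration for n <= 15; the two-sided p is the null probability of a
statistic at least as far from `n(n+1)/4` as observed, which for the
symmetric, tie-free null equals the classical doubled one-sided rule), and
pooled enriched/non-enriched counts get a two-sided Fisher exact test.
`grid_search()` maps (n_search, n_expand) cells to mean enriched counts and
mean query cosine and returns the grid without taking an argmax: the two
metrics trade off (wider searches return more enriched samples but drift
off topic), so the operating point is a judgement call, not an
optimization.

`n_search = 10` and `n_expand = 10` are pragmatic defaults at desk scale;
both are plain knobs and the grid search exists precisely because no single
value is canonical.

# The synthetic corpus

`generate_corpus()` plants structure that every pipeline stage can be
tested against: studies belong to latent topics; each topic owns a disjoint
vocabulary (study text is template sentences filled from it, ending in a
keyword line, as GEO summaries often do) and a disjoint gene signature;
counts are negative binomial (mean 50, size 10 -- overdispersed like real
bulk RNA-seq) with the signature multiplied by `fold_change` in each
study's treated condition. Defaults -- 5 topics, 10 studies per topic, 4
samples per study over 2 conditions, 2000 genes, 20-gene signatures,
fold change 4 -- define the benchmark conditions used by the acceptance
checks; `fold_change = 1` yields the matched null corpus for calibrating
the permutation filter. `make_query()` pairs a keyword-dense text query
with the topic's signature, mirroring how curated gene sets carry a text
description of their derivation.

What the generator does **not** emulate: library-size variation, batch
effects, correlated gene modules, single-cell sparsity, and -- most
importantly -- the lexical messiness of real metadata. Topic vocabularies
are disjoint by default (an overlap parameter adds shared confuser words),
so passing tests demonstrate that the machinery is correct and the planted
signal is recoverable; they do not certify retrieval quality on real
corpora, where a semantic embedder rather than the hash embedder will
usually be needed.

# Numerical and design decisions

- **Determinism everywhere.** Ranking ties break lexicographically (radix
  order, C locale); gene-rank ties break by gene id; every stochastic
  component (projector, permutations, generator) takes an explicit seed;
  repeated `build_index()` / `end_to_end()` runs from one `run_config()`
  are bit-identical. Embedding databases persist as a raw little-endian
  float64 stream plus a JSON sidecar (ids, dimensions, provenance) because
  byte-stable output is a contract here; the corpus itself stays HDF5.
- **Zero vectors.** An all-zero query is refused ("degenerate query"); an
  all-zero database row scores cosine 0 rather than NaN.
- **Empty-field handling.** Missing optional metadata datasets become empty
  strings; empty fields are skipped when text is assembled.
- **Permutation p-values** use the plus-one rule, so p = 0 is impossible
  and the null distribution is a proper p-value grid.
- **BH** is delegated to `stats::p.adjust` behind input validation;
  Fisher's exact test to `stats::fisher.test`. The Wilcoxon signed-rank
  test is implemented here because its contract (exact enumeration for
  n <= 15, normal approximation beyond, explicit degenerate-input error) is
  part of the package's reproducibility surface; `stats::wilcox.test`
  serves as a cross-check in the test suite.
- **Expansion excludes each seed from its own neighbour list** (self-hits
  are uninformative; the seed is already a stage-1 result) and collapses
  condition-level hits to studies keeping the best score.
- **Result ordering** lists stage-1 studies first (they answer the query
  directly), then stage-2 studies by score; "top-N studies" in the
  recovery analyses refers to this order.

# Problem sizes

The test suite and the acceptance script run entirely on generated data:
unit tests use corpora of roughly 300--500 genes and 50--80 samples; the
JL preservation check uses 50 profiles over 5000 genes at k = 1000; the
null-calibration corpus has 400 samples over 2000 genes with 199
permutations; the end-to-end recovery corpus is the generator default (200
samples, 2000 genes) with 499 permutations. These sizes were chosen so that
each check exercises the full code path at statistically meaningful scale
while the whole suite stays comfortably interactive.

# Known limitations

- The hash embedder is lexical; retrieval quality on real metadata depends
  on plugging in a sentence-embedding model via `text_embedder()`.
- The indicator pseudo-profile is a coarse stand-in for a transcriptome
  query; a user with an actual expression profile should project it
  directly with `project_vector()`.
- The gene-permutation null conditions on each sample's ranking; it tests
  "is this set higher-ranked than a random set of the same size", not
  cross-sample differential enrichment.
- Exhaustive cosine scan is the search contract. It is exact and fast into
  the hundreds of thousands of rows, but no approximate-NN index is
  provided; one could be added only if it reproduces exact results.
- No batch correction, gene-identifier mapping, or normalization beyond
  the two preprocessing options is attempted.
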