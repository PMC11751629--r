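# txscout

Two-stage text and transcriptome retrieval over RNA-seq corpora.

Large expression repositories (GEO / ARCHS4-style collections of uniformly
processed counts plus free-text metadata) are hard to search because
relevance has two faces: experiments can be related by what their
descriptions *say* (semantic similarity) or by what their transcriptomes
*do* (transcriptional similarity), and the two often disagree. txscout
indexes a corpus in both spaces and retrieves with a two-stage strategy
that combines them:

- **Metadata index** — one vector per study: the study's title, summary and
  overall design, embedded by a pluggable text embedder (a deterministic
  signed feature-hashing embedder with 384 dimensions is built in; any
  sentence-embedding model can be wrapped via `text_embedder()`).
- **Transcriptome index** — one vector per study × experimental condition:
  counts averaged per condition and projected to 1000 dimensions with a
  seeded Gaussian Johnson–Lindenstrauss transform, which approximately
  preserves pairwise distances between profiles.
- **Retrieval** — exhaustive cosine k-nearest-neighbour search. The default
  strategy `S_PLUS_T` retrieves `n_search` studies by text, then expands the
  candidate list with each hit's `n_expand` transcriptome neighbours; the
  other five crossings of the two spaces (`S_ONLY`, `T_ONLY`, `T_PLUS_S`,
  `S_PLUS_S`, `T_PLUS_T`) are available, with gene-set queries entering
  transcriptome space as indicator pseudo-profiles.
- **Enrichment filter** — per-sample single-sample GSEA (rank-weighted
  running sum, `ES = Σ_i (P_in(i) − P_out(i))`), gene-permutation p-values,
  Benjamini–Hochberg adjustment, and an FDR < 0.05 cut that keeps only
  samples statistically enriched for the query gene set.
- **Benchmarking** — enriched-sample counts, mean query–metadata cosine,
  mean interpoint distances (L1 in JL space, L2 in metadata space),
  normalized Jaccard distance between sample sets, win/tie/loss proportions
  with exact Wilcoxon and Fisher tests, and an (n_search, n_expand) grid
  search.
- **Synthetic corpora** — a seeded generator of ARCHS4-style HDF5 corpora
  with planted topics (disjoint vocabularies and negative-binomial counts
  carrying fold-change gene signatures), so the whole pipeline is testable
  without any download.

See `vignettes/two-stage-retrieval.Rmd` for the models, defaults and design
decisions.

## Worked example

```r
library(txscout)

gen <- generate_corpus(generator_config(seed = 8))   # 5 topics, 50 studies
dir <- tempfile(); dir.create(dir)
write_fixture(gen$corpus, file.path(dir, "corpus.h5"))

cfg <- run_config(file.path(dir, "corpus.h5"), out_dir = dir)
build_index(cfg)
#> index built: 50 studies (metadata), 100 condition profiles (transcriptome)

dbs    <- load_index(cfg)
corpus <- read_archs4_h5(cfg$corpus)
q <- make_query(gen$topics[[4]], seed = 2)
q$text
#> "autoimmune antigen gene expression in chemokine and lymphocyte"

res <- run_strategy(q, "S_PLUS_T", corpus, dbs, n_search = 10, n_expand = 10)
res
#> query_result [S_PLUS_T]: 10 stage-1 + 100 stage-2 hits -> 37 studies, 148 samples
head(res$stage1_hits, 3)
#>   study_id     score rank
#> 1 GSE00038 0.5345225    1
#> 2 GSE00035 0.5292377    2
#> 3 GSE00033 0.5106622    3

filt <- filter_enriched(res, corpus, q$gene_set, threshold = 0.05,
                        n_perm = 499, seed = 1)
filt$n_after
#> 20   # of 148 returned samples, only these are enriched at FDR < 0.05
head(filt$table[filt$table$enriched, ], 2)
#>  sample_id       es     p      q enriched
#>  GSM000122 996.9358 0.002 0.0148     TRUE
#>  GSM000124 994.0634 0.002 0.0148     TRUE
```

The stage-1 scores are cosine similarities between the query embedding and
study metadata embeddings (all ten stage-1 studies here carry the query's
planted topic). The enrichment table gives each sample's ssGSEA score, its
gene-permutation p-value (floor 1/(n_perm+1) = 0.002) and BH q-value; the
20 retained samples are the treated samples of the query topic's studies.

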