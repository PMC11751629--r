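#' Mean cosine similarity between a query and study metadata
#'
#' Measures whether retrieved studies stay semantically close to the query:
#' the arithmetic mean of cosine similarities between the query vector and
#' the metadata vectors of the listed studies.
#'
#' @param query_vec non-zero numeric query embedding.
#' @param study_ids non-empty character vector of study keys.
#' @param metadata_db metadata [embedding_db()].
#' @return numeric scalar in [-1, 1].
#' @export
mean_query_cosine <- function(query_vec, study_ids, metadata_db) {
  if (!length(study_ids)) stop("empty study list")
  rows <- match(study_ids, metadata_db$ids)
  if (anyNA(rows))
    stop("studies absent from metadata db: ",
         paste(study_ids[is.na(rows)], collapse = ", "))
  vv <- metadata_db$vectors[rows, , drop = FALSE]
  mean(.cosine_scores(as.numeric(query_vec), vv))
}

#' Mean interpoint distance of a set of embedding vectors
#'
#' The mean over all unordered pairs of the chosen distance. Used to
#' quantify how tightly a retrieved sample set clusters in transcriptome
#' (L1 over JL vectors) or semantic (distances over metadata vectors) space.
#'
#' @param vectors numeric matrix, one vector per row (>= 2 rows).
#' @param metric `"l1"`, `"l2"` or `"cosine_dist"` (1 - cosine similarity).
#' @return numeric scalar >= 0.
#' @export
mean_interpoint_distance <- function(vectors,
                                     metric = c("l1", "l2", "cosine_dist")) {
  metric <- match.arg(metric)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2)
    stop("undefined interpoint distance: need at least 2 vectors")
  if (metric %in% c("l1", "l2")) {
    d <- dist(vectors, method = if (metric == "l1") "manhattan" else
              "euclidean")
    return(mean(d))
  }
  nrm <- sqrt(rowSums(vectors^2))
  vn <- vectors / ifelse(nrm > 0, nrm, 1)
  cs <- tcrossprod(vn)
  mean(1 - cs[lower.tri(cs)])
}

#' Normalized Jaccard distance between two id sets
#'
#' `1 - |a intersect b| / |a union b|`; 0 for identical sets (and, by
#' convention, two empty sets), 1 for disjoint non-empty sets. Used to ask
#' how much two retrieval strategies' sample sets overlap.
#'
#' @param a,b character (or atomic) vectors, treated as sets.
#' @return numeric in [0, 1].
#' @export
normalized_jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test on `x - y`. Zero differences are dropped; absolute
#' differences are ranked (average ranks on ties) and the statistic is the
#' sum of ranks of positive differences. For n <= 15 the p-value is exact:
#' all 2^n sign assignments are enumerated and the p-value is the null
#' probability of a statistic at least as far from its mean n(n+1)/4 as the
#' observed one. For larger n a normal approximation with variance
#' `sum(r^2)/4` is used.
#'
#' @param x,y equal-length numeric vectors.
#' @return list with `statistic` (signed-rank sum W) and `p.value`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("degenerate test: all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 15) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W <- as.numeric(signs %*% r)
    p <- mean(abs(W - mu) >= abs(w - mu) - 1e-12)
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    p <- 2 * pnorm(-abs(w - mu) / sigma)
  }
  list(statistic = w, p.value = min(p, 1))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables (with the observed
#' margins) no more probable than the observed one. Any zero margin gives
#' p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

.metric_directions <- c(n_returned = 1, n_enriched = 1, mean_query_cosine = 1,
                        mean_l1_transcriptome = -1,
                        mean_semantic_distance = -1)

.result_metrics <- function(result, query, corpus, dbs, enrich) {
  studies <- result$studies
  qvec <- embed_query(query$text, dbs$embedder)
  mqc <- if (length(studies)) mean_query_cosine(qvec, studies, dbs$metadata)
         else NA_real_
  # transcriptome spread of the returned studies' condition vectors
  study_of <- .study_map(dbs$transcriptome)
  trows <- which(study_of %in% studies)
  ml1 <- if (length(trows) >= 2)
    mean_interpoint_distance(dbs$transcriptome$vectors[trows, , drop = FALSE],
                             "l1") else NA_real_
  mrows <- match(studies, dbs$metadata$ids)
  msd <- if (length(mrows) >= 2)
    mean_interpoint_distance(dbs$metadata$vectors[mrows, , drop = FALSE],
                             "l2") else NA_real_
  filt <- filter_enriched(result, corpus, query$gene_set,
                          threshold = enrich$fdr, alpha = enrich$alpha,
                          n_perm = enrich$n_perm, seed = enrich$seed)
  data.frame(n_returned = length(result$samples),
             n_enriched = filt$n_after,
             mean_query_cosine = mqc,
             mean_l1_transcriptome = ml1,
             mean_semantic_distance = msd)
}

#' Benchmark retrieval strategies over a query set
#'
#' Runs every strategy on every query and records, per run: the number of
#' returned samples, the number of those enriched for the query gene set at
#' the chosen FDR, the mean query-metadata cosine, and the mean interpoint
#' distances of the returned studies in transcriptome (L1) and semantic (L2)
#' space. For every ordered strategy pair and metric it then reports the
#' proportion of queries where the first strategy was strictly better
#' (higher for counts and query cosine, lower for interpoint distances),
#' strictly worse, or tied, plus a paired Wilcoxon signed-rank p-value and a
#' Fisher exact p-value on pooled enriched/non-enriched sample counts.
#'
#' @param queries list of queries, each `list(id, text, gene_set)`.
#' @param strategies character vector of strategy ids to compare.
#' @param corpus,dbs as in [run_strategy()].
#' @param n_search,n_expand retrieval breadth parameters.
#' @param enrich list of enrichment settings
#'   (`alpha`, `n_perm`, `seed`, `fdr`).
#' @return list with `per_query` (one row per query x strategy) and
#'   `summary` (one row per strategy pair x metric).
#' @export
compare_strategies <- function(queries, strategies, corpus, dbs,
                               n_search = 10, n_expand = 10,
                               enrich = list(alpha = 0.25, n_perm = 99,
                                             seed = 1, fdr = 0.05)) {
  stopifnot(length(queries) >= 1)
  rows <- list()
  for (q in queries) {
    for (st in strategies) {
      res <- tryCatch(
        run_strategy(list(text = q$text, gene_set = q$gene_set), st,
                     corpus, dbs, n_search, n_expand),
        error = function(e) {
          warning("strategy ", st, " failed on query ", q$id, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) {
        rows[[length(rows) + 1]] <- data.frame(
          query_id = q$id, strategy = st, failed = TRUE,
          n_returned = NA_integer_, n_enriched = NA_integer_,
          mean_query_cosine = NA_real_, mean_l1_transcriptome = NA_real_,
          mean_semantic_distance = NA_real_, stringsAsFactors = FALSE)
        next
      }
      m <- .result_metrics(res, q, corpus, dbs, enrich)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(query_id = q$id, strategy = st, failed = FALSE,
                   stringsAsFactors = FALSE), m)
    }
  }
  per_query <- do.call(rbind, rows)
  rownames(per_query) <- NULL

  summ <- list()
  metrics <- names(.metric_directions)
  for (a in strategies) for (b in strategies) {
    pa <- per_query[per_query$strategy == a & !per_query$failed, ]
    pb <- per_query[per_query$strategy == b & !per_query$failed, ]
    common <- intersect(pa$query_id, pb$query_id)
    pa <- pa[match(common, pa$query_id), ]
    pb <- pb[match(common, pb$query_id), ]
    for (met in metrics) {
      dir <- .metric_directions[[met]]
      va <- pa[[met]] * dir
      vb <- pb[[met]] * dir
      ok <- !is.na(va) & !is.na(vb)
      va <- va[ok]; vb <- vb[ok]
      nq <- length(va)
      if (!nq) next
      wil <- tryCatch(wilcoxon_signed_rank(va, vb)$p.value,
                      error = function(e) NA_real_)
      fis <- if (met == "n_enriched") {
        tb <- rbind(c(sum(pa$n_enriched[ok]),
                      sum(pa$n_returned[ok] - pa$n_enriched[ok])),
                    c(sum(pb$n_enriched[ok]),
                      sum(pb$n_returned[ok] - pb$n_enriched[ok])))
        fisher_exact_2x2(tb)
      } else NA_real_
      summ[[length(summ) + 1]] <- data.frame(
        strategy = a, versus = b, metric = met, n_queries = nq,
        win = mean(va > vb), tie = mean(va == vb), loss = mean(va < vb),
        wilcoxon_p = wil, fisher_p = fis, stringsAsFactors = FALSE)
    }
  }
  summary <- if (length(summ)) do.call(rbind, summ) else
    data.frame(strategy = character(), versus = character(),
               metric = character(), n_queries = integer(), win = numeric(),
               tie = numeric(), loss = numeric(), wilcoxon_p = numeric(),
               fisher_p = numeric(), stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(per_query = per_query, summary = summary)
}

#' Grid search over retrieval breadth parameters
#'
#' Evaluates every (n_search, n_expand) cell on a set of tuning queries,
#' reporting the mean number of enriched samples and the mean query-metadata
#' cosine per cell. No argmax is taken: the grid is returned for inspection,
#' since the two metrics trade off and the right operating point depends on
#' the downstream use.
#'
#' @param queries tuning queries as in [compare_strategies()].
#' @param n_search_grid,n_expand_grid integer vectors of grid values.
#' @param corpus,dbs as in [run_strategy()].
#' @param strategy strategy id evaluated over the grid.
#' @param enrich enrichment settings as in [compare_strategies()].
#' @return data.frame with one row per grid cell: `n_search`, `n_expand`,
#'   `mean_n_enriched`, `mean_n_returned`, `mean_query_cosine`, `failed`.
#' @export
grid_search <- function(queries, n_search_grid, n_expand_grid, corpus, dbs,
                        strategy = "S_PLUS_T",
                        enrich = list(alpha = 0.25, n_perm = 99, seed = 1,
                                      fdr = 0.05)) {
  if (!length(n_search_grid) || !length(n_expand_grid))
    stop("parameter grid must be non-empty")
  cells <- expand.grid(n_search = n_search_grid, n_expand = n_expand_grid)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ns <- cells$n_search[i]; ne <- cells$n_expand[i]
    cell <- tryCatch({
      pq <- compare_strategies(queries, strategy, corpus, dbs,
                               n_search = ns, n_expand = ne,
                               enrich = enrich)$per_query
      data.frame(n_search = ns, n_expand = ne,
                 mean_n_enriched = mean(pq$n_enriched, na.rm = TRUE),
                 mean_n_returned = mean(pq$n_returned, na.rm = TRUE),
                 mean_query_cosine = mean(pq$mean_query_cosine, na.rm = TRUE),
                 failed = anyNA(pq$n_enriched))
    }, error = function(e)
      data.frame(n_search = ns, n_expand = ne, mean_n_enriched = NA_real_,
                 mean_n_returned = NA_real_, mean_query_cosine = NA_real_,
                 failed = TRUE))
    out[[i]] <- cell
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
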