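#' Single-sample GSEA enrichment score
#'
#' Genes are ranked by expression, highest first (ties broken by gene id for
#' determinism). Walking down the ranking, an in-set running sum accumulates
#' rank weights of member genes, `P_in(i) = sum_{j<=i, g_j in S} r_j^alpha /
#' sum_{g in S} r_g^alpha` with `r_j = n - position_j + 1` the descending
#' rank weight, while the out-of-set sum accumulates `1/(n - |S|)` per
#' non-member. The enrichment score is the sum over all positions of
#' `P_in - P_out` (the area between the two running sums), positive when set
#' genes concentrate at the top of the ranking.
#'
#' @param expr named numeric vector of expression values over the gene
#'   universe (names are gene ids), all finite.
#' @param set a [gene_set()]; must overlap the universe and not cover it
#'   entirely.
#' @param alpha non-negative rank-weighting exponent; 0 weights all ranks
#'   equally, the conventional 0.25 up-weights extreme ranks mildly.
#' @return numeric enrichment score.
#' @export
ssgsea_es <- function(expr, set, alpha = 0.25) {
  stopifnot(inherits(set, "gene_set"), alpha >= 0)
  gene_ids <- names(expr)
  if (is.null(gene_ids)) stop("expr must be named by gene id")
  if (any(!is.finite(expr))) stop("expr must be finite")
  member <- gene_ids %in% set$genes
  m <- sum(member)
  n <- length(expr)
  if (m == 0) stop("gene set '", set$name, "' does not overlap the universe")
  if (m == n) stop("gene set covers the whole universe; score undefined")
  ord <- order(-expr, gene_ids, method = "radix")
  .es_from_order(member[ord], n, m, alpha)
}

# core running-sum evaluation given set membership in ranked order
.es_from_order <- function(mem_sorted, n, m, alpha) {
  rw <- (n:1)^alpha
  win <- rw * mem_sorted
  p_in <- cumsum(win) / sum(win)
  p_out <- cumsum(!mem_sorted) / (n - m)
  sum(p_in - p_out)
}

#' ssGSEA scores for every sample of a count matrix
#'
#' @param counts genes x samples numeric matrix with gene ids as rownames.
#' @param set a [gene_set()].
#' @param alpha rank-weighting exponent, see [ssgsea_es()].
#' @param samples optional character vector restricting/ordering the columns
#'   scored (default: all columns).
#' @return named numeric vector of enrichment scores, one per sample.
#' @export
ssgsea_matrix <- function(counts, set, alpha = 0.25, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(samples)) samples <- colnames(counts)
  missing <- setdiff(samples, colnames(counts))
  if (length(missing))
    stop("samples absent from counts: ", paste(missing, collapse = ", "))
  vapply(samples, function(s) {
    tryCatch(ssgsea_es(counts[, s], set, alpha),
             error = function(e) stop("ssGSEA failed for sample ", s, ": ",
                                      conditionMessage(e)))
  }, numeric(1))
}

#' Gene-permutation p-values for ssGSEA scores
#'
#' The null keeps each sample's expression ranking fixed and permutes which
#' genes carry the set label: for each of `n_perm` draws, a random subset of
#' the universe of the same size as the observed overlap is scored, and the
#' p-value is `(1 + #{ES_perm >= ES_obs}) / (1 + n_perm)`. The same
#' permutations are shared across samples, so per-sample p-values are
#' comparable and the whole computation is seeded.
#'
#' @inheritParams ssgsea_matrix
#' @param n_perm number of permutations (>= 1); 199 gives a p-value grid of
#'   1/200.
#' @param seed RNG seed for the shared permutations.
#' @return list with `es` (observed scores) and `p` (p-values in (0, 1]),
#'   both named by sample.
#' @export
permutation_pvalues <- function(counts, set, alpha = 0.25, n_perm = 199,
                                seed = 1, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(samples)) samples <- colnames(counts)
  gene_ids <- rownames(counts)
  n <- length(gene_ids)
  member <- gene_ids %in% set$genes
  m <- sum(member)
  if (m == 0) stop("gene set '", set$name, "' does not overlap the universe")
  if (m == n) stop("gene set covers the whole universe")
  perm_members <- withr::with_seed(seed, lapply(seq_len(n_perm), function(b) {
    flag <- logical(n)
    flag[sample.int(n, m)] <- TRUE
    flag
  }))
  rw <- (n:1)^alpha
  es <- numeric(length(samples))
  p <- numeric(length(samples))
  for (si in seq_along(samples)) {
    expr <- counts[, samples[si]]
    ord <- order(-expr, gene_ids, method = "radix")
    obs <- .es_from_order(member[ord], n, m, alpha)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (.es_from_order(perm_members[[b]][ord], n, m, alpha) >= obs)
        exceed <- exceed + 1L
    }
    es[si] <- obs
    p[si] <- (1 + exceed) / (1 + n_perm)
  }
  names(es) <- names(p) <- samples
  list(es = es, p = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up FDR adjustment, `q_(i) = min_{j>=i} (m p_(j) / j)`
#' capped at 1 and mapped back to input order. Input p-values must lie in
#' (0, 1].
#'
#' @param pvals numeric vector of p-values.
#' @return numeric vector of q-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Filter retrieved samples by gene-set enrichment
#'
#' Scores every sample returned by a retrieval run with ssGSEA, computes
#' gene-permutation p-values and BH q-values, and retains the samples with
#' `q < threshold` -- the FDR filter that keeps only samples statistically
#' enriched for the query gene set.
#'
#' @param result a `query_result` from [run_strategy()].
#' @param corpus the [tx_corpus()] the result was retrieved from.
#' @param set the query [gene_set()].
#' @param threshold FDR threshold, default 0.05; a threshold of 1 disables
#'   the filter (every sample is retained).
#' @param alpha,n_perm,seed see [permutation_pvalues()].
#' @return list with `table` (data.frame: sample_id, es, p, q, enriched),
#'   `retained` (sample ids with q < threshold), `n_before`, `n_after`.
#' @export
filter_enriched <- function(result, corpus, set, threshold = 0.05,
                            alpha = 0.25, n_perm = 199, seed = 1) {
  stopifnot(inherits(result, "query_result"), inherits(corpus, "tx_corpus"))
  samples <- result$samples
  if (!length(samples)) {
    warning("query result contains no samples; nothing to filter")
    tab <- data.frame(sample_id = character(), es = numeric(),
                      p = numeric(), q = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE)
    return(list(table = tab, retained = character(),
                n_before = 0L, n_after = 0L))
  }
  missing <- setdiff(samples, corpus$samples$sample_id)
  if (length(missing))
    stop("result samples absent from corpus: ", paste(missing, collapse = ", "))
  pv <- permutation_pvalues(corpus$counts, set, alpha = alpha,
                            n_perm = n_perm, seed = seed, samples = samples)
  q <- bh_adjust(pv$p)
  tab <- data.frame(sample_id = samples, es = unname(pv$es),
                    p = unname(pv$p), q = q,
                    enriched = if (threshold >= 1) rep(TRUE, length(q))
                               else q < threshold,
                    stringsAsFactors = FALSE)
  list(table = tab, retained = tab$sample_id[tab$enriched],
       n_before = nrow(tab), n_after = sum(tab$enriched))
}
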