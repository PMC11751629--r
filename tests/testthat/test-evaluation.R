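test_that("mean query-metadata cosine matches direct computation", {
  db <- embedding_db(c("A", "B"), rbind(c(1, 0), c(0, 1)))
  expect_equal(mean_query_cosine(c(1, 0), c("A", "B"), db), 0.5)
  expect_equal(mean_query_cosine(c(1, 0), c("A", "A"), db), 1)
  expect_error(mean_query_cosine(c(1, 0), character(), db), "empty")
  withr::with_seed(23, {
    for (rep in 1:30) {
      vecs <- matrix(rnorm(12), nrow = 4)
      dbr <- embedding_db(paste0("s", 1:4), vecs)
      q <- rnorm(3)
      want <- mean(sapply(1:4, function(i)
        sum(q * vecs[i, ]) / sqrt(sum(q^2) * sum(vecs[i, ]^2))))
      expect_equal(mean_query_cosine(q, paste0("s", 1:4), dbr), want,
                   tolerance = 1e-9)
    }
  })
})

test_that("mean interpoint distance matches exhaustive pair enumeration", {
  expect_equal(mean_interpoint_distance(rbind(c(0, 0), c(3, 4)), "l1"), 7)
  expect_equal(mean_interpoint_distance(rbind(c(0, 0), c(3, 4)), "l2"), 5)
  expect_equal(mean_interpoint_distance(rbind(c(1, 2), c(1, 2)), "l1"), 0)
  expect_error(mean_interpoint_distance(rbind(c(1, 2)), "l1"),
               "undefined interpoint")
  withr::with_seed(29, {
    for (metric in c("l1", "l2", "cosine_dist")) {
      for (rep in 1:20) {
        vecs <- matrix(rnorm(sample(3:8, 1) * 4, sd = 2), ncol = 4)
        expect_equal(mean_interpoint_distance(vecs, metric),
                     oracle_interpoint(vecs, metric), tolerance = 1e-9)
      }
    }
  })
})

test_that("normalized Jaccard distance behaves as a metric on sets", {
  expect_equal(normalized_jaccard_distance(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(normalized_jaccard_distance(letters[1:3], letters[1:3]), 0)
  expect_equal(normalized_jaccard_distance("a", "b"), 1)
  expect_equal(normalized_jaccard_distance(character(), character()), 0)
  withr::with_seed(37, {
    for (rep in 1:50) {
      a <- sample(10, sample(0:6, 1))
      b <- sample(10, sample(0:6, 1))
      cc <- sample(10, sample(0:6, 1))
      dab <- normalized_jaccard_distance(a, b)
      expect_equal(dab, normalized_jaccard_distance(b, a))
      expect_gte(dab, 0); expect_lte(dab, 1)
      expect_lte(dab, normalized_jaccard_distance(a, cc) +
                   normalized_jaccard_distance(cc, b) + 1e-12)
    }
  })
})

test_that("signed-rank test is exact by enumeration for small n", {
  # all-positive differences, n = 3: only {all +, all -} are as extreme
  res <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(res$p.value, 0.25)
  expect_equal(res$statistic, 6)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "degenerate test")
  expect_equal(wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))$p.value,
               oracle_wilcoxon(c(2, 3, 4), c(1, 1, 1)))
})

test_that("signed-rank p-values agree with the reference implementation", {
  withr::with_seed(41, {
    for (rep in 1:100) {
      n <- sample(5:12, 1)
      x <- rnorm(n); y <- rnorm(n)     # continuous: no ties, no zeros
      got <- wilcoxon_signed_rank(x, y)
      ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                 exact = TRUE))
      expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
      expect_equal(got$p.value, oracle_wilcoxon(x, y), tolerance = 1e-12)
    }
    # large-n branch: normal approximation without continuity correction
    x <- rnorm(25); y <- rnorm(25)
    got <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                              correct = FALSE)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
  })
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(2, 0), c(0, 2))), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(3, 2))), 1)  # zero margin
  expect_error(fisher_exact_2x2(rbind(c(-1, 1), c(1, 1))), "non-negative")
  withr::with_seed(43, {
    for (rep in 1:100) {
      tab <- matrix(rpois(4, 4), 2)
      expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab),
                   tolerance = 1e-9)
    }
  })
})

test_that("strategy comparison reports wins, ties and losses that sum to one", {
  sb <- small_bench()
  queries <- lapply(1:3, function(ti) {
    q <- make_query(sb$gen$topics[[ti]], seed = ti)
    list(id = paste0("q", ti), text = q$text, gene_set = q$gene_set)
  })
  rep <- compare_strategies(queries, c("S_ONLY", "S_PLUS_T"), sb$corpus,
                            sb$dbs, n_search = 3, n_expand = 3,
                            enrich = list(alpha = 0.25, n_perm = 49,
                                          seed = 1, fdr = 0.05))
  expect_true(all(rep$per_query$n_enriched <= rep$per_query$n_returned))
  sums <- rep$summary$win + rep$summary$tie + rep$summary$loss
  expect_equal(sums, rep(1, nrow(rep$summary)))
  # a strategy against itself is all ties
  self <- rep$summary[rep$summary$strategy == rep$summary$versus, ]
  expect_true(all(self$win == 0 & self$tie == 1 & self$loss == 0))
  # expansion returns a superset of studies, so counts never shrink
  pq <- rep$per_query
  nr_s <- pq$n_returned[pq$strategy == "S_ONLY"]
  nr_st <- pq$n_returned[pq$strategy == "S_PLUS_T"]
  expect_true(all(nr_st >= nr_s))
})

test_that("two-stage retrieval enriches at least as many samples as one-stage on most queries", {
  sb <- small_bench()
  queries <- lapply(1:3, function(ti) {
    q <- make_query(sb$gen$topics[[ti]], seed = 10 + ti)
    list(id = paste0("q", ti), text = q$text, gene_set = q$gene_set)
  })
  rep <- compare_strategies(queries, c("S_PLUS_T", "S_ONLY"), sb$corpus,
                            sb$dbs, n_search = 3, n_expand = 4,
                            enrich = list(alpha = 0.25, n_perm = 99,
                                          seed = 2, fdr = 0.1))
  row <- rep$summary[rep$summary$strategy == "S_PLUS_T" &
                       rep$summary$versus == "S_ONLY" &
                       rep$summary$metric == "n_enriched", ]
  expect_gte(row$win + row$tie, 0.7)
})

test_that("grid search cells match direct runs and grow with search breadth", {
  sb <- small_bench()
  q <- make_query(sb$gen$topics[[2]], seed = 9)
  queries <- list(list(id = "q1", text = q$text, gene_set = q$gene_set))
  enrich <- list(alpha = 0.25, n_perm = 49, seed = 3, fdr = 0.05)

  g11 <- grid_search(queries, 3, 2, sb$corpus, sb$dbs, enrich = enrich)
  expect_identical(nrow(g11), 1L)
  direct <- compare_strategies(queries, "S_PLUS_T", sb$corpus, sb$dbs,
                               n_search = 3, n_expand = 2,
                               enrich = enrich)$per_query
  expect_equal(g11$mean_n_enriched, direct$n_enriched)
  expect_equal(g11$mean_query_cosine, direct$mean_query_cosine)

  # n_expand = 0 row reproduces the stage-1-only strategy
  g <- grid_search(queries, c(2, 4), c(0, 2), sb$corpus, sb$dbs,
                   enrich = enrich)
  s_only <- compare_strategies(queries, "S_ONLY", sb$corpus, sb$dbs,
                               n_search = 2, n_expand = 0,
                               enrich = enrich)$per_query
  row0 <- g[g$n_search == 2 & g$n_expand == 0, ]
  expect_equal(row0$mean_n_enriched, s_only$n_enriched)
  # returned-sample counts are monotone in n_search within each n_expand
  for (ne in unique(g$n_expand)) {
    sub <- g[g$n_expand == ne, ]
    sub <- sub[order(sub$n_search), ]
    expect_true(all(diff(sub$mean_n_returned) >= 0))
  }
  expect_error(grid_search(queries, integer(), 1, sb$corpus, sb$dbs),
               "non-empty")
})
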