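test_that("cosine kNN scores and orders hits correctly on worked examples", {
  db <- embedding_db(c("x", "y"), rbind(c(1, 0), c(0, 1)))
  hits <- knn_cosine(c(1, 0), db, 2)
  expect_identical(hits$id, c("x", "y"))
  expect_equal(hits$score, c(1, 0))

  one <- embedding_db("r", rbind(c(2, 1, 2)))
  expect_equal(knn_cosine(c(1, 2, 2), one, 1)$score, 8 / 9)

  # self-query returns itself first with score 1
  sb <- small_bench()
  mdb <- sb$dbs$metadata
  hits <- knn_cosine(mdb$vectors[3, ], mdb, 3)
  expect_identical(hits$id[1], mdb$ids[3])
  expect_equal(hits$score[1], 1, tolerance = 1e-12)

  expect_error(knn_cosine(c(0, 0), db, 1), "degenerate query")
  expect_error(knn_cosine(c(1, 0), embedding_db(character(),
                                                matrix(0, 0, 2)), 1), "empty")
  # n beyond db size returns all; ties break lexicographically
  tie <- embedding_db(c("b", "a"), rbind(c(1, 0), c(1, 0)))
  hits <- knn_cosine(c(1, 0), tie, 10)
  expect_identical(hits$id, c("a", "b"))
})

test_that("cosine kNN agrees with an exhaustive-scan oracle on random dbs", {
  withr::with_seed(21, {
    for (rep in 1:100) {
      nr <- sample(2:9, 1); d <- sample(2:5, 1)
      vecs <- matrix(rnorm(nr * d), nrow = nr)
      ids <- paste0("id", sample(100, nr))
      q <- rnorm(d)
      n <- sample(nr, 1)
      got <- knn_cosine(q, embedding_db(ids, vecs), n)
      want <- oracle_knn(q, vecs, ids, n)
      expect_identical(got$id, want$id)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  })
})

test_that("semantic search retrieves planted-topic studies", {
  sb <- small_bench()
  # query equal to a study's text ranks that study first
  txt <- assemble_study_text(sb$corpus$studies[5, ])
  hits <- search_semantic(txt, sb$dbs$metadata, sb$dbs$embedder, 3)
  expect_identical(hits$study_id[1], sb$corpus$studies$study_id[5])

  q <- make_query(sb$gen$topics[[2]], seed = 6)
  hits <- search_semantic(q$text, sb$dbs$metadata, sb$dbs$embedder, 4)
  expect_gte(mean(sb$topic_of[hits$study_id] == "topic02"), 0.75)
  expect_identical(nrow(search_semantic(q$text, sb$dbs$metadata,
                                        sb$dbs$embedder, 1)), 1L)
  # scores are non-increasing
  expect_true(all(diff(hits$score) <= 1e-12))
})

test_that("transcriptome search finds signature-bearing studies and collapses conditions", {
  sb <- small_bench()
  q <- make_query(sb$gen$topics[[1]], seed = 2)
  hits <- search_transcriptome(q$gene_set, sb$dbs$transcriptome,
                               sb$dbs$projector, sb$corpus$gene_ids,
                               n_search = 4)
  expect_identical(sb$topic_of[[hits$study_id[1]]], "topic01")
  expect_false(anyDuplicated(hits$study_id) > 0)
  # n beyond the db returns every study exactly once
  all_hits <- search_transcriptome(q$gene_set, sb$dbs$transcriptome,
                                   sb$dbs$projector, sb$corpus$gene_ids,
                                   n_search = 1000)
  expect_setequal(all_hits$study_id, sb$corpus$studies$study_id)
})

test_that("expansion excludes seeds, honours n_expand = 0, and unions neighbourhoods", {
  sb <- small_bench()
  seeds <- data.frame(study_id = sb$corpus$studies$study_id[1:2])
  ex <- expand_hits(seeds, "transcriptome", sb$dbs, n_expand = 3)
  expect_true(all(ex$seed_study %in% seeds$study_id))
  expect_false(any(ex$study_id == ex$seed_study))
  expect_identical(
    nrow(expand_hits(seeds, "transcriptome", sb$dbs, n_expand = 0)), 0L)

  # an exact transcriptome duplicate of the seed comes back with score 1
  db <- sb$dbs$transcriptome
  v <- db$vectors
  dup <- rbind(v, v[1, , drop = FALSE])
  dup_db <- embedding_db(
    c(db$ids, "DUP||c"), dup,
    meta = modifyList(db$meta, list(
      study_id = c(unlist(db$meta$study_id), "DUP"),
      condition_label = c(unlist(db$meta$condition_label), "c"))))
  seed1 <- data.frame(study_id = unlist(db$meta$study_id)[1])
  ex <- expand_hits(seed1, "transcriptome",
                    list(transcriptome = dup_db), n_expand = 2)
  expect_identical(ex$study_id[1], "DUP")
  expect_equal(ex$score[1], 1, tolerance = 1e-12)

  # orthogonal blocks: two seeds with disjoint neighbourhoods union cleanly
  blocks <- rbind(diag(4)[rep(1, 3), ], diag(4)[rep(2, 3), ])
  bdb <- embedding_db(paste0("s", 1:6, "||c"), blocks,
                      meta = list(study_id = paste0("s", 1:6),
                                  condition_label = rep("c", 6)))
  ex <- expand_hits(data.frame(study_id = c("s1", "s4")), "transcriptome",
                    list(transcriptome = bdb), n_expand = 2)
  expect_identical(sum(ex$seed_study == "s1") + sum(ex$seed_study == "s4"),
                   nrow(ex))
  expect_setequal(ex$study_id[ex$seed_study == "s1"], c("s2", "s3"))
  expect_setequal(ex$study_id[ex$seed_study == "s4"], c("s5", "s6"))
})

test_that("strategy dispatch validates the query type", {
  sb <- small_bench()
  q <- make_query(sb$gen$topics[[1]], seed = 2)
  expect_error(run_strategy(list(gene_set = q$gene_set), "S_PLUS_T",
                            sb$corpus, sb$dbs), "text query")
  expect_error(run_strategy(list(text = q$text), "T_PLUS_S",
                            sb$corpus, sb$dbs), "gene-set query")
})

test_that("S_ONLY equals plain semantic search and results are deterministic", {
  sb <- small_bench()
  q <- make_query(sb$gen$topics[[3]], seed = 4)
  res <- run_strategy(q, "S_ONLY", sb$corpus, sb$dbs, n_search = 5)
  direct <- search_semantic(q$text, sb$dbs$metadata, sb$dbs$embedder, 5)
  expect_identical(res$stage1_hits, direct)
  expect_identical(res$studies, direct$study_id)
  expect_identical(nrow(res$stage2_hits), 0L)

  res2 <- run_strategy(q, "S_ONLY", sb$corpus, sb$dbs, n_search = 5)
  expect_identical(res, res2)
  for (st in c("S_PLUS_T", "T_PLUS_S", "S_PLUS_S", "T_PLUS_T")) {
    a <- run_strategy(q, st, sb$corpus, sb$dbs, n_search = 3, n_expand = 3)
    b <- run_strategy(q, st, sb$corpus, sb$dbs, n_search = 3, n_expand = 3)
    expect_identical(a, b)
  }
})

test_that("returned studies cover the full sample roster and carry topic signal", {
  sb <- small_bench()
  q <- make_query(sb$gen$topics[[1]], seed = 8)
  res <- run_strategy(q, "S_PLUS_T", sb$corpus, sb$dbs,
                      n_search = 4, n_expand = 2)
  expect_true(all(res$studies %in% sb$corpus$studies$study_id))
  expect_setequal(res$samples,
                  sb$corpus$samples$sample_id[
                    sb$corpus$samples$study_id %in% res$studies])
  top4 <- head(res$studies, 4)
  expect_gte(mean(sb$topic_of[top4] == "topic01"), 0.75)
})

test_that("increasing search or expansion breadth never drops a study", {
  sb <- small_bench()
  for (ti in 1:3) {
    q <- make_query(sb$gen$topics[[ti]], seed = ti)
    prev <- character()
    for (ns in c(2, 4, 8)) {
      res <- run_strategy(q, "S_PLUS_T", sb$corpus, sb$dbs,
                          n_search = ns, n_expand = 3)
      expect_true(all(prev %in% res$studies))
      prev <- res$studies
    }
    prev <- character()
    for (ne in c(0, 2, 5)) {
      res <- run_strategy(q, "S_PLUS_T", sb$corpus, sb$dbs,
                          n_search = 3, n_expand = ne)
      expect_true(all(prev %in% res$studies))
      prev <- res$studies
    }
  }
})
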