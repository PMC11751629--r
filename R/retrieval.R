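#' Retrieval strategy identifiers
#'
#' Two-stage retrieval sequences over the metadata (S, semantic) and
#' transcriptome (T) embedding spaces: a first-pass search in one space
#' optionally followed by expansion of the candidate study list in either
#' space. `S_PLUS_T` (text search, transcriptome expansion) is the default:
#' combining both spaces retrieves studies with similar molecular patterns
#' even when their descriptions differ.
#'
#' @return character vector of the six strategy ids.
#' @export
retrieval_strategies <- function() {
  c("S_ONLY", "T_ONLY", "S_PLUS_T", "T_PLUS_S", "S_PLUS_S", "T_PLUS_T")
}

.cosine_scores <- function(query_vec, vectors) {
  qn <- sqrt(sum(query_vec^2))
  if (qn == 0) stop("degenerate query: zero embedding vector")
  rn <- sqrt(rowSums(vectors^2))
  s <- as.numeric(vectors %*% query_vec) / (rn * qn)
  s[rn == 0] <- 0  # zero rows carry no direction; score them neutral
  s
}

#' Exhaustive cosine-similarity k-nearest-neighbour search
#'
#' Scores every database row against the query by cosine similarity and
#' returns the top `n`, highest first; ties are broken by lexicographic id
#' so results are reproducible. `n` larger than the database returns all
#' rows.
#'
#' @param query_vec non-zero numeric vector, same dimension as the database.
#' @param db an [embedding_db()].
#' @param n number of neighbours (>= 1).
#' @return data.frame with columns `id`, `score` (non-increasing), and
#'   `rank`.
#' @export
knn_cosine <- function(query_vec, db, n) {
  stopifnot(inherits(db, "embedding_db"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be >= 1")
  if (!nrow(db$vectors)) stop("embedding db is empty")
  if (length(query_vec) != ncol(db$vectors))
    stop("query has dimension ", length(query_vec), ", db has ",
         ncol(db$vectors))
  s <- .cosine_scores(as.numeric(query_vec), db$vectors)
  ord <- order(-s, db$ids, method = "radix")
  take <- ord[seq_len(min(n, length(ord)))]
  data.frame(id = db$ids[take], score = s[take],
             rank = seq_along(take), stringsAsFactors = FALSE)
}

#' Stage-1 natural-language search
#'
#' Embeds the query text and runs cosine kNN over the metadata database.
#'
#' @param query_text free-text query.
#' @param metadata_db metadata [embedding_db()] (one row per study).
#' @param embedder the [text_embedder()] the database was built with.
#' @param n_search number of studies to return.
#' @return data.frame `study_id`, `score`, `rank`.
#' @export
search_semantic <- function(query_text, metadata_db,
                            embedder = hash_text_embedder(), n_search = 10) {
  q <- embed_query(query_text, embedder)
  hits <- knn_cosine(q, metadata_db, n_search)
  data.frame(study_id = hits$id, score = hits$score, rank = hits$rank,
             stringsAsFactors = FALSE)
}

.collapse_to_studies <- function(hits, study_of) {
  # condition-level hits -> study level, keeping each study's best score
  stud <- study_of[match(hits$id, names(study_of))]
  keep <- !duplicated(stud)
  data.frame(study_id = stud[keep], score = hits$score[keep],
             rank = seq_len(sum(keep)), stringsAsFactors = FALSE)
}

.study_map <- function(transcriptome_db) {
  m <- as.character(unlist(transcriptome_db$meta$study_id))
  if (length(m) != length(transcriptome_db$ids))
    stop("transcriptome db lacks a per-row study_id mapping in meta")
  names(m) <- transcriptome_db$ids
  m
}

#' Stage-1 transcriptome search from a gene-set query
#'
#' The gene set becomes an indicator pseudo-profile over the corpus gene
#' universe, is projected with the same JL projector as the database, and
#' cosine kNN runs over the condition profiles. Condition-level hits are
#' collapsed to studies, keeping each study's best score.
#'
#' @param set a [gene_set()].
#' @param transcriptome_db transcriptome [embedding_db()].
#' @param projector the [fit_jl_projector()] used at build time.
#' @param n_search number of studies to return.
#' @param gene_ids corpus gene universe; defaults to length `projector$n_genes`
#'   taken from the db meta if recorded there.
#' @return data.frame `study_id`, `score`, `rank`.
#' @export
search_transcriptome <- function(set, transcriptome_db, projector, gene_ids,
                                 n_search = 10) {
  pseudo <- geneset_to_pseudoprofile(set, gene_ids)
  preprocess <- transcriptome_db$meta$preprocess %||% "raw_mean"
  q <- project_vector(pseudo, projector, preprocess)
  study_of <- .study_map(transcriptome_db)
  # scan deep enough that n_search distinct studies survive the collapse
  n_rows <- nrow(transcriptome_db$vectors)
  hits <- knn_cosine(q, transcriptome_db, n_rows)
  collapsed <- .collapse_to_studies(hits, study_of)
  head(collapsed, n_search)
}

#' Stage-2 expansion of a candidate study list
#'
#' Each stage-1 study becomes a query in its own right: its metadata vector
#' (semantic mode) or all of its condition vectors (transcriptome mode) are
#' searched against the corresponding database, the seed study itself is
#' excluded from its own neighbour list, and per-seed results are collapsed
#' to at most `n_expand` studies each. The union is returned tagged with the
#' seed that retrieved each study.
#'
#' @param hits stage-1 data.frame with a `study_id` column (non-empty).
#' @param mode `"semantic"` or `"transcriptome"` -- which space to expand in.
#' @param dbs list with `metadata` and/or `transcriptome` [embedding_db()]s.
#' @param n_expand neighbours per seed study; 0 disables expansion.
#' @return data.frame `study_id`, `score`, `seed_study`, sorted by
#'   descending score (deduplicated across seeds, best score kept).
#' @export
expand_hits <- function(hits, mode = c("transcriptome", "semantic"), dbs,
                        n_expand = 10) {
  mode <- match.arg(mode)
  empty <- data.frame(study_id = character(), score = numeric(),
                      seed_study = character(), stringsAsFactors = FALSE)
  if (n_expand == 0) return(empty)
  if (!nrow(hits)) stop("expansion requires non-empty stage-1 hits")
  seeds <- unique(hits$study_id)
  out <- list()
  if (mode == "semantic") {
    db <- dbs$metadata
    for (seed in seeds) {
      row <- match(seed, db$ids)
      if (is.na(row)) {
        warning("seed study ", seed, " absent from metadata db; skipped")
        next
      }
      q <- db$vectors[row, ]
      if (all(q == 0)) next
      nn <- knn_cosine(q, db, n_expand + 1)
      nn <- nn[nn$id != seed, , drop = FALSE]
      nn <- head(nn, n_expand)
      if (nrow(nn))
        out[[seed]] <- data.frame(study_id = nn$id, score = nn$score,
                                  seed_study = seed, stringsAsFactors = FALSE)
    }
  } else {
    db <- dbs$transcriptome
    study_of <- .study_map(db)
    for (seed in seeds) {
      rows <- which(study_of == seed)
      if (!length(rows)) {
        warning("seed study ", seed, " absent from transcriptome db; skipped")
        next
      }
      per_seed <- list()
      for (r in rows) {
        q <- db$vectors[r, ]
        if (all(q == 0)) next
        nn <- knn_cosine(q, db, nrow(db$vectors))
        nn$study <- study_of[match(nn$id, names(study_of))]
        nn <- nn[nn$study != seed, , drop = FALSE]
        nn <- nn[!duplicated(nn$study), , drop = FALSE]
        per_seed[[length(per_seed) + 1]] <-
          head(data.frame(study_id = nn$study, score = nn$score,
                          stringsAsFactors = FALSE), n_expand)
      }
      if (!length(per_seed)) next
      merged <- do.call(rbind, per_seed)
      merged <- merged[order(-merged$score, merged$study_id,
                             method = "radix"), , drop = FALSE]
      merged <- merged[!duplicated(merged$study_id), , drop = FALSE]
      merged <- head(merged, n_expand)
      if (nrow(merged))
        out[[seed]] <- data.frame(study_id = merged$study_id,
                                  score = merged$score, seed_study = seed,
                                  stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(-res$score, res$study_id, res$seed_study,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run a two-stage retrieval strategy
#'
#' Dispatches on the strategy id: S-first strategies need `query_text`,
#' T-first strategies need `gene_set`. The result lists stage-1 and stage-2
#' hits with their scores and provenance, the deduplicated union of studies
#' (stage-1 order first, then stage-2 by score), and every corpus sample
#' belonging to those studies.
#'
#' @param query list with `text` (character) and/or `gene_set`
#'   (a [gene_set()]).
#' @param strategy one of [retrieval_strategies()].
#' @param corpus the [tx_corpus()] (for the gene universe and the sample
#'   roster of returned studies).
#' @param dbs list with `metadata`, `transcriptome` ([embedding_db()]s),
#'   `projector` ([fit_jl_projector()]) and `embedder` ([text_embedder()]).
#' @param n_search stage-1 breadth (studies), default 10.
#' @param n_expand stage-2 breadth (studies per seed), default 10; 0 makes
#'   any two-stage strategy equal to its stage-1-only counterpart.
#' @return Object of class `query_result`.
#' @export
run_strategy <- function(query, strategy = "S_PLUS_T", corpus, dbs,
                         n_search = 10, n_expand = 10) {
  strategy <- match.arg(strategy, retrieval_strategies())
  first <- substr(strategy, 1, 1)
  if (first == "S" && (is.null(query$text) || !nzchar(query$text)))
    stop("strategy ", strategy, " requires a text query")
  if (first == "T" && is.null(query$gene_set))
    stop("strategy ", strategy, " requires a gene-set query")

  stage1 <- if (first == "S") {
    search_semantic(query$text, dbs$metadata, dbs$embedder, n_search)
  } else {
    search_transcriptome(query$gene_set, dbs$transcriptome, dbs$projector,
                         corpus$gene_ids, n_search)
  }

  second <- if (strategy %in% c("S_ONLY", "T_ONLY")) NULL
            else substr(strategy, nchar(strategy), nchar(strategy))
  stage2 <- if (is.null(second) || n_expand == 0) {
    data.frame(study_id = character(), score = numeric(),
               seed_study = character(), stringsAsFactors = FALSE)
  } else {
    expand_hits(stage1,
                mode = if (second == "S") "semantic" else "transcriptome",
                dbs = dbs, n_expand = n_expand)
  }

  studies <- unique(c(stage1$study_id, stage2$study_id))
  samples <- corpus$samples$sample_id[corpus$samples$study_id %in% studies]
  structure(list(
    query = list(text = query$text,
                 gene_set = if (!is.null(query$gene_set)) query$gene_set$name),
    strategy = strategy,
    stage1_hits = stage1, stage2_hits = stage2,
    studies = studies, samples = samples,
    params = list(n_search = n_search, n_expand = n_expand)),
    class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat("query_result [", x$strategy, "]: ", nrow(x$stage1_hits),
      " stage-1 + ", nrow(x$stage2_hits), " stage-2 hits -> ",
      length(x$studies), " studies, ", length(x$samples), " samples\n",
      sep = "")
  invisible(x)
}
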