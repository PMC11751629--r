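#' Run configuration for index building and querying
#'
#' Everything that affects results lives here (and is logged into every
#' output's sidecar), so any run is reproducible from its config alone.
#'
#' @param corpus path to the HDF5 corpus.
#' @param out_dir directory for index files and query outputs.
#' @param embedder text embedder name (`"hash-fnv1a"` is built in).
#' @param embed_dim metadata embedding dimension (default 384).
#' @param jl_k transcriptome embedding dimension (default 1000).
#' @param jl_seed seed of the JL projection matrix.
#' @param preprocess `"raw_mean"` or `"log1p_cpm"` (see
#'   [project_profiles()]).
#' @param strategy default retrieval strategy.
#' @param n_search,n_expand retrieval breadth defaults.
#' @param alpha,n_perm,fdr,seed enrichment-filter settings (ssGSEA exponent,
#'   permutation count, FDR threshold, permutation seed).
#' @return list of class `run_config`.
#' @export
run_config <- function(corpus, out_dir = dirname(corpus),
                       embedder = "hash-fnv1a", embed_dim = 384,
                       jl_k = 1000, jl_seed = 1, preprocess = "raw_mean",
                       strategy = "S_PLUS_T", n_search = 10, n_expand = 10,
                       alpha = 0.25, n_perm = 499, fdr = 0.05, seed = 1) {
  cfg <- list(corpus = corpus, out_dir = out_dir, embedder = embedder,
              embed_dim = embed_dim, jl_k = jl_k, jl_seed = jl_seed,
              preprocess = preprocess, strategy = strategy,
              n_search = n_search, n_expand = n_expand, alpha = alpha,
              n_perm = n_perm, fdr = fdr, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Read/write a run configuration as JSON
#'
#' @param path JSON path.
#' @param config a [run_config()].
#' @return `load_run_config` returns the [run_config()];
#'   `save_run_config` returns `path` invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

.resolve_embedder <- function(config) {
  if (identical(config$embedder, "hash-fnv1a"))
    return(hash_text_embedder(config$embed_dim))
  stop("unknown embedder '", config$embedder,
       "'; register an adapter via text_embedder() and pass it directly to ",
       "the build functions")
}

.index_paths <- function(config) {
  list(metadata = file.path(config$out_dir, "metadata_db.bin"),
       transcriptome = file.path(config$out_dir, "transcriptome_db.bin"))
}

#' Build the metadata and transcriptome indexes of a corpus
#'
#' Reads the corpus, embeds study text into the metadata database, and
#' projects condition-averaged counts into the transcriptome database; both
#' are persisted (binary array + JSON sidecar) under `config$out_dir`.
#' Re-running with the same config writes bit-identical files. On failure no
#' partial index files are left behind.
#'
#' @param config a [run_config()].
#' @param embedder optional [text_embedder()] overriding the config name.
#' @return list with paths `metadata`, `transcriptome` (invisibly usable via
#'   [load_embedding_db()]).
#' @export
build_index <- function(config, embedder = NULL) {
  stopifnot(inherits(config, "run_config"))
  paths <- .index_paths(config)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(c(written, paste0(written, ".json"))), add = TRUE)
  if (is.null(embedder)) embedder <- .resolve_embedder(config)
  corpus <- read_archs4_h5(config$corpus)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)

  mdb <- build_metadata_db(corpus, embedder)
  save_embedding_db(mdb, paths$metadata)
  written <- c(written, paths$metadata)

  tdb <- build_transcriptome_db(corpus, k = config$jl_k,
                                seed = config$jl_seed,
                                preprocess = config$preprocess)
  save_embedding_db(tdb$db, paths$transcriptome)
  written <- c(written, paths$transcriptome)
  ok <- TRUE
  message("index built: ", nrow(mdb$vectors), " studies (metadata), ",
          nrow(tdb$db$vectors), " condition profiles (transcriptome)")
  invisible(paths)
}

#' Load a previously built index
#'
#' Rebuilds the JL projector deterministically from the parameters recorded
#' in the transcriptome database sidecar, so query-time projection matches
#' build-time exactly.
#'
#' @param config a [run_config()].
#' @param embedder optional [text_embedder()] overriding the config name.
#' @return list with `metadata`, `transcriptome`, `projector`, `embedder` --
#'   the `dbs` argument of [run_strategy()].
#' @export
load_index <- function(config, embedder = NULL) {
  paths <- .index_paths(config)
  if (!file.exists(paths$metadata) || !file.exists(paths$transcriptome))
    stop("index not found under ", config$out_dir,
         ": run build_index() first")
  if (is.null(embedder)) embedder <- .resolve_embedder(config)
  mdb <- load_embedding_db(paths$metadata)
  tdb <- load_embedding_db(paths$transcriptome)
  projector <- fit_jl_projector(tdb$meta$n_genes, k = tdb$meta$k,
                                seed = tdb$meta$jl_seed)
  list(metadata = mdb, transcriptome = tdb, projector = projector,
       embedder = embedder)
}

#' Run the full query pipeline: retrieve, enrich, write outputs
#'
#' Executes the configured two-stage retrieval for one query against a built
#' index, applies the ssGSEA FDR filter when a gene set is supplied, and
#' writes `result.json` (stage-wise hits with scores and provenance, plus
#' the config) and `enrichment.tsv` (sample_id, es, p, q, enriched) under
#' `config$out_dir`. Per-stage counts (studies, samples before/after
#' filtering) are logged.
#'
#' @param config a [run_config()].
#' @param query_text free-text query (required for S-first strategies).
#' @param set optional [gene_set()] (required for T-first strategies and for
#'   enrichment filtering).
#' @param embedder optional [text_embedder()] override.
#' @return list with `result` (the `query_result`), `enrichment` (the filter
#'   output or NULL), and `files` (paths written).
#' @export
end_to_end <- function(config, query_text = NULL, set = NULL,
                       embedder = NULL) {
  stopifnot(inherits(config, "run_config"))
  dbs <- load_index(config, embedder)
  corpus <- read_archs4_h5(config$corpus)
  result <- run_strategy(list(text = query_text, gene_set = set),
                         config$strategy, corpus, dbs,
                         n_search = config$n_search,
                         n_expand = config$n_expand)
  message("retrieved ", length(result$studies), " studies / ",
          length(result$samples), " samples (stage 1: ",
          nrow(result$stage1_hits), ", stage 2: ",
          nrow(result$stage2_hits), ")")
  enrichment <- NULL
  if (!is.null(set)) {
    enrichment <- filter_enriched(result, corpus, set,
                                  threshold = config$fdr,
                                  alpha = config$alpha,
                                  n_perm = config$n_perm,
                                  seed = config$seed)
    message("enrichment filter (FDR < ", config$fdr, "): ",
            enrichment$n_after, " of ", enrichment$n_before,
            " samples retained")
  }
  files <- list(result = file.path(config$out_dir, "result.json"))
  payload <- list(
    config = unclass(config),
    query = result$query, strategy = result$strategy,
    params = result$params,
    stage1_hits = result$stage1_hits, stage2_hits = result$stage2_hits,
    studies = result$studies, samples = result$samples,
    n_samples_before_filter = length(result$samples),
    n_samples_after_filter = if (is.null(enrichment)) NULL else
      enrichment$n_after)
  jsonlite::write_json(payload, files$result, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  if (!is.null(enrichment)) {
    files$enrichment <- file.path(config$out_dir, "enrichment.tsv")
    write.table(enrichment$table, files$enrichment, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(result = result, enrichment = enrichment, files = files)
}
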