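# Shared fixtures, built in code at test time.

# a 2-study, 4-sample, 6-gene corpus with hand-picked counts
tiny_corpus <- function() {
  counts <- matrix(
    c(1, 3, 0, 5, 2, 4,
      3, 5, 0, 5, 2, 4,
      10, 1, 2, 0, 7, 1,
      12, 3, 2, 0, 7, 1),
    nrow = 6)
  tx_corpus(
    counts,
    gene_ids = paste0("g", 1:6),
    samples = data.frame(
      sample_id = paste0("GSM", 1:4),
      study_id = c("GSEA1", "GSEA1", "GSEB2", "GSEB2"),
      condition_label = c("ctrl", "ctrl", "treat", "treat"),
      title = paste("sample", 1:4),
      source_name = c("heart", "heart", "liver", "liver"),
      characteristics = c("rep: 1", "rep: 2", "", "rep: 2")),
    studies = data.frame(
      study_id = c("GSEA1", "GSEB2"),
      title = c("Cardiac remodeling study", "Liver fibrosis study"),
      summary = c("RNA-seq of heart tissue", "RNA-seq of liver tissue"),
      overall_design = c("case versus control", "")))
}

# small planted-topic corpus + built indexes, cached per session
small_bench <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gen <- generate_corpus(generator_config(
      n_topics = 3, studies_per_topic = 4, samples_per_study = 4,
      n_genes = 400, signature_size = 15, fold_change = 4,
      baseline_mean = 30, seed = 11))
    embedder <- hash_text_embedder(128)
    mdb <- build_metadata_db(gen$corpus, embedder)
    tx <- build_transcriptome_db(gen$corpus, k = 150, seed = 5)
    cache <<- list(
      gen = gen, corpus = gen$corpus,
      dbs = list(metadata = mdb, transcriptome = tx$db,
                 projector = tx$projector, embedder = embedder),
      topic_of = setNames(gen$truth$topic_id, gen$truth$study_id))
    cache
  }
})

random_gene_universe <- function(n) sprintf("g%04d", seq_len(n))
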