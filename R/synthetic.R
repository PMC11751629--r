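# Term bank for topic vocabularies: enough disjoint biomedical-flavoured
# words that the hash embedder separates topics by lexical overlap alone.
.TERM_BANK <- c(
  "cardiomyocyte", "myocardial", "infarction", "hypertrophy", "arrhythmia",
  "ischemia", "ventricular", "aortic",
  "hepatocyte", "liver", "steatosis", "fibrosis", "cholestasis", "cirrhosis",
  "bile", "portal",
  "neuron", "cortex", "hippocampus", "synaptic", "astrocyte", "microglia",
  "dopaminergic", "axonal",
  "lymphocyte", "cytokine", "inflammation", "interferon", "macrophage",
  "antigen", "autoimmune", "chemokine",
  "tumor", "carcinoma", "metastasis", "oncogene", "proliferation",
  "apoptosis", "melanoma", "leukemia",
  "islet", "insulin", "glucose", "adipocyte", "metabolic", "obesity",
  "lipolysis", "glycolysis",
  "alveolar", "pulmonary", "asthma", "bronchial", "epithelium", "surfactant",
  "emphysema", "hypoxia",
  "nephron", "glomerular", "tubular", "podocyte", "proteinuria", "uremic",
  "dialysis", "renin")

.TITLE_TEMPLATES <- c(
  "Transcriptional profiling of %s %s",
  "RNA-seq analysis of %s in %s",
  "Gene expression changes during %s %s")
.SUMMARY_TEMPLATES <- c(
  "We performed RNA sequencing of %s samples to investigate %s and %s responses.",
  "Bulk RNA-seq characterizing %s regulation under %s stimulation with %s involvement.",
  "This study profiles %s tissue to dissect %s signalling and %s activity.")
.DESIGN_TEMPLATES <- c(
  "Samples of %s exposed to %s versus matched controls.",
  "Paired %s specimens with and without %s treatment.")
# queries are keyword-dense, the way people actually search
.QUERY_TEMPLATES <- c(
  "%s %s gene expression in %s and %s",
  "transcriptome of %s %s with %s %s",
  "%s and %s signatures in %s %s samples")

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the planted-topic benchmark corpus: five topics with
#' disjoint vocabularies and disjoint 20-gene upregulated signatures, ten
#' studies per topic, four samples per study split over two conditions
#' (control/treated), 2000 genes, negative-binomial baseline counts
#' (mean 50, size 10 -- the overdispersion typical of bulk RNA-seq), and a
#' four-fold signature induction in each study's treated condition.
#'
#' @param n_topics number of latent topics.
#' @param studies_per_topic studies generated per topic.
#' @param samples_per_study samples per study (split evenly across
#'   conditions).
#' @param conditions_per_study experimental conditions per study; the last
#'   condition carries the topic signature induction.
#' @param n_genes gene universe size.
#' @param signature_size upregulated genes per topic (disjoint across
#'   topics).
#' @param fold_change multiplicative induction of signature genes in the
#'   treated condition; 1 means no signal (a null corpus).
#' @param nb_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param baseline_mean negative-binomial mean of unperturbed counts.
#' @param vocab_size topic vocabulary size (words per topic, pairwise
#'   disjoint).
#' @param vocab_overlap number of shared "confuser" words appended to every
#'   topic's vocabulary (0 = fully disjoint; raising it makes text retrieval
#'   harder).
#' @param seed seed fixing every random draw.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_topics = 5, studies_per_topic = 10,
                             samples_per_study = 4, conditions_per_study = 2,
                             n_genes = 2000, signature_size = 20,
                             fold_change = 4, nb_dispersion = 10,
                             baseline_mean = 50, vocab_size = 8,
                             vocab_overlap = 0, seed = 1) {
  cfg <- list(n_topics = n_topics, studies_per_topic = studies_per_topic,
              samples_per_study = samples_per_study,
              conditions_per_study = conditions_per_study,
              n_genes = n_genes, signature_size = signature_size,
              fold_change = fold_change, nb_dispersion = nb_dispersion,
              baseline_mean = baseline_mean, vocab_size = vocab_size,
              vocab_overlap = vocab_overlap, seed = seed)
  num <- setdiff(names(cfg), "vocab_overlap")
  if (any(vapply(cfg[num], function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all generator_config values (except vocab_overlap) must be positive")
  if (cfg$vocab_overlap < 0) stop("vocab_overlap must be >= 0")
  if (cfg$signature_size * cfg$n_topics > cfg$n_genes)
    stop("signature_size x n_topics exceeds n_genes: signatures cannot be ",
         "disjoint")
  if (cfg$conditions_per_study > cfg$samples_per_study)
    stop("more conditions than samples per study")
  class(cfg) <- "generator_config"
  cfg
}

.topic_words <- function(n_topics, vocab_size, vocab_overlap) {
  need <- n_topics * vocab_size + vocab_overlap
  bank <- .TERM_BANK
  if (need > length(bank))
    bank <- c(bank, sprintf("factor%03d", seq_len(need - length(bank))))
  shared <- if (vocab_overlap > 0) bank[seq_len(vocab_overlap)] else character()
  rest <- bank[(vocab_overlap + 1):length(bank)]
  lapply(seq_len(n_topics), function(t)
    c(rest[((t - 1) * vocab_size + 1):(t * vocab_size)], shared))
}

.fill_template <- function(template, words) {
  k <- lengths(regmatches(template, gregexpr("%s", template, fixed = TRUE)))
  do.call(sprintf, c(list(template), as.list(sample(words, k))))
}

#' Generate a synthetic ARCHS4-style corpus with planted topics
#'
#' Studies are grouped into latent topics. Each topic owns a vocabulary
#' (study and sample text is filled from sentence templates using those
#' words) and an upregulated gene signature; counts are negative-binomial
#' around `baseline_mean`, with the signature genes' mean multiplied by
#' `fold_change` in each study's treated condition. Everything -- counts,
#' text, labels -- is a deterministic function of the config seed, so a
#' corpus, the queries derived from it, and every downstream result can be
#' regenerated exactly.
#'
#' @param config a [generator_config()].
#' @return list with `corpus` (a [tx_corpus()]), `truth` (data.frame:
#'   study_id, topic_id), `sample_truth` (data.frame: sample_id, study_id,
#'   topic_id, condition, signature_active), and `topics` (list of topic
#'   specs with `topic_id`, `vocabulary`, `signature_genes`, `fold_change`,
#'   `templates`).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(cfg) {
  n_studies <- cfg$n_topics * cfg$studies_per_topic
  n_samples <- n_studies * cfg$samples_per_study
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  vocab <- .topic_words(cfg$n_topics, cfg$vocab_size, cfg$vocab_overlap)
  topics <- lapply(seq_len(cfg$n_topics), function(t) {
    sig <- gene_ids[((t - 1) * cfg$signature_size + 1):
                    (t * cfg$signature_size)]
    list(topic_id = sprintf("topic%02d", t), vocabulary = vocab[[t]],
         signature_genes = sig, fold_change = cfg$fold_change,
         templates = list(title = .TITLE_TEMPLATES,
                          summary = .SUMMARY_TEMPLATES,
                          design = .DESIGN_TEMPLATES))
  })

  counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_samples)
  sample_rows <- vector("list", n_samples)
  study_rows <- vector("list", n_studies)
  truth <- vector("list", n_studies)
  sample_truth <- vector("list", n_samples)
  cond_names <- if (cfg$conditions_per_study == 2) c("control", "treated")
    else c("control", sprintf("treated%d",
                              seq_len(cfg$conditions_per_study - 1)))
  si <- 0L
  for (st in seq_len(n_studies)) {
    t <- (st - 1) %/% cfg$studies_per_topic + 1
    topic <- topics[[t]]
    study_id <- sprintf("GSE%05d", st)
    study_rows[[st]] <- data.frame(
      study_id = study_id,
      title = .fill_template(sample(.TITLE_TEMPLATES, 1), topic$vocabulary),
      # GEO-style summaries typically end in a keyword line; it also makes
      # study text cover the topic lexicon instead of a 2-3 word draw
      summary = paste0(.fill_template(sample(.SUMMARY_TEMPLATES, 1),
                                      topic$vocabulary),
                       " Keywords: ",
                       paste(topic$vocabulary, collapse = ", ")),
      overall_design = .fill_template(sample(.DESIGN_TEMPLATES, 1),
                                      topic$vocabulary),
      stringsAsFactors = FALSE)
    truth[[st]] <- data.frame(study_id = study_id, topic_id = topic$topic_id,
                              stringsAsFactors = FALSE)
    cond_of <- rep(seq_len(cfg$conditions_per_study),
                   length.out = cfg$samples_per_study)
    sig_idx <- match(topic$signature_genes, gene_ids)
    for (sm in seq_len(cfg$samples_per_study)) {
      si <- si + 1L
      cond <- cond_of[sm]
      induced <- cond == cfg$conditions_per_study && cfg$fold_change != 1
      mu <- rep(cfg$baseline_mean, cfg$n_genes)
      if (cond == cfg$conditions_per_study)
        mu[sig_idx] <- mu[sig_idx] * cfg$fold_change
      counts[, si] <- rnbinom(cfg$n_genes, size = cfg$nb_dispersion, mu = mu)
      sample_id <- sprintf("GSM%06d", si)
      w <- sample(topic$vocabulary, 2)
      sample_rows[[si]] <- data.frame(
        sample_id = sample_id, study_id = study_id,
        condition_label = cond_names[cond],
        title = paste(w[1], "sample replicate", (sm - 1) %/%
                        cfg$conditions_per_study + 1),
        source_name = paste(w[2], "tissue"),
        characteristics = paste0("condition: ", cond_names[cond]),
        stringsAsFactors = FALSE)
      sample_truth[[si]] <- data.frame(
        sample_id = sample_id, study_id = study_id,
        topic_id = topic$topic_id, condition = cond_names[cond],
        signature_active = induced, stringsAsFactors = FALSE)
    }
  }
  corpus <- tx_corpus(counts, gene_ids, do.call(rbind, sample_rows),
                      do.call(rbind, study_rows))
  list(corpus = corpus, truth = do.call(rbind, truth),
       sample_truth = do.call(rbind, sample_truth), topics = topics)
}

#' Derive a benchmark query from a topic
#'
#' Mirrors how curated gene sets pair a member list with a text description
#' of the experimental condition: the query text is a filled sentence from
#' the topic's templates and the gene set is the topic's planted signature.
#'
#' @param topic a topic spec from [generate_corpus()].
#' @param seed seed for the template draw (queries are deterministic per
#'   (topic, seed)).
#' @return list with `text` and `gene_set` (a [gene_set()] whose description
#'   is the text).
#' @export
make_query <- function(topic, seed = 1) {
  text <- withr::with_seed(seed, .fill_template(
    sample(.QUERY_TEMPLATES, 1), topic$vocabulary))
  list(text = text,
       gene_set = gene_set(paste0(topic$topic_id, "_signature"), text,
                           topic$signature_genes))
}

#' Write a synthetic corpus fixture to HDF5
#'
#' Thin wrapper over [write_corpus_h5()] so generated corpora land in the
#' exact layout [read_archs4_h5()] expects by default.
#'
#' @param corpus a [tx_corpus()].
#' @param path output HDF5 path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(corpus, path) {
  write_corpus_h5(corpus, path, archs4_layout())
}
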