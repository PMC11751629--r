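#' Aggregate counts into per-study condition profiles
#'
#' Samples are grouped within each study by an experimental-condition key
#' and each group's count columns are averaged gene-wise, giving one mean
#' profile per (study, condition). These condition profiles are the units
#' indexed in the transcriptome embedding space.
#'
#' The default key uses the sample's `condition_label` when non-empty, falls
#' back to its `source_name` text, and finally to the sample's own id (a
#' singleton condition), since public corpora rarely state conditions in a
#' single canonical field.
#'
#' @param corpus a [tx_corpus()].
#' @param condition_key `NULL` for the default rule, or a
#'   `function(samples_df) -> character` returning one label per sample.
#' @return Object of class `condition_profiles`: `study_id` and
#'   `condition_label` vectors, a profiles x genes `means` matrix,
#'   `n_samples` per profile, and the corpus `gene_ids`. Profiles are
#'   ordered by (study, condition).
#' @export
aggregate_conditions <- function(corpus, condition_key = NULL) {
  stopifnot(inherits(corpus, "tx_corpus"))
  s <- corpus$samples
  if (is.null(condition_key)) {
    label <- s$condition_label
    label <- ifelse(nzchar(label), label,
                    ifelse(nzchar(s$source_name), s$source_name, s$sample_id))
  } else {
    label <- as.character(condition_key(s))
    if (length(label) != nrow(s))
      stop("condition_key must return one label per sample")
  }
  key <- paste(s$study_id, label, sep = "\r")
  groups <- split(seq_len(nrow(s)), key)
  ord <- order(names(groups), method = "radix")
  groups <- groups[ord]
  n_profiles <- length(groups)
  means <- matrix(0, nrow = n_profiles, ncol = length(corpus$gene_ids))
  study_id <- condition_label <- character(n_profiles)
  n_samples <- integer(n_profiles)
  for (i in seq_len(n_profiles)) {
    idx <- groups[[i]]
    parts <- strsplit(names(groups)[i], "\r", fixed = TRUE)[[1]]
    study_id[i] <- parts[1]
    condition_label[i] <- if (length(parts) > 1) parts[2] else ""
    means[i, ] <- rowMeans(corpus$counts[, idx, drop = FALSE])
    n_samples[i] <- length(idx)
  }
  empty <- setdiff(corpus$studies$study_id, study_id)
  if (length(empty))
    warning("studies without samples skipped: ", paste(empty, collapse = ", "))
  structure(list(study_id = study_id, condition_label = condition_label,
                 means = means, n_samples = n_samples,
                 gene_ids = corpus$gene_ids),
            class = "condition_profiles")
}

#' @export
print.condition_profiles <- function(x, ...) {
  cat("condition_profiles:", length(x$study_id), "profiles x",
      length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Fit a seeded Johnson-Lindenstrauss random projection
#'
#' A dense Gaussian projection: a `k x n_genes` matrix with i.i.d.
#' N(0, 1/k) entries, fully determined by `(n_genes, k, seed)`. By the JL
#' lemma, projecting with it approximately preserves pairwise Euclidean
#' distances between profiles with high probability, which is what makes
#' cosine search in the reduced space meaningful.
#'
#' @param n_genes input dimension (gene universe size).
#' @param k output dimension; default 1000, a width at which distances
#'   between thousands of profiles are preserved to within ~20%.
#' @param seed RNG seed; the same seed always reproduces the same matrix, so
#'   query-time projection matches build-time.
#' @return Object of class `jl_projector` with fields `n_genes`, `k`,
#'   `seed`, `matrix`.
#' @export
fit_jl_projector <- function(n_genes, k = 1000, seed = 1) {
  n_genes <- as.integer(n_genes); k <- as.integer(k); seed <- as.integer(seed)
  if (is.na(k) || k < 1) stop("k must be >= 1")
  if (is.na(n_genes) || n_genes < 1) stop("n_genes must be >= 1")
  if (k > n_genes)
    warning("k (", k, ") exceeds n_genes (", n_genes, "): no reduction")
  mat <- withr::with_seed(seed,
    matrix(rnorm(as.numeric(k) * n_genes), nrow = k, ncol = n_genes))
  mat <- mat / sqrt(k)
  structure(list(n_genes = n_genes, k = k, seed = seed, matrix = mat),
            class = "jl_projector")
}

#' @export
print.jl_projector <- function(x, ...) {
  cat("jl_projector:", x$n_genes, "genes ->", x$k, "dims (seed", x$seed, ")\n")
  invisible(x)
}

.preprocess_profile <- function(x, preprocess) {
  switch(preprocess,
    raw_mean = x,
    log1p_cpm = {
      tot <- sum(x)
      if (tot > 0) log1p(x / tot * 1e6) else x
    },
    stop("unknown preprocess '", preprocess, "'"))
}

#' Project condition profiles into the transcriptome embedding space
#'
#' Each profile's mean-count vector is (optionally) preprocessed and
#' multiplied by the JL matrix. With the default `raw_mean` preprocessing
#' the map is linear in the counts.
#'
#' @param profiles a `condition_profiles` object from
#'   [aggregate_conditions()].
#' @param projector a [fit_jl_projector()] whose `n_genes` matches the
#'   profile length.
#' @param preprocess `"raw_mean"` (default; the averaged counts go in as-is)
#'   or `"log1p_cpm"` (counts-per-million then log1p, for scale robustness).
#' @return An [embedding_db()] keyed by `study_id||condition_label`, with
#'   `meta$study_id` / `meta$condition_label` carrying the per-row mapping
#'   and the projector parameters recorded for query-time reuse.
#' @export
project_profiles <- function(profiles, projector,
                             preprocess = c("raw_mean", "log1p_cpm")) {
  stopifnot(inherits(profiles, "condition_profiles"),
            inherits(projector, "jl_projector"))
  preprocess <- match.arg(preprocess)
  if (ncol(profiles$means) != projector$n_genes)
    stop("profile length ", ncol(profiles$means),
         " does not match projector input dimension ", projector$n_genes)
  pre <- t(apply(profiles$means, 1, .preprocess_profile, preprocess))
  if (nrow(profiles$means) == 1) pre <- matrix(pre, nrow = 1)
  vectors <- pre %*% t(projector$matrix)
  ids <- paste(profiles$study_id, profiles$condition_label, sep = "||")
  embedding_db(ids, vectors,
               meta = list(space = "transcriptome",
                           study_id = profiles$study_id,
                           condition_label = profiles$condition_label,
                           n_genes = projector$n_genes, k = projector$k,
                           jl_seed = projector$seed,
                           preprocess = preprocess))
}

#' Project a single profile vector with a fitted projector
#'
#' @param x numeric vector of length `projector$n_genes`.
#' @param projector a [fit_jl_projector()].
#' @param preprocess as in [project_profiles()].
#' @return numeric vector of length `projector$k`.
#' @export
project_vector <- function(x, projector,
                           preprocess = c("raw_mean", "log1p_cpm")) {
  preprocess <- match.arg(preprocess)
  if (length(x) != projector$n_genes)
    stop("vector length ", length(x), " does not match projector input ",
         "dimension ", projector$n_genes)
  as.numeric(projector$matrix %*% .preprocess_profile(as.numeric(x),
                                                      preprocess))
}

#' Turn a gene set into an indicator pseudo-profile
#'
#' For transcriptome-first search, a gene-set query is represented as an
#' indicator vector over the corpus gene universe (1 for member genes
#' present, 0 otherwise), which is then projected like any condition
#' profile. High cosine similarity in the projected space then flags
#' profiles whose expression mass concentrates on the set.
#'
#' @param set a [gene_set()].
#' @param gene_ids corpus gene universe (ordered).
#' @return numeric 0/1 vector of length `length(gene_ids)`.
#' @export
geneset_to_pseudoprofile <- function(set, gene_ids) {
  stopifnot(inherits(set, "gene_set"))
  v <- as.numeric(gene_ids %in% set$genes)
  if (!any(v > 0))
    stop("empty query profile: gene set '", set$name,
         "' shares no genes with the corpus universe")
  v
}

#' Build the transcriptome embedding database of a corpus
#'
#' Convenience wrapper: aggregate condition profiles, fit (or reuse) a JL
#' projector, and project.
#'
#' @inheritParams aggregate_conditions
#' @param k,seed projector parameters (see [fit_jl_projector()]).
#' @param preprocess see [project_profiles()].
#' @param projector optionally a pre-fitted [fit_jl_projector()].
#' @return list with elements `db` (the [embedding_db()]) and `projector`.
#' @export
build_transcriptome_db <- function(corpus, k = 1000, seed = 1,
                                   preprocess = "raw_mean",
                                   condition_key = NULL, projector = NULL) {
  profiles <- aggregate_conditions(corpus, condition_key)
  if (is.null(projector))
    projector <- fit_jl_projector(length(corpus$gene_ids), k = k, seed = seed)
  db <- project_profiles(profiles, projector, preprocess)
  list(db = db, projector = projector)
}
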