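#' Construct a corpus of counts plus sample/study metadata
#'
#' A corpus bundles a genes x samples count matrix with per-sample records
#' (accession, parent study, condition label, free metadata text) and
#' per-study records (title, summary, overall design). It is the unit of
#' ingestion for index building: study text feeds the metadata embedding
#' space, counts feed the transcriptome embedding space.
#'
#' @param counts numeric matrix, genes x samples, non-negative.
#' @param gene_ids character vector of unique gene symbols, one per row of
#'   `counts`.
#' @param samples data.frame with columns `sample_id`, `study_id`, and
#'   optionally `condition_label`, `title`, `source_name`, `characteristics`
#'   (missing optional columns are filled with empty strings). One row per
#'   column of `counts`, in column order. A `sample_text` column, if absent,
#'   is derived as the single-space concatenation of the non-empty title,
#'   source name and characteristics fields.
#' @param studies data.frame with columns `study_id` and optionally `title`,
#'   `summary`, `overall_design`.
#'
#' @return An object of class `tx_corpus`.
#' @export
tx_corpus <- function(counts, gene_ids, samples, studies) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("corpus counts must be finite and non-negative")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length (", length(gene_ids), ") does not match count rows (",
         nrow(counts), ")")
  if (anyDuplicated(gene_ids))
    stop("gene_ids must be unique")
  samples <- .complete_sample_df(samples)
  studies <- .complete_study_df(studies)
  if (nrow(samples) != ncol(counts))
    stop("sample table has ", nrow(samples), " rows but counts has ",
         ncol(counts), " columns")
  if (anyDuplicated(samples$sample_id))
    stop("sample_id values must be unique")
  if (anyDuplicated(studies$study_id))
    stop("study_id values must be unique")
  missing_studies <- setdiff(samples$study_id, studies$study_id)
  if (length(missing_studies))
    stop("samples reference studies absent from the study table: ",
         paste(missing_studies, collapse = ", "))
  rownames(counts) <- gene_ids
  colnames(counts) <- samples$sample_id
  structure(
    list(counts = counts, gene_ids = gene_ids,
         samples = samples, studies = studies),
    class = "tx_corpus")
}

.complete_sample_df <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("sample_id", "study_id"))
    if (is.null(samples[[col]])) stop("sample table lacks required column ", col)
  for (col in c("condition_label", "title", "source_name", "characteristics"))
    if (is.null(samples[[col]])) samples[[col]] <- rep("", nrow(samples))
  samples[] <- lapply(samples, function(v) {
    v <- as.character(v); v[is.na(v)] <- ""; v
  })
  if (is.null(samples$sample_text))
    samples$sample_text <- .concat_fields(
      samples$title, samples$source_name, samples$characteristics)
  rownames(samples) <- NULL
  samples[c("sample_id", "study_id", "condition_label", "title",
            "source_name", "characteristics", "sample_text")]
}

.concat_fields <- function(...) {
  parts <- list(...)
  vapply(seq_along(parts[[1]]), function(i) {
    p <- vapply(parts, `[[`, character(1), i)
    paste(p[nzchar(p)], collapse = " ")
  }, character(1))
}

.complete_study_df <- function(studies) {
  studies <- as.data.frame(studies, stringsAsFactors = FALSE)
  if (is.null(studies$study_id)) stop("study table lacks required column study_id")
  for (col in c("title", "summary", "overall_design"))
    if (is.null(studies[[col]])) studies[[col]] <- rep("", nrow(studies))
  studies[] <- lapply(studies, as.character)
  rownames(studies) <- NULL
  studies[c("study_id", "title", "summary", "overall_design")]
}

#' @export
print.tx_corpus <- function(x, ...) {
  cat("tx_corpus:", length(x$gene_ids), "genes x", nrow(x$samples),
      "samples in", nrow(x$studies), "studies\n")
  invisible(x)
}

#' Default ARCHS4-style HDF5 layout map
#'
#' Dataset paths follow the ARCHS4 v2 naming scheme (expression matrix under
#' `data/`, per-sample metadata under `meta/samples/`). Because public
#' corpus builds have shifted field names across releases, every reader call
#' takes the layout as data rather than hard-coding it; per-study text lives
#' under `meta/studies/` (corpus files must already carry it -- no live GEO
#' supplementation is performed).
#'
#' Entries under `samples` and `studies` other than `sample_id`/`study_id`
#' are optional: a missing dataset yields empty strings.
#'
#' @return Nested list naming HDF5 dataset paths for counts, gene ids, and
#'   the per-sample and per-study metadata fields.
#' @export
archs4_layout <- function() {
  list(
    counts = "data/expression",
    genes = "meta/genes/symbol",
    samples = list(
      sample_id = "meta/samples/geo_accession",
      study_id = "meta/samples/series_id",
      title = "meta/samples/title",
      source_name = "meta/samples/source_name_ch1",
      characteristics = "meta/samples/characteristics_ch1",
      condition = "meta/samples/condition"),
    studies = list(
      study_id = "meta/studies/series_id",
      title = "meta/studies/title",
      summary = "meta/studies/summary",
      overall_design = "meta/studies/overall_design"))
}

.h5_dataset_paths <- function(path) {
  info <- rhdf5::h5ls(path)
  sub("^/+", "", paste(info$group, info$name, sep = "/"))
}

.h5_read_or <- function(path, name, present, default = NULL) {
  if (!(name %in% present)) return(default)
  as.vector(rhdf5::h5read(path, name))
}

#' Read an ARCHS4-style HDF5 corpus
#'
#' @param path HDF5 file path.
#' @param layout layout map as returned by [archs4_layout()]; override
#'   entries to match other corpus dialects.
#' @return A [tx_corpus()] object. Samples keep their stored order; each
#'   sample's `sample_text` is the single-space concatenation of its
#'   non-empty title, source name and characteristics fields.
#' @export
read_archs4_h5 <- function(path, layout = archs4_layout()) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  present <- .h5_dataset_paths(path)
  for (req in c(layout$counts, layout$genes,
                layout$samples$sample_id, layout$samples$study_id)) {
    if (!(req %in% present))
      stop("corpus format error: missing required dataset '", req,
           "' in ", path)
  }
  counts <- rhdf5::h5read(path, layout$counts)
  gene_ids <- as.character(rhdf5::h5read(path, layout$genes))
  sample_id <- as.character(rhdf5::h5read(path, layout$samples$sample_id))
  study_id <- as.character(rhdf5::h5read(path, layout$samples$study_id))
  if (ncol(counts) != length(sample_id))
    stop("corpus format error: counts has ", ncol(counts),
         " columns but ", length(sample_id), " sample ids are present")
  n <- length(sample_id)
  opt <- function(field) {
    v <- .h5_read_or(path, layout$samples[[field]], present,
                     default = rep("", n))
    v[is.na(v)] <- ""
    as.character(v)
  }
  title <- opt("title")
  source_name <- opt("source_name")
  characteristics <- opt("characteristics")
  condition <- opt("condition")
  samples <- data.frame(
    sample_id = sample_id, study_id = study_id,
    condition_label = condition, title = title, source_name = source_name,
    characteristics = characteristics, stringsAsFactors = FALSE)

  st_id <- .h5_read_or(path, layout$studies$study_id, present)
  if (is.null(st_id)) {
    studies <- data.frame(study_id = unique(study_id),
                          stringsAsFactors = FALSE)
  } else {
    m <- length(st_id)
    sopt <- function(field) {
      v <- .h5_read_or(path, layout$studies[[field]], present,
                       default = rep("", m))
      v[is.na(v)] <- ""
      as.character(v)
    }
    studies <- data.frame(
      study_id = as.character(st_id), title = sopt("title"),
      summary = sopt("summary"), overall_design = sopt("overall_design"),
      stringsAsFactors = FALSE)
  }
  tx_corpus(counts, gene_ids, samples, studies)
}

#' Write a corpus as an ARCHS4-style HDF5 file
#'
#' Inverse of [read_archs4_h5()]: the written file round-trips counts and
#' metadata strings exactly under the same layout map.
#'
#' @param corpus a [tx_corpus()].
#' @param path output HDF5 path (overwritten if present).
#' @param layout layout map, see [archs4_layout()].
#' @return `path`, invisibly.
#' @export
write_corpus_h5 <- function(corpus, path, layout = archs4_layout()) {
  stopifnot(inherits(corpus, "tx_corpus"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  groups <- unique(dirname(c(
    layout$counts, layout$genes, unlist(layout$samples),
    unlist(layout$studies))))
  for (g in sort(groups[groups != "."])) {
    parts <- strsplit(g, "/")[[1]]
    for (k in seq_along(parts)) {
      sub <- paste(parts[seq_len(k)], collapse = "/")
      if (!.h5_group_exists(path, sub)) rhdf5::h5createGroup(path, sub)
    }
  }
  cm <- corpus$counts
  dimnames(cm) <- NULL
  rhdf5::h5write(cm, path, layout$counts)
  rhdf5::h5write(corpus$gene_ids, path, layout$genes)
  s <- corpus$samples
  rhdf5::h5write(s$sample_id, path, layout$samples$sample_id)
  rhdf5::h5write(s$study_id, path, layout$samples$study_id)
  rhdf5::h5write(s$title, path, layout$samples$title)
  rhdf5::h5write(s$source_name, path, layout$samples$source_name)
  rhdf5::h5write(s$characteristics, path, layout$samples$characteristics)
  rhdf5::h5write(s$condition_label, path, layout$samples$condition)
  st <- corpus$studies
  rhdf5::h5write(st$study_id, path, layout$studies$study_id)
  rhdf5::h5write(st$title, path, layout$studies$title)
  rhdf5::h5write(st$summary, path, layout$studies$summary)
  rhdf5::h5write(st$overall_design, path, layout$studies$overall_design)
  invisible(path)
}

.h5_group_exists <- function(path, group) {
  info <- rhdf5::h5ls(path)
  if (!nrow(info)) return(FALSE)
  group %in% .h5_dataset_paths(path)
}

#' Assemble the searchable text of a study
#'
#' Concatenates title, summary and overall design with single spaces,
#' skipping empty fields. This string is what the metadata embedder sees.
#'
#' @param study one row of a corpus study table (list or data.frame row with
#'   `title`, `summary`, `overall_design`).
#' @return character scalar (empty if all fields are empty).
#' @export
assemble_study_text <- function(study) {
  parts <- c(study$title, study$summary, study$overall_design)
  parts <- parts[!is.na(parts) & nzchar(parts)]
  paste(parts, collapse = " ")
}

#' Read gene sets from a GMT file
#'
#' GMT is the MSigDB interchange format: one gene set per line,
#' tab-separated as name, description, then gene symbols. Duplicate symbols
#' within a line are collapsed (first occurrence kept).
#'
#' @param path GMT file path.
#' @return List of gene sets, each `list(name, description, genes)`, in file
#'   order. Empty file gives an empty list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT parse error at line ", i, ": expected at least 3 tab-",
           "separated fields, found ", length(fields))
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT parse error at line ", i, ": gene set '", fields[1],
           "' has no genes")
    j <- j + 1L
    out[[j]] <- gene_set(fields[1], fields[2], genes)
  }
  out[seq_len(j)]
}

#' Construct a gene set
#'
#' @param name set name.
#' @param description free-text description (MSigDB sets describe the
#'   experimental condition the set was derived from; used as the text query
#'   paired with the set).
#' @param genes character vector of gene symbols (deduplicated, order kept).
#' @return `list(name, description, genes)` of class `gene_set`.
#' @export
gene_set <- function(name, description = "", genes = character()) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set '", name, "' must contain genes")
  structure(list(name = as.character(name),
                 description = as.character(description),
                 genes = genes),
            class = "gene_set")
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
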