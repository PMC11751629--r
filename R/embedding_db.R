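#' Construct an embedding database
#'
#' An embedding database holds one fixed-length real vector per key: study
#' accessions for the metadata space, study/condition pairs for the
#' transcriptome space. All retrieval is exhaustive cosine search over its
#' rows.
#'
#' @param ids character vector of unique keys, one per row.
#' @param vectors numeric matrix, `length(ids)` rows; all entries finite.
#' @param meta named list of provenance (embedder name, dimension, seed,
#'   and any extra per-row annotation such as parallel `study_id` vectors).
#' @return Object of class `embedding_db`.
#' @export
embedding_db <- function(ids, vectors, meta = list()) {
  ids <- as.character(ids)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(ids) != nrow(vectors))
    stop("embedding db: ", length(ids), " ids but ", nrow(vectors), " rows")
  if (anyDuplicated(ids))
    stop("embedding db ids must be unique")
  if (length(vectors) && any(!is.finite(vectors)))
    stop("embedding db vectors must be finite")
  dimnames(vectors) <- NULL
  structure(list(ids = ids, vectors = vectors, meta = meta),
            class = "embedding_db")
}

#' @export
print.embedding_db <- function(x, ...) {
  cat("embedding_db:", nrow(x$vectors), "entries x", ncol(x$vectors),
      "dims (", x$meta$embedder %||% "unknown embedder", ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.DB_FORMAT <- "txscout-embedding-db-1"

#' Persist an embedding database
#'
#' Writes two files: `path` holds the vectors as a raw little-endian float64
#' stream (row after row), and `<path>.json` is a sidecar with the format
#' tag, dimensions, ids and provenance meta. Both are byte-deterministic for
#' a given database, so repeated index builds are bit-identical.
#'
#' @param db an [embedding_db()].
#' @param path output path for the binary array; the JSON sidecar is written
#'   next to it.
#' @return `path`, invisibly.
#' @export
save_embedding_db <- function(db, path) {
  stopifnot(inherits(db, "embedding_db"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(t(db$vectors)), con, size = 8, endian = "little")
  sidecar <- list(format = .DB_FORMAT, n = nrow(db$vectors),
                  dim = ncol(db$vectors), ids = db$ids, meta = db$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load a persisted embedding database
#'
#' @param path path given to [save_embedding_db()].
#' @return The [embedding_db()] with ids, vectors (bit-exact) and meta
#'   restored.
#' @export
load_embedding_db <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("embedding db not found: ", path)
  if (!file.exists(sidecar_path))
    stop("embedding db sidecar not found: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!identical(sc$format, .DB_FORMAT))
    stop("embedding db format mismatch: expected '", .DB_FORMAT,
         "', found '", sc$format, "'")
  n <- as.integer(sc$n); d <- as.integer(sc$dim)
  expected_bytes <- as.numeric(n) * d * 8
  if (file.info(path)$size != expected_bytes)
    stop("embedding db file is truncated or corrupt: expected ",
         expected_bytes, " bytes, found ", file.info(path)$size)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "double", n = n * d, size = 8, endian = "little")
  vectors <- matrix(vals, nrow = n, ncol = d, byrow = TRUE)
  meta <- sc$meta
  if (is.null(meta)) meta <- list()
  embedding_db(as.character(sc$ids), vectors, as.list(meta))
}
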