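#' 32-bit FNV-1a hash of character strings
#'
#' Fowler-Noll-Vo 1a over the UTF-8 bytes of each string: the hash starts at
#' the offset basis, and each byte is XORed in and then multiplied by the
#' FNV prime 16777619 modulo 2^32. Implemented in split 16-bit arithmetic so
#' the result is exact in doubles; no process-level hash randomization is
#' involved, so values are identical across platforms and sessions.
#'
#' @param x character vector.
#' @param init offset basis (default the standard 2166136261; the signed
#'   feature hasher uses a second basis to draw an independent sign bit).
#' @return numeric vector of hash values in `[0, 2^32)`.
#' @export
fnv1a32 <- function(x, init = 2166136261) {
  vapply(x, function(s) {
    h <- init
    for (b in utf8ToInt(s)) {
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256L))
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      h <- (lo * 16777619 + ((hi * 403) %% 65536) * 65536) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

.tokenize <- function(text) {
  regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))[[1]]
}

#' Signed feature-hashing text embedding
#'
#' A deterministic bag-of-tokens embedder: text is lowercased and split on
#' non-alphanumeric characters; each token is assigned a bucket in
#' `[1, dim]` by FNV-1a and a sign by the parity of a second FNV-1a pass
#' with a different offset basis; token counts are accumulated with their
#' signs and the result is L2-normalized. Empty text maps to the zero
#' vector. Identical text always yields an identical vector, across
#' processes and platforms.
#'
#' This is the built-in stand-in for a pretrained sentence embedder: it
#' captures lexical overlap, not meaning, but satisfies the same vector
#' contract, so any retrieval behaviour is unchanged when a semantic model
#' is plugged in via [text_embedder()].
#'
#' @param text character scalar.
#' @param dim embedding dimension (default 384, matching the output width of
#'   compact sentence-transformer models so the pipeline shape is realistic).
#' @return L2-normalized numeric vector of length `dim` (all-zero for empty
#'   text).
#' @export
hash_embed <- function(text, dim = 384) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1) stop("embedding dim must be >= 1")
  v <- numeric(dim)
  if (is.na(text) || !nzchar(text)) return(v)
  toks <- .tokenize(text)
  if (!length(toks)) return(v)
  counts <- table(toks)
  uniq <- names(counts)
  bucket <- fnv1a32(uniq) %% dim + 1
  sign <- ifelse(fnv1a32(uniq, init = 40389) %% 2 == 0, 1, -1)
  contrib <- sign * as.numeric(counts)
  for (i in seq_along(uniq)) v[bucket[i]] <- v[bucket[i]] + contrib[i]
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Define a text embedder
#'
#' All retrieval code depends only on this contract: `embed(text)` returns a
#' length-`dim`, L2-normalized numeric vector (zero vector for empty text),
#' and identical text gives identical output. Register an adapter around any
#' pretrained sentence model by passing its scoring closure as `fn`.
#'
#' @param name embedder name, recorded in database provenance.
#' @param dim output dimension.
#' @param fn function(text) -> numeric vector of length `dim`.
#' @return Object of class `text_embedder`.
#' @export
text_embedder <- function(name, dim, fn) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1) stop("embedding dim must be >= 1")
  stopifnot(is.function(fn))
  structure(list(name = name, dim = dim, fn = fn), class = "text_embedder")
}

#' The built-in hash embedder
#'
#' @param dim output dimension, default 384.
#' @return A [text_embedder()] wrapping [hash_embed()].
#' @export
hash_text_embedder <- function(dim = 384) {
  force(dim)
  text_embedder("hash-fnv1a", dim, function(text) hash_embed(text, dim))
}

#' Embed a query string
#'
#' @param text query text.
#' @param embedder a [text_embedder()].
#' @return numeric vector of length `embedder$dim`.
#' @export
embed_query <- function(text, embedder = hash_text_embedder()) {
  stopifnot(inherits(embedder, "text_embedder"))
  v <- embedder$fn(text)
  if (length(v) != embedder$dim)
    stop("embedder '", embedder$name, "' returned length ", length(v),
         ", expected ", embedder$dim)
  as.numeric(v)
}

#' Build the metadata embedding database of a corpus
#'
#' One row per study, in corpus study order: the study's assembled text
#' (title, summary, overall design; see [assemble_study_text()]) passed
#' through the embedder.
#'
#' @param corpus a [tx_corpus()].
#' @param embedder a [text_embedder()] (default: the 384-d hash embedder).
#' @return An [embedding_db()] keyed by study_id.
#' @export
build_metadata_db <- function(corpus, embedder = hash_text_embedder()) {
  stopifnot(inherits(corpus, "tx_corpus"))
  n <- nrow(corpus$studies)
  vectors <- matrix(0, nrow = n, ncol = embedder$dim)
  for (i in seq_len(n)) {
    txt <- assemble_study_text(corpus$studies[i, ])
    v <- tryCatch(embed_query(txt, embedder), error = function(e)
      stop("embedding failed for study ", corpus$studies$study_id[i], ": ",
           conditionMessage(e)))
    vectors[i, ] <- v
  }
  embedding_db(corpus$studies$study_id, vectors,
               meta = list(embedder = embedder$name, dim = embedder$dim,
                           space = "metadata"))
}
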