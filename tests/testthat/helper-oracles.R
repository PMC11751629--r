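# Independent brute-force / enumeration oracles. These are deliberately
# written as explicit loops over the defining formulas, not by reusing the
# package's vectorized code paths.

# ssGSEA running-sum score, position by position
oracle_ssgsea <- function(expr, set_genes, alpha) {
  ids <- names(expr)
  ord <- order(-expr, ids, method = "radix")
  ids_sorted <- ids[ord]
  n <- length(ids_sorted)
  inset <- ids_sorted %in% set_genes
  m <- sum(inset)
  denom_in <- 0
  for (j in seq_len(n)) if (inset[j]) denom_in <- denom_in + (n - j + 1)^alpha
  es <- 0; p_in <- 0; p_out <- 0
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + (n - i + 1)^alpha / denom_in
    else p_out <- p_out + 1 / (n - m)
    es <- es + (p_in - p_out)
  }
  es
}

# Benjamini-Hochberg step-up, q_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * p[o[j]] / j)
    q[o[i]] <- min(best, 1)
  }
  q
}

# exhaustive cosine scan with explicit per-row arithmetic
oracle_knn <- function(query, vectors, ids, n) {
  s <- numeric(nrow(vectors))
  qn <- sqrt(sum(query^2))
  for (i in seq_len(nrow(vectors))) {
    num <- sum(query * vectors[i, ])
    rn <- sqrt(sum(vectors[i, ]^2))
    s[i] <- if (rn == 0) 0 else num / (rn * qn)
  }
  ord <- order(-s, ids, method = "radix")
  take <- ord[seq_len(min(n, length(ord)))]
  data.frame(id = ids[take], score = s[take], stringsAsFactors = FALSE)
}

# two-sided Fisher by hypergeometric enumeration over all tables with the
# observed margins (relative tolerance on probability ties as is standard)
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(a_vals, function(a)
    dhyper(a, c1, n - c1, r1), numeric(1))
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided signed-rank p via enumeration of all sign assignments
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    W <- sum(r[bits == 1])
    if (abs(W - mu) >= abs(w - mu) - 1e-12) count <- count + 1L
  }
  count / 2^n
}

# mean pairwise distance by explicit double loop
oracle_interpoint <- function(vectors, metric) {
  n <- nrow(vectors)
  total <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diff <- vectors[i, ] - vectors[j, ]
    d <- switch(metric,
      l1 = sum(abs(diff)),
      l2 = sqrt(sum(diff^2)),
      cosine_dist = 1 - sum(vectors[i, ] * vectors[j, ]) /
        (sqrt(sum(vectors[i, ]^2)) * sqrt(sum(vectors[j, ]^2))))
    total <- total + d
    pairs <- pairs + 1
  }
  total / pairs
}
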