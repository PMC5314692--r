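# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from first principles (plain
# loops and closed forms) and share no code with the package internals.

# Noisy-OR scoring oracle: enumerate all evidence per pair, keep the max
# score per platform, multiply out the closed forms directly.
oracle_score_database <- function(evidence, prior = NULL) {
  keys <- sort(unique(c(evidence$key, names(prior))))
  out <- data.frame(key = keys, p_prev = 0, p_new = 0, p_final = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    ev <- evidence[evidence$key == keys[i], , drop = FALSE]
    p_new <- 0
    if (nrow(ev)) {
      s_per_platform <- vapply(split(ev$s_i, ev$platform), max, numeric(1))
      prod_term <- 1
      for (s in s_per_platform) prod_term <- prod_term * (1 - s)
      p_new <- 1 - prod_term
    }
    p_prev <- if (!is.null(prior) && keys[i] %in% names(prior))
      unname(prior[[keys[i]]]) else 0
    out$p_prev[i] <- p_prev
    out$p_new[i] <- p_new
    out$p_final[i] <- 1 - (1 - p_prev) * (1 - p_new)
  }
  out
}

# Exact hypergeometric upper-tail via binomial coefficients.
oracle_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# AUC as the fraction of correctly ordered (positive, negative) pairs.
oracle_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Tie-free Spearman rho straight from the rank-difference formula.
oracle_spearman <- function(rank_a, rank_b) {
  n <- length(rank_a)
  1 - 6 * sum((rank_a - rank_b)^2) / (n * (n^2 - 1))
}

# All-pairs shortest-path lengths by plain BFS over an adjacency list.
oracle_all_distances <- function(keys) {
  p <- ppintegrate::key_parts(keys)
  p <- p[!p$self, , drop = FALSE]
  nodes <- sort(unique(c(p$a, p$b)))
  adj <- lapply(setNames(nodes, nodes), function(v)
    c(p$b[p$a == v], p$a[p$b == v]))
  dists <- c()
  for (i in seq_along(nodes)) {
    d <- setNames(rep(Inf, length(nodes)), nodes)
    d[nodes[i]] <- 0
    frontier <- nodes[i]
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(d[nxt])]
      d[nxt] <- d[frontier[1]] + 1
      frontier <- nxt
    }
    if (i < length(nodes)) {
      dists <- c(dists, d[nodes[(i + 1):length(nodes)]])
    }
  }
  unname(dists)
}

# SNAP-style interpolated percentile of an integer distance multiset.
oracle_interp_percentile <- function(dist, pct) {
  tab <- table(dist)
  d <- as.numeric(names(tab))
  cdf <- cumsum(as.numeric(tab)) / length(dist)
  hi <- which(cdf >= pct)[1]
  if (hi == 1) return(d[1])
  d[hi - 1] + (pct - cdf[hi - 1]) / (cdf[hi] - cdf[hi - 1]) *
    (d[hi] - d[hi - 1])
}

# --- small fixture builders -------------------------------------------------

make_evidence <- function(key, source, platform, s_i) {
  p <- ppintegrate::key_parts(key)
  data.frame(key = key, a = p$a, b = p$b, source = source,
             platform = platform, s_i = s_i, stringsAsFactors = FALSE)
}

make_source_table <- function(name, key, platform = name, s_i = 0.5) {
  source_table(make_evidence(key, name, platform, s_i), source_name = name)
}

random_evidence_tables <- function(n_pairs, n_sources = 3L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("G%03d", 1:60)
  keys <- character(0)
  while (length(keys) < n_pairs) {
    a <- sample(ids, 2 * n_pairs, replace = TRUE)
    b <- sample(ids, 2 * n_pairs, replace = TRUE)
    keys <- unique(c(keys, canonical_pair(a[a != b], b[a != b])))
  }
  keys <- keys[seq_len(n_pairs)]
  platforms <- c("curated_literature", "affinity_purification",
                 "yeast_two_hybrid", "co_expression", "text_mining")
  lapply(seq_len(n_sources), function(si) {
    n_rows <- rpois(1, n_pairs) + 1L
    k <- sample(keys, n_rows, replace = TRUE)   # duplicates on purpose
    make_source_table(paste0("src", si), k,
                      platform = sample(platforms, n_rows, replace = TRUE),
                      s_i = round(runif(n_rows), 3))
  })
}

# Tiny two-level ontology used across GO-similarity tests:
# root -> {A, B}; A -> {A1, A2}. Genes: g1={A1}, g2={A2}, g3={B}, g4={A}.
toy_corpus <- function() {
  dag <- data.frame(
    child = c("BP:A", "BP:B", "BP:A1", "BP:A2"),
    parent = c("BP:root", "BP:root", "BP:A", "BP:A"),
    namespace = "BP", stringsAsFactors = FALSE)
  gaf <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    term = c("BP:A1", "BP:A2", "BP:B", "BP:A"), stringsAsFactors = FALSE)
  build_corpus(gaf, dag)
}
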