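## Network-property comparisons of interactomes: largest component,
## scale-free degree fit, effective diameter, and hub rank correlation.

keys_to_graph <- function(db) {
  db <- unique(db)
  p <- key_parts(db)
  p <- p[!p$self, , drop = FALSE]  # self-loops carry no path information
  igraph::graph_from_data_frame(p[, c("a", "b")], directed = FALSE)
}

#' Largest connected component of an interactome
#'
#' @param db Character vector of canonical keys.
#' @return An undirected `igraph` graph. Ties between equally large
#'   components are broken toward the component containing the
#'   lexicographically smallest node.
#' @export
largest_component <- function(db) {
  if (length(db) == 0L) stop("empty database", call. = FALSE)
  g <- keys_to_graph(db)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    best <- best[order(firsts)][1L]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Log-log degree-distribution fit
#'
#' Least-squares regression of `log10(count)` on `log10(degree)` over the
#' raw degree histogram (degrees with at least one node; zero-degree nodes
#' excluded). A strongly negative slope with high R-squared indicates the
#' scale-free regime typical of PPI networks.
#'
#' @param db Character vector of canonical keys, or an `igraph` graph.
#' @return A `degree_fit`: list with `slope`, `intercept`, `r_squared` and
#'   the degree `histogram`.
#' @export
degree_fit <- function(db) {
  deg <- if (inherits(db, "igraph")) igraph::degree(db) else key_degrees(db)
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 3L) {
    stop("need at least 3 distinct degrees for a log-log fit", call. = FALSE)
  }
  d <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  fit <- stats::lm(log10(cnt) ~ log10(d))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 histogram = data.frame(degree = d, count = cnt)),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat("<degree_fit> slope ", round(x$slope, 3), ", intercept ",
      round(x$intercept, 3), ", R^2 ", round(x$r_squared, 3), "\n", sep = "")
  invisible(x)
}

#' Effective diameter of a connected network
#'
#' The interpolated `percentile` (default 90th) of the shortest-path-length
#' distribution over distinct node pairs. Following the SNAP convention, the
#' value interpolates linearly between the largest integer distance whose
#' cumulative share is below the percentile and the next one; if the
#' percentile is already reached at distance 1 the effective diameter is 1.
#' For graphs of at most `exact_below` nodes all pairs are used; larger
#' graphs are estimated by BFS from `n_sources` uniformly sampled source
#' nodes.
#'
#' @param graph An `igraph` graph (connected; run [largest_component()]
#'   first) or a key vector describing one.
#' @param percentile Quantile of the distance distribution, in (0, 1].
#' @param n_sources BFS sources for the sampled estimate.
#' @param seed Integer seed for source sampling.
#' @param exact_below Node-count threshold under which the exact all-pairs
#'   distribution is used.
#' @return Effective diameter (numeric, possibly fractional).
#' @export
effective_diameter <- function(graph, percentile = 0.9, n_sources = 100L,
                               seed = 1L, exact_below = 2000L) {
  if (!inherits(graph, "igraph")) graph <- keys_to_graph(graph)
  if (!igraph::is_connected(graph)) {
    stop("graph is disconnected; compute largest_component() first",
         call. = FALSE)
  }
  n <- igraph::vcount(graph)
  if (n < 2L) return(0)
  if (n <= exact_below) {
    dmat <- igraph::distances(graph)
    dist <- dmat[upper.tri(dmat)]
  } else {
    set.seed(seed)
    src <- sample.int(n, min(n_sources, n))
    dmat <- igraph::distances(graph, v = src)
    dist <- as.numeric(dmat)
    dist <- dist[dist > 0]
  }
  interpolated_percentile(dist, percentile)
}

# Linear interpolation of the percentile over integer distances (SNAP rule).
interpolated_percentile <- function(dist, percentile) {
  tab <- table(dist)
  d <- as.numeric(names(tab))
  cdf <- cumsum(as.numeric(tab)) / length(dist)
  hi <- which(cdf >= percentile)[1L]
  if (hi == 1L) return(d[1L])
  cdf_lo <- cdf[hi - 1L]
  d[hi - 1L] + (percentile - cdf_lo) / (cdf[hi] - cdf_lo) *
    (d[hi] - d[hi - 1L])
}

#' Spearman's rank correlation over a shared item set
#'
#' With no ties the textbook formula
#' \deqn{\rho = 1 - 6 \sum_i d_i^2 / (n (n^2 - 1))}
#' is used exactly, `d_i` being the per-item rank differences. With ties,
#' average ranks and the general product-moment correlation of ranks are
#' used, and the result is flagged (`ties = TRUE`).
#'
#' @param ranking_a,ranking_b Named numeric vectors: item scores (higher =
#'   better) or ranks; only items present in both are compared.
#' @param scores_are_ranks If `TRUE` the inputs are ranks (lower = better);
#'   otherwise they are scores ranked in decreasing order.
#' @return A `rank_correlation`: list with `rho`, `n`, per-item rank
#'   differences `d` and the `ties` flag.
#' @export
spearman_rho <- function(ranking_a, ranking_b, scores_are_ranks = FALSE) {
  common <- intersect(names(ranking_a), names(ranking_b))
  n <- length(common)
  if (n < 2L) stop("need at least 2 shared items", call. = FALSE)
  va <- ranking_a[common]
  vb <- ranking_b[common]
  ra <- if (scores_are_ranks) rank(va, ties.method = "average")
        else rank(-va, ties.method = "average")
  rb <- if (scores_are_ranks) rank(vb, ties.method = "average")
        else rank(-vb, ties.method = "average")
  ties <- anyDuplicated(ra) > 0L || anyDuplicated(rb) > 0L
  d <- ra - rb
  rho <- if (ties) stats::cor(ra, rb) else 1 - 6 * sum(d^2) / (n * (n^2 - 1))
  structure(list(rho = rho, n = n, d = setNames(d, common), ties = ties),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat("<rank_correlation> rho = ", round(x$rho, 4), " over n = ", x$n,
      if (x$ties) " (ties: average-rank correlation)" else "", "\n", sep = "")
  invisible(x)
}

#' Hub rank correlation between two interactomes
#'
#' Takes the top-k hubs (by degree, ties lexicographic) of the row database
#' `db_a`, restricts to those also present in `db_b`, ranks the shared hubs
#' by degree within each database, and returns Spearman's rho. The
#' construction is asymmetric by design: it conditions on `db_a`'s hub list.
#'
#' @param db_a,db_b Character vectors of canonical keys.
#' @param k Number of hubs taken from `db_a`.
#' @return A `rank_correlation`, or `NA` (with a warning) when fewer than 2
#'   hubs are shared.
#' @export
hub_rank_correlation <- function(db_a, db_b, k = 100L) {
  hubs <- hub_set(db_a, k)
  deg_a <- key_degrees(db_a)
  deg_b <- key_degrees(db_b)
  shared <- intersect(hubs, names(deg_b))
  if (length(shared) < 2L) {
    warning("fewer than 2 of db_a's top-", k,
            " hubs are present in db_b; correlation undefined")
    return(NA)
  }
  spearman_rho(deg_a[shared], deg_b[shared])
}

#' Summary network statistics of an interactome
#'
#' Convenience wrapper computing the statistics used when comparing
#' database releases: size, largest-component coverage, degree fit, and
#' effective diameter.
#'
#' @inheritParams effective_diameter
#' @param db Character vector of canonical keys.
#' @param min_star Optional star-tier floor; requires `scored` rows.
#' @param scored Optional `scored_interactions` used with `min_star`.
#' @return List of summary statistics.
#' @export
network_summary <- function(db = NULL, scored = NULL, min_star = NULL,
                            percentile = 0.9, n_sources = 100L, seed = 1L,
                            exact_below = 2000L) {
  if (is.null(db)) {
    stopifnot(!is.null(scored))
    db <- scored$key
    if (!is.null(min_star)) db <- scored$key[scored$star >= min_star]
  }
  db <- unique(db)
  lcc <- largest_component(db)
  fit <- tryCatch(degree_fit(db), error = function(e) NULL)
  list(n_interactions = length(db),
       n_proteins = length(key_proteins(db)),
       lcc_nodes = igraph::vcount(lcc),
       lcc_edges = igraph::ecount(lcc),
       effective_diameter = effective_diameter(
         lcc, percentile = percentile, n_sources = n_sources, seed = seed,
         exact_below = exact_below),
       degree_fit = fit)
}
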