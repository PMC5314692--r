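## Stochastic-error, false-positive, and systematic-bias evaluation of an
## integrated interactome against external reference sets.

#' Gold-standard pair enrichment by repeated random sampling (MPE)
#'
#' Draws `n_samples` random samples of `sample_size` distinct pairs from the
#' database (without replacement within a sample, independently across
#' samples) and counts each sample's overlap with a gold-standard pair set.
#' The resulting overlap distribution characterizes how strongly the database
#' is enriched for validated pairs: the higher its mean and the better it
#' separates from a competing database's distribution, the better the data
#' quality. For a database of size N containing m gold pairs the overlap is
#' hypergeometric with expectation `sample_size * m / N`.
#'
#' @param db Character vector of canonical keys.
#' @param gold Character vector of gold-standard keys.
#' @param sample_size Pairs per sample (must not exceed `length(db)`).
#' @param n_samples Number of repeated samples.
#' @param seed Integer seed; the distribution is reproducible under it.
#' @return An `mpe_distribution`: overlap counts, binned histogram, mean,
#'   standard deviation, and the hypergeometric expectation.
#' @export
mpe_distribution <- function(db, gold, sample_size = 1000L,
                             n_samples = 1000L, seed = 1L) {
  db <- unique(db)
  gold <- unique(gold)
  if (sample_size > length(db)) {
    stop("sample_size (", sample_size, ") exceeds database size (",
         length(db), ")", call. = FALSE)
  }
  in_gold <- db %in% gold
  m <- sum(in_gold)
  expectation <- sample_size * m / length(db)
  set.seed(seed)
  overlaps <- vapply(seq_len(n_samples), function(i)
    sum(in_gold[sample.int(length(db), sample_size)]), integer(1))
  structure(list(sample_size = as.integer(sample_size),
                 n_samples = as.integer(n_samples),
                 overlaps = overlaps,
                 histogram = bin_overlaps(overlaps, expectation),
                 mean = mean(overlaps), sd = stats::sd(overlaps),
                 expectation = expectation, seed = as.integer(seed)),
            class = "mpe_distribution")
}

# Width-1 bins when the expected overlap is small; Sturges otherwise.
bin_overlaps <- function(overlaps, expectation) {
  if (expectation < 50) {
    breaks <- seq(min(overlaps) - 0.5, max(overlaps) + 0.5, by = 1)
  } else {
    breaks <- pretty(range(overlaps), n = grDevices::nclass.Sturges(overlaps))
  }
  h <- graphics::hist(overlaps, breaks = breaks, plot = FALSE)
  data.frame(lower = h$breaks[-length(h$breaks)], upper = h$breaks[-1],
             count = h$counts)
}

#' @export
print.mpe_distribution <- function(x, ...) {
  cat("<mpe_distribution> ", x$n_samples, " samples of ", x$sample_size,
      " pairs: mean overlap ", round(x$mean, 2), " (sd ", round(x$sd, 2),
      "), hypergeometric expectation ", round(x$expectation, 2), "\n",
      sep = "")
  invisible(x)
}

#' Normalized sample size for databases of different sizes
#'
#' When comparing overlap distributions between databases whose sizes differ,
#' the fixed-size gold standard is used in full, so the larger database must
#' be sampled proportionally more: the normalized sample size is
#' `round(base_sample * size_ratio)`.
#'
#' @param base_sample Sample size used for the reference database.
#' @param size_ratio Ratio of the target database's size to the reference's.
#' @return Integer sample size.
#' @export
normalized_sample_size <- function(base_sample, size_ratio) {
  if (!is.finite(size_ratio) || size_ratio <= 0) {
    stop("size_ratio must be positive", call. = FALSE)
  }
  as.integer(round(base_sample * size_ratio))
}

#' False-positive ratio against a curated negative set
#'
#' \deqn{E = O / N}
#' where O is the number of database pairs found in the negative (known
#' non-interacting) pair set and N is the database size.
#'
#' @param db Character vector of canonical keys.
#' @param negatives Character vector of negative-set keys.
#' @return A list with `O` (overlap count), `N_db` (database size) and `E`.
#' @export
false_positive_ratio <- function(db, negatives) {
  db <- unique(db)
  if (length(db) == 0L) stop("empty database", call. = FALSE)
  O <- length(intersect(db, unique(negatives)))
  structure(list(O = O, N_db = length(db), E = O / length(db)),
            class = "false_positive_report")
}

#' @export
print.false_positive_report <- function(x, ...) {
  cat("<false_positive_report> O = ", x$O, ", N = ", x$N_db,
      ", E = ", signif(x$E, 4), "\n", sep = "")
  invisible(x)
}

#' Rank-based AUC of confidence scores
#'
#' Mann-Whitney AUC of `p_final` separating gold-standard pairs from
#' negative-set pairs among the scored interactions: the probability that a
#' random positive outranks a random negative, ties counting one half.
#' Positives and negatives are taken as the scored keys present in each
#' reference set; a warning is raised if the two reference sets intersect.
#'
#' @param scored A `scored_interactions` data frame.
#' @param positives,negatives Character vectors of reference keys.
#' @return AUC in [0, 1].
#' @export
score_auc <- function(scored, positives, negatives) {
  if (length(intersect(positives, negatives))) {
    warning("positive and negative reference sets overlap; ",
            "overlapping pairs count in both classes")
  }
  pos <- scored$p_final[scored$key %in% positives]
  neg <- scored$p_final[scored$key %in% negatives]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("need at least one scored positive and one scored negative",
         call. = FALSE)
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Systematic-bias protein sets
#'
#' `absent_protein_set()` returns reference-proteome proteins that
#' participate in no database pair (absent-protein bias).
#' `missing_overlap_set()` returns proteins of gold-standard pairs that are
#' not covered by the database/gold overlap (missing-overlap bias).
#' `hub_set()` returns the top-k proteins by degree of connectivity (hub
#' enrichment bias), ties broken lexicographically for determinism.
#'
#' @param db Character vector of canonical keys.
#' @param reference_proteome Character vector of protein accessions.
#' @return Sorted character vector of protein accessions (for `hub_set()`, a
#'   ranked vector, highest degree first).
#' @export
absent_protein_set <- function(db, reference_proteome) {
  sort(setdiff(unique(reference_proteome), key_proteins(db)))
}

#' @rdname absent_protein_set
#' @param gold Character vector of gold-standard keys.
#' @export
missing_overlap_set <- function(db, gold) {
  gold <- unique(gold)
  covered <- intersect(unique(db), gold)
  sort(setdiff(key_proteins(gold), key_proteins(covered)))
}

#' @rdname absent_protein_set
#' @param k Number of hubs to return.
#' @export
hub_set <- function(db, k = 100L) {
  deg <- key_degrees(db)
  if (length(deg) == 0L) stop("empty database", call. = FALSE)
  if (k > length(deg)) {
    warning("k = ", k, " exceeds the protein count (", length(deg),
            "); returning all proteins")
    k <- length(deg)
  }
  ord <- order(-deg, names(deg))
  names(deg)[ord][seq_len(k)]
}

# degree of connectivity per protein over distinct pairs
key_degrees <- function(db) {
  db <- unique(db)
  if (length(db) == 0L) return(setNames(integer(0), character(0)))
  p <- key_parts(db)
  ends <- c(p$a[!p$self], p$b[!p$self], p$a[p$self])
  tab <- table(ends)
  setNames(as.integer(tab), names(tab))
}

#' Hypergeometric term enrichment with Benjamini-Hochberg adjustment
#'
#' For each ontology term annotated in the background, tests whether the
#' study set is enriched for the term with a one-sided hypergeometric tail
#' (equivalently Fisher's exact test for enrichment), then adjusts across
#' terms by Benjamini-Hochberg. Annotations are used with ancestor
#' propagation.
#'
#' @param set Character vector of study genes (must be a subset of
#'   `background`).
#' @param background Character vector of background genes.
#' @param corpus A `go_corpus` (see [read_annotations()]).
#' @param namespace Ontology namespace to test; default all namespaces.
#' @param alpha Adjusted-p threshold for the `significant` flag.
#' @return Data frame with columns `namespace`, `term`, `set_count`,
#'   `background_count`, `set_size`, `background_size`, `p`, `p_adjust`,
#'   `significant`, sorted by adjusted p.
#' @export
enrichment <- function(set, background, corpus,
                       namespace = names(corpus$namespaces), alpha = 0.05) {
  set <- unique(set)
  background <- unique(background)
  if (length(set) == 0L) stop("empty study set", call. = FALSE)
  if (!all(set %in% background)) {
    stop("study set must be a subset of the background", call. = FALSE)
  }
  rows <- list()
  for (ns in namespace) {
    nsd <- corpus$namespaces[[ns]]
    ann <- nsd$propagated[intersect(background, names(nsd$propagated))]
    if (length(ann) == 0L) next
    bg_genes <- names(ann)
    set_genes <- intersect(set, bg_genes)
    term_bg <- table(unlist(ann, use.names = FALSE))
    term_set <- table(unlist(ann[set_genes], use.names = FALSE))
    terms <- names(term_bg)
    k <- as.integer(term_set[terms])
    k[is.na(k)] <- 0L
    K <- as.integer(term_bg)
    N <- length(bg_genes)
    n <- length(set_genes)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    rows[[ns]] <- data.frame(namespace = ns, term = terms, set_count = k,
                             background_count = K, set_size = n,
                             background_size = N, p = p,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no annotated background genes in the requested namespace(s)",
         call. = FALSE)
  }
  out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjust < alpha
  out <- out[order(out$p_adjust, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
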