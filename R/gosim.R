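## Gene Ontology semantic similarity of interacting partners. Term-level
## similarity uses Lin's information-content measure; gene-level similarity
## is the best-match average (BMA) over the two genes' direct term sets; the
## cross-namespace functional similarity is the mean of the biological-
## process and molecular-function scores where both are defined.

# Lin similarity between two terms: 2*IC(MICA) / (IC(t1) + IC(t2)).
# Degenerate case: if both terms carry zero information (e.g. the root),
# similarity is 0 — sharing an uninformative term is no evidence.
lin_term_sim <- function(t1, t2, nsd) {
  ic1 <- nsd$ic[[t1]]
  ic2 <- nsd$ic[[t2]]
  if (is.na(ic1) || is.na(ic2)) return(NA_real_)
  common <- intersect(nsd$ancestors[[t1]], nsd$ancestors[[t2]])
  if (length(common) == 0L) return(0)
  mica <- max(nsd$ic[common], na.rm = TRUE)
  denom <- ic1 + ic2
  if (denom <= 0) return(0)
  min(1, 2 * mica / denom)
}

bma_gene_sim <- function(terms1, terms2, nsd) {
  simmat <- matrix(NA_real_, length(terms1), length(terms2))
  for (i in seq_along(terms1)) {
    for (j in seq_along(terms2)) {
      simmat[i, j] <- lin_term_sim(terms1[i], terms2[j], nsd)
    }
  }
  if (all(is.na(simmat))) return(NA_real_)
  row_best <- apply(simmat, 1L, max, na.rm = TRUE)
  col_best <- apply(simmat, 2L, max, na.rm = TRUE)
  mean(c(mean(row_best), mean(col_best)))
}

#' Functional similarity of a gene pair
#'
#' Computes an information-content similarity per ontology namespace (Lin
#' term similarity, best-match averaged over the two genes' annotated term
#' sets) and combines namespaces. A gene annotated in neither requested
#' namespace yields `NA` (undefined), not an error.
#'
#' @param g1,g2 Gene/protein accessions.
#' @param corpus A `go_corpus` (see [read_annotations()]).
#' @param namespace Namespaces to use; defaults to all in the corpus.
#' @param combine How to combine the per-namespace scores: `"mean"`
#'   (functional-similarity convention) or `"max"`.
#' @return Similarity in [0, 1], or `NA` when undefined.
#' @export
gene_pair_gosim <- function(g1, g2, corpus,
                            namespace = names(corpus$namespaces),
                            combine = c("mean", "max")) {
  combine <- match.arg(combine)
  per_ns <- vapply(namespace, function(ns) {
    nsd <- corpus$namespaces[[ns]]
    t1 <- nsd$direct[[g1]]
    t2 <- nsd$direct[[g2]]
    if (is.null(t1) || is.null(t2)) return(NA_real_)
    bma_gene_sim(t1, t2, nsd)
  }, numeric(1))
  per_ns <- per_ns[!is.na(per_ns)]
  if (length(per_ns) == 0L) return(NA_real_)
  if (combine == "mean") mean(per_ns) else max(per_ns)
}

pair_gosim <- function(keys, corpus, namespace = names(corpus$namespaces),
                       combine = "mean") {
  p <- key_parts(keys)
  vapply(seq_len(nrow(p)), function(i)
    gene_pair_gosim(p$a[i], p$b[i], corpus, namespace, combine), numeric(1))
}

#' Per-tier GO similarity comparison against random pairs
#'
#' Samples up to `n_per_tier` interactions from each requested star tier,
#' computes their pairwise functional similarity, and compares each tier's
#' sample against a baseline of random pairs drawn from the annotated gene
#' universe using Welch's two-sample t-test. Tiers with fewer than two
#' defined similarity values are skipped with a warning.
#'
#' @param scored A `scored_interactions` data frame.
#' @param corpus A `go_corpus`.
#' @param tiers Integer star tiers to evaluate.
#' @param n_per_tier Interactions sampled per tier (and random baseline
#'   pairs).
#' @param seed Integer seed.
#' @param combine Namespace combination rule (see [gene_pair_gosim()]).
#' @return A `gosim_report`: per-tier similarity samples, tier means, the
#'   random baseline, and a table of Welch t statistics and p-values.
#' @export
tier_gosim_test <- function(scored, corpus, tiers = 1:5, n_per_tier = 200L,
                            seed = 1L, combine = "mean") {
  set.seed(seed)
  universe <- sort(unique(unlist(lapply(corpus$namespaces, function(nsd)
    names(nsd$direct)), use.names = FALSE)))
  if (length(universe) < 2L) stop("no annotated genes in corpus",
                                  call. = FALSE)
  samples <- list()
  skipped <- integer(0)
  for (tier in tiers) {
    keys <- scored$key[scored$star == tier]
    if (length(keys) > n_per_tier) {
      keys <- keys[sample.int(length(keys), n_per_tier)]
    }
    sims <- if (length(keys)) pair_gosim(keys, corpus, combine = combine)
            else numeric(0)
    sims <- sims[!is.na(sims)]
    if (length(sims) < 2L) {
      warning("tier ", tier, " has fewer than 2 pairs with defined ",
              "similarity; skipped")
      skipped <- c(skipped, tier)
      next
    }
    samples[[paste0("star", tier)]] <- sims
  }
  g1 <- universe[sample.int(length(universe), n_per_tier, replace = TRUE)]
  g2 <- universe[sample.int(length(universe), n_per_tier, replace = TRUE)]
  keep <- g1 != g2
  baseline <- vapply(which(keep), function(i)
    gene_pair_gosim(g1[i], g2[i], corpus, combine = combine), numeric(1))
  baseline <- baseline[!is.na(baseline)]
  tests <- do.call(rbind, lapply(names(samples), function(nm) {
    tt <- stats::t.test(samples[[nm]], baseline)
    data.frame(tier = nm, n = length(samples[[nm]]),
               mean = mean(samples[[nm]]), baseline_mean = mean(baseline),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  structure(list(samples = samples, baseline = baseline, tests = tests,
                 skipped_tiers = skipped, combine = combine,
                 seed = as.integer(seed)),
            class = "gosim_report")
}

#' @export
print.gosim_report <- function(x, ...) {
  cat("<gosim_report> baseline mean ", round(mean(x$baseline), 3),
      " over ", length(x$baseline), " random pairs\n", sep = "")
  if (!is.null(x$tests)) print(x$tests, ...)
  if (length(x$skipped_tiers)) {
    cat("skipped tiers:", paste(x$skipped_tiers, collapse = ", "), "\n")
  }
  invisible(x)
}
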