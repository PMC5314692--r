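## Seeded generators for every input the toolkit consumes: a scale-free
## truth network, overlapping evidence sources with controlled redundancy
## and noise, a gold standard partially embedded in the truth, a negative
## set with controlled contamination, a toy ontology with propagated
## annotations, and gene sets drawn from network neighborhoods. Together
## they let the whole pipeline run and be tested without any downloads.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe a small but structured study system: a 500-protein,
#' 2,000-interaction scale-free truth network observed by five partially
#' overlapping evidence sources whose platform reliabilities span the usual
#' curated-to-predicted range; a gold standard covering 20% of the truth; a
#' negative set of non-edges; a two-namespace ontology in which interacting
#' proteins tend to share leaf terms; and curated-style gene sets sampled
#' from network neighborhoods.
#'
#' @param n_proteins Number of proteins in the truth network.
#' @param n_edges Number of truth interactions (>= n_proteins - 1).
#' @param sources Data frame with columns `name`, `platform`, `coverage`
#'   (fraction of truth edges observed) and `noise` (spurious edges as a
#'   fraction of the source's true edges).
#' @param gold_coverage Fraction of truth edges in the gold standard.
#' @param n_negatives Size of the negative pair set.
#' @param negative_contamination Fraction of negatives drawn from truth
#'   edges instead of non-edges.
#' @param ontology_depth,ontology_branching Shape of each namespace's term
#'   tree.
#' @param share_prob Probability that a truth edge's endpoints are given a
#'   shared leaf term.
#' @param n_gene_sets,set_size_range Count and size range of the generated
#'   gene sets.
#' @param seed Integer master seed; each generator derives its own stream.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 500L,
                         n_edges = 2000L,
                         sources = default_synth_sources(),
                         gold_coverage = 0.2,
                         n_negatives = 400L,
                         negative_contamination = 0.0,
                         ontology_depth = 3L,
                         ontology_branching = 3L,
                         share_prob = 0.8,
                         n_gene_sets = 20L,
                         set_size_range = c(10L, 20L),
                         seed = 1L) {
  fr <- c(sources$coverage, sources$noise, gold_coverage,
          negative_contamination, share_prob)
  if (any(fr < 0) || any(c(gold_coverage, negative_contamination,
                           share_prob, sources$coverage) > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_proteins < 3L || n_edges < n_proteins - 1L) {
    stop("need n_proteins >= 3 and n_edges >= n_proteins - 1", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_edges = as.integer(n_edges), sources = sources,
                 gold_coverage = gold_coverage,
                 n_negatives = as.integer(n_negatives),
                 negative_contamination = negative_contamination,
                 ontology_depth = as.integer(ontology_depth),
                 ontology_branching = as.integer(ontology_branching),
                 share_prob = share_prob,
                 n_gene_sets = as.integer(n_gene_sets),
                 set_size_range = as.integer(set_size_range),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_synth_sources <- function() {
  data.frame(
    name     = c("curated_a", "apms", "y2h", "coexpr", "textmine"),
    platform = c("curated_literature", "affinity_purification",
                 "yeast_two_hybrid", "co_expression", "text_mining"),
    coverage = c(0.25, 0.40, 0.35, 0.50, 0.60),
    noise    = c(0.05, 0.20, 0.30, 0.50, 1.00),
    stringsAsFactors = FALSE)
}

synth_protein_ids <- function(n) sprintf("P%05d", seq_len(n))

#' Scale-free truth network
#'
#' Preferential attachment with an exact edge count: a degree-preferential
#' spanning tree (guaranteeing connectivity) followed by additional
#' degree-preferential edges until `n_edges` distinct non-self edges exist.
#' An Erdos-Renyi alternative is available for flat-degree fixtures.
#'
#' @param cfg A `synth_config`.
#' @param model `"pa"` (preferential attachment, default) or `"er"`.
#' @return Character vector of canonical keys, `length == cfg$n_edges`,
#'   forming a connected graph over `cfg$n_proteins` proteins.
#' @export
synth_truth_network <- function(cfg, model = c("pa", "er")) {
  model <- match.arg(model)
  set.seed(derive_seed(cfg$seed, 101L))
  ids <- synth_protein_ids(cfg$n_proteins)
  n <- cfg$n_proteins
  if (model == "er") {
    keys <- sample(all_nonself_keys_sample(ids, cfg$n_edges * 4L))
    tree <- spanning_tree_keys(ids)
    keys <- unique(c(tree, keys))[seq_len(cfg$n_edges)]
    return(sort(keys))
  }
  deg <- integer(n)
  edge_a <- integer(cfg$n_edges)
  edge_b <- integer(cfg$n_edges)
  seen <- new.env(parent = emptyenv(), size = cfg$n_edges * 2L)
  # spanning tree: node i attaches to an earlier node with prob ~ degree + 1
  edge_a[1L] <- 1L; edge_b[1L] <- 2L
  deg[1:2] <- 1L
  assign("1-2", TRUE, envir = seen)
  for (i in 3:n) {
    j <- sample.int(i - 1L, 1L, prob = deg[seq_len(i - 1L)] + 1)
    edge_a[i - 1L] <- j; edge_b[i - 1L] <- i
    deg[c(i, j)] <- deg[c(i, j)] + 1L
    assign(paste(j, i, sep = "-"), TRUE, envir = seen)
  }
  m <- n - 1L
  while (m < cfg$n_edges) {
    u <- sample.int(n, 1L, prob = deg + 1)
    v <- sample.int(n, 1L, prob = deg + 1)
    if (u == v) next
    kk <- paste(min(u, v), max(u, v), sep = "-")
    if (!is.null(get0(kk, envir = seen, inherits = FALSE))) next
    m <- m + 1L
    edge_a[m] <- min(u, v); edge_b[m] <- max(u, v)
    deg[c(u, v)] <- deg[c(u, v)] + 1L
    assign(kk, TRUE, envir = seen)
  }
  sort(canonical_pair(ids[edge_a], ids[edge_b]))
}

spanning_tree_keys <- function(ids) {
  n <- length(ids)
  parent <- c(NA_integer_, vapply(2:n, function(i)
    sample.int(i - 1L, 1L), integer(1)))
  canonical_pair(ids[parent[-1L]], ids[-1L])
}

# sample up to n_try random distinct non-self pairs (may contain truth edges)
all_nonself_keys_sample <- function(ids, n_try) {
  a <- sample(ids, n_try, replace = TRUE)
  b <- sample(ids, n_try, replace = TRUE)
  keep <- a != b
  unique(canonical_pair(a[keep], b[keep]))
}

random_nonedges <- function(ids, truth, n_wanted, exclude = character(0)) {
  out <- character(0)
  truth_set <- c(truth, exclude)
  tries <- 0L
  while (length(out) < n_wanted && tries < 50L) {
    cand <- all_nonself_keys_sample(ids, max(2L * n_wanted, 100L))
    cand <- setdiff(cand, c(truth_set, out))
    out <- c(out, cand)
    tries <- tries + 1L
  }
  if (length(out) < n_wanted) {
    stop("could not sample ", n_wanted, " non-edges; graph too dense",
         call. = FALSE)
  }
  out[seq_len(n_wanted)]
}

#' Synthetic evidence sources over a truth network
#'
#' Each configured source observes a random `coverage` fraction of the truth
#' edges plus `noise * (observed truth edges)` spurious non-truth edges, all
#' labelled with the source's platform and scored with that platform's
#' reliability index. Because sources sample the same truth independently,
#' true interactions are corroborated by several platforms (and earn high
#' noisy-OR scores) while spurious ones usually are not — the structure the
#' confidence model is designed to exploit.
#'
#' @param truth Character vector of truth keys (see [synth_truth_network()]).
#' @param cfg A `synth_config`.
#' @param reliability A `reliability_config` supplying platform scores.
#' @return Named list of `source_table` objects.
#' @export
synth_sources <- function(truth, cfg,
                          reliability = reliability_config()) {
  ids <- synth_protein_ids(cfg$n_proteins)
  out <- list()
  for (i in seq_len(nrow(cfg$sources))) {
    src <- cfg$sources[i, ]
    set.seed(derive_seed(cfg$seed, 200L + i))
    n_true <- round(src$coverage * length(truth))
    true_keys <- if (n_true > 0L) sample(truth, n_true) else character(0)
    n_noise <- round(src$noise * n_true)
    noise_keys <- if (n_noise > 0L)
      random_nonedges(ids, truth, n_noise) else character(0)
    keys <- c(true_keys, noise_keys)
    parts <- key_parts(keys)
    out[[src$name]] <- source_table(
      data.frame(key = keys, a = parts$a, b = parts$b, source = src$name,
                 platform = src$platform,
                 s_i = platform_reliability(src$platform, reliability),
                 stringsAsFactors = FALSE),
      source_name = src$name)
  }
  out
}

#' Synthetic gold standard and negative set
#'
#' The gold standard is a uniform subset of the truth edges
#' (`gold_coverage`); the negative set is `n_negatives` random non-edges,
#' optionally contaminated with `negative_contamination` truth edges to
#' emulate the imperfection of curated negative references.
#'
#' @inheritParams synth_sources
#' @return Character vector of canonical keys.
#' @export
synth_gold <- function(truth, cfg) {
  set.seed(derive_seed(cfg$seed, 301L))
  n <- round(cfg$gold_coverage * length(truth))
  if (n > length(truth)) stop("gold coverage exceeds truth size",
                              call. = FALSE)
  sort(sample(truth, n))
}

#' @rdname synth_gold
#' @export
synth_negatives <- function(truth, cfg) {
  set.seed(derive_seed(cfg$seed, 302L))
  ids <- synth_protein_ids(cfg$n_proteins)
  n_cont <- round(cfg$negative_contamination * cfg$n_negatives)
  n_clean <- cfg$n_negatives - n_cont
  if (n_cont > length(truth)) {
    stop("contamination count exceeds truth size", call. = FALSE)
  }
  cont <- if (n_cont > 0L) sample(truth, n_cont) else character(0)
  clean <- random_nonedges(ids, truth, n_clean)
  sort(c(cont, clean))
}

#' Synthetic ontology and annotations
#'
#' Builds one complete `ontology_branching`-ary term tree of depth
#' `ontology_depth` per namespace (BP and MF), annotates every protein to a
#' random leaf per namespace, then walks the truth edges and, with
#' probability `share_prob`, adds one endpoint's leaf to the other
#' endpoint's annotations — so interacting proteins share informative terms
#' at a controlled rate, which is what GO-similarity validation assumes of
#' real interactomes.
#'
#' @inheritParams synth_sources
#' @return List with `gaf` (gene/term data frame), `dag` (child/parent/
#'   namespace data frame) and the built `corpus`.
#' @export
synth_annotations <- function(truth, cfg) {
  set.seed(derive_seed(cfg$seed, 401L))
  ids <- synth_protein_ids(cfg$n_proteins)
  dag_rows <- list()
  gaf_rows <- list()
  for (ns in c("BP", "MF")) {
    tree <- complete_tree_edges(ns, cfg$ontology_depth,
                                cfg$ontology_branching)
    dag_rows[[ns]] <- tree$edges
    leaves <- tree$leaves
    home <- sample(leaves, length(ids), replace = TRUE)
    ann <- data.frame(gene = ids, term = home, stringsAsFactors = FALSE)
    p <- key_parts(truth)
    share <- stats::runif(nrow(p)) < cfg$share_prob
    extra <- data.frame(
      gene = p$b[share],
      term = ann$term[match(p$a[share], ann$gene)],
      stringsAsFactors = FALSE)
    gaf_rows[[ns]] <- unique(rbind(ann, extra))
  }
  gaf <- do.call(rbind, gaf_rows)
  dag <- do.call(rbind, dag_rows)
  rownames(gaf) <- rownames(dag) <- NULL
  list(gaf = gaf, dag = dag, corpus = build_corpus(gaf, dag))
}

# complete b-ary tree: term tokens "<ns>:<level>_<index>"; root level 0
complete_tree_edges <- function(ns, depth, branching) {
  edges <- list()
  level_nodes <- paste0(ns, ":root")
  all_leaves <- level_nodes
  for (lev in seq_len(depth)) {
    children <- paste0(ns, ":", lev, "_",
                       seq_len(length(level_nodes) * branching))
    parents <- rep(level_nodes, each = branching)
    edges[[lev]] <- data.frame(child = children, parent = parents,
                               namespace = ns, stringsAsFactors = FALSE)
    level_nodes <- children
    all_leaves <- children
  }
  list(edges = do.call(rbind, edges), leaves = all_leaves)
}

#' Synthetic curated gene sets from network neighborhoods
#'
#' Each gene set is grown by breadth-first expansion from a random seed
#' protein until its size falls within `set_size_range`, so the sets are
#' network-coherent and rediscovery through one-step expansion is feasible
#' but not trivial.
#'
#' @inheritParams synth_sources
#' @return Named list of character vectors.
#' @export
synth_gene_sets <- function(truth, cfg) {
  set.seed(derive_seed(cfg$seed, 501L))
  p <- key_parts(truth)
  g <- igraph::graph_from_data_frame(p[, c("a", "b")], directed = FALSE)
  nodes <- igraph::V(g)$name
  sets <- list()
  lo <- cfg$set_size_range[1L]
  hi <- cfg$set_size_range[2L]
  guard <- 0L
  while (length(sets) < cfg$n_gene_sets && guard < cfg$n_gene_sets * 20L) {
    guard <- guard + 1L
    seed_node <- sample(nodes, 1L)
    target <- sample(lo:hi, 1L)
    members <- bfs_neighborhood(g, seed_node, target)
    if (length(members) >= lo) {
      sets[[sprintf("SET%03d", length(sets) + 1L)]] <-
        sort(members[seq_len(min(length(members), target))])
    }
  }
  if (length(sets) < cfg$n_gene_sets) {
    warning("only ", length(sets), " of ", cfg$n_gene_sets,
            " gene sets could be grown to the requested size")
  }
  sets
}

bfs_neighborhood <- function(g, seed_node, target) {
  members <- seed_node
  frontier <- seed_node
  while (length(members) < target && length(frontier) > 0L) {
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, frontier),
                               names), use.names = FALSE))
    nb <- setdiff(nb, members)
    if (length(nb) == 0L) break
    nb <- sample(nb)  # randomize fill order within a ring
    take <- nb[seq_len(min(length(nb), target - length(members)))]
    members <- c(members, take)
    frontier <- take
  }
  members
}

#' Write a full synthetic fixture directory
#'
#' Materializes every generated input in the on-disk formats the readers
#' consume: per-source evidence TSVs, gold and negative pair lists, mapping
#' table, GAF-lite annotations with the DAG edge list, and a GMT file.
#'
#' @param cfg A `synth_config`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory objects.
#' @export
synth_write_all <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- synth_truth_network(cfg)
  sources <- synth_sources(truth, cfg)
  gold <- synth_gold(truth, cfg)
  negatives <- synth_negatives(truth, cfg)
  ann <- synth_annotations(truth, cfg)
  sets <- synth_gene_sets(truth, cfg)
  ids <- synth_protein_ids(cfg$n_proteins)

  paths <- list()
  for (nm in names(sources)) {
    paths[[paste0("source_", nm)]] <- file.path(dir, paste0(nm, ".tsv"))
    st <- sources[[nm]]
    writeLines(paste(st$a, st$b, st$platform, format_num(st$s_i), sep = "\t"),
               paths[[paste0("source_", nm)]])
  }
  paths$truth <- file.path(dir, "truth.tsv")
  write_pair_list(truth, paths$truth)
  paths$gold <- file.path(dir, "gold.tsv")
  write_pair_list(gold, paths$gold)
  paths$negatives <- file.path(dir, "negatives.tsv")
  write_pair_list(negatives, paths$negatives)
  paths$mapping <- file.path(dir, "mapping.tsv")
  writeLines(c("#raw_id\tcanonical_accession\treviewed",
               paste(ids, ids, "Y", sep = "\t")), paths$mapping)
  paths$gaf <- file.path(dir, "annotations.tsv")
  writeLines(paste(ann$gaf$gene, ann$gaf$term, sep = "\t"), paths$gaf)
  paths$dag <- file.path(dir, "ontology_dag.tsv")
  writeLines(paste(ann$dag$child, ann$dag$parent, ann$dag$namespace,
                   sep = "\t"), paths$dag)
  paths$gmt <- file.path(dir, "gene_sets.gmt")
  write_gmt(sets, paths$gmt)
  invisible(list(paths = paths, truth = truth, sources = sources,
                 gold = gold, negatives = negatives, annotations = ann,
                 gene_sets = sets, config = cfg))
}
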