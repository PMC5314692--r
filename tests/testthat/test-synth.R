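test_that("truth network has the exact size, connectivity, reproducibility", {
  cfg <- synth_config(n_proteins = 100, n_edges = 300, seed = 61)
  truth <- synth_truth_network(cfg)
  expect_length(truth, 300)
  expect_false(any(is_self_key(truth)))
  expect_equal(length(key_proteins(truth)), 100)
  g <- largest_component(truth)
  expect_equal(igraph::vcount(g), 100)  # connected by construction
  expect_identical(truth, synth_truth_network(cfg))
  er <- synth_truth_network(cfg, model = "er")
  expect_length(er, 300)
  # preferential attachment concentrates degree more than Erdos-Renyi
  expect_gt(max(key_degrees(truth)), max(key_degrees(er)))
})

test_that("scale-free generator yields a steep log-log degree fit", {
  cfg <- synth_config(n_proteins = 600, n_edges = 2400, seed = 62)
  fit <- degree_fit(synth_truth_network(cfg))
  expect_lt(fit$slope, -1)
  expect_gt(fit$slope, -3.5)
  expect_gt(fit$r_squared, 0.5)
})

test_that("sources hit their coverage and noise targets exactly", {
  cfg <- synth_config(n_proteins = 200, n_edges = 800, seed = 63)
  truth <- synth_truth_network(cfg)
  src <- synth_sources(truth, cfg)
  expect_named(src, cfg$sources$name)
  for (i in seq_len(nrow(cfg$sources))) {
    st <- src[[i]]
    n_true <- round(cfg$sources$coverage[i] * 800)
    n_noise <- round(cfg$sources$noise[i] * n_true)
    expect_equal(nrow(st), n_true + n_noise)
    expect_equal(sum(st$key %in% truth), n_true)
    expect_equal(unique(st$platform), cfg$sources$platform[i])
  }
  # full coverage, zero noise reproduces the truth exactly
  cfg1 <- synth_config(n_proteins = 100, n_edges = 300,
                       sources = data.frame(name = "all", platform = "p",
                                            coverage = 1, noise = 0),
                       seed = 64)
  t1 <- synth_truth_network(cfg1)
  expect_setequal(synth_sources(t1, cfg1)$all$key, t1)
})

test_that("two half-coverage sources overlap near the binomial expectation", {
  cfg <- synth_config(
    n_proteins = 300, n_edges = 2000,
    sources = data.frame(name = c("s1", "s2"), platform = c("p1", "p2"),
                         coverage = 0.5, noise = 0),
    seed = 65)
  truth <- synth_truth_network(cfg)
  src <- synth_sources(truth, cfg)
  ov <- length(intersect(src$s1$key, src$s2$key))
  expected <- 0.25 * 2000
  se <- sqrt(2000 * 0.25 * 0.75)
  expect_lt(abs(ov - expected), 3 * se)
})

test_that("gold and negatives have stated sizes and contamination", {
  cfg <- synth_config(n_proteins = 200, n_edges = 1000, gold_coverage = 0.2,
                      n_negatives = 100, negative_contamination = 0.1,
                      seed = 66)
  truth <- synth_truth_network(cfg)
  gold <- synth_gold(truth, cfg)
  expect_length(gold, 200)
  expect_true(all(gold %in% truth))
  neg <- synth_negatives(truth, cfg)
  expect_length(neg, 100)
  expect_equal(sum(neg %in% truth), 10)   # contamination 0.1 of 100
  cfg0 <- synth_config(n_proteins = 200, n_edges = 1000,
                       negative_contamination = 0, n_negatives = 100,
                       seed = 66)
  expect_length(intersect(synth_negatives(truth, cfg0), truth), 0)
})

test_that("annotations share terms across edges at the configured rate", {
  cfg <- synth_config(n_proteins = 150, n_edges = 500, share_prob = 1,
                      seed = 67)
  truth <- synth_truth_network(cfg)
  ann <- synth_annotations(truth, cfg)
  direct <- ann$corpus$namespaces$BP$direct
  p <- key_parts(truth)
  shares <- vapply(seq_len(nrow(p)), function(i)
    length(intersect(direct[[p$a[i]]], direct[[p$b[i]]])) > 0, logical(1))
  expect_true(all(shares))  # share_prob = 1: every edge shares a leaf
  # depth-1 DAG: everything is annotated to leaves directly under the root
  cfg_d1 <- synth_config(n_proteins = 50, n_edges = 100, ontology_depth = 1,
                         ontology_branching = 2, seed = 68)
  t1 <- synth_truth_network(cfg_d1)
  a1 <- synth_annotations(t1, cfg_d1)
  expect_setequal(unique(a1$dag$parent[a1$dag$namespace == "BP"]), "BP:root")
})

test_that("gene sets respect the size range and live on the network", {
  cfg <- synth_config(n_proteins = 200, n_edges = 800,
                      set_size_range = c(10L, 20L), seed = 69)
  truth <- synth_truth_network(cfg)
  sets <- synth_gene_sets(truth, cfg)
  expect_length(sets, cfg$n_gene_sets)
  expect_true(all(lengths(sets) >= 10 & lengths(sets) <= 20))
  expect_true(all(unlist(sets) %in% key_proteins(truth)))
})

test_that("generators are bit-reproducible and files round-trip", {
  cfg <- synth_config(n_proteins = 80, n_edges = 240, n_gene_sets = 5,
                      seed = 70)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- synth_write_all(cfg, d1)
  r2 <- synth_write_all(cfg, d2)
  expect_identical(r1$truth, r2$truth)
  expect_identical(r1$gold, r2$gold)
  expect_identical(lapply(r1$sources, as.data.frame),
                   lapply(r2$sources, as.data.frame))
  for (f in names(r1$paths)) {
    expect_identical(readLines(r1$paths[[f]]), readLines(r2$paths[[f]]))
  }
  # round-trip through the readers
  mapping <- read_mapping(r1$paths$mapping)
  st <- read_source_table(r1$paths$source_curated_a, "curated_a", mapping)
  expect_setequal(st$key, r1$sources$curated_a$key)
  expect_equal(sort(read_pair_list(r1$paths$gold, mapping)), r1$gold)
  sets <- read_gmt(r1$paths$gmt)
  expect_identical(lapply(sets, sort), lapply(r1$gene_sets, sort))
  corpus <- read_annotations(r1$paths$gaf, r1$paths$dag)
  expect_setequal(names(corpus$namespaces), c("BP", "MF"))
})
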