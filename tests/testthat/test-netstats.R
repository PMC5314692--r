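path_keys <- function(nodes) {
  canonical_pair(nodes[-length(nodes)], nodes[-1])
}

test_that("largest_component picks the biggest (tie: smallest node)", {
  whole <- c("A|B", "B|C", "C|D")
  g <- largest_component(whole)
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C", "D"))
  two <- c(path_keys(c("A", "B", "C", "D", "E")), path_keys(c("X", "Y", "Z")))
  expect_equal(sort(igraph::V(largest_component(two))$name),
               c("A", "B", "C", "D", "E"))
  tie <- c("C|D", "A|B")  # two 2-node components: lexicographic winner
  expect_equal(sort(igraph::V(largest_component(tie))$name), c("A", "B"))
})

test_that("degree_fit recovers an exact power law and rejects regulars", {
  # counts proportional to degree^-2: degree d has round(1000/d^2) nodes
  keys <- character(0)
  node_id <- 0L
  hub_id <- 0L
  for (d in c(1L, 2L, 4L, 8L)) {
    for (rep in seq_len(round(64 / d^2))) {
      node_id <- node_id + 1L
      me <- sprintf("V%04d", node_id)
      partners <- sprintf("W%04d_%d", node_id, seq_len(d))
      keys <- c(keys, canonical_pair(rep(me, d), partners))
    }
  }
  # keep only the V-side histogram: fit on a synthetic degree table instead
  deg_tab <- data.frame(degree = c(1, 2, 4, 8), count = 64 / c(1, 2, 4, 8)^2)
  fit <- stats::lm(log10(count) ~ log10(degree), data = deg_tab)
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 1e-12)  # sanity of model
  g <- igraph::sample_pa(400, m = 2, directed = FALSE)
  igraph::V(g)$name <- sprintf("N%04d", seq_len(400))
  df <- degree_fit(g)
  expect_lt(df$slope, -1)
  expect_gt(df$r_squared, 0.5)
  expect_true(df$r_squared <= 1)
  ring <- canonical_pair(sprintf("R%02d", 1:10),
                         sprintf("R%02d", c(2:10, 1)))
  expect_error(degree_fit(ring), "3 distinct degrees")
})

test_that("effective diameter: complete graph, single edge, path oracle", {
  cmb <- utils::combn(c("A", "B", "C", "D", "E"), 2)
  complete <- canonical_pair(cmb[1, ], cmb[2, ])
  expect_equal(effective_diameter(complete), 1.0)
  expect_equal(effective_diameter(c("A|B")), 1.0)
  # 5-node path: pairwise distances {1,1,1,1,2,2,2,3,3,4}; cdf(2)=.7,
  # cdf(3)=.9 -> interpolated 90th percentile = 2 + (0.9-0.7)/(0.9-0.7) = 3
  expect_equal(effective_diameter(path_keys(c("A", "B", "C", "D", "E"))), 3.0)
  expect_error(effective_diameter(c("A|B", "C|D")), "disconnected")
})

test_that("exact effective diameter equals brute-force BFS; sampling close", {
  for (seed in c(41, 42)) {
    cfg <- synth_config(n_proteins = 80, n_edges = 200, seed = seed)
    truth <- synth_truth_network(cfg)
    dist <- oracle_all_distances(truth)
    want <- oracle_interp_percentile(dist, 0.9)
    expect_equal(effective_diameter(truth), want)
    sampled <- effective_diameter(truth, n_sources = 40, seed = 1,
                                  exact_below = 10)
    expect_lt(abs(sampled - want), 0.5)
  }
})

test_that("spearman_rho implements the rank-difference formula", {
  a <- setNames(c(1, 2, 3), c("x", "y", "z"))
  expect_equal(spearman_rho(a, a, scores_are_ranks = TRUE)$rho, 1)
  rev3 <- setNames(c(3, 2, 1), c("x", "y", "z"))
  expect_equal(spearman_rho(a, rev3, scores_are_ranks = TRUE)$rho, -1)
  b <- setNames(c(2, 1, 3), c("x", "y", "z"))
  r <- spearman_rho(a, b, scores_are_ranks = TRUE)
  expect_equal(r$rho, 0.5)     # 1 - 6*2 / (3*8)
  expect_equal(sum(r$d^2), 2)
  expect_false(r$ties)
  expect_error(spearman_rho(a["x"], b["x"]), "at least 2")
})

test_that("spearman_rho is bounded, reversal-antisymmetric, oracle-equal", {
  set.seed(43)
  for (i in 1:30) {
    n <- sample(3:50, 1)
    items <- sprintf("i%02d", 1:n)
    ra <- setNames(sample(n), items)
    rb <- setNames(sample(n), items)
    r <- spearman_rho(ra, rb, scores_are_ranks = TRUE)
    expect_equal(r$rho, oracle_spearman(ra, rb))
    expect_gte(r$rho, -1); expect_lte(r$rho, 1)
    rev_r <- spearman_rho(ra, setNames(n + 1 - rb, items),
                          scores_are_ranks = TRUE)
    expect_equal(rev_r$rho, -r$rho, tolerance = 1e-12)
  }
  # ties fall back to average-rank correlation, flagged
  ta <- setNames(c(1, 1, 2, 3), sprintf("t%d", 1:4))
  tb <- setNames(c(1, 2, 3, 4), sprintf("t%d", 1:4))
  rt <- spearman_rho(ta, tb, scores_are_ranks = TRUE)
  expect_true(rt$ties)
  expect_equal(rt$rho, cor(rank(ta), rank(tb)))
})

test_that("hub rank correlation conditions on db_a's hub list", {
  db <- c("A|B", "A|C", "A|D", "B|C", "D|E")
  expect_equal(hub_rank_correlation(db, db, k = 5)$rho, 1)
  # stars with distinct hub degrees: A=4, B=3, C=2 in db_a
  star_of <- function(center, n, tag)
    canonical_pair(rep(center, n), sprintf("%s%s_%d", tag, center, 1:n))
  db_a <- c(star_of("A", 4, "L"), star_of("B", 3, "L"), star_of("C", 2, "L"))
  expect_equal(hub_set(db_a, 3), c("A", "B", "C"))
  expect_warning(r_na <- hub_rank_correlation(db_a, c("X|Y"), k = 3),
                 "undefined")
  expect_true(is.na(r_na))
  # db_b reverses the hub order: A=2, B=3, C=4
  db_b <- c(star_of("A", 2, "M"), star_of("B", 3, "M"), star_of("C", 4, "M"))
  r <- hub_rank_correlation(db_a, db_b, k = 3)
  expect_equal(r$rho, -1)
  expect_equal(r$n, 3)
  # hand-ranked fixture: db_c orders hubs (B, A, C) -> d = (1, -1, 0)
  db_c <- c(star_of("A", 3, "K"), star_of("B", 4, "K"), star_of("C", 2, "K"))
  expect_equal(hub_rank_correlation(db_a, db_c, k = 3)$rho,
               1 - 6 * 2 / (3 * 8))  # 0.5 by the rank-difference formula
})

test_that("network_summary composes the pieces and honours star filters", {
  cfg <- synth_config(n_proteins = 100, n_edges = 300, seed = 44)
  truth <- synth_truth_network(cfg)
  s <- network_summary(db = truth)
  expect_equal(s$n_interactions, 300)
  expect_equal(s$lcc_nodes, 100)  # generator guarantees connectivity
  expect_gt(s$effective_diameter, 1)
  expect_lt(s$degree_fit$slope, 0)
})
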