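make_keys <- function(n, prefix = "N") {
  # n distinct canonical pairs over a token universe
  ids <- sprintf("%s%04d", prefix, seq_len(ceiling(sqrt(8 * n)) + 2))
  cmb <- utils::combn(ids, 2)
  canonical_pair(cmb[1, seq_len(n)], cmb[2, seq_len(n)])
}

test_that("MPE saturates and zeroes at the overlap extremes", {
  db <- make_keys(100)
  sat <- mpe_distribution(db, db, sample_size = 20, n_samples = 50, seed = 1)
  expect_true(all(sat$overlaps == 20L))
  none <- mpe_distribution(db, c("X|Y"), sample_size = 20, n_samples = 50,
                           seed = 1)
  expect_true(all(none$overlaps == 0L))
  expect_error(mpe_distribution(db, db, sample_size = 101), "exceeds")
})

test_that("MPE mean tracks the hypergeometric expectation", {
  db <- make_keys(5000)
  gold <- db[seq_len(250)]                    # 5% embedded
  m <- mpe_distribution(db, gold, sample_size = 500, n_samples = 400,
                        seed = 7)
  expect_equal(m$expectation, 500 * 250 / 5000)   # 25
  sd_hyp <- sqrt(500 * 0.05 * 0.95 * (5000 - 500) / (5000 - 1))
  expect_lt(abs(m$mean - m$expectation), 3 * sd_hyp / sqrt(400))
  # reproducible under the seed
  m2 <- mpe_distribution(db, gold, sample_size = 500, n_samples = 400,
                         seed = 7)
  expect_identical(m$overlaps, m2$overlaps)
  expect_equal(sum(m$histogram$count), 400)
})

test_that("normalized sample size scales by the database size ratio", {
  expect_equal(normalized_sample_size(10000, 4.85), 48500L)
  expect_equal(normalized_sample_size(1000, 1.0), 1000L)
  expect_equal(normalized_sample_size(1000, 0.5), 500L)
  expect_error(normalized_sample_size(1000, 0), "positive")
})

test_that("false positive ratio is the negative-set overlap share", {
  db <- make_keys(10)
  r <- false_positive_ratio(db, db[1:2])
  expect_equal(r$O, 2L)
  expect_equal(r$E, 0.2)
  expect_equal(false_positive_ratio(db, c("Q|R"))$E, 0)
  expect_error(false_positive_ratio(character(0), db), "empty")
})

test_that("rank AUC matches pair enumeration, with half-credit ties", {
  scored <- scored_interactions(data.frame(
    key = c("a|b", "c|d", "e|f", "g|h"), a = c("a", "c", "e", "g"),
    b = c("b", "d", "f", "h"), p_prev = 0,
    p_new = c(0.9, 0.4, 0.5, 0.1), p_final = c(0.9, 0.4, 0.5, 0.1),
    star = assign_star(c(0.9, 0.4, 0.5, 0.1)), sources = "s"))
  expect_equal(score_auc(scored, c("a|b", "c|d"), c("e|f", "g|h")), 0.75)
  # separable and constant cases
  expect_equal(score_auc(scored, c("a|b"), c("g|h")), 1.0)
  tied <- scored
  tied$p_new <- tied$p_final <- rep(0.5, 4)
  tied$star <- assign_star(tied$p_final)
  expect_equal(score_auc(tied, c("a|b", "c|d"), c("e|f", "g|h")), 0.5)
  expect_error(score_auc(scored, "x|y", "g|h"), "at least one")
})

test_that("rank AUC equals the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    keys <- make_keys(n)
    p <- round(runif(n), 2)  # rounding forces ties
    scored <- scored_interactions(data.frame(
      key = keys, key_parts(keys)[, c("a", "b")], p_prev = 0, p_new = p,
      p_final = p, star = assign_star(p), sources = "s"))
    pos <- sample(keys, sample(2:(n - 2), 1))
    neg <- setdiff(keys, pos)
    expect_equal(score_auc(scored, pos, neg),
                 oracle_auc(scored$p_final[scored$key %in% pos],
                            scored$p_final[scored$key %in% neg]))
  }
})

test_that("bias sets: absent proteins, missing overlap, hubs", {
  db <- c("A|B", "B|C", "B|D", "B|E")
  expect_equal(absent_protein_set(db, c("A", "B", "Z", "Q")), c("Q", "Z"))
  expect_equal(absent_protein_set(character(0), c("A", "B")), c("A", "B"))
  expect_equal(absent_protein_set(db, c("A", "B")), character(0))

  gold <- c("A|B", "X|Y", "B|C")
  expect_equal(missing_overlap_set(db, gold), c("X", "Y"))
  expect_equal(missing_overlap_set(gold, gold), character(0))
  expect_equal(missing_overlap_set(c("Q|R"), gold),
               sort(c("A", "B", "C", "X", "Y")))

  # star graph: center first; ties broken lexicographically
  expect_equal(hub_set(db, k = 2), c("B", "A"))
  expect_warning(all_h <- hub_set(db, k = 99), "returning all")
  expect_equal(all_h, c("B", "A", "C", "D", "E"))
  fixture <- c("A|B", "A|C", "A|D", "B|C", "E|F")
  expect_equal(hub_set(fixture, k = 6), c("A", "B", "C", "D", "E", "F"))
})

test_that("enrichment p-values match the exact combinatorial tail sum", {
  # background of 20 genes; term T annotates 4, study set of 5 contains 3
  genes <- sprintf("g%02d", 1:20)
  gaf <- data.frame(gene = genes, term = "X:root")
  gaf <- rbind(gaf, data.frame(gene = genes[1:4], term = "X:T"))
  dag <- data.frame(child = "X:T", parent = "X:root", namespace = "X")
  corpus <- build_corpus(gaf, dag)
  set <- c(genes[1:3], genes[10:11])
  tab <- enrichment(set, genes, corpus)
  expect_equal(tab$p[tab$term == "X:T"], oracle_hyper_tail(3, 4, 20, 5))
  # a term annotating the whole background is never enriched
  expect_equal(tab$p[tab$term == "X:root"], 1)
  # set == background -> all p = 1
  all_tab <- enrichment(genes, genes, corpus)
  expect_true(all(all_tab$p == 1))
  expect_true(all(tab$p_adjust >= tab$p))
  expect_error(enrichment(character(0), genes, corpus), "empty")
  expect_error(enrichment(c("zz"), genes, corpus), "subset")
})

test_that("enrichment matches the oracle across random small instances", {
  set.seed(33)
  for (i in 1:10) {
    N <- sample(10:30, 1)
    genes <- sprintf("h%02d", seq_len(N))
    K <- sample(2:(N - 1), 1)
    gaf <- rbind(data.frame(gene = genes, term = "X:root"),
                 data.frame(gene = sample(genes, K), term = "X:T"))
    corpus <- build_corpus(gaf, data.frame(child = "X:T", parent = "X:root",
                                           namespace = "X"))
    n <- sample(2:(N - 1), 1)
    set <- sample(genes, n)
    k <- sum(set %in% gaf$gene[gaf$term == "X:T"])
    tab <- enrichment(set, genes, corpus)
    want <- if (k == 0) 1 else oracle_hyper_tail(k, K, N, n)
    expect_equal(tab$p[tab$term == "X:T"], want, tolerance = 1e-12)
  }
})
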