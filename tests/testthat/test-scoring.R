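test_that("score components follow their definitions", {
  de_tbl <- tibble::tibble(gene_id = c("a", "b", "c"),
                           t_statistic = c(-3, 2, -4))
  expect_equal(de_score("a", de_tbl), 3)
  expect_equal(de_score(c("b", "c"), de_tbl), 3)
  expect_error(de_score(c("a", "zz"), de_tbl), "zz")
  set.seed(2)
  tt <- rnorm(10)
  tbl10 <- tibble::tibble(gene_id = letters[1:10], t_statistic = tt)
  expect_equal(de_score(letters[1:10], tbl10), sum(abs(tt)) / 10,
               tolerance = 1e-14)

  expect_equal(dc_score(tibble::tibble(weight = 5)), 5)
  expect_equal(dc_score(tibble::tibble(weight = numeric(0))), 0)
  w <- runif(7, 1, 10)
  expect_equal(dc_score(tibble::tibble(weight = w)), sum(w) / 7,
               tolerance = 1e-14)

  expect_equal(combined_score(10, 20, 1), 10)
  expect_equal(combined_score(10, 20, 0), 20)
  expect_equal(combined_score(10, 20, 0.7), 13)
  expect_error(combined_score(1, 1, 1.01), "alpha")
})

test_that("greedy first addition maximizes score on a star DCN", {
  t_vals <- c(s = 0, n1 = 0, n2 = 0, n3 = 0)
  edges <- data.frame(a = c("s", "s", "s"), b = c("n1", "n2", "n3"),
                      w = c(10, 5, 1))
  dcn <- make_toy_dcn(edges, t_vals)
  sub <- greedy_search(dcn, "s", search_params(2, 0.1, alpha = 0))
  expect_equal(sub$nodes[2], "n1")
  expect_equal(sub$dc_score, 10)
})

test_that("greedy search equals the step-by-step naive oracle on toy DCNs", {
  # a 6-node DCN with fixed weights and t values
  t_vals <- c(A = 8, B = 2, C = 12, D = 1, E = 6, F = 20)
  edges <- data.frame(
    a = c("A", "A", "B", "B", "C", "D", "E"),
    b = c("B", "C", "C", "D", "E", "E", "F"),
    w = c(4, 9, 2, 7, 5, 3, 11)
  )
  dcn <- make_toy_dcn(edges, t_vals)
  for (seed in c("A", "C", "F")) {
    for (alpha in c(0, 0.4, 0.7, 1)) {
      for (rate in c(0.01, 0.1, 0.5)) {
        sub <- greedy_search(dcn, seed, search_params(2, rate, alpha))
        o <- oracle_greedy(seed, t_vals, edges, 2, rate, alpha)
        expect_identical(sub$nodes, o$nodes)
        expect_equal(sub$trace$score, o$trace, tolerance = 1e-12)
      }
    }
  }
  # and across random toy DCNs
  set.seed(14)
  for (rep in 1:10) {
    ids <- paste0("g", 1:7)
    tv <- setNames(runif(7, 0, 15), ids)
    ee <- t(utils::combn(ids, 2))
    pick <- runif(nrow(ee)) < 0.5
    if (sum(pick) < 3) pick[1:3] <- TRUE
    edf <- data.frame(a = ee[pick, 1], b = ee[pick, 2],
                      w = runif(sum(pick), 0, 12))
    present <- unique(c(edf$a, edf$b))
    dcn2 <- make_toy_dcn(edf, tv[present])
    seed2 <- present[1]
    sub2 <- greedy_search(dcn2, seed2, search_params(3, 0.05, 0.6))
    o2 <- oracle_greedy(seed2, tv[present], edf, 3, 0.05, 0.6)
    expect_identical(sub2$nodes, o2$nodes)
    expect_equal(sub2$trace$score, o2$trace, tolerance = 1e-12)
  }
})

test_that("an extreme improvement rate stops the search immediately", {
  t_vals <- c(A = 5, B = 5, C = 5)
  edges <- data.frame(a = c("A", "B"), b = c("B", "C"), w = c(2, 2))
  dcn <- make_toy_dcn(edges, t_vals)
  sub <- greedy_search(dcn, "A", search_params(2, 1e6, 0.7))
  expect_length(sub$nodes, 1L)
  expect_error(greedy_search(dcn, "ZZ", search_params()), "not a DCN node")
})

test_that("the distance bound restricts candidates to the seed's d-ball", {
  # path A - B - C - D: with d_max = 1 only B is reachable from A
  t_vals <- c(A = 1, B = 10, C = 50, D = 90)
  edges <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                      w = c(1, 100, 100))
  dcn <- make_toy_dcn(edges, t_vals)
  sub1 <- greedy_search(dcn, "A", search_params(1, 0.01, 0.5))
  expect_setequal(sub1$nodes, c("A", "B"))
  sub3 <- greedy_search(dcn, "A", search_params(3, 0.01, 0.5))
  expect_true(length(sub3$nodes) > 2)
})

test_that("search is deterministic and ties break lexicographically", {
  t_vals <- c(S = 0, B2 = 4, B1 = 4)
  edges <- data.frame(a = c("S", "S"), b = c("B2", "B1"), w = c(3, 3))
  dcn <- make_toy_dcn(edges, t_vals)
  sub <- greedy_search(dcn, "S", search_params(2, 0.1, 0.5))
  expect_equal(sub$nodes[2], "B1")
  # node order in the input edge table does not matter
  dcn_rev <- make_toy_dcn(edges[2:1, ], t_vals[c(2, 3, 1)])
  sub_rev <- greedy_search(dcn_rev, "S", search_params(2, 0.1, 0.5))
  expect_identical(sub$nodes, sub_rev$nodes)
})

test_that("accepted steps always clear the relative improvement threshold", {
  # heterogeneous toy DCN guarantees multi-step traces
  set.seed(72)
  ids <- paste0("g", 1:10)
  tv <- setNames(c(1, 20, 3, 15, 2, 30, 5, 8, 25, 4), ids)
  ee <- t(utils::combn(ids, 2))
  pick <- runif(nrow(ee)) < 0.5
  dcn <- make_toy_dcn(
    data.frame(a = ee[pick, 1], b = ee[pick, 2], w = runif(sum(pick), 0, 20)),
    tv
  )
  n_multi <- 0L
  for (s in dcn$nodes$gene_id) {
    sub <- greedy_search(dcn, s, search_params(2, 0.1, 0.7))
    sc <- sub$trace$score
    expect_gte(length(sc), 1L)
    if (length(sc) > 2) {
      n_multi <- n_multi + 1L
      gains <- diff(sc[-1]) / sc[2:(length(sc) - 1)]
      expect_true(all(gains > 0.1))
    }
  }
  expect_gt(n_multi, 0L)
})

test_that("alpha limits reduce the combined score to its components", {
  t_vals <- c(A = 8, B = 2, C = 12, D = 1)
  edges <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                      w = c(4, 9, 2))
  dcn <- make_toy_dcn(edges, t_vals)
  s1 <- greedy_search(dcn, "A", search_params(2, 0.05, 1))
  expect_equal(s1$score, s1$de_score, tolerance = 1e-14)
  s0 <- greedy_search(dcn, "A", search_params(2, 0.05, 0))
  expect_equal(s0$score, s0$dc_score, tolerance = 1e-14)
})

test_that("search_all_seeds returns one subnetwork per seed of the biotype", {
  t_vals <- c(L1 = 3, L2 = 4, L3 = 5, P1 = 6, P2 = 7)
  edges <- data.frame(a = c("L1", "L2", "L3", "P1"),
                      b = c("P1", "P2", "P1", "P2"),
                      w = c(5, 6, 7, 8))
  dcn <- make_toy_dcn(edges, t_vals,
                      biotype = c("lncRNA", "lncRNA", "lncRNA", "PCG", "PCG"))
  subs <- search_all_seeds(dcn, search_params(2, 0.1, 0.7))
  expect_length(subs, 3L)
  expect_setequal(names(subs), c("L1", "L2", "L3"))
  subs_pcg <- search_all_seeds(dcn, search_params(2, 0.1, 0.7),
                               seed_biotype = "PCG")
  expect_setequal(names(subs_pcg), c("P1", "P2"))
  expect_equal(nrow(tidy(subs)), 3L)
})

test_that("subnetwork score identity holds within tolerance", {
  res <- run_small_pipeline(seed = 81, module_size = 6, n_background = 40)
  subs <- search_all_seeds(res$dcn)
  for (s in subs) {
    expect_equal(s$score,
                 combined_score(s$de_score, s$dc_score, s$alpha),
                 tolerance = 1e-9)
  }
})

test_that("subnetwork sizes respond monotonically to the search knobs", {
  res <- run_small_pipeline(seed = 91, module_size = 6, n_background = 60,
                            n_modules = 2)
  # use every node as seed to average over enough searches
  seeds <- res$dcn$nodes$gene_id
  mean_sizes <- vapply(c(0.05, 0.1, 0.3), function(rate) {
    mean(vapply(seeds, function(s)
      length(greedy_search(res$dcn, s, search_params(2, rate, 0.7))$nodes),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sizes) <= 0))
  mean_sizes_d <- vapply(1:3, function(d) {
    mean(vapply(seeds, function(s)
      length(greedy_search(res$dcn, s, search_params(d, 0.05, 0.7))$nodes),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sizes_d) >= 0))
})
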