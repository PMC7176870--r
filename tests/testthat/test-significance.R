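# Shared fixture: two planted modules of unequal strength (strong DE shift
# vs. mild), the DCN, the greedy subnetworks, and a hand-built subnetwork
# spanning the full strong module (fixed topology for the two null models).
sig_fixture <- (function() {
  cache <- NULL
  function() {
    if (is.null(cache)) {
      res <- run_small_pipeline(seed = 101, module_size = 6,
                                n_background = 80, n_modules = 2,
                                de_shift = c(2, 0.4))
      subs <- search_all_seeds(res$dcn)
      full <- make_subnetwork(res$cohort$truth$module_genes[[1]],
                              res$dcn, res$de)
      cache <<- c(res, list(subs = subs, full = full))
    }
    cache
  }
})()

test_that("P1 and P2 use the add-one convention and are seed-reproducible", {
  fx <- sig_fixture()
  cfg <- analysis_config(rng_seed = 7)
  r1 <- permutation_test_labels(fx$full, fx$ds, cfg)
  r2 <- random_subnetwork_test(fx$full, fx$dcn, fx$de, cfg)
  # strong planted signal: observed above every null score in both models
  expect_true(all(r1$null_scores < r1$observed_score))
  expect_equal(r1$p1, 1 / 101)
  # the observed score beats random draws except (possibly) re-draws of the
  # module itself, so p2 sits at the add-one floor up to those ties
  expect_gte(mean(r2$null_scores < r2$observed_score), 0.95)
  expect_equal(r2$p2, (1 + sum(r2$null_scores >= r2$observed_score)) / 101)
  expect_lt(r2$p2, 0.05)
  # p-values bounded away from 0 by the add-one rule
  expect_gte(r1$p1, 1 / 101)
  expect_gte(r2$p2, 1 / 101)
  # bit-for-bit reproducibility from the config seed
  r1b <- permutation_test_labels(fx$full, fx$ds, cfg)
  r2b <- random_subnetwork_test(fx$full, fx$dcn, fx$de, cfg)
  expect_identical(r1$null_scores, r1b$null_scores)
  expect_identical(r2$null_scores, r2b$null_scores)
  # different seed -> different permutations
  r1c <- permutation_test_labels(fx$full, fx$ds, analysis_config(rng_seed = 8))
  expect_false(identical(r1$null_scores, r1c$null_scores))
})

test_that("an observed score at the null median gives p near 0.5", {
  # 50 of the 100 null draws sit at or above 50.5 -> (1 + 50) / 101
  expect_equal(dcnet:::perm_pvalue(50.5, 1:100), 51 / 101)
  expect_equal(dcnet:::perm_pvalue(200, 1:100), 1 / 101)
  expect_equal(dcnet:::perm_pvalue(0, 1:100), 1)
})

test_that("label-permutation p-values are approximately uniform under the null", {
  # fixed 4-node topology scored on pure-noise cohorts, many replicates
  ids <- c("a", "b", "c", "d")
  t_vals <- setNames(rep(0, 4), ids)
  edges <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "d"), w = 1)
  dcn <- make_toy_dcn(edges, t_vals)
  de_null <- tibble::tibble(gene_id = ids, t_statistic = 0)
  sub <- make_subnetwork(ids, dcn, de_null)
  n_rep <- 200
  set.seed(33)
  seeds <- sample.int(1e6, n_rep)
  pvals <- vapply(seq_len(n_rep), function(i) {
    ds <- make_tiny_dataset(n_genes = 4, n_pairs = 20, seed = seeds[i])
    rownames(ds$exprs) <- ids
    ds$genes$gene_id <- ids
    cfg <- analysis_config(rng_seed = seeds[i], n_permutations = 49L)
    permutation_test_labels(sub, ds, cfg)$p1
  }, numeric(1))
  # Kolmogorov band at alpha = .01 for n = 200, plus the lattice spacing of
  # add-one p-values at 49 permutations
  grid <- seq(0, 1, by = 0.01)
  ecdf_vals <- vapply(grid, function(q) mean(pvals <= q), numeric(1))
  expect_lt(max(abs(ecdf_vals - grid)), 1.63 / sqrt(n_rep) + 1 / 50)
  # at 49 permutations the add-one p lattice is k/50, so P(p < .05) = 2/50
  expect_lt(abs(mean(pvals < 0.05) - 0.04), 0.03)
})

test_that("P2 is calibrated when the subnetwork is itself a random draw", {
  fx <- sig_fixture()
  dcn <- fx$dcn
  pool <- dcn$nodes$gene_id
  set.seed(55)
  pvals <- vapply(1:150, function(i) {
    members <- sample(pool, 3)
    fake <- make_subnetwork(members, dcn, fx$de)
    # mimic the top-e rule the null draws use: e = observed edge count
    random_subnetwork_test(fake, dcn, fx$de,
                           analysis_config(rng_seed = i,
                                           n_permutations = 49L))$p2
  }, numeric(1))
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.06)
  expect_gt(mean(pvals), 0.35)
})

test_that("the full planted module is flagged by both tests", {
  fx <- sig_fixture()
  set <- structure(list(M1 = fx$full), class = "dc_subnetwork_set")
  sig <- assess_subnetworks(set, fx$ds, fx$dcn, fx$de, fx$cfg)
  expect_equal(nrow(sig), 1L)
  expect_lt(sig$p1, 0.05)
  expect_lt(sig$p2, 0.05)
  expect_true(sig$significant)
  # greedy 2-node subnetworks from the strong module still clear P1
  strong_seed <- fx$cohort$truth$module_genes[[1]][1]
  sig_greedy <- assess_subnetworks(
    structure(fx$subs[strong_seed], class = "dc_subnetwork_set"),
    fx$ds, fx$dcn, fx$de, fx$cfg
  )
  expect_lt(sig_greedy$p1, 0.05)
})

test_that("random subnetworks respect the edge-count and empty-edge rules", {
  fx <- sig_fixture()
  cfg <- analysis_config(rng_seed = 12, n_permutations = 20L)
  r <- random_subnetwork_test(fx$full, fx$dcn, fx$de, cfg)
  expect_length(r$null_scores, 20L)
  # a gene set with zero internal edges scores alpha * DE only
  de_iso <- tibble::tibble(gene_id = c("X", "Y"), t_statistic = c(2, -4))
  expect_equal(combined_score(de_score(c("X", "Y"), de_iso), 0, 0.7), 0.7 * 3)
  # asking for more genes than the DCN holds is an error
  too_big <- fx$full
  too_big$nodes <- c(too_big$nodes, sprintf("PAD%02d", 1:99))
  expect_error(random_subnetwork_test(too_big, fx$dcn, fx$de, cfg),
               "fewer nodes")
})

test_that("cross-dataset validation flags recurrent modules only", {
  fx <- sig_fixture()
  make_cohort <- function(seed, with_modules = TRUE) {
    specs <- if (with_modules) fx$cohort$truth$specs else list()
    suppressMessages(generate_cohort(specs, 80, 60, seed = seed)$dataset)
  }
  datasets <- list(train = fx$ds, test = make_cohort(202),
                   valid = make_cohort(203))
  cfg <- analysis_config(rng_seed = 5, n_permutations = 30L)
  set <- structure(list(M1 = fx$full), class = "dc_subnetwork_set")
  cv <- cross_dataset_validate(set, datasets, fx$dcn, cfg)
  expect_equal(nrow(cv$per_dataset), 3L)
  expect_true(all(cv$per_dataset$evaluable))
  expect_true(cv$summary$differential)

  # module planted in cohort 1 only -> not differential (and here the
  # module genes are absent from the noise cohorts: non-evaluable)
  datasets_neg <- list(train = fx$ds,
                       noise1 = make_cohort(204, with_modules = FALSE),
                       noise2 = make_cohort(205, with_modules = FALSE))
  cv_neg <- cross_dataset_validate(set, datasets_neg, fx$dcn, cfg)
  expect_false(any(cv_neg$summary$differential))
  expect_equal(sum(!cv_neg$per_dataset$evaluable), 2L)

  # single dataset reduces to the two-test result
  cv_one <- cross_dataset_validate(set, datasets["train"], fx$dcn, cfg)
  expect_equal(cv_one$summary$differential, cv_one$per_dataset$significant)
})

test_that("core-module extraction matches exhaustive enumeration on toys", {
  sets <- list(
    S1 = c("a", "b", "c", "d", "x1"),
    S2 = c("a", "b", "c", "d", "x2"),
    S3 = c("a", "b", "c", "d", "x3", "x4")
  )
  cm <- find_core_modules(sets, min_genes = 4, min_capture = 3)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$genes[[1]], c("a", "b", "c", "d"))
  expect_equal(cm$n_capture, 3L)
  expect_setequal(cm$subnetworks[[1]], c("S1", "S2", "S3"))
  o <- oracle_core_modules(sets, 4, 3)
  expect_length(o, 1L)
  expect_equal(cm$genes[[1]], o[[1]])

  # pairwise disjoint subnetworks give nothing
  disjoint <- list(S1 = c("a", "b", "c", "d"), S2 = c("e", "f", "g", "h"))
  expect_equal(nrow(find_core_modules(disjoint, 4, 3)), 0L)

  # min_capture = 1: every subnetwork of size >= min_genes yields itself
  cm1 <- find_core_modules(disjoint, min_genes = 4, min_capture = 1)
  expect_equal(nrow(cm1), 2L)
  expect_setequal(
    vapply(cm1$genes, paste, collapse = ",", FUN.VALUE = character(1)),
    c("a,b,c,d", "e,f,g,h")
  )

  # richer toy against the exhaustive oracle; every reported module is one
  # of the oracle's maximal qualifying sets and audits its own invariants
  sets2 <- list(
    A = c("g1", "g2", "g3", "g4", "g5"),
    B = c("g1", "g2", "g3", "g4", "g9"),
    C = c("g1", "g2", "g3", "g5", "g9"),
    D = c("g1", "g2", "g3", "g4", "g5"),
    E = c("g7", "g8", "g9", "g10")
  )
  cm2 <- find_core_modules(sets2, min_genes = 3, min_capture = 3)
  o2 <- oracle_core_modules(sets2, 3, 3)
  for (i in seq_len(nrow(cm2))) {
    g <- sort(cm2$genes[[i]])
    expect_true(any(vapply(o2, identical, logical(1), y = g)))
    caps <- cm2$subnetworks[[i]]
    expect_gte(length(caps), 3L)
    expect_gte(cm2$n_genes[i], 3L)
    for (s in caps) expect_true(all(cm2$genes[[i]] %in% sets2[[s]]))
  }
})
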