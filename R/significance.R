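# Permutation-based subnetwork significance: the label-permutation null (P1),
# the random-subnetwork null (P2), cross-dataset validation, and core-module
# extraction.

# Score a fixed subnetwork topology from raw expression submatrices.
# Weights are |delta_z| recomputed from the given condition assignment;
# undefined correlations (zero variance under a permutation) contribute 0.
score_topology <- function(nodes, edge_i, edge_j, nor, tum, alpha) {
  k <- ncol(tum)
  d <- tum - nor
  dbar <- rowMeans(d)
  dsd <- apply(d, 1L, sd)
  tstat <- ifelse(dsd == 0, 0, dbar / (dsd / sqrt(k)))
  de <- mean(abs(tstat))
  if (length(edge_i) == 0L) return(combined_score(de, 0, alpha))
  ii <- match(edge_i, nodes)
  jj <- match(edge_j, nodes)
  r_n <- rowwise_cor(nor[ii, , drop = FALSE], nor[jj, , drop = FALSE])
  r_t <- rowwise_cor(tum[ii, , drop = FALSE], tum[jj, , drop = FALSE])
  r_n[is.na(r_n)] <- 0
  r_t[is.na(r_t)] <- 0
  dz <- (fisher_z(r_t) - fisher_z(r_n)) / sqrt(2 / (k - 3))
  combined_score(de, mean(abs(dz)), alpha)
}

# n_permutations x n_pairs matrix of within-pair swap flags (paired scheme)
# or condition reassignments (free scheme handled at the caller).
make_swap_matrix <- function(n_pairs, n_permutations) {
  matrix(
    runif(n_permutations * n_pairs) < 0.5,
    nrow = n_permutations, ncol = n_pairs
  )
}

#' Label-permutation significance of a subnetwork (P1)
#'
#' Keeps the subnetwork's node and edge sets fixed and rebuilds its score
#' under permuted condition labels: per permutation each sample pair's
#' normal/tumour labels are swapped independently with probability 1/2
#' (preserving the paired design; a free shuffle of all labels is available
#' via `config$p1_scheme = "free"`), then the paired t statistics, the two
#' correlations, delta_z and the combined score are recomputed. P1 is the
#' add-one rank of the observed score in this null:
#' `(1 + #\{null >= observed\}) / (n_permutations + 1)`.
#'
#' @param subnetwork A `dc_subnetwork`.
#' @param ds The [expr_dataset()] to score against.
#' @param config An [analysis_config()]; `rng_seed` fully determines the
#'   permutations when `perms` is not supplied.
#' @param perms Optional pre-drawn swap matrix (permutations x pairs), so a
#'   whole subnetwork set can share one set of label permutations.
#' @return A list with `observed_score`, `p1` and `null_scores`.
#' @export
permutation_test_labels <- function(subnetwork, ds, config = analysis_config(),
                                    perms = NULL) {
  stopifnot(inherits(subnetwork, "dc_subnetwork"), inherits(ds, "expr_dataset"))
  if (config$n_permutations < 1L) abort("`n_permutations` must be >= 1.")
  nodes <- subnetwork$nodes
  missing <- setdiff(nodes, rownames(ds$exprs))
  if (length(missing)) {
    abort(sprintf("Genes absent from dataset: %s", paste(missing, collapse = ", ")))
  }
  nor <- condition_matrix(ds, "normal")[nodes, , drop = FALSE]
  tum <- condition_matrix(ds, "tumour")[nodes, , drop = FALSE]
  k <- ncol(nor)
  ei <- subnetwork$edges$gene_i
  ej <- subnetwork$edges$gene_j
  alpha <- subnetwork$alpha

  observed <- score_topology(nodes, ei, ej, nor, tum, alpha)
  if (is.null(perms)) {
    set.seed(config$rng_seed)
    perms <- if (config$p1_scheme == "paired") {
      make_swap_matrix(k, config$n_permutations)
    } else {
      t(replicate(config$n_permutations, sample(2L * k)))
    }
  }
  null_scores <- vapply(seq_len(nrow(perms)), function(b) {
    if (config$p1_scheme == "paired") {
      sw <- perms[b, ]
      n2 <- nor; t2 <- tum
      n2[, sw] <- tum[, sw, drop = FALSE]
      t2[, sw] <- nor[, sw, drop = FALSE]
    } else {
      all_cols <- cbind(nor, tum)[, perms[b, ], drop = FALSE]
      n2 <- all_cols[, seq_len(k), drop = FALSE]
      t2 <- all_cols[, k + seq_len(k), drop = FALSE]
    }
    score_topology(nodes, ei, ej, n2, t2, alpha)
  }, numeric(1))
  list(
    observed_score = observed,
    p1 = perm_pvalue(observed, null_scores),
    null_scores = null_scores
  )
}

#' Random-subnetwork significance (P2)
#'
#' Builds, for a real subnetwork with n genes and e edges, random
#' counterparts consisting of the seed plus n - 1 genes drawn uniformly
#' without replacement from the DCN nodes; the DCN edges among the selected
#' genes are sorted by weight and the top e form the random subnetwork's
#' edge set (all of them when fewer than e exist). P2 is the add-one rank of
#' the observed score in the distribution of random-subnetwork scores.
#'
#' @param subnetwork A `dc_subnetwork`.
#' @param dcn The DCN the subnetwork was found in.
#' @param de_table DE table supplying t statistics.
#' @param config An [analysis_config()]; `rng_seed` determines the draws.
#' @return A list with `observed_score`, `p2` and `null_scores`.
#' @export
random_subnetwork_test <- function(subnetwork, dcn, de_table,
                                   config = analysis_config()) {
  stopifnot(inherits(subnetwork, "dc_subnetwork"), inherits(dcn, "dcn"))
  nodes <- subnetwork$nodes
  n <- length(nodes)
  pool <- setdiff(dcn$nodes$gene_id, subnetwork$seed)
  if (length(pool) < n - 1L) {
    abort("DCN has fewer nodes than the subnetwork requests.")
  }
  e <- nrow(subnetwork$edges)
  alpha <- subnetwork$alpha
  observed <- combined_score(
    de_score(nodes, de_table), dc_score(subnetwork$edges), alpha
  )
  set.seed(config$rng_seed)
  null_scores <- vapply(seq_len(config$n_permutations), function(b) {
    members <- c(subnetwork$seed, sample(pool, n - 1L))
    ind <- dcn$edges[dcn$edges$gene_i %in% members &
                       dcn$edges$gene_j %in% members, , drop = FALSE]
    if (nrow(ind) > e) {
      ind <- ind[order(ind$weight, decreasing = TRUE)[seq_len(e)], , drop = FALSE]
    }
    combined_score(de_score(members, de_table), dc_score(ind), alpha)
  }, numeric(1))
  list(
    observed_score = observed,
    p2 = perm_pvalue(observed, null_scores),
    null_scores = null_scores
  )
}

#' Run both significance tests over a subnetwork set
#'
#' @param subnetworks A `dc_subnetwork_set`.
#' @param ds The dataset for the label-permutation test.
#' @param dcn The DCN for the random-subnetwork test.
#' @param de_table DE table supplying t statistics.
#' @param config An [analysis_config()]. One shared set of label
#'   permutations is drawn from `rng_seed` for all subnetworks.
#' @return A tibble: `seed`, `n_nodes`, `n_edges`, `observed_score`, `p1`,
#'   `p2`, `significant` (both p-values < 0.05), with the null score vectors
#'   in list columns.
#' @export
assess_subnetworks <- function(subnetworks, ds, dcn, de_table,
                               config = analysis_config()) {
  k <- length(unique(ds$samples$pair_id))
  set.seed(config$rng_seed)
  perms <- if (config$p1_scheme == "paired") {
    make_swap_matrix(k, config$n_permutations)
  } else {
    t(replicate(config$n_permutations, sample(2L * k)))
  }
  purrr::map_dfr(unclass(subnetworks), function(s) {
    r1 <- permutation_test_labels(s, ds, config, perms = perms)
    r2 <- random_subnetwork_test(s, dcn, de_table, config)
    tibble(
      seed = s$seed,
      n_nodes = length(s$nodes),
      n_edges = nrow(s$edges),
      observed_score = r2$observed_score,
      p1 = r1$p1,
      p2 = r2$p2,
      significant = r1$p1 < 0.05 & r2$p2 < 0.05,
      null_p1 = list(r1$null_scores),
      null_p2 = list(r2$null_scores)
    )
  })
}

# Reweight a DCN's fixed topology against another dataset: node t statistics
# and edge |delta_z| recomputed from that dataset; edges with a gene absent
# from the dataset are dropped.
reweight_dcn <- function(dcn, ds, de_table) {
  present <- rownames(ds$exprs)
  e <- dcn$edges[dcn$edges$gene_i %in% present & dcn$edges$gene_j %in% present, ]
  nor <- condition_matrix(ds, "normal")
  tum <- condition_matrix(ds, "tumour")
  k <- ncol(nor)
  r_n <- rowwise_cor(nor[e$gene_i, , drop = FALSE], nor[e$gene_j, , drop = FALSE])
  r_t <- rowwise_cor(tum[e$gene_i, , drop = FALSE], tum[e$gene_j, , drop = FALSE])
  r_n[is.na(r_n)] <- 0
  r_t[is.na(r_t)] <- 0
  dz <- delta_z(r_n, r_t, k, k)
  e$r_n <- r_n
  e$r_t <- r_t
  e$delta_z <- dz$delta_z
  e$weight <- abs(dz$delta_z)
  nodes <- dcn$nodes[dcn$nodes$gene_id %in% present, , drop = FALSE]
  nodes$t_statistic <- de_table$t_statistic[match(nodes$gene_id, de_table$gene_id)]
  out <- dcn
  out$edges <- e
  out$nodes <- nodes
  out
}

#' Cross-dataset validation of subnetworks
#'
#' Keeps every subnetwork's topology fixed and recomputes its score and both
#' significance tests in each supplied dataset (node t statistics and edge
#' weights re-derived from that dataset's expression values). A subnetwork
#' is flagged `differential` only when it is significant (both tests,
#' p < 0.05) in every dataset where it is evaluable, and evaluable in all.
#'
#' @param subnetworks A `dc_subnetwork_set`.
#' @param datasets Named list of [expr_dataset()] objects.
#' @param dcn The training DCN (topology source for the random-subnetwork
#'   null in each dataset).
#' @param config An [analysis_config()].
#' @return A list: `per_dataset` (tibble with one row per subnetwork x
#'   dataset: score, p1, p2, significant, evaluable) and `summary` (tibble
#'   with per-subnetwork counts and the final `differential` flag).
#' @export
cross_dataset_validate <- function(subnetworks, datasets, dcn,
                                   config = analysis_config()) {
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  per <- purrr::imap_dfr(datasets, function(ds, nm) {
    de <- suppressMessages(call_differential_expression(ds))
    rdcn <- reweight_dcn(dcn, ds, de)
    k <- length(unique(ds$samples$pair_id))
    set.seed(config$rng_seed)
    perms <- make_swap_matrix(k, config$n_permutations)
    purrr::map_dfr(unclass(subnetworks), function(s) {
      evaluable <- all(s$nodes %in% rownames(ds$exprs))
      if (!evaluable) {
        return(tibble(
          dataset = nm, seed = s$seed, score = NA_real_,
          p1 = NA_real_, p2 = NA_real_, significant = FALSE, evaluable = FALSE
        ))
      }
      r1 <- permutation_test_labels(s, ds, config, perms = perms)
      r2 <- random_subnetwork_test(s, rdcn, de, config)
      tibble(
        dataset = nm, seed = s$seed, score = r1$observed_score,
        p1 = r1$p1, p2 = r2$p2,
        significant = r1$p1 < 0.05 & r2$p2 < 0.05, evaluable = TRUE
      )
    })
  })
  summary <- per %>%
    group_by(.data$seed) %>%
    summarise(
      n_datasets = n(),
      n_evaluable = sum(.data$evaluable),
      n_significant = sum(.data$significant),
      differential = all(.data$evaluable) & all(.data$significant),
      .groups = "drop"
    )
  list(per_dataset = per, summary = summary)
}

# Number of subnetworks (rows of membership matrix) containing every gene
# in `genes`.
joint_capture <- function(membership, genes) {
  sum(rowSums(membership[, genes, drop = FALSE]) == length(genes))
}

#' Extract core differential co-expression modules
#'
#' Finds gene sets recurrently captured by the subnetworks: starting from
#' each gene contained in at least `min_capture` subnetworks, greedily adds
#' the gene that keeps the joint capture count (number of subnetworks
#' containing every member) at or above `min_capture` while maximizing it
#' (ties broken by lexicographically smallest gene id), until no addition
#' qualifies. Modules with at least `min_genes` genes are kept; modules that
#' are subsets of another reported module are dropped.
#'
#' @param subnetworks A `dc_subnetwork_set`, or a named list of gene-id
#'   vectors.
#' @param min_genes Minimum module size (default 4).
#' @param min_capture Minimum number of capturing subnetworks (default 3).
#' @return A tibble: `module_id`, `hub` (most frequently captured member),
#'   `n_genes`, `n_capture`, and list columns `genes` and `subnetworks`.
#' @export
find_core_modules <- function(subnetworks, min_genes = 4L, min_capture = 3L) {
  sets <- if (inherits(subnetworks, "dc_subnetwork_set")) {
    purrr::map(unclass(subnetworks), "nodes")
  } else {
    subnetworks
  }
  if (is.null(names(sets))) names(sets) <- paste0("S", seq_along(sets))
  all_genes <- sort(unique(unlist(sets)))
  if (length(all_genes) == 0L) return(empty_core_modules())
  membership <- vapply(
    all_genes,
    function(g) vapply(sets, function(s) g %in% s, logical(1)),
    logical(length(sets))
  )
  membership <- matrix(membership, nrow = length(sets),
                       dimnames = list(names(sets), all_genes))
  gene_freq <- colSums(membership)
  starts <- all_genes[gene_freq >= min_capture]
  modules <- list()
  for (g0 in starts) {
    mod <- g0
    repeat {
      capturing <- rowSums(membership[, mod, drop = FALSE]) == length(mod)
      cand <- setdiff(all_genes[colSums(membership[capturing, , drop = FALSE]) > 0], mod)
      if (length(cand) == 0L) break
      counts <- vapply(cand, function(x) joint_capture(membership, c(mod, x)),
                       numeric(1))
      ok <- counts >= min_capture
      if (!any(ok)) break
      cand <- cand[ok]
      counts <- counts[ok]
      pick <- sort(cand[counts == max(counts)])[1L]
      mod <- c(mod, pick)
    }
    if (length(mod) >= min_genes) {
      mod <- sort(mod)
      capt <- names(sets)[rowSums(membership[, mod, drop = FALSE]) == length(mod)]
      modules[[paste(mod, collapse = "|")]] <- list(genes = mod, capture = capt)
    }
  }
  if (length(modules) == 0L) return(empty_core_modules())
  modules <- unname(modules)
  gene_sets <- purrr::map(modules, "genes")
  is_subset <- vapply(seq_along(gene_sets), function(i) {
    any(vapply(seq_along(gene_sets), function(j) {
      i != j && length(gene_sets[[i]]) <= length(gene_sets[[j]]) &&
        all(gene_sets[[i]] %in% gene_sets[[j]]) &&
        !(length(gene_sets[[i]]) == length(gene_sets[[j]]) && i > j)
    }, logical(1)))
  }, logical(1))
  modules <- modules[!is_subset]
  purrr::imap_dfr(modules, function(m, i) {
    freq <- gene_freq[m$genes]
    hub <- sort(m$genes[freq == max(freq)])[1L]
    tibble(
      module_id = paste0("CM", i),
      hub = hub,
      n_genes = length(m$genes),
      n_capture = length(m$capture),
      genes = list(m$genes),
      subnetworks = list(m$capture)
    )
  })
}

empty_core_modules <- function() {
  tibble(
    module_id = character(0), hub = character(0),
    n_genes = integer(0), n_capture = integer(0),
    genes = list(), subnetworks = list()
  )
}
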