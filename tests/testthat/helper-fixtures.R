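# Small in-code fixtures shared across test files.

# Minimal valid paired dataset: g genes x p pairs of hand-set or random data.
make_tiny_dataset <- function(exprs = NULL, n_genes = 5, n_pairs = 6,
                              biotype = NULL, seed = 42) {
  set.seed(seed)
  if (is.null(exprs)) {
    exprs <- matrix(rnorm(n_genes * 2 * n_pairs, mean = 8),
                    nrow = n_genes)
  }
  n_genes <- nrow(exprs)
  n_pairs <- ncol(exprs) / 2
  rownames(exprs) <- sprintf("G%02d", seq_len(n_genes))
  pid <- sprintf("P%02d", seq_len(n_pairs))
  colnames(exprs) <- c(paste0(pid, "_N"), paste0(pid, "_T"))
  if (is.null(biotype)) {
    biotype <- rep(c("lncRNA", "PCG"), length.out = n_genes)
  }
  expr_dataset(
    exprs,
    tibble::tibble(gene_id = rownames(exprs), biotype = biotype),
    tibble::tibble(
      sample_id = colnames(exprs),
      pair_id = rep(pid, 2),
      condition = rep(c("normal", "tumour"), each = n_pairs)
    )
  )
}

# A hand-built DCN over explicit nodes/edges, for search and P2 tests.
make_toy_dcn <- function(edges, t_vals, biotype = NULL) {
  ids <- names(t_vals)
  if (is.null(biotype)) biotype <- rep("lncRNA", length(ids))
  pair <- dcnet:::canonical_pair(edges$a, edges$b)
  structure(
    list(
      edges = tibble::tibble(
        gene_i = pair$gene_i, gene_j = pair$gene_j,
        r_n = 0.9, r_t = 0, z_n = atanh(0.9), z_t = 0,
        delta_z = -edges$w, p_z_raw = 0, p_z_adj = 0,
        weight = edges$w
      ),
      nodes = tibble::tibble(
        gene_id = ids, biotype = biotype,
        t_statistic = unname(t_vals), de_status = "ns"
      ),
      provenance = list(t_z = 1e-7, t_n = 1e-7, t_t = 1e-7,
                       n_normal = 60L, n_tumour = 60L,
                       bh_universe = "union_edges")
    ),
    class = "dcn"
  )
}

# Standard planted-module cohort -> full set of intermediate objects.
run_small_pipeline <- function(seed, module_size = 8, n_background = 150,
                               n_pairs = 60, rho_n = 0.9, rho_t = 0,
                               de_shift = 1, n_modules = 1) {
  de_shift <- rep_len(de_shift, n_modules)
  specs <- lapply(seq_len(n_modules), function(i) {
    planted_module_spec(
      sprintf("M%d_G%02d", i, seq_len(module_size)),
      rho_n, rho_t, de_shift = de_shift[i]
    )
  })
  ch <- generate_cohort(specs, n_background, n_pairs, seed = seed)
  ds <- suppressMessages(filter_low_variance(ch$dataset))
  de <- suppressMessages(call_differential_expression(ds))
  cn <- suppressMessages(correlation_table(ds, "normal"))
  ct <- suppressMessages(correlation_table(ds, "tumour"))
  cfg <- analysis_config(rng_seed = seed)
  ncn <- build_network(cn, cfg$t_n, annotation = ds$genes)
  tcn <- build_network(ct, cfg$t_t, annotation = ds$genes)
  dcn <- build_dcn(cn, ct, ncn, tcn, cfg, de)
  list(cohort = ch, ds = ds, de = de, corr_n = cn, corr_t = ct,
       ncn = ncn, tcn = tcn, dcn = dcn, cfg = cfg)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Hand-built subnetwork over an explicit node set, scored from a DCN and a
# DE table (used where a fixed topology, not the greedy result, is wanted).
make_subnetwork <- function(nodes, dcn, de, alpha = 0.7) {
  ind <- dcn$edges[dcn$edges$gene_i %in% nodes & dcn$edges$gene_j %in% nodes, ]
  de_s <- de_score(nodes, de)
  dc_s <- dc_score(ind)
  structure(
    list(seed = nodes[1], nodes = nodes, edges = ind,
         de_score = de_s, dc_score = dc_s,
         score = combined_score(de_s, dc_s, alpha),
         alpha = alpha, isolated = FALSE,
         trace = tibble::tibble(step = 0L, added = nodes[1],
                                n_nodes = length(nodes),
                                n_edges = nrow(ind),
                                de_score = de_s, dc_score = dc_s,
                                score = combined_score(de_s, dc_s, alpha))),
    class = "dc_subnetwork"
  )
}
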