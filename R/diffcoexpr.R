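#' Fisher z-transformation of a correlation coefficient
#'
#' `z = 0.5 * log((1 + r) / (1 - r))` = arctanh(r). For a sample of size n the
#' transformed correlation is approximately normal with variance 1/(n - 3),
#' which is what makes the difference-of-correlations z-test tractable.
#' Correlations are clamped to +/-(1 - 1e-15) so numerically perfect
#' correlations transform to large finite values rather than infinities.
#'
#' @param r Numeric vector of correlations in \[-1, 1\].
#' @return Fisher z values, same length.
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r) || any(is.na(r)) || any(abs(r) > 1 + 1e-8)) {
    abort("`r` must be numeric with |r| <= 1.")
  }
  r <- pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15)
  0.5 * log((1 + r) / (1 - r))
}

#' Difference-of-correlations z statistic
#'
#' Tests whether a gene pair's Pearson correlation differs between the two
#' conditions: `delta_z = (z_T - z_N) / sqrt(1/(n_T - 3) + 1/(n_N - 3))`,
#' standard normal under the null of equal population correlations; the
#' p-value is the two-sided normal tail.
#'
#' @param r_n,r_t Correlations in the normal and tumour samples (vectors
#'   recycle against each other).
#' @param n_n,n_t Sample counts per condition, both > 3.
#' @return A tibble with columns `delta_z` and `p_raw`.
#' @export
delta_z <- function(r_n, r_t, n_n, n_t) {
  if (any(n_n <= 3) || any(n_t <= 3)) {
    abort("Sample counts must exceed 3 (variance 1/(n - 3)).")
  }
  dz <- (fisher_z(r_t) - fisher_z(r_n)) / sqrt(1 / (n_t - 3) + 1 / (n_n - 3))
  tibble(delta_z = dz, p_raw = 2 * pnorm(-abs(dz)))
}

#' Assemble the differential co-expression network (DCN)
#'
#' Joins the two conditions' correlation tables, computes the
#' difference-of-correlations z statistic per pair, BH-adjusts the z-test
#' p-values, and keeps the pairs that satisfy both DCN conditions: the
#' correlations differ significantly (adjusted z-test p < `t_z`) and the
#' pair is co-expressed in at least one condition (edge of the NCN or TCN).
#' Each retained edge carries the weight `|delta_z|`, the extent of
#' differential co-expression; the signed `delta_z` is kept alongside.
#'
#' The BH universe for the z-test is either the NCN-union-TCN edge pairs
#' (default: only those pairs can enter the DCN) or all evaluated pairs,
#' per `config$bh_universe`.
#'
#' @param corr_n,corr_t Correlation tibbles from [correlation_table()] for
#'   the normal and tumour samples.
#' @param ncn,tcn The thresholded co-expression networks from
#'   [build_network()].
#' @param config An [analysis_config()].
#' @param de Optional DE table from [call_differential_expression()]; when
#'   given, node attributes (biotype, t statistic, DE status) are attached.
#' @return An object of class `dcn` with elements `edges` (tibble:
#'   `gene_i`, `gene_j`, `r_n`, `r_t`, `z_n`, `z_t`, `delta_z`, `p_z_raw`,
#'   `p_z_adj`, `weight`), `nodes` (tibble) and `provenance`.
#' @export
build_dcn <- function(corr_n, corr_t, ncn, tcn, config = analysis_config(),
                      de = NULL) {
  n_n <- attr(corr_n, "n_samples")
  n_t <- attr(corr_t, "n_samples")
  if (is.null(n_n) || is.null(n_t)) {
    abort("Correlation tables must carry an `n_samples` attribute.")
  }
  if (!identical(n_n, ncn$n_samples) || !identical(n_t, tcn$n_samples)) {
    abort("Sample counts of correlation tables and networks disagree.")
  }
  joined <- inner_join(
    corr_n %>% rename(r_n = "r", p_n_raw = "p_raw", p_n_adj = "p_adj"),
    corr_t %>% rename(r_t = "r", p_t_raw = "p_raw", p_t_adj = "p_adj"),
    by = c("gene_i", "gene_j")
  )
  key <- pair_key(joined$gene_i, joined$gene_j)
  in_ncn <- key %in% pair_key(ncn$edges$gene_i, ncn$edges$gene_j)
  in_tcn <- key %in% pair_key(tcn$edges$gene_i, tcn$edges$gene_j)
  coexpressed <- in_ncn | in_tcn

  universe <- if (config$bh_universe == "union_edges") coexpressed else
    rep(TRUE, nrow(joined))
  dz <- delta_z(joined$r_n, joined$r_t, n_n, n_t)
  p_adj <- rep(NA_real_, nrow(joined))
  p_adj[universe] <- bh_adjust(dz$p_raw[universe])

  keep <- !is.na(p_adj) & p_adj < config$t_z & coexpressed
  edges <- tibble(
    gene_i = joined$gene_i[keep],
    gene_j = joined$gene_j[keep],
    r_n = joined$r_n[keep],
    r_t = joined$r_t[keep],
    z_n = fisher_z(joined$r_n[keep]),
    z_t = fisher_z(joined$r_t[keep]),
    delta_z = dz$delta_z[keep],
    p_z_raw = dz$p_raw[keep],
    p_z_adj = p_adj[keep],
    weight = abs(dz$delta_z[keep])
  )
  node_ids <- sort(unique(c(edges$gene_i, edges$gene_j)))
  nodes <- tibble(gene_id = node_ids)
  if (!is.null(de)) {
    nodes <- nodes %>% left_join(
      de %>% select(all_of(c("gene_id", "biotype", "t_statistic",
                             de_status = "status"))),
      by = "gene_id"
    )
  }
  structure(
    list(
      edges = edges,
      nodes = nodes,
      provenance = list(
        t_z = config$t_z, t_n = ncn$threshold, t_t = tcn$threshold,
        n_normal = n_n, n_tumour = n_t,
        bh_universe = config$bh_universe
      )
    ),
    class = "dcn"
  )
}

#' @export
print.dcn <- function(x, ...) {
  cat(sprintf(
    "<dcn> %d nodes, %d edges (t_z = %g, BH universe: %s)\n",
    nrow(x$nodes), nrow(x$edges), x$provenance$t_z, x$provenance$bh_universe
  ))
  invisible(x)
}

#' @export
tidy.dcn <- function(x, ...) x$edges

#' @export
glance.dcn <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    t_z = x$provenance$t_z,
    bh_universe = x$provenance$bh_universe,
    mean_weight = if (nrow(x$edges)) mean(x$edges$weight) else NA_real_
  )
}

# Any of: coexpr_network, dcn, igraph, or a plain edge-list data frame
# (first two columns = endpoints) -> undirected igraph.
as_dcnet_igraph <- function(x) {
  if (inherits(x, "igraph")) return(x)
  if (inherits(x, "coexpr_network")) {
    el <- x$edges %>% select(all_of(c("gene_i", "gene_j", "r", "p_adj")))
    return(igraph::graph_from_data_frame(el, directed = FALSE))
  }
  if (inherits(x, "dcn")) {
    el <- x$edges %>% select(all_of(c("gene_i", "gene_j", "weight", "delta_z")))
    g <- igraph::graph_from_data_frame(
      el, directed = FALSE,
      vertices = if (nrow(x$nodes)) x$nodes
    )
    return(g)
  }
  if (is.data.frame(x)) {
    return(igraph::graph_from_data_frame(x, directed = FALSE))
  }
  abort("Cannot interpret object as a network.")
}
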