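#' Pearson correlation table for one condition
#'
#' Computes the Pearson correlation of every unordered gene pair across the
#' samples of one condition, its two-sided p-value from the t distribution
#' with n - 2 degrees of freedom, and the BH-adjusted p-value over all
#' computed pairs. Pairs involving a gene with zero variance within the
#' condition (where r is undefined) are excluded.
#'
#' @param ds An [expr_dataset()].
#' @param condition `"normal"` or `"tumour"`.
#' @return A tibble with columns `gene_i`, `gene_j` (pair canonicalized so
#'   `gene_i < gene_j`), `r`, `p_raw`, `p_adj`, plus attributes `condition`,
#'   `n_samples` and `dropped_genes`.
#' @export
correlation_table <- function(ds, condition = c("normal", "tumour")) {
  stopifnot(inherits(ds, "expr_dataset"))
  condition <- match.arg(condition)
  x <- condition_matrix(ds, condition)
  n <- ncol(x)
  if (n < 4L) abort("Need at least 4 samples per condition (n - 3 > 0).")
  v <- apply(x, 1L, sd)
  dropped <- rownames(x)[v == 0]
  if (length(dropped)) {
    inform(sprintf(
      "%d gene(s) with zero variance in %s samples excluded from correlations.",
      length(dropped), condition
    ))
    x <- x[v > 0, , drop = FALSE]
  }
  g <- nrow(x)
  if (g < 2L) abort("Fewer than 2 genes with nonzero variance.")
  cm <- cor(t(x))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  ids <- rownames(x)
  pair <- canonical_pair(ids[idx[, 1L]], ids[idx[, 2L]])
  r <- cm[idx]
  r <- pmin(pmax(r, -1), 1)
  p_raw <- cor_pvalue(r, n)
  out <- tibble(
    gene_i = pair$gene_i,
    gene_j = pair$gene_j,
    r = r,
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw)
  )
  attr(out, "condition") <- condition
  attr(out, "n_samples") <- n
  attr(out, "dropped_genes") <- dropped
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH step-up adjusted p-values, returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  assert_prob(p_values, "p_values")
  p.adjust(p_values, method = "BH")
}

#' Build a thresholded co-expression network
#'
#' Retains the gene pairs whose BH-adjusted correlation p-value falls below
#' the threshold; the network's node set is the genes incident to at least
#' one retained edge.
#'
#' @param edges Correlation tibble from [correlation_table()].
#' @param threshold Adjusted-p cutoff in (0, 1); the default 1e-7 is the
#'   stringent cutoff used throughout the pipeline.
#' @param condition,n_samples Condition label and per-condition sample count;
#'   taken from the `edges` attributes when omitted.
#' @param annotation Optional gene annotation tibble (`gene_id`, `biotype`)
#'   enabling edge-class counts (PCG-PCG, PCG-lncRNA, lncRNA-lncRNA).
#' @return An object of class `coexpr_network` with elements `edges`,
#'   `nodes`, `condition`, `n_samples`, `threshold`, `annotation`.
#' @export
build_network <- function(edges, threshold = 1e-7,
                          condition = attr(edges, "condition"),
                          n_samples = attr(edges, "n_samples"),
                          annotation = NULL) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly in (0, 1).")
  }
  kept <- edges[edges$p_adj < threshold, , drop = FALSE]
  structure(
    list(
      edges = as_tibble(kept),
      nodes = sort(unique(c(kept$gene_i, kept$gene_j))),
      condition = condition %||% NA_character_,
      n_samples = n_samples %||% NA_integer_,
      threshold = threshold,
      annotation = if (!is.null(annotation)) as_tibble(annotation)
    ),
    class = "coexpr_network"
  )
}

#' Build one condition's co-expression network from a dataset
#'
#' Convenience wrapper chaining [correlation_table()] and [build_network()].
#'
#' @inheritParams correlation_table
#' @inheritParams build_network
#' @export
build_coexpression_network <- function(ds, condition, threshold = 1e-7) {
  ct <- correlation_table(ds, condition)
  build_network(ct, threshold, annotation = ds$genes)
}

edge_class <- function(gene_i, gene_j, annotation) {
  bt <- setNames(annotation$biotype, annotation$gene_id)
  a <- bt[gene_i]
  b <- bt[gene_j]
  dplyr::case_when(
    a == "PCG" & b == "PCG" ~ "PCG-PCG",
    a == "lncRNA" & b == "lncRNA" ~ "lncRNA-lncRNA",
    TRUE ~ "PCG-lncRNA"
  )
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf(
    "<coexpr_network: %s> %d nodes, %d edges (adjusted p < %g, n = %s)\n",
    x$condition, length(x$nodes), nrow(x$edges), x$threshold, x$n_samples
  ))
  invisible(x)
}

#' @export
tidy.coexpr_network <- function(x, ...) {
  out <- x$edges
  if (!is.null(x$annotation)) {
    out$edge_class <- edge_class(out$gene_i, out$gene_j, x$annotation)
  }
  out
}

#' One-row summary of a co-expression network
#'
#' @param x A `coexpr_network`.
#' @param ... Unused.
#' @return A tibble with node/edge counts, including per-biotype node counts
#'   and per-class edge counts when annotation is attached.
#' @export
glance.coexpr_network <- function(x, ...) {
  base <- tibble(
    condition = x$condition,
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    threshold = x$threshold,
    n_samples = x$n_samples
  )
  if (is.null(x$annotation) || nrow(x$edges) == 0L) return(base)
  bt <- setNames(x$annotation$biotype, x$annotation$gene_id)
  cls <- edge_class(x$edges$gene_i, x$edges$gene_j, x$annotation)
  base %>% mutate(
    n_pcg = sum(bt[x$nodes] == "PCG"),
    n_lncrna = sum(bt[x$nodes] == "lncRNA"),
    edges_pcg_pcg = sum(cls == "PCG-PCG"),
    edges_pcg_lncrna = sum(cls == "PCG-lncRNA"),
    edges_lncrna_lncrna = sum(cls == "lncRNA-lncRNA")
  )
}

#' Write a network edge list as TSV
#'
#' @param x A `coexpr_network` or `dcn` object.
#' @param path Output file. A `# key=value` provenance header is prepended.
#' @export
write_edge_list <- function(x, path) {
  edges <- if (inherits(x, c("coexpr_network", "dcn"))) x$edges else as_tibble(x)
  hdr <- character(0)
  if (inherits(x, "coexpr_network")) {
    hdr <- sprintf(
      "# condition=%s n_samples=%s threshold=%g",
      x$condition, x$n_samples, x$threshold
    )
  } else if (inherits(x, "dcn")) {
    hdr <- sprintf(
      "# t_z=%g t_n=%g t_t=%g n_normal=%d n_tumour=%d bh_universe=%s",
      x$provenance$t_z, x$provenance$t_n, x$provenance$t_t,
      x$provenance$n_normal, x$provenance$n_tumour, x$provenance$bh_universe
    )
  }
  writeLines(hdr, path)
  suppressMessages(readr::write_tsv(edges, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Export a network to GraphML
#'
#' @param x A `coexpr_network` or `dcn`.
#' @param path Output `.graphml` file.
#' @export
write_graphml <- function(x, path) {
  g <- as_dcnet_igraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
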