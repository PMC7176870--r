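#' Topological summary of a network
#'
#' Standard summaries of a simple undirected graph: node/edge counts, degree
#' statistics, mean local clustering coefficient (triangles over possible,
#' with degree < 2 nodes assigned 0), diameter of the largest connected
#' component, mean shortest path over connected node pairs, and a power-law
#' fit of the degree distribution (when at least 3 distinct degrees exist).
#' Biotype node/edge class counts are included when the graph carries a
#' `biotype` vertex attribute.
#'
#' @param network A `coexpr_network`, `dcn`, igraph graph, or edge-list data
#'   frame (first two columns the endpoints).
#' @return A one-row tibble of class `topology_summary`; the per-node degree
#'   and clustering vectors are kept in the `degrees` / `clustering`
#'   attributes.
#' @export
network_summary <- function(network) {
  g <- as_dcnet_igraph(network)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0L) abort("Empty graph.")
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  pl <- tryCatch(
    power_law_fit(deg[deg > 0]),
    error = function(e) list(slope = NA_real_, r_squared = NA_real_)
  )
  out <- tibble(
    n_nodes = n,
    n_edges = m,
    mean_degree = mean(deg),
    median_degree = median(deg),
    max_degree = max(deg),
    mean_clustering = mean(cc),
    diameter = as.integer(igraph::diameter(giant, weights = NA)),
    mean_shortest_path = igraph::mean_distance(g, weights = NA, unconnected = TRUE),
    power_law_slope = pl$slope,
    power_law_r_squared = pl$r_squared
  )
  bt <- igraph::vertex_attr(g, "biotype")
  if (!is.null(bt)) {
    el <- igraph::as_edgelist(g)
    a <- bt[match(el[, 1], igraph::V(g)$name)]
    b <- bt[match(el[, 2], igraph::V(g)$name)]
    cls <- ifelse(a == "PCG" & b == "PCG", "PCG-PCG",
                  ifelse(a == "lncRNA" & b == "lncRNA", "lncRNA-lncRNA",
                         "PCG-lncRNA"))
    out <- out %>% mutate(
      n_pcg = sum(bt == "PCG", na.rm = TRUE),
      n_lncrna = sum(bt == "lncRNA", na.rm = TRUE),
      edges_pcg_pcg = sum(cls == "PCG-PCG"),
      edges_pcg_lncrna = sum(cls == "PCG-lncRNA"),
      edges_lncrna_lncrna = sum(cls == "lncRNA-lncRNA")
    )
  }
  attr(out, "degrees") <- deg
  attr(out, "clustering") <- cc
  class(out) <- c("topology_summary", class(out))
  out
}

#' @export
glance.topology_summary <- function(x, ...) {
  y <- x
  attr(y, "degrees") <- NULL
  attr(y, "clustering") <- NULL
  class(y) <- setdiff(class(y), "topology_summary")
  y
}

#' Random-graph baselines for a network
#'
#' Generates replicate random graphs matched to the observed network and
#' summarizes each: `gnm` draws uniform G(n, m) graphs with the observed
#' node and edge counts; `degree_preserving` rewires the observed graph by
#' repeated double-edge swaps (10 x edges swap attempts), preserving the
#' degree sequence exactly. The comparison reports the small-world
#' diagnostics (observed vs. mean random clustering and path length) and
#' the two-sample Kolmogorov-Smirnov statistic between the observed degree
#' distribution and each replicate's.
#'
#' @param network As in [network_summary()].
#' @param model `"gnm"` or `"degree_preserving"`.
#' @param n_replicates Number of random replicates.
#' @param seed Integer RNG seed.
#' @return A list: `replicates` (tibble of per-replicate summaries),
#'   `comparison` (one-row tibble: observed and mean-random clustering and
#'   path length, their ratios, mean KS statistic).
#' @export
random_baseline <- function(network, model = c("gnm", "degree_preserving"),
                            n_replicates = 20L, seed = 1L) {
  model <- match.arg(model)
  g <- as_dcnet_igraph(network)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  obs <- network_summary(g)
  obs_deg <- attr(obs, "degrees")
  set.seed(seed)
  reps <- purrr::map_dfr(seq_len(n_replicates), function(b) {
    rg <- if (model == "gnm") {
      igraph::sample_gnm(n, m)
    } else {
      igraph::rewire(g, igraph::keeping_degseq(niter = 10L * m))
    }
    s <- network_summary(rg)
    ks <- suppressWarnings(
      stats::ks.test(igraph::degree(rg), obs_deg)$statistic
    )
    glance(s) %>% mutate(replicate = b, ks_degree = unname(ks))
  })
  comparison <- tibble(
    model = model,
    observed_clustering = obs$mean_clustering,
    random_clustering = mean(reps$mean_clustering),
    clustering_ratio = obs$mean_clustering / mean(reps$mean_clustering),
    observed_path_length = obs$mean_shortest_path,
    random_path_length = mean(reps$mean_shortest_path),
    path_length_ratio = obs$mean_shortest_path / mean(reps$mean_shortest_path),
    mean_ks_degree = mean(reps$ks_degree)
  )
  list(replicates = reps, comparison = comparison, model = model)
}

#' Least-squares power-law fit of a degree distribution
#'
#' Bins the degree sequence into its empirical frequency distribution P(k),
#' drops zero-frequency bins, and fits ordinary least squares on
#' (log10 k, log10 P(k)). The slope estimates the scale-free exponent.
#'
#' @param degrees Positive integer degree sequence.
#' @return A list with `slope`, `r_squared` and the binned `table`.
#' @export
power_law_fit <- function(degrees) {
  if (any(degrees <= 0)) abort("Degrees must be positive.")
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  if (length(k) < 3L) abort("Need at least 3 distinct degrees to fit.")
  pk <- as.numeric(tab) / sum(tab)
  fit <- lm(log10(pk) ~ log10(k))
  list(
    slope = unname(coef(fit)[2L]),
    r_squared = summary(fit)$r.squared,
    table = tibble(degree = k, probability = pk)
  )
}

#' Clustering coefficient as a function of degree
#'
#' Bins nodes by degree and reports the mean local clustering coefficient
#' per degree, plus the OLS slope of log10 c(k) on log10 k (degree >= 2 and
#' c > 0 bins only, since log of zero clustering is undefined). A slope
#' near -1 is the signature of hierarchical modularity.
#'
#' @param network As in [network_summary()].
#' @return A list: `by_degree` tibble (`degree`, `mean_clustering`,
#'   `n_nodes`) and `slope`.
#' @export
clustering_vs_degree <- function(network) {
  s <- network_summary(network)
  deg <- attr(s, "degrees")
  cc <- attr(s, "clustering")
  by_deg <- tibble(degree = deg, clustering = cc) %>%
    group_by(.data$degree) %>%
    summarise(
      mean_clustering = mean(.data$clustering),
      n_nodes = n(), .groups = "drop"
    )
  fit_rows <- by_deg %>% filter(.data$degree >= 2, .data$mean_clustering > 0)
  if (nrow(fit_rows) < 3L) abort("Need at least 3 usable degree bins to fit.")
  fit <- lm(log10(mean_clustering) ~ log10(degree), data = fit_rows)
  list(by_degree = by_deg, slope = unname(coef(fit)[2L]))
}
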