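#' Subnetwork scores
#'
#' A subnetwork G = (V, E) of the DCN is scored by combining differential
#' expression and differential co-expression:
#' * `de_score`: mean over V of the absolute paired t statistic, |t_i|;
#' * `dc_score`: mean over E of the edge weights |delta_z|; defined as 0 for
#'   an empty edge set so a bare seed has a well-defined score;
#' * `combined_score`: `alpha * DE + (1 - alpha) * DC`.
#'
#' @param nodes Character vector of member gene ids.
#' @param de_table Tibble carrying `gene_id` and `t_statistic` for every node.
#' @return `de_score`: the mean absolute t statistic.
#' @export
de_score <- function(nodes, de_table) {
  t_vals <- de_table$t_statistic[match(nodes, de_table$gene_id)]
  if (anyNA(t_vals)) {
    abort(sprintf(
      "Missing t statistic for: %s",
      paste(nodes[is.na(t_vals)], collapse = ", ")
    ))
  }
  mean(abs(t_vals))
}

#' @rdname de_score
#' @param edges Tibble with a `weight` column (or a numeric weight vector).
#' @return `dc_score`: the mean absolute edge weight, 0 if no edges.
#' @export
dc_score <- function(edges) {
  w <- if (is.data.frame(edges)) edges$weight else edges
  if (length(w) == 0L) return(0)
  mean(abs(w))
}

#' @rdname de_score
#' @param de,dc Component scores.
#' @param alpha Weight in \[0, 1\] on the differential-expression component.
#' @return `combined_score`: the alpha-weighted combination.
#' @export
combined_score <- function(de, dc, alpha) {
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].")
  }
  alpha * de + (1 - alpha) * dc
}

#' Greedy-search parameters
#'
#' @param d_max Maximum number of edges on the shortest path (in the full
#'   DCN) between a candidate node and the seed. Default 2.
#' @param improvement_rate Minimum relative score gain
#'   `(new - old) / old` required to accept an addition. Default 0.1.
#' @param alpha Score weight, default 0.7.
#' @param improvement_mode `"relative"` (default) or `"absolute"` gain.
#' @return A list of class `search_params`.
#' @export
search_params <- function(d_max = 2L, improvement_rate = 0.1, alpha = 0.7,
                          improvement_mode = c("relative", "absolute")) {
  if (!is_scalar_number(d_max) || d_max < 1) abort("`d_max` must be >= 1.")
  if (!is_scalar_number(improvement_rate) || improvement_rate <= 0) {
    abort("`improvement_rate` must be positive.")
  }
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].")
  }
  structure(
    list(
      d_max = as.integer(d_max), improvement_rate = improvement_rate,
      alpha = alpha, improvement_mode = match.arg(improvement_mode)
    ),
    class = "search_params"
  )
}

# Internal: adjacency + weight lookups for a dcn.
dcn_lookups <- function(dcn) {
  e <- dcn$edges
  adj <- split(c(e$gene_j, e$gene_i), c(e$gene_i, e$gene_j))
  w <- setNames(e$weight, pair_key(e$gene_i, e$gene_j))
  t_vals <- if ("t_statistic" %in% names(dcn$nodes)) {
    setNames(dcn$nodes$t_statistic, dcn$nodes$gene_id)
  } else {
    setNames(rep(NA_real_, nrow(dcn$nodes)), dcn$nodes$gene_id)
  }
  list(adj = adj, w = w, t = t_vals)
}

#' Grow a seed-anchored subnetwork by greedy search
#'
#' Starting from a seed gene, iteratively adds the DCN neighbour of the
#' current subnetwork that maximizes the combined score, bringing along all
#' DCN edges between the new node and the current members. A candidate is
#' admissible only if its unweighted shortest-path distance to the seed in
#' the full DCN is at most `d_max`; the best candidate is accepted only if
#' the score improves by more than `improvement_rate` (relative by default).
#' Ties on score are broken by lexicographically smallest gene id, making
#' the search deterministic.
#'
#' @param dcn A [build_dcn()] result whose nodes carry t statistics.
#' @param seed A gene id present in the DCN.
#' @param params A [search_params()] list.
#' @return An object of class `dc_subnetwork`: seed, member `nodes` (in
#'   insertion order), `edges` (DCN edge subset), the three scores, and a
#'   per-iteration `trace` tibble.
#' @export
greedy_search <- function(dcn, seed, params = search_params()) {
  stopifnot(inherits(dcn, "dcn"))
  if (!seed %in% dcn$nodes$gene_id) {
    abort(sprintf("Seed '%s' is not a DCN node.", seed))
  }
  lk <- dcn_lookups(dcn)
  if (anyNA(lk$t[c(seed, unlist(lk$adj[seed]))])) {
    abort("DCN nodes lack t statistics; build the DCN with a DE table.")
  }
  g <- as_dcnet_igraph(dcn)
  dist_to_seed <- igraph::distances(g, v = seed, weights = NA)[1L, ]

  nodes <- seed
  edge_keys <- character(0)
  sum_t <- abs(lk$t[[seed]])
  sum_w <- 0
  n_v <- 1L
  n_e <- 0L
  score_of <- function(st, nv, sw, ne) {
    combined_score(st / nv, if (ne > 0L) sw / ne else 0, params$alpha)
  }
  cur <- score_of(sum_t, n_v, sum_w, n_e)
  trace <- list(tibble(
    step = 0L, added = seed, n_nodes = 1L, n_edges = 0L,
    de_score = sum_t, dc_score = 0, score = cur
  ))

  repeat {
    cand <- setdiff(unique(unlist(lk$adj[nodes], use.names = FALSE)), nodes)
    cand <- cand[dist_to_seed[cand] <= params$d_max]
    if (length(cand) == 0L) break
    cand <- sort(cand)
    best <- NULL
    best_score <- -Inf
    for (v in cand) {
      nb <- intersect(lk$adj[[v]], nodes)
      wv <- lk$w[pair_key(v, nb)]
      tv <- lk$t[[v]]
      if (is.na(tv)) abort(sprintf("Node '%s' lacks a t statistic.", v))
      sc <- score_of(sum_t + abs(tv), n_v + 1L,
                     sum_w + sum(wv), n_e + length(wv))
      if (sc > best_score) {
        best_score <- sc
        best <- list(v = v, nb = nb, wv = wv, tv = tv)
      }
    }
    improved <- if (params$improvement_mode == "relative") {
      if (cur > 0) (best_score - cur) / cur > params$improvement_rate
      else best_score > cur
    } else {
      best_score - cur > params$improvement_rate
    }
    if (!improved) break
    nodes <- c(nodes, best$v)
    edge_keys <- c(edge_keys, pair_key(best$v, best$nb))
    sum_t <- sum_t + abs(best$tv)
    sum_w <- sum_w + sum(best$wv)
    n_v <- n_v + 1L
    n_e <- n_e + length(best$wv)
    cur <- best_score
    trace[[length(trace) + 1L]] <- tibble(
      step = n_v - 1L, added = best$v, n_nodes = n_v, n_edges = n_e,
      de_score = sum_t / n_v, dc_score = if (n_e) sum_w / n_e else 0,
      score = cur
    )
  }

  edges <- dcn$edges[pair_key(dcn$edges$gene_i, dcn$edges$gene_j) %in%
                       edge_keys, , drop = FALSE]
  structure(
    list(
      seed = seed,
      nodes = nodes,
      edges = as_tibble(edges),
      de_score = sum_t / n_v,
      dc_score = if (n_e) sum_w / n_e else 0,
      score = cur,
      alpha = params$alpha,
      params = params,
      isolated = n_v == 1L,
      trace = bind_rows(trace)
    ),
    class = "dc_subnetwork"
  )
}

#' @export
print.dc_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<dc_subnetwork: seed %s> %d nodes, %d edges; DE=%.3f DC=%.3f D=%.3f%s\n",
    x$seed, length(x$nodes), nrow(x$edges),
    x$de_score, x$dc_score, x$score,
    if (x$isolated) " [isolated seed]" else ""
  ))
  invisible(x)
}

#' @export
tidy.dc_subnetwork <- function(x, ...) x$trace

#' @export
glance.dc_subnetwork <- function(x, ...) {
  tibble(
    seed = x$seed, n_nodes = length(x$nodes), n_edges = nrow(x$edges),
    de_score = x$de_score, dc_score = x$dc_score, score = x$score,
    alpha = x$alpha, isolated = x$isolated
  )
}

#' Run the greedy search from every seed of a biotype
#'
#' Uses each gene of the requested biotype (by default every lncRNA in the
#' DCN) as the seed of an independent greedy search.
#'
#' @inheritParams greedy_search
#' @param seed_biotype `"lncRNA"` (default) or `"PCG"`.
#' @return An object of class `dc_subnetwork_set`: a named list of
#'   `dc_subnetwork` objects, one per seed; `tidy()` gives the flat summary.
#' @export
search_all_seeds <- function(dcn, params = search_params(),
                             seed_biotype = "lncRNA") {
  stopifnot(inherits(dcn, "dcn"))
  if (!"biotype" %in% names(dcn$nodes)) {
    abort("DCN nodes lack biotypes; build the DCN with a DE table.")
  }
  seeds <- sort(dcn$nodes$gene_id[dcn$nodes$biotype %in% seed_biotype])
  subs <- purrr::map(seeds, ~ greedy_search(dcn, .x, params))
  names(subs) <- seeds
  structure(subs, class = "dc_subnetwork_set")
}

#' @export
print.dc_subnetwork_set <- function(x, ...) {
  cat(sprintf("<dc_subnetwork_set> %d subnetworks\n", length(x)))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.dc_subnetwork_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}

#' Write subnetworks as JSON
#'
#' One JSON record per subnetwork: seed, member nodes, edges, scores and
#' the greedy trace.
#'
#' @param subnetworks A `dc_subnetwork_set` (or list of `dc_subnetwork`).
#' @param path Output file.
#' @export
write_subnetworks_json <- function(subnetworks, path) {
  recs <- purrr::map(unclass(subnetworks), function(s) {
    list(
      seed = s$seed, nodes = s$nodes,
      edges = s$edges[, c("gene_i", "gene_j", "weight")],
      de_score = s$de_score, dc_score = s$dc_score, score = s$score,
      alpha = s$alpha, trace = s$trace
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
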