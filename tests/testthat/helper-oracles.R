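# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles, sharing no code path with the package.

# BH step-up: p_(i) -> min_{j >= i} min(1, m p_(j) / j), back in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Correlation p-value by explicit covariance algebra and the t CDF.
oracle_cor_p <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}

# Paired t statistic by the textbook formula.
oracle_paired_t <- function(tum, nor) {
  d <- tum - nor
  k <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(k))
  list(t = tt, p = 2 * pt(-abs(tt), df = k - 1))
}

# Greedy subnetwork search re-implemented naively on explicit structures:
# t_vals named vector, edge data frame (a, b, w). Distances by hand BFS.
oracle_greedy <- function(seed, t_vals, edges, d_max, rate, alpha) {
  nbrs <- function(v) {
    c(edges$b[edges$a == v], edges$a[edges$b == v])
  }
  ew <- function(u, v) {
    hit <- (edges$a == u & edges$b == v) | (edges$a == v & edges$b == u)
    edges$w[hit]
  }
  # BFS hop counts from seed
  dist <- setNames(rep(Inf, length(t_vals)), names(t_vals))
  dist[seed] <- 0
  frontier <- seed
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (u in nbrs(v)) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  score <- function(nodes) {
    es <- edges[(edges$a %in% nodes) & (edges$b %in% nodes), ]
    de <- mean(abs(t_vals[nodes]))
    dc <- if (nrow(es)) mean(abs(es$w)) else 0
    alpha * de + (1 - alpha) * dc
  }
  nodes <- seed
  trace <- score(nodes)
  repeat {
    cand <- setdiff(unique(unlist(lapply(nodes, nbrs))), nodes)
    cand <- cand[dist[cand] <= d_max]
    if (!length(cand)) break
    scs <- vapply(sort(cand), function(v) score(c(nodes, v)), numeric(1))
    best <- names(scs)[which.max(scs)]
    old <- score(nodes)
    gain_ok <- if (old > 0) (max(scs) - old) / old > rate else max(scs) > old
    if (!gain_ok) break
    nodes <- c(nodes, best)
    trace <- c(trace, max(scs))
  }
  list(nodes = nodes, trace = trace)
}

# Topology summary by triple enumeration and all-pairs BFS.
oracle_topology <- function(edges_df) {
  nodes <- sort(unique(c(edges_df[[1]], edges_df[[2]])))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges_df))) {
    adj[edges_df[[1]][i], edges_df[[2]][i]] <- TRUE
    adj[edges_df[[2]][i], edges_df[[1]][i]] <- TRUE
  }
  deg <- rowSums(adj)
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && adj[nb[a], nb[b]]) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
  bfs <- function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]
      q <- q[-1]
      for (u in which(adj[v, ])) {
        if (is.infinite(d[u])) {
          d[u] <- d[v] + 1
          q <- c(q, u)
        }
      }
    }
    d
  }
  dists <- t(vapply(seq_len(n), bfs, numeric(n)))
  finite <- dists[upper.tri(dists)][is.finite(dists[upper.tri(dists)])]
  list(
    n_nodes = n,
    n_edges = nrow(edges_df),
    mean_degree = mean(deg),
    max_degree = max(deg),
    mean_clustering = mean(cc),
    mean_shortest_path = mean(finite),
    diameter_overall = max(finite)
  )
}

# Complete-linkage agglomeration, step by step, on a distance matrix.
oracle_complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- max(d[clusters[[i]], clusters[[j]]])
          if (h < best_h) {
            best_h <- h
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Exhaustive core-module search on a toy subnetwork list: enumerate every
# gene subset, keep those captured by >= min_capture subnetworks with
# >= min_genes genes, drop non-maximal ones.
oracle_core_modules <- function(sets, min_genes, min_capture) {
  genes <- sort(unique(unlist(sets)))
  out <- list()
  idx <- seq_along(genes)
  for (size in min_genes:length(genes)) {
    for (comb in utils::combn(idx, size, simplify = FALSE)) {
      s <- genes[comb]
      capture <- sum(vapply(sets, function(x) all(s %in% x), logical(1)))
      if (capture >= min_capture) out[[length(out) + 1]] <- s
    }
  }
  if (!length(out)) return(out)
  maximal <- out[vapply(seq_along(out), function(i) {
    !any(vapply(seq_along(out), function(j) {
      i != j && length(out[[i]]) < length(out[[j]]) && all(out[[i]] %in% out[[j]])
    }, logical(1)))
  }, logical(1))]
  unique(lapply(maximal, sort))
}
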