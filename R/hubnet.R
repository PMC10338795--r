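#' Coerce an edge list or igraph object to a simple undirected PPI graph
#'
#' @param x An igraph object or a data frame with two columns of node labels
#'   (e.g. `node_a`, `node_b`).
#' @return A simple undirected igraph with named vertices.
#' @export
as_ppi_graph <- function(x) {
  if (igraph::is_igraph(x)) {
    g <- x
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) abort("edge list needs two columns of node labels.")
    g <- igraph::graph_from_data_frame(x[, 1:2], directed = FALSE)
  } else {
    abort("`x` must be an igraph object or an edge-list data frame.")
  }
  g <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

centrality_methods <- c("MCC", "MNC", "EPC", "Betweenness", "BottleNeck",
                        "Closeness", "Degree", "EcCentricity", "Radiality",
                        "Stress")

# BFS shortest-path distances and path counts from every source;
# returns list(d = distance matrix, sigma = path-count matrix)
bfs_paths <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ds <- rep(Inf, n); sg <- numeric(n)
    ds[s] <- 0; sg[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (is.infinite(ds[w])) {
            ds[w] <- ds[u] + 1
            nxt <- c(nxt, w)
            sg[w] <- sg[w] + sg[u]
          } else if (ds[w] == ds[u] + 1) {
            sg[w] <- sg[w] + sg[u]
          }
        }
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- ds
    sigma[s, ] <- sg
  }
  list(d = d, sigma = sigma)
}

stress_scores <- function(g) {
  n <- igraph::vcount(g)
  bp <- bfs_paths(g)
  d <- bp$d; sigma <- bp$sigma
  out <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- outer(d[, v], d[v, ], `+`) == d
    m <- outer(sigma[, v], sigma[v, ]) * on_path
    m[!is.finite(d)] <- 0
    m[v, ] <- 0; m[, v] <- 0
    out[v] <- sum(m[upper.tri(m)])
  }
  out
}

mnc_scores <- function(g) {
  vapply(igraph::V(g), function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) == 0) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    max(igraph::components(sub)$csize)
  }, numeric(1))
}

mcc_scores <- function(g) {
  n <- igraph::vcount(g)
  score <- numeric(n)
  if (igraph::ecount(g) > 0) {
    cliques <- igraph::max_cliques(g, min = 2)
    for (cl in cliques) {
      score[as.integer(cl)] <- score[as.integer(cl)] + factorial(length(cl) - 1)
    }
  }
  score
}

eccentricity_scores <- function(g, d = NULL) {
  if (is.null(d)) d <- igraph::distances(g)
  apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0) 0 else 1 / max(reach)
  })
}

radiality_scores <- function(g, d = NULL) {
  if (is.null(d)) d <- igraph::distances(g)
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  # per-component diameter
  diam <- vapply(seq_len(comp$no), function(k) {
    idx <- which(comp$membership == k)
    if (length(idx) < 2) return(0)
    max(d[idx, idx][is.finite(d[idx, idx])])
  }, numeric(1))
  vapply(seq_len(n), function(v) {
    row <- d[v, ]
    reach <- which(is.finite(row) & row > 0)
    if (length(reach) == 0) return(0)
    sum(diam[comp$membership[v]] + 1 - row[reach]) / (n - 1)
  }, numeric(1))
}

harmonic_closeness_scores <- function(g, d = NULL) {
  if (is.null(d)) d <- igraph::distances(g)
  apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    sum(1 / reach)
  })
}

# deterministic shortest-path tree: every non-root vertex attaches to its
# smallest-labelled predecessor (neighbor one step closer to the root)
bottleneck_scores <- function(g, d = NULL) {
  n <- igraph::vcount(g)
  if (is.null(d)) d <- igraph::distances(g)
  labels <- igraph::V(g)$name
  lab_order <- order(labels)
  rank_of <- integer(n); rank_of[lab_order] <- seq_len(n)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  score <- numeric(n)
  for (s in seq_len(n)) {
    ds <- d[s, ]
    parent <- rep(NA_integer_, n)
    subtree <- numeric(n)
    members <- which(is.finite(ds))
    for (w in members) {
      if (w == s) next
      preds <- adj[[w]][ds[adj[[w]]] == ds[w] - 1]
      parent[w] <- preds[which.min(rank_of[preds])]
    }
    # accumulate subtree sizes from the deepest layer up
    ord <- members[order(ds[members], decreasing = TRUE)]
    subtree[members] <- 1
    for (w in ord) {
      if (!is.na(parent[w])) subtree[parent[w]] <- subtree[parent[w]] + subtree[w]
    }
    score <- score + (subtree > n / 4)
  }
  score
}

epc_scores <- function(g, realizations = 1000, keep_prob = 0.5, seed = NULL) {
  if (is.null(seed)) abort("EPC requires a `seed` for its Monte-Carlo realizations.")
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  with_seed(seed, {
    acc <- numeric(n)
    for (r in seq_len(realizations)) {
      keep <- if (keep_prob >= 1) rep(TRUE, m) else runif(m) < keep_prob
      sub <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
      comp <- igraph::components(sub)
      acc <- acc + comp$csize[comp$membership]
    }
    acc / realizations
  })
}

#' Compute one of the ten hub-ranking node centralities
#'
#' Implements the ten measures used for consensus hub-gene detection
#' (CytoHubba conventions): Degree, harmonic Closeness, Betweenness, Stress,
#' EcCentricity (reciprocal eccentricity), Radiality, MNC (largest connected
#' component of the open neighborhood), MCC (sum of `(|C|-1)!` over maximal
#' cliques containing the node), BottleNeck (number of deterministic
#' shortest-path trees in which the node's subtree exceeds a quarter of the
#' graph) and EPC (mean component size over seeded Bernoulli edge-retention
#' realizations).
#'
#' @param graph An igraph object or edge-list data frame
#'   (see [as_ppi_graph()]).
#' @param method One of "MCC", "MNC", "EPC", "Betweenness", "BottleNeck",
#'   "Closeness", "Degree", "EcCentricity", "Radiality", "Stress".
#' @param epc_realizations Monte-Carlo realizations for EPC.
#' @param epc_keep_prob Edge retention probability for EPC.
#' @param seed Seed for EPC (required for that method, ignored otherwise).
#' @return A tibble `node`, `score` in graph vertex order.
#' @examples
#' g <- igraph::make_ring(5)
#' compute_centrality(g, "Degree")
#' @export
compute_centrality <- function(graph, method, epc_realizations = 1000,
                               epc_keep_prob = 0.5, seed = NULL) {
  g <- as_ppi_graph(graph)
  if (igraph::vcount(g) == 0) abort("graph must be non-empty.")
  if (!method %in% centrality_methods) {
    abort(sprintf("unknown centrality method '%s'.", method))
  }
  score <- switch(method,
    Degree = as.numeric(igraph::degree(g)),
    Closeness = harmonic_closeness_scores(g),
    Betweenness = as.numeric(igraph::betweenness(g, directed = FALSE)),
    Stress = stress_scores(g),
    EcCentricity = eccentricity_scores(g),
    Radiality = radiality_scores(g),
    MNC = mnc_scores(g),
    MCC = mcc_scores(g),
    BottleNeck = bottleneck_scores(g),
    EPC = epc_scores(g, epc_realizations, epc_keep_prob, seed)
  )
  tibble(node = igraph::V(g)$name, score = unname(score))
}

#' Top fraction of nodes by centrality score
#'
#' Sorts descending by score with ties broken by ascending node label and
#' keeps `ceiling(fraction * n)` nodes, guaranteeing a non-empty set for any
#' non-empty graph.
#'
#' @param scores A tibble `node`, `score` (from [compute_centrality()]).
#' @param fraction Fraction of nodes to keep, in (0, 1\].
#' @return Character vector of the top node labels.
#' @export
rank_top_fraction <- function(scores, fraction = 0.10) {
  if (!is.data.frame(scores) || nrow(scores) == 0) {
    abort("`scores` must be a non-empty node/score table.")
  }
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  k <- ceiling(fraction * nrow(scores))
  ord <- order(-scores$score, scores$node)
  scores$node[ord][seq_len(k)]
}

#' Consensus hub genes from ten centrality rankings
#'
#' Runs all ten centrality measures, takes the top `fraction` of nodes from
#' each ranking, and intersects the ten top sets to form the consensus hub
#' list.
#'
#' @inheritParams compute_centrality
#' @param fraction Top fraction per method (default 0.10).
#' @param seed Seed for the EPC realizations.
#' @return A `hub_consensus` object: list with `consensus` (character),
#'   `top_sets` (named list per method), `scores` (wide tibble of all ten
#'   scores) and `fraction`.
#' @examples
#' net <- sim_ppi_network(60, n_planted_hubs = 3, seed = 1)
#' hc <- consensus_hubs(net$graph, seed = 2, epc_realizations = 100)
#' hc$consensus
#' @export
consensus_hubs <- function(graph, fraction = 0.10, seed = 1L,
                           epc_realizations = 1000, epc_keep_prob = 0.5) {
  g <- as_ppi_graph(graph)
  if (igraph::vcount(g) < 10) abort("consensus hub detection needs >= 10 nodes.")
  scores <- purrr::map(
    setNames(centrality_methods, centrality_methods),
    ~ compute_centrality(g, .x, epc_realizations = epc_realizations,
                         epc_keep_prob = epc_keep_prob, seed = seed)
  )
  top_sets <- purrr::map(scores, rank_top_fraction, fraction = fraction)
  consensus <- sort(Reduce(intersect, top_sets))
  wide <- purrr::reduce(
    purrr::imap(scores, ~ setNames(.x, c("node", .y))),
    dplyr::left_join, by = "node"
  )
  structure(
    list(consensus = consensus, top_sets = top_sets, scores = wide,
         fraction = fraction),
    class = "hub_consensus")
}

#' @export
print.hub_consensus <- function(x, ...) {
  cat(sprintf("Consensus hubs (top %.0f%% of %d nodes per method, 10 methods): %d genes\n",
              100 * x$fraction, nrow(x$scores), length(x$consensus)))
  if (length(x$consensus) > 0) {
    cat("  ", paste(head(x$consensus, 20), collapse = ", "),
        if (length(x$consensus) > 20) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}
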