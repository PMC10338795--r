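# Brute-force oracles for the ten centrality measures, independent of the
# package implementation (and of igraph): explicit recursive enumeration of
# simple paths, cliques and trees on adjacency matrices. Only feasible for
# tiny graphs (<= ~8 nodes), which is exactly their job.

# random labelled graph as a symmetric adjacency matrix
random_small_graph <- function(n, p = 0.45) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  labels <- sample(paste0("n", sample(100:999, n)))
  dimnames(a) <- list(labels, labels)
  a
}

adj_to_igraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# all simple paths s -> t as vectors of vertex indices
oracle_simple_paths <- function(a, s, t) {
  n <- nrow(a)
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (a[u, w] == 1 && !(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

# shortest-path distances, counts, and per-vertex through-counts by
# exhaustive path enumeration
oracle_paths_summary <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n); diag(d) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  through <- array(0, c(n, n, n)) # [s, t, v] shortest s-t paths through v
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- oracle_simple_paths(a, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1)) - 1L
    d[s, t] <- min(lens)
    sp <- paths[lens == min(lens)]
    sigma[s, t] <- length(sp)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through[s, t, v] <- sum(vapply(sp, function(p) v %in% p, logical(1)))
    }
  }
  list(d = d, sigma = sigma, through = through)
}

oracle_degree <- function(a) rowSums(a)

oracle_closeness <- function(a, ps = oracle_paths_summary(a)) {
  sapply(seq_len(nrow(a)), function(v) {
    dv <- ps$d[v, -v]
    sum(1 / dv[is.finite(dv)])
  })
}

oracle_betweenness <- function(a, ps = oracle_paths_summary(a)) {
  n <- nrow(a)
  sapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || ps$sigma[s, t] == 0) next
      tot <- tot + ps$through[s, t, v] / ps$sigma[s, t]
    }
    tot
  })
}

oracle_stress <- function(a, ps = oracle_paths_summary(a)) {
  n <- nrow(a)
  sapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v) next
      tot <- tot + ps$through[s, t, v]
    }
    tot
  })
}

oracle_eccentricity <- function(a, ps = oracle_paths_summary(a)) {
  sapply(seq_len(nrow(a)), function(v) {
    dv <- ps$d[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0) 0 else 1 / max(dv)
  })
}

oracle_radiality <- function(a, ps = oracle_paths_summary(a)) {
  n <- nrow(a)
  reach <- is.finite(ps$d)
  sapply(seq_len(n), function(v) {
    others <- setdiff(which(reach[v, ]), v)
    if (length(others) == 0) return(0)
    comp <- c(v, others)
    diam <- max(ps$d[comp, comp][is.finite(ps$d[comp, comp])])
    sum(diam + 1 - ps$d[v, others]) / (n - 1)
  })
}

# maximal cliques by exhaustive subset check
oracle_max_cliques <- function(a) {
  n <- nrow(a)
  subsets <- lapply(seq_len(2^n - 1), function(mask) which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    length(s) < 2 || all(a[s, s][upper.tri(a[s, s])] == 1)
  }, logical(1))
  cliques <- subsets[is_clique]
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(cl2) {
      length(cl2) > length(cliques[[i]]) && all(cliques[[i]] %in% cl2)
    }, logical(1)))
  }, logical(1))
  cliques[keep]
}

oracle_mcc <- function(a) {
  cl <- oracle_max_cliques(a)
  cl <- cl[vapply(cl, length, integer(1)) >= 2]
  score <- numeric(nrow(a))
  for (c in cl) score[c] <- score[c] + factorial(length(c) - 1)
  score
}

# largest connected set within the open neighborhood, by reachability
oracle_mnc <- function(a, ps = oracle_paths_summary(a)) {
  n <- nrow(a)
  sapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    if (length(nb) == 0) return(0)
    sub <- a[nb, nb, drop = FALSE]
    # reachability inside the induced subgraph via its own path summary
    m <- length(nb)
    reach <- diag(m) == 1
    cur <- sub > 0
    for (k in seq_len(m)) {
      reach <- reach | cur
      cur <- (cur %*% (sub > 0)) > 0
    }
    comp_sizes <- sapply(seq_len(m), function(i) sum(reach[i, ]))
    max(comp_sizes)
  })
}

oracle_component_sizes <- function(a, ps = oracle_paths_summary(a)) {
  reach <- is.finite(ps$d)
  sapply(seq_len(nrow(a)), function(v) sum(reach[v, ]))
}

# deterministic shortest-path tree: non-root vertices attach to their
# smallest-labelled predecessor; subtree membership by parent-chain walking
oracle_bottleneck <- function(a, ps = oracle_paths_summary(a)) {
  n <- nrow(a)
  labels <- rownames(a)
  score <- numeric(n)
  for (s in seq_len(n)) {
    ds <- ps$d[s, ]
    parent <- rep(NA_integer_, n)
    for (w in seq_len(n)) {
      if (w == s || !is.finite(ds[w])) next
      preds <- which(a[w, ] == 1 & ds == ds[w] - 1)
      parent[w] <- preds[order(labels[preds])][1]
    }
    in_subtree <- function(x, v) {
      while (!is.na(x)) {
        if (x == v) return(TRUE)
        x <- parent[x]
      }
      FALSE
    }
    for (v in seq_len(n)) {
      if (!is.finite(ds[v])) next
      # subtree of v = vertices whose parent chain passes through v
      members <- sum(vapply(which(is.finite(ds)), function(x) in_subtree(x, v),
                            logical(1)))
      score[v] <- score[v] + (members > n / 4)
    }
  }
  score
}

oracle_centrality <- function(a, method) {
  ps <- oracle_paths_summary(a)
  switch(method,
    Degree = oracle_degree(a),
    Closeness = oracle_closeness(a, ps),
    Betweenness = oracle_betweenness(a, ps),
    Stress = oracle_stress(a, ps),
    EcCentricity = oracle_eccentricity(a, ps),
    Radiality = oracle_radiality(a, ps),
    MNC = oracle_mnc(a, ps),
    MCC = oracle_mcc(a),
    BottleNeck = oracle_bottleneck(a, ps),
    stop("no oracle for ", method)
  )
}
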