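# Shared fixtures and independent oracles used across the test files.

# random balanced dot-bracket string with at most `maxlen` characters
rand_dotbracket <- function(maxlen = 12) {
  n <- sample.int(maxlen + 1L, 1L) - 1L
  build <- function(budget) {
    out <- ""
    while (budget > 0) {
      if (stats::runif(1) < 0.4 && budget >= 2) {
        inner_budget <- sample.int(budget - 1L, 1L) - 1L
        inner <- build(inner_budget)
        out <- paste0(out, "(", inner, ")")
        budget <- budget - nchar(inner) - 2L
      } else {
        out <- paste0(out, ".")
        budget <- budget - 1L
      }
    }
    out
  }
  build(n)
}

# random symmetric distance matrix on n points with integer entries,
# deliberately tie-rich to exercise the deterministic tie-breaking
rand_distmat <- function(n, values = 1:6) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- sample(values, n * (n - 1) / 2, replace = TRUE)
  m <- m + t(m)
  dimnames(m) <- list(paste0("F", seq_len(n)), paste0("F", seq_len(n)))
  m
}

# Naive agglomeration that recomputes every inter-cluster distance from
# its definition (min / max / mean over all cross pairs) at each step.
# Shares only the tie rule with the Lance-Williams implementation.
naive_agglomerate <- function(m, method) {
  n <- nrow(m)
  members <- as.list(seq_len(n))      # original point indices per cluster
  node <- -seq_len(n)
  heights <- numeric(0)
  merges <- NULL
  cluster_dist <- function(a, b) {
    vals <- m[members[[a]], members[[b]], drop = FALSE]
    switch(method, upgma = mean(vals), single = min(vals),
           complete = max(vals))
  }
  step <- 0L
  while (length(members) > 1L) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- cluster_dist(i, j)
      key <- c(d, min(min(members[[i]]), min(members[[j]])),
               max(min(members[[i]]), min(members[[j]])))
      if (is.null(best) ||
          key[1] < best$key[1] - 1e-12 ||
          (abs(key[1] - best$key[1]) <= 1e-12 &&
           (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3]))))
        best <- list(i = i, j = j, d = d, key = key)
    }
    step <- step + 1L
    heights[step] <- best$d
    pair <- c(node[best$i], node[best$j])
    merges <- rbind(merges, pair[order(pair >= 0L, abs(pair))])
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    node[best$i] <- step
    members[[best$j]] <- NULL
    node <- node[-best$j]
  }
  list(merge = merges, height = heights)
}

# minimum-spanning-tree edge weights by Prim's algorithm
mst_edge_weights <- function(m) {
  n <- nrow(m)
  intree <- c(TRUE, rep(FALSE, n - 1L))
  best <- m[1, ]
  w <- numeric(0)
  for (k in seq_len(n - 1L)) {
    cand <- which(!intree)
    v <- cand[which.min(best[cand])]
    w <- c(w, best[v])
    intree[v] <- TRUE
    best <- pmin(best, m[v, ])
  }
  unname(sort(w))
}

# independently coded cluster enumeration: fresh top-down recursion per
# node instead of the package's bottom-up memoized pass
enumerate_clusters_recursive <- function(t) {
  leafset <- function(k) {
    if (k < 0L) return(t$labels[-k])
    c(leafset(t$merge[k, 1]), leafset(t$merge[k, 2]))
  }
  c(lapply(t$labels, function(l) list(members = l, height = 0)),
    lapply(seq_along(t$height), function(s)
      list(members = leafset(s), height = t$height[s])))
}

# brute-force maximal Jaccard over an explicit cluster list
naive_alpha <- function(clusters, g) {
  max(vapply(clusters, function(cl) {
    length(intersect(cl$members, g)) / length(union(cl$members, g))
  }, numeric(1)))
}
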