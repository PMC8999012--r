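# Independent brute-force oracles for cross-checking the implementation.
# Everything here is written from the definitions, not from the package code.

# Floyd-Warshall all-pairs shortest paths on an interactome (small graphs only)
fw_distances <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) {
    d[el[i, 1], el[i, 2]] <- 1
    d[el[i, 2], el[i, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# direct formula evaluation of the five proximity metrics from a distance
# matrix, with summaries written out longhand
brute_summary <- function(v, metric) {
  v <- sort(v)
  n <- length(v)
  if (metric == "minimum") return(v[1])
  if (metric == "maximum") return(v[n])
  if (metric == "mean") return(sum(v) / n)
  if (metric == "median") {
    return(if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2)
  }
  if (metric == "mode") {
    best_val <- NA_real_
    best_count <- -1L
    for (u in unique(v)) {  # unique() of sorted v is ascending
      cnt <- sum(v == u)
      if (cnt > best_count) {  # strict: first (smallest) value wins ties
        best_count <- cnt
        best_val <- u
      }
    }
    return(best_val)
  }
  stop("unknown metric")
}

brute_proximity <- function(dmat, t_nodes, s_nodes, metric) {
  vals <- vapply(t_nodes, function(t) {
    row <- dmat[t, s_nodes]
    row <- row[is.finite(row)]
    if (length(row) == 0) return(NA_real_)
    brute_summary(row, metric)
  }, numeric(1))
  mean(vals[!is.na(vals)])
}

# exhaustive evaluation of the two-max KS statistic
brute_ks <- function(tags, n) {
  v <- sort(tags)
  t <- length(v)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

# independent BH step-up adjustment from the definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# small random test interactome (connected not guaranteed)
random_interactome <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(sprintf("n%02d", seq_len(n)), 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  as_interactome(data.frame(from = pairs[keep, 1], to = pairs[keep, 2]))
}
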