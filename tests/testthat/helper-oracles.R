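## Independent oracles, kept deliberately naive so they share no code path
## with the implementation they check.

## Benjamini-Hochberg by direct definition: sort ascending, scale by m/i,
## running minimum from the largest p, cap at 1, map back to input order.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

## Hypergeometric upper tail P(X >= k) by summing binomial-coefficient
## point masses.
hyper_upper_brute <- function(k, K, N, n) {
  i <- seq(max(k, 0, n - (N - K)), min(n, K))
  if (length(i) == 0L || min(n, K) < k) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## All-pairs-shortest-path centralities on an adjacency matrix: distances
## by Floyd-Warshall, shortest-path counts by dynamic programming over
## increasing distance, betweenness via the pair-dependency formula.
apsp_centralities <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]

  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(D[s, ]))
    for (t in reach[order(D[s, reach])]) {
      if (t == s) next
      pred <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }

  bc <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    bc[v] <- acc
  }

  cc <- vapply(seq_len(n), function(v) {
    d <- D[v, ][is.finite(D[v, ])]
    if (length(d) <= 1L) 0 else (length(d) - 1) / sum(d)
  }, 0)

  cl <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2L) return(0)
    sum(A[nb, nb]) / 2 / choose(length(nb), 2)
  }, 0)

  list(dc = rowSums(A > 0), bc = bc, cc = cc, clustering = cl)
}

## Small named undirected graph from an edge matrix, plus its adjacency.
edges_df <- function(pairs, source = "db1", evidence = "physical") {
  data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
             source = source, evidence = evidence, stringsAsFactors = FALSE)
}

graph_from_pairs <- function(pairs) {
  igraph::graph_from_data_frame(edges_df(pairs), directed = FALSE)
}

adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

## Random simple graph with <= n nodes for oracle sweeps.
random_small_graph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  dimnames(A) <- list(letters[seq_len(n)], letters[seq_len(n)])
  A
}

## Annotated toy network: builds a group network directly from calls-like
## rows so hub/centrality behaviour can be tested without the simulator.
toy_calls <- function(ids, group, log2_fc, status = NULL) {
  if (is.null(status)) status <- ifelse(log2_fc > 0, "up", "down")
  data.frame(protein_id = ids, group = group, fold_change = 2^log2_fc,
             log2_fc = log2_fc, p_raw = 0.01, p_adj = 0.05, cv_percent = 5,
             status = status, testable = TRUE, stringsAsFactors = FALSE)
}
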