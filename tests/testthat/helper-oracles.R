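# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force enumeration and textbook formulas only.

# Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j)
brute_bh <- function(p, m = length(p)) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, m * p[ord] / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# DTW by exhaustive enumeration of every monotone warping path from (1,1)
# to (n,m) with steps right/down/diagonal; cost = sum of |a_i - b_j| over
# all visited cells.
brute_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# all shortest paths between two nodes of an undirected graph (logical
# adjacency matrix), by depth-limited DFS at the BFS distance
all_shortest_paths_brute <- function(adj, s, t) {
  n <- nrow(adj)
  dist <- rep(Inf, n); dist[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in which(adj[v, ])) {
      if (dist[w] == Inf) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  if (!is.finite(dist[t])) return(list())
  paths <- list()
  dfs <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ])) {
      if (dist[w] == dist[v] + 1) dfs(c(path, w))
    }
  }
  dfs(s)
  paths
}

# betweenness by explicit shortest-path enumeration: for each pair, each
# shortest path contributes 1/(number of shortest paths) to its interior
# nodes
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_shortest_paths_brute(adj, s, t)
      if (!length(paths)) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(paths)
      }
    }
  }
  btw
}

# adjusted Rand index from the contingency table definition
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# one-sided hypergeometric upper tail from binomial coefficients
hyper_tail_manual <- function(k, K, N, n) {
  # P(X >= k), X = |overlap| of a size-n draw with a size-K subset of N
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# gene-level log2 timecourse from a bare matrix
make_tc <- function(log2mat, divs, n_rep, detection = NULL) {
  nt <- length(divs)
  samples <- data.frame(
    sample = sprintf("DIV%02d_r%d", rep(divs, each = n_rep),
                     rep(seq_len(n_rep), nt)),
    div = rep(divs, each = n_rep),
    replicate = rep(seq_len(n_rep), nt)
  )
  colnames(log2mat) <- samples$sample
  timecourse(log2mat, samples, detection = detection, level = "gene",
             log2 = TRUE)
}

# expression matrix whose Spearman threshold graph realizes a hub-and-
# spoke ("star") or chain ("path") topology: children = shared latent +
# independent noise, so parent-child rank correlation is high and
# child-child correlation is roughly its square. Returns the matrix and a
# cut separating the two correlation tiers (asserted by the caller).
two_tier_graph_expression <- function(kind = c("path", "star"),
                                      n_leaves = 4, n_samples = 80,
                                      seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  base <- rnorm(n_samples)
  mix <- function() 0.85 * base + sqrt(1 - 0.85^2) * rnorm(n_samples)
  if (kind == "path") {
    m <- rbind(g1 = mix(), g2 = base, g3 = mix())
  } else {
    leaves <- t(vapply(seq_len(n_leaves), function(i) mix(),
                       numeric(n_samples)))
    rownames(leaves) <- paste0("leaf", seq_len(n_leaves))
    m <- rbind(center = base, leaves)
  }
  rho <- cor(t(m), method = "spearman")
  strong <- if (kind == "path") c(rho[1, 2], rho[2, 3]) else rho[1, -1]
  weak <- if (kind == "path") rho[1, 3] else rho[-1, -1][upper.tri(
    diag(n_leaves))]
  list(m = m, cut = (min(strong) + max(weak)) / 2,
       separated = min(strong) > max(weak))
}
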