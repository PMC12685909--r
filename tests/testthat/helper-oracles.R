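# Independent oracles used across the suite. Each is deliberately written
# from the defining formula (or by brute force), not by calling the package.

# Welch t-test from the textbook formulas.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx / nx + vy / ny)
  df <- (vx / nx + vy / ny)^2 /
    ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Holm step-down by brute force over the definition.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, p[o[i]] * (m - i + 1))
    adj[o[i]] <- min(run, 1)
  }
  adj
}

# One-way ANOVA from sums of squares.
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(sapply(groups, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df = c(df1, df2), p = pf(f, df1, df2, lower.tail = FALSE))
}

# Simple regression from the normal equations.
oracle_linfit <- function(x, y) {
  n <- length(x)
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  f <- r2 * (n - 2) / (1 - r2)
  list(slope = slope, intercept = intercept, r2 = r2, f = f,
       p = pf(f, 1, n - 2, lower.tail = FALSE))
}

# Patristic distances by explicit root-path enumeration on the edge table:
# depth of each node from the root, tip-to-root node paths, LCA by path
# intersection, d(a, b) = depth(a) + depth(b) - 2 depth(LCA).
oracle_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    p <- node
    while (node != root) {
      node <- parent[node]
      p <- c(p, node)
    }
    p
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + elen[node]
      node <- parent[node]
    }
    d
  }
  d <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(n_tip)) for (b in seq_len(n_tip)) {
    if (a >= b) next
    # the LCA is the deepest shared node on the two root paths
    shared <- intersect(path_to_root(a), path_to_root(b))
    lca <- shared[which.max(sapply(shared, depth))]
    d[a, b] <- d[b, a] <- depth(a) + depth(b) - 2 * depth(lca)
  }
  d
}

# A tiny deterministic plate-table data frame used by several tests.
make_plate_df <- function() {
  data.frame(
    host = rep(c("H1", "H2"), each = 6),
    phage = rep(c("CONTROL", "CONTROL", "ANC", "ANC", "EVO", "EVO"), 2),
    replicate = rep(1:2, 6),
    od24 = c(0.545, 0.555, 0.460, 0.470, 0.145, 0.135,
             0.645, 0.655, 0.545, 0.555, 0.345, 0.335),
    stringsAsFactors = FALSE
  )
}
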