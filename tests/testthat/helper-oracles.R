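# Independent reference implementations used as oracles. These deliberately
# use different algorithms (explicit enumeration, projection matrices,
# igraph) from the package code paths they check.

# brute-force Onnela clustering: enumerate all ordered neighbor pairs
oracle_clustering <- function(w) {
  w <- w / max(w)
  n <- nrow(w)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    cyc <- 0
    for (j in nb) for (l in nb) {
      if (j != l && w[j, l] > 0) {
        cyc <- cyc + (w[i, j] * w[j, l] * w[l, i])^(1 / 3)
      }
    }
    vals[i] <- cyc / (k * (k - 1))
  }
  mean(vals)
}

# global efficiency via igraph shortest paths (lengths = 1/weight)
oracle_efficiency <- function(w) {
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# binary clustering coefficient by direct triangle counting
oracle_binary_clustering <- function(a) {
  n <- nrow(a)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (j in nb) for (l in nb) if (j < l && a[j, l] > 0) tri <- tri + 1
    vals[i] <- 2 * tri / (k * (k - 1))
  }
  mean(vals)
}

# residualize on nuisance via an explicit projection matrix, then correlate
oracle_partial_cor <- function(y1, y2, nuisance) {
  x <- cbind(1, nuisance)
  proj <- diag(length(y1)) - x %*% solve(crossprod(x)) %*% t(x)
  stats::cor(proj %*% y1, proj %*% y2)
}

# R mirror of the compiled double-edge-swap rewiring, consuming the same
# RNG draws (three uniforms per attempt) in the same order
r_rewire <- function(edges, n, attempts) {
  m <- nrow(edges)
  adj <- matrix(FALSE, n, n)
  for (e in seq_len(m)) {
    adj[edges[e, 1], edges[e, 2]] <- adj[edges[e, 2], edges[e, 1]] <- TRUE
  }
  if (m < 2) return(edges)
  for (it in seq_len(attempts)) {
    u <- runif(3)
    e1 <- min(floor(u[1] * m) + 1, m)
    e2 <- min(floor(u[2] * m) + 1, m)
    if (e1 == e2) next
    a <- edges[e1, 1]; b <- edges[e1, 2]
    cc <- edges[e2, 1]; d <- edges[e2, 2]
    if (u[3] < 0.5) {
      x1 <- a; y1 <- d; x2 <- cc; y2 <- b
    } else {
      x1 <- a; y1 <- cc; x2 <- b; y2 <- d
    }
    if (x1 == y1 || x2 == y2) next
    if (adj[x1, y1] || adj[x2, y2]) next
    if (min(x1, y1) == min(x2, y2) && max(x1, y1) == max(x2, y2)) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[cc, d] <- adj[d, cc] <- FALSE
    adj[x1, y1] <- adj[y1, x1] <- TRUE
    adj[x2, y2] <- adj[y2, x2] <- TRUE
    edges[e1, ] <- c(x1, y1)
    edges[e2, ] <- c(x2, y2)
  }
  edges
}

# random symmetric nonnegative weight matrix with zero diagonal
random_weights <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- runif(sum(ut))
  vals[runif(sum(ut)) > density] <- 0
  w[ut] <- vals
  w + t(w)
}

sorted_degrees <- function(edges, n) {
  sort(tabulate(c(edges[, 1], edges[, 2]), nbins = n))
}

# small well-behaved cohort for regression tests
small_cohort <- function(n = 400, seed = 1) {
  cfg <- qc_config(n = n, seed = seed)
  generate_cohort(cfg)
}
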