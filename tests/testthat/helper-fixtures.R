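# shared fixtures and independent oracles, built in code at test time

# random symmetric matrix with zero diagonal
rand_sym <- function(n, sd = 0.2) {
  z <- matrix(stats::rnorm(n * n, sd = sd), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}

# random dense non-negative weighted graph (all weights distinct a.s.)
rand_weighted_graph <- function(n) {
  w <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# sparse random connected graph for MST enumeration (few edges)
rand_sparse_graph <- function(n, n_extra = 5) {
  m <- matrix(0, n, n)
  perm <- sample(n)
  for (k in 2:n) {  # random spanning tree guarantees connectivity
    i <- perm[k]; j <- perm[sample(k - 1, 1)]
    m[i, j] <- m[j, i] <- stats::runif(1, 0.05, 1)
  }
  free <- which(upper.tri(m) & m == 0)
  add <- sample(free, min(n_extra, length(free)))
  m[add] <- stats::runif(length(add), 0.05, 1)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# brute-force minimum spanning distance: enumerate all (n-1)-edge subsets
brute_force_mst_distance <- function(m) {
  n <- nrow(m)
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  ne <- nrow(idx)
  best <- Inf
  combs <- utils::combn(ne, n - 1)
  for (c in seq_len(ncol(combs))) {
    sel <- combs[, c]
    ed <- data.frame(from = idx[sel, 1], to = idx[sel, 2])
    # union-find acyclicity/spanning check on the subset
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (k in seq_len(nrow(ed))) {
      ra <- find(ed$from[k]); rb <- find(ed$to[k])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    d <- sum(1 / m[cbind(idx[sel, 1], idx[sel, 2])])
    if (d < best) best <- d
  }
  best
}

# Floyd-Warshall all-pairs shortest paths on distances 1/weight
floyd_efficiency <- function(m) {
  n <- nrow(m)
  D <- matrix(Inf, n, n)
  D[m > 0] <- 1 / m[m > 0]
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# brute-force connected components of an edge list by label propagation
brute_force_components <- function(edges, n) {
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$from[k]; b <- edges$to[k]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        lab[a] <- lab[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# quick subjects table without simulating any time series
subjects_df <- function(n_young, n_old) {
  n <- n_young + n_old
  data.frame(subject = sprintf("s%02d", seq_len(n)),
             group = c(rep("young", n_young), rep("old", n_old)),
             mean_fd = stats::runif(n, 0.05, 0.3),
             education = c(stats::rnorm(n_young, 17, 1.5),
                           stats::rnorm(n_old, 14, 2)),
             stringsAsFactors = FALSE)
}

# stack of random symmetric z matrices, optionally with a planted shift on a
# connected edge set (a clique over `clique_nodes`)
rand_stack <- function(n_sub, n_nodes, sd = 0.2, shift = 0, clique_nodes = 1:5) {
  lapply(seq_len(n_sub), function(i) {
    z <- rand_sym(n_nodes, sd)
    if (shift != 0) {
      s <- z[clique_nodes, clique_nodes]
      s[upper.tri(s)] <- s[upper.tri(s)] + shift
      s[lower.tri(s)] <- t(s)[lower.tri(s)]
      z[clique_nodes, clique_nodes] <- s
    }
    z
  })
}

# planted clique edge pairs (i < j) for recall computations
clique_edges <- function(nodes) {
  t(utils::combn(sort(nodes), 2))
}

# small box-world template atlas for map fixtures
box_template <- function() {
  tpl <- array(0L, c(14, 14, 10))
  tpl[2:8, 2:8, 2:6] <- 1L
  tpl[9:13, 9:13, 5:9] <- 2L
  tpl
}
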