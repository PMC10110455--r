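test_that("negative weights are zeroed and positives untouched", {
  m <- rand_sym(6)
  pos <- zero_negative(m)
  expect_true(all(pos >= 0))
  expect_identical(pos[m > 0], m[m > 0])
  expect_equal(zero_negative(abs(m)), abs(m), ignore_attr = TRUE)
  expect_equal(zero_negative(-abs(m)), matrix(0, 6, 6), ignore_attr = TRUE)
})

test_that("segregation matches its closed form and limits", {
  part <- c(a = "A", b = "A", c = "B", d = "B")
  m <- matrix(0.3, 4, 4, dimnames = list(names(part), names(part)))
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 0.6
  diag(m) <- 0
  expect_equal(system_segregation(m, part)$segregation, 0.5)

  blockdiag <- m; blockdiag[blockdiag == 0.3] <- 0
  expect_equal(system_segregation(blockdiag, part)$segregation, 1)

  uniform <- matrix(0.4, 4, 4, dimnames = dimnames(m)); diag(uniform) <- 0
  expect_equal(system_segregation(uniform, part)$segregation, 0)

  # scale invariance
  set.seed(4)
  r <- abs(rand_sym(8)); rownames(r) <- colnames(r) <- letters[1:8]
  p8 <- setNames(rep(c("A", "B"), each = 4), letters[1:8])
  expect_equal(system_segregation(r, p8)$segregation,
               system_segregation(5.7 * r, p8)$segregation)

  expect_error(system_segregation(matrix(0, 4, 4,
                                         dimnames = dimnames(m)), part),
               "not positive")
})

test_that("per-network segregation uses edges to all other nodes", {
  part <- c(a = "A", b = "A", c = "B", d = "B")
  m <- matrix(0.2, 4, 4, dimnames = list(names(part), names(part)))
  m[1, 2] <- m[2, 1] <- 0.8   # within A
  m[3, 4] <- m[4, 3] <- 0.4   # within B
  diag(m) <- 0
  out <- system_segregation(m, part, scope = "network")
  expect_equal(out$segregation[out$network == "A"], (0.8 - 0.2) / 0.8)
  expect_equal(out$segregation[out$network == "B"], (0.4 - 0.2) / 0.4)
  part_s <- c(part[1:3], d = "C")
  expect_error(system_segregation(m, part_s, scope = "network"), "single node")
})

test_that("MST solves the simple cases by inspection", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- 0.8
  m[1, 3] <- m[3, 1] <- 0.1
  tree <- minimum_spanning_tree(m)
  expect_equal(nrow(tree), 2)
  expect_setequal(paste(tree$from, tree$to), c("1 2", "2 3"))
  # a tree input is its own MST
  tree_only <- m; tree_only[1, 3] <- tree_only[3, 1] <- 0
  expect_equal(minimum_spanning_tree(tree_only)$weight, c(0.9, 0.8))
  # disconnected input errors with component sizes
  disc <- matrix(0, 4, 4); disc[1, 2] <- disc[2, 1] <- 1
  disc[3, 4] <- disc[4, 3] <- 1
  expect_error(minimum_spanning_tree(disc), "disconnected")
})

test_that("MST total distance equals exhaustive enumeration", {
  set.seed(7)
  for (i in 1:6) {
    m <- rand_sparse_graph(8, n_extra = 6)
    tree <- minimum_spanning_tree(m)
    expect_equal(sum(tree$distance), brute_force_mst_distance(m),
                 tolerance = 1e-12)
    # cross-check against igraph's MST total weight
    g <- igraph::graph_from_adjacency_matrix(m, weighted = TRUE,
                                             mode = "undirected")
    gm <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(sum(1 / igraph::E(gm)$weight), sum(tree$distance),
                 tolerance = 1e-12)
  }
})

test_that("global efficiency matches closed forms and a Floyd oracle", {
  K <- matrix(1, 5, 5); diag(K) <- 0
  expect_equal(global_efficiency(K), 1)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), 5 / 6)
  set.seed(12)
  for (i in 1:8) {
    m <- rand_weighted_graph(7)
    m[m < 0.4] <- 0  # some missing edges, possibly disconnected
    expect_equal(global_efficiency(m), floyd_efficiency(m), tolerance = 1e-12)
  }
})

test_that("GCE has its degenerate bounds and hand-computed value", {
  K <- matrix(1, 4, 4); diag(K) <- 0
  expect_equal(gce(K, K)$gce, 0)  # efficiency 1, cost 1
  empty <- matrix(0, 4, 4)
  expect_equal(gce(empty, K), list(gce = 0, efficiency = 0, cost = 0))
  # 4-cycle selection from the complete unit graph:
  # shortest paths: adjacent 1, diagonal 2 -> E = (8*1 + 4*0.5)/12 = 5/6
  cyc <- matrix(0, 4, 4)
  cyc[1, 2] <- cyc[2, 3] <- cyc[3, 4] <- cyc[4, 1] <- 1
  cyc <- pmax(cyc, t(cyc))
  out <- gce(cyc, K)
  expect_equal(out$efficiency, 5 / 6)
  expect_equal(out$cost, 4 / 6)
  expect_equal(out$gce, 5 / 6 - 4 / 6)
  expect_error(gce(empty, empty), "zero total weight")
})

test_that("OMST of a tree is the tree itself", {
  m <- matrix(0, 5, 5)
  for (k in 1:4) m[k, k + 1] <- m[k + 1, k] <- 0.5 + 0.1 * k
  o <- omst(m)
  expect_equal(o$rounds_used, 1)
  expect_equal(o$n_rounds_total, 1)
  expect_equal(o$adjacency, m, ignore_attr = TRUE)
})

test_that("OMST round count maximizes the exhaustive prefix GCE trace", {
  set.seed(21)
  for (i in 1:5) {
    m <- rand_weighted_graph(5)
    o <- omst(m)
    # independent prefix evaluation: extract MSTs with igraph, score each
    # prefix union with Floyd efficiency and direct cost sums
    mn <- m / max(m)
    residual <- mn
    union_adj <- matrix(0, 5, 5)
    trace <- numeric(0)
    repeat {
      g <- igraph::graph_from_adjacency_matrix(residual, weighted = TRUE,
                                               mode = "undirected")
      if (igraph::components(g)$no > 1 || igraph::ecount(g) < 4) break
      tm <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
      el <- igraph::as_edgelist(tm, names = FALSE)
      if (nrow(el) < 4) break
      for (e in seq_len(nrow(el))) {
        a <- el[e, 1]; b <- el[e, 2]
        union_adj[a, b] <- union_adj[b, a] <- mn[a, b]
        residual[a, b] <- residual[b, a] <- 0
      }
      eff <- floyd_efficiency(union_adj)
      cost <- sum(union_adj[upper.tri(union_adj)]) / sum(mn[upper.tri(mn)])
      trace <- c(trace, eff - cost)
      if (!any(residual > 0)) break
    }
    expect_equal(length(trace), o$n_rounds_total)
    expect_equal(o$gce_trace, trace, tolerance = 1e-10)
    expect_equal(o$rounds_used, which.max(trace))
    expect_equal(o$gce, max(trace), tolerance = 1e-10)
  }
})

test_that("OMST is connected, symmetric, and scale-invariant", {
  set.seed(31)
  for (i in 1:25) {
    m <- rand_weighted_graph(8)
    o <- omst(m)
    adj <- o$adjacency
    expect_equal(adj, t(adj))
    ed <- data.frame(from = which(upper.tri(adj) & adj > 0, arr.ind = TRUE)[, 1],
                     to = which(upper.tri(adj) & adj > 0, arr.ind = TRUE)[, 2])
    expect_equal(length(unique(brute_force_components(ed, 8))), 1)
    # scaling all weights leaves the selected edge set identical
    o2 <- omst(m * 3.7)
    expect_equal(o2$adjacency > 0, adj > 0)
    expect_equal(o2$rounds_used, o$rounds_used)
  }
})

test_that("raw participation coefficient has its closed forms", {
  part <- c(a = "A", b = "A", c = "B", d = "B")
  # all edges within the own community -> PC 0
  m <- matrix(0, 4, 4, dimnames = list(names(part), names(part)))
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 1
  pc <- participation_coefficient(m, part, n_null = 3, seed = 1)
  expect_equal(pc$pc_raw, rep(0, 4))
  # equal split over M = 2 communities -> 1 - 1/2
  m2 <- matrix(0, 4, 4, dimnames = dimnames(m))
  m2[1, 2] <- m2[2, 1] <- m2[1, 3] <- m2[3, 1] <- 1
  m2[2, 4] <- m2[4, 2] <- m2[3, 4] <- m2[4, 3] <- 1
  pc2 <- participation_coefficient(m2, part, n_null = 3, seed = 1)
  expect_equal(pc2$pc_raw, rep(0.5, 4))
  # community relabeling leaves raw PC unchanged
  part_rl <- c(a = "x9", b = "x9", c = "q", d = "q")
  pc3 <- participation_coefficient(m2, part_rl, n_null = 3, seed = 1)
  expect_equal(pc3$pc_raw, pc2$pc_raw)
})

test_that("normalized PC agrees with an explicit-rewiring oracle", {
  set.seed(77)
  # 10-node two-community weighted graph
  part <- setNames(rep(c("A", "B"), each = 5), letters[1:10])
  m <- rand_weighted_graph(10)
  m[m < 0.35] <- 0
  rownames(m) <- colnames(m) <- letters[1:10]
  pc <- participation_coefficient(m, part, n_null = 100, seed = 5)

  # oracle: independent double-edge-swap rewiring and weight permutation
  ed <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  w <- m[ed]
  comm <- part[letters[1:10]]
  null_kim <- array(NA_real_, c(10, 2, 100))
  set.seed(999)
  for (b in 1:100) {
    e <- ed
    for (it in 1:(10 * nrow(e))) {
      pick <- sample(nrow(e), 2)
      e1 <- e[pick[1], ]; e2 <- e[pick[2], ]
      # propose swap keeping degrees: (a-b),(c-d) -> (a-d),(c-b)
      a <- e1[1]; bb <- e1[2]; cc <- e2[1]; dd <- e2[2]
      if (length(unique(c(a, bb, cc, dd))) < 4) next
      n1 <- sort(c(a, dd)); n2 <- sort(c(cc, bb))
      exists <- function(p) any(e[, 1] == p[1] & e[, 2] == p[2])
      if (exists(n1) || exists(n2)) next
      e[pick[1], ] <- n1; e[pick[2], ] <- n2
    }
    adj <- matrix(0, 10, 10)
    wp <- sample(w)
    adj[e] <- wp; adj[e[, c(2, 1)]] <- wp
    null_kim[, , b] <- cbind(rowSums(adj[, comm == "A"]),
                             rowSums(adj[, comm == "B"]))
  }
  kim_med <- apply(null_kim, c(1, 2), median)
  k <- rowSums(m)
  kim <- cbind(rowSums(m[, comm == "A"]), rowSums(m[, comm == "B"]))
  oracle <- 1 - sqrt(rowSums(((kim - kim_med) / k)^2))
  # Monte-Carlo agreement: two independent 100-null medians
  expect_lt(max(abs(pc$pc_norm - oracle)), 0.15)
  expect_lt(mean(abs(pc$pc_norm - oracle)), 0.06)
})

test_that("hub rule selects nodes at least one SD above the group mean", {
  v <- c(0, 0, 0, 0, 10)  # mean 2, sample SD sqrt(20) -> threshold 6.47
  expect_equal(unname(define_hubs(v)), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(define_hubs(v + 3), define_hubs(v))  # translation invariant
  expect_warning(h <- define_hubs(rep(1, 5)), "zero variance")
  expect_false(any(h))
  # group-wise thresholds are computed within groups
  grouped <- define_hubs(c(v, v / 10), rep(c("old", "young"), each = 5))
  expect_true(grouped$old[5]); expect_true(grouped$young[5])
})

test_that("OMST dominates MST and proportional thresholds in GCE", {
  set.seed(41)
  for (i in 1:5) {
    m <- rand_weighted_graph(12)
    tc <- threshold_comparison(m)
    g_omst <- tc$gce[tc$method == "OMST"]
    expect_gte(g_omst, tc$gce[tc$method == "MST"])
    expect_true(all(g_omst >= tc$gce[tc$method == "proportional"] - 1e-12))
  }
})

test_that("proportional threshold keeps the stated edge count", {
  set.seed(51)
  m <- rand_weighted_graph(104)
  tc <- threshold_comparison(m, densities = 0.10)
  expect_equal(tc$n_edges[tc$method == "proportional"],
               round(0.10 * 104 * 103 / 2))
})
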