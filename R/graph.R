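
#' Zero out negative edge weights
#'
#' Sets negative entries of a symmetric connectivity matrix to zero, the
#' convention used before segregation, integration and hub analyses (the
#' within/between-network summaries and edge-wise group tests keep the full
#' signed matrices).
#'
#' @param m symmetric numeric matrix
#' @return matrix with negatives replaced by 0, positives untouched
#' @export
zero_negative <- function(m) {
  check_symmetric(m, "m")
  out <- pmax(m, 0)
  attributes(out) <- attributes(m)[c("dim", "dimnames")]
  out
}

#' Brain system segregation
#'
#' Segregation = (mean within-system correlation - mean between-system
#' correlation) / mean within-system correlation. With \code{scope =
#' "global"}, the within mean runs over all within-community off-diagonal
#' edges and the between mean over all between-community edges. With
#' \code{scope = "network"}, a segregation value is returned per community:
#' the within mean over that community's internal edges and the between mean
#' over edges from its nodes to all other nodes.
#'
#' @param m symmetric non-negative connectivity matrix with node ids
#' @param partition named node-to-community vector covering all nodes
#' @param scope \code{"global"} or \code{"network"}
#' @return for global scope, a list with \code{segregation}, \code{z_within},
#'   \code{z_between}; for network scope, a data frame with one row per
#'   community
#' @export
system_segregation <- function(m, partition, scope = c("global", "network")) {
  scope <- match.arg(scope)
  check_symmetric(m, "m")
  if (any(m < 0)) stop_("matrix has negative weights; apply zero_negative() first")
  nodes <- rownames(m) %||% names(partition)[seq_len(nrow(m))]
  check_partition(partition, nodes)
  comm <- partition[nodes]
  ut <- upper.tri(m)
  same <- outer(comm, comm, "==")

  if (scope == "global") {
    zw <- mean(m[ut & same])
    zb <- mean(m[ut & !same])
    if (!is.finite(zw) || zw <= 0)
      stop_("mean within-system correlation is not positive; segregation undefined")
    return(list(segregation = (zw - zb) / zw, z_within = zw, z_between = zb))
  }

  comms <- unique(comm)
  out <- lapply(comms, function(cm) {
    inside <- comm == cm
    if (sum(inside) < 2)
      stop_(sprintf("community '%s' has a single node; within mean undefined", cm))
    zw <- mean(m[ut & outer(inside, inside, "&")])
    cross <- outer(inside, !inside, "&") | outer(!inside, inside, "&")
    zb <- mean(m[ut & cross])
    if (!is.finite(zw) || zw <= 0)
      stop_(sprintf("community '%s': within mean not positive", cm))
    data.frame(network = cm, segregation = (zw - zb) / zw,
               z_within = zw, z_between = zb, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# edge list (i < j, weight > 0) of a symmetric matrix
edge_list <- function(m) {
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  data.frame(from = idx[, 1], to = idx[, 2], weight = m[idx])
}

# union-find connectivity check; returns component membership
components_of <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$from[k]); rb <- find(edges$to[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

#' Minimum spanning tree under reciprocal-weight distances
#'
#' Kruskal's algorithm on distances d = 1/weight, so strong connections are
#' short edges and the MST is the maximum-weight spanning tree of the
#' connectivity matrix. Ties are broken by a stable sort on (distance,
#' smaller node index, larger node index), making the tree deterministic.
#'
#' @param m symmetric non-negative weighted adjacency matrix
#' @return data frame of tree edges (\code{from}, \code{to}, \code{weight},
#'   \code{distance}), n - 1 rows
#' @export
minimum_spanning_tree <- function(m) {
  check_symmetric(m, "m")
  if (any(m < 0)) stop_("weights must be non-negative")
  n <- nrow(m)
  ed <- edge_list(m)
  comp <- components_of(n, ed)
  if (length(unique(comp)) > 1) {
    sizes <- table(comp)
    stop_(sprintf("graph is disconnected (%d components of sizes %s)",
                  length(sizes), paste(sort(sizes, decreasing = TRUE),
                                       collapse = ", ")))
  }
  ed$distance <- 1 / ed$weight
  ed <- ed[order(ed$distance, ed$from, ed$to), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(ed))
  n_found <- 0L
  for (k in seq_len(nrow(ed))) {
    ra <- find(ed$from[k]); rb <- find(ed$to[k])
    if (ra != rb) {
      parent[ra] <- rb
      keep[k] <- TRUE
      n_found <- n_found + 1L
      if (n_found == n - 1L) break
    }
  }
  out <- ed[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' E = 1/(N(N-1)) * sum over i != j of 1/L_ij, with path lengths computed on
#' distances d = 1/weight. Unreachable pairs contribute 0.
#'
#' @param m symmetric non-negative weighted adjacency matrix (>= 2 nodes)
#' @return global efficiency in [0, max weight]
#' @export
global_efficiency <- function(m) {
  check_symmetric(m, "m")
  n <- nrow(m)
  if (n < 2) stop_("need at least 2 nodes")
  if (any(m < 0)) stop_("weights must be non-negative")
  ed <- edge_list(m)
  if (!nrow(ed)) return(0)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  L <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / L
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global cost efficiency of an edge selection
#'
#' GCE = global efficiency of the selected graph minus its cost, where cost
#' is the total selected edge weight divided by the total weight of the
#' original fully weighted graph.
#'
#' @param selected symmetric adjacency of the selected edges (original
#'   weights)
#' @param original symmetric adjacency of the full graph
#' @return list with \code{gce}, \code{efficiency}, \code{cost}
#' @export
gce <- function(selected, original) {
  check_symmetric(selected, "selected")
  check_symmetric(original, "original")
  w_tot <- sum(original[upper.tri(original)])
  if (w_tot <= 0) stop_("original graph has zero total weight")
  cost <- sum(selected[upper.tri(selected)]) / w_tot
  eff <- if (any(selected > 0)) global_efficiency(selected) else 0
  list(gce = eff - cost, efficiency = eff, cost = cost)
}

#' Orthogonalized minimum spanning tree graph filtering
#'
#' Iteratively extracts edge-disjoint MSTs: the MST of the remaining graph is
#' added to the selection and its edges removed, and after each round the
#' global cost efficiency of the accumulated union (against the original
#' graph) is recorded. Extraction stops when the remaining graph disconnects
#' or runs out of edges. The returned graph is the union of the first k MSTs
#' where k maximizes the GCE trace. For the trace, weights are rescaled by
#' the graph's maximum weight so that efficiency and cost are compared on a
#' common [0, 1] scale; this makes the selected edge set invariant under
#' positive rescaling of the input weights.
#'
#' @param m symmetric non-negative connected weighted adjacency matrix
#' @param max_rounds optional cap on the number of MST rounds
#' @return object of class \code{omst_graph}: list with \code{adjacency}
#'   (selected edges at their original weights), \code{rounds_used},
#'   \code{gce_trace}, \code{gce}, \code{efficiency}, \code{cost} (all on
#'   the max-normalized weight scale), \code{n_rounds_total}
#' @export
omst <- function(m, max_rounds = Inf) {
  check_symmetric(m, "m")
  node_ids <- rownames(m)
  n <- nrow(m)
  residual <- unclass(m)
  attributes(residual) <- attributes(residual)[c("dim", "dimnames")]
  if (any(residual < 0)) stop_("weights must be non-negative")
  wmax <- max(residual)
  if (wmax <= 0) stop_("graph has no positive weights")
  mn <- residual / wmax  # normalized scale for the GCE trace
  union_sel <- matrix(0, n, n)
  trace <- numeric(0)
  msts <- list()
  repeat {
    tree <- tryCatch(minimum_spanning_tree(residual), error = function(e) NULL)
    if (is.null(tree)) break  # residual graph disconnected: no further MST
    k <- length(msts) + 1L
    msts[[k]] <- tree
    for (e in seq_len(nrow(tree))) {
      i <- tree$from[e]; j <- tree$to[e]
      union_sel[i, j] <- union_sel[j, i] <- mn[i, j]
      residual[i, j] <- residual[j, i] <- 0
    }
    trace[k] <- gce(union_sel, mn)$gce
    if (k >= max_rounds || !any(residual > 0)) break
  }
  if (!length(trace))
    stop_("input graph is disconnected; OMST undefined")
  k_best <- which.max(trace)
  adj <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  adjn <- matrix(0, n, n)
  for (k in seq_len(k_best)) {
    tree <- msts[[k]]
    for (e in seq_len(nrow(tree))) {
      i <- tree$from[e]; j <- tree$to[e]
      adj[i, j] <- adj[j, i] <- tree$weight[e]
      adjn[i, j] <- adjn[j, i] <- mn[i, j]
    }
  }
  g <- gce(adjn, mn)
  structure(list(adjacency = adj, rounds_used = k_best, gce_trace = trace,
                 gce = g$gce, efficiency = g$efficiency, cost = g$cost,
                 n_rounds_total = length(trace)),
            class = "omst_graph")
}

#' @export
print.omst_graph <- function(x, ...) {
  cat(sprintf(
    "OMST graph: %d nodes, %d edges (%d of %d MST rounds), cost %.3f, GCE %.4f\n",
    nrow(x$adjacency), sum(x$adjacency[upper.tri(x$adjacency)] > 0),
    x$rounds_used, x$n_rounds_total, x$cost, x$gce))
  invisible(x)
}

#' Participation coefficients with degree-preserving normalization
#'
#' Raw participation coefficient of node i: PC_i = 1 - sum over communities m
#' of (k_i(m)/k_i)^2, with k the weighted degree (strength). The normalized
#' PC replaces each within-community degree by its deviation from the median
#' over degree-preserving null networks: 1 - sqrt(B0 * sum_m ((k_i(m) -
#' k_i(m)_rand)/k_i)^2). Nulls are generated by double-edge swaps that
#' preserve the binary degree sequence, with edge weights reassigned by
#' permutation.
#'
#' @param m symmetric non-negative weighted adjacency matrix
#' @param partition named node-to-community vector
#' @param n_null number of null networks (default 100)
#' @param b0 normalization constant of the printed formula (default 1)
#' @param seed integer seed for the null generation
#' @return data frame: node, degree (strength), pc_raw, pc_norm
#' @export
participation_coefficient <- function(m, partition, n_null = 100, b0 = 1,
                                      seed = NULL) {
  check_symmetric(m, "m")
  if (any(m < 0)) stop_("weights must be non-negative")
  nodes <- rownames(m) %||% names(partition)[seq_len(nrow(m))]
  check_partition(partition, nodes)
  comm <- factor(partition[nodes])
  comms <- levels(comm)
  n <- nrow(m)

  within_degrees <- function(adj) {
    # node x community matrix of community-summed strengths
    sapply(comms, function(cm) rowSums(adj[, comm == cm, drop = FALSE]))
  }
  k <- rowSums(m)
  kim <- within_degrees(m)
  pc_raw <- ifelse(k > 0, 1 - rowSums((kim / pmax(k, 1e-300))^2), NA_real_)

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(as.integer(seed))
  }
  ed <- edge_list(m)
  g0 <- igraph::graph_from_data_frame(ed[, c("from", "to")], directed = FALSE,
                                      vertices = data.frame(name = seq_len(n)))
  null_kim <- array(NA_real_, c(n, length(comms), n_null))
  for (b in seq_len(n_null)) {
    gr <- igraph::rewire(g0, igraph::keeping_degseq(niter = 10 * nrow(ed)))
    em <- igraph::as_edgelist(gr, names = FALSE)
    w <- sample(ed$weight)
    adj <- matrix(0, n, n)
    adj[em] <- w
    adj[em[, c(2, 1)]] <- w
    null_kim[, , b] <- within_degrees(adj)
  }
  kim_med <- apply(null_kim, c(1, 2), stats::median)
  dev <- (kim - kim_med) / pmax(k, 1e-300)
  pc_norm <- ifelse(k > 0, 1 - sqrt(b0 * rowSums(dev^2)), NA_real_)

  data.frame(node = nodes, degree = k, pc_raw = pc_raw, pc_norm = pc_norm,
             stringsAsFactors = FALSE)
}

#' Connector hubs by the mean + 1 SD rule
#'
#' A node is a connector hub in a group when its participation coefficient is
#' at least one (sample) standard deviation above that group's mean PC.
#'
#' @param pc numeric vector of PC values (node names optional)
#' @param groups optional grouping factor of the same length; hubs are
#'   defined within each group's distribution
#' @return logical vector (or, with groups, a named list of logical vectors)
#'   flagging hubs
#' @export
define_hubs <- function(pc, groups = NULL) {
  one_group <- function(v) {
    v_ok <- v[!is.na(v)]
    if (length(v_ok) < 2) stop_("need at least 2 nodes with defined PC")
    s <- stats::sd(v_ok)
    if (s < 1e-12) {
      warning("zero variance in PC values; no hubs defined", call. = FALSE)
      return(stats::setNames(rep(FALSE, length(v)), names(v)))
    }
    stats::setNames(!is.na(v) & v >= mean(v_ok) + s, names(v))
  }
  if (is.null(groups)) return(one_group(pc))
  lapply(split(pc, groups), one_group)
}

#' Compare graph-filtering methods by global cost efficiency
#'
#' Computes the GCE of the OMST, the single MST, and proportional thresholds
#' retaining the stated fractions of strongest edges, all on the
#' max-normalized weight scale used by \code{\link{omst}} so the methods are
#' comparable. Proportionally thresholded graphs may be disconnected; their
#' efficiency then counts unreachable pairs as 0 and the row is flagged.
#'
#' @param m symmetric non-negative connected weighted adjacency matrix
#' @param densities retained edge fractions for proportional thresholding
#' @return data frame: method, density (NA for OMST/MST), gce, n_edges,
#'   connected
#' @export
threshold_comparison <- function(m, densities = seq(0.05, 0.20, by = 0.05)) {
  check_symmetric(m, "m")
  if (any(m < 0)) stop_("weights must be non-negative")
  m <- unclass(m) / max(m)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  n <- nrow(m)
  o <- omst(m)
  mst_edges <- minimum_spanning_tree(m)
  mst_adj <- matrix(0, n, n)
  for (e in seq_len(nrow(mst_edges))) {
    i <- mst_edges$from[e]; j <- mst_edges$to[e]
    mst_adj[i, j] <- mst_adj[j, i] <- mst_edges$weight[e]
  }
  rows <- list(
    data.frame(method = "OMST", density = NA_real_, gce = o$gce,
               n_edges = sum(o$adjacency[upper.tri(o$adjacency)] > 0),
               connected = TRUE),
    data.frame(method = "MST", density = NA_real_, gce = gce(mst_adj, m)$gce,
               n_edges = nrow(mst_edges), connected = TRUE))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  ord <- order(-w, ut[, 1], ut[, 2])
  n_edges_total <- n * (n - 1) / 2
  for (d in densities) {
    keep <- ord[seq_len(round(d * n_edges_total))]
    adj <- matrix(0, n, n)
    adj[ut[keep, , drop = FALSE]] <- w[keep]
    adj <- adj + t(adj)
    conn <- length(unique(components_of(n, edge_list(adj)))) == 1 &&
      all(rowSums(adj > 0) > 0)
    rows[[length(rows) + 1]] <-
      data.frame(method = "proportional", density = d,
                 gce = gce(adj, m)$gce, n_edges = length(keep),
                 connected = conn)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a weighted adjacency as an edge-list text file
#'
#' @param m symmetric weighted adjacency
#' @param path output path (tab-delimited: node_i, node_j, weight)
#' @return \code{path}, invisibly
#' @export
write_edge_list <- function(m, path) {
  ed <- edge_list(m)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  out <- data.frame(node_i = ids[ed$from], node_j = ids[ed$to],
                    weight = ed$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
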