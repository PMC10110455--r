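
# stack coercion: list of symmetric matrices or node x node x subject array
# -> subjects x edges matrix of upper-triangle values
stack_to_edges <- function(stack) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) != 3L)
    stop_("matrix stack must be a list of matrices or a 3D array")
  n <- dim(stack)[1]
  if (dim(stack)[2] != n) stop_("stacked matrices must be square")
  ids <- dimnames(stack)[[1]] %||% paste0("node", seq_len(n))
  Y <- t(apply(stack, 3, function(m) m[upper.tri(m)]))
  list(Y = Y, n_nodes = n, node_ids = ids)
}

# vectorized edge-wise regression: closure returning t statistics of column
# 'col' of the fixed design X for every column of an outcome matrix Y;
# the projector is precomputed once so permutation refits are two matrix
# products
edgewise_fitter <- function(X, col) {
  XtXinv <- solve(crossprod(X))
  px <- XtXinv %*% t(X)
  cjj <- XtXinv[col, col]
  df <- nrow(X) - ncol(X)
  function(Y) {
    B <- px %*% Y
    res <- Y - X %*% B
    sigma2 <- colSums(res^2) / df
    list(t = B[col, ] / sqrt(sigma2 * cjj), df = df)
  }
}

# connected components of a suprathreshold edge set; returns list of edge
# index vectors, largest first
edge_components <- function(pairs, supra, n_nodes) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  ed <- data.frame(from = pairs[idx, 1], to = pairs[idx, 2])
  comp <- components_of(n_nodes, ed)
  comp_of_edge <- comp[ed$from]
  split(idx, comp_of_edge)[order(-tabulate(factor(comp_of_edge)))]
}

#' Configuration for the network-based statistic
#'
#' @param threshold_p one-sided cluster-forming p-value threshold (used when
#'   \code{threshold_t} is NULL; the t threshold is derived from the
#'   edge-wise design's residual degrees of freedom)
#' @param threshold_t explicit cluster-forming t threshold
#' @param alpha FWE-corrected significance level per direction (default
#'   0.025, i.e. 0.05 split over the two directions)
#' @param n_perm number of group-label permutations (>= 100)
#' @param direction \code{"group1_gt_group2"} or \code{"group2_gt_group1"}
#' @return list of class \code{nbs_config}
#' @export
nbs_config <- function(threshold_p = 0.01, threshold_t = NULL, alpha = 0.025,
                       n_perm = 1000,
                       direction = c("group1_gt_group2", "group2_gt_group1")) {
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_number(n_perm, "n_perm", lower = 100, integer = TRUE)
  if (is.null(threshold_t)) check_number(threshold_p, "threshold_p",
                                         lower = 1e-12, upper = 1 - 1e-12)
  else check_number(threshold_t, "threshold_t")
  structure(list(threshold_p = threshold_p, threshold_t = threshold_t,
                 alpha = alpha, n_perm = n_perm,
                 direction = match.arg(direction)),
            class = "nbs_config")
}

#' Network-based statistic with covariates and permutation FWE control
#'
#' Edge-wise inference on two stacks of connectivity matrices: each edge is
#' regressed on group plus per-subject covariates and the one-sided t
#' statistic of the group effect is thresholded; connected components of the
#' suprathreshold edge graph are extracted and their sizes (edge counts)
#' compared against a permutation null of the maximal component size.
#' Permutations follow the Freedman-Lane scheme: edges are residualized on
#' the covariate-only model, residuals are permuted over subjects and added
#' back to the covariate fit, and the full model is refit.
#'
#' @param stack1,stack2 connectivity matrices per group: lists of symmetric
#'   matrices or node x node x subject arrays on identical node sets
#' @param config an \code{\link{nbs_config}}
#' @param covariates optional data frame of per-subject scalar covariates,
#'   rows ordered as group1 subjects then group2 subjects
#' @param seed integer seed for the permutations
#' @return object of class \code{nbs_outcome}: list with \code{t}
#'   (node x node t matrix), \code{threshold_t}, \code{df},
#'   \code{components} (list of edge data frames), \code{component_sizes},
#'   \code{p_fwe}, \code{null_max_size}, \code{config}
#' @export
nbs <- function(stack1, stack2, config = nbs_config(), covariates = NULL,
                seed = NULL) {
  stopifnot(inherits(config, "nbs_config"))
  s1 <- stack_to_edges(stack1)
  s2 <- stack_to_edges(stack2)
  if (s1$n_nodes != s2$n_nodes)
    stop_("groups have different node sets")
  n1 <- nrow(s1$Y); n2 <- nrow(s2$Y)
  if (n1 < 3 || n2 < 3) stop_("need at least 3 subjects per group")
  Y <- rbind(s1$Y, s2$Y)
  n <- n1 + n2
  n_nodes <- s1$n_nodes
  pairs <- upper_pairs(n_nodes)

  grp <- c(rep(1, n1), rep(0, n2))
  if (config$direction == "group2_gt_group1") grp <- 1 - grp
  Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop_("covariates must have one row per subject (group1 then group2)")
    cv <- scale(as.matrix(covariates), scale = FALSE)  # mean-centered
    Z <- cbind(Z, cv)
  }
  X <- cbind(Z, group = grp)
  gcol <- ncol(X)

  fit_t <- edgewise_fitter(X, gcol)
  obs <- fit_t(Y)
  t_thr <- config$threshold_t %||% stats::qt(1 - config$threshold_p, obs$df)
  supra <- obs$t > t_thr
  comps <- edge_components(pairs, supra, n_nodes)
  sizes <- lengths(comps)

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(as.integer(seed))
  }
  # Freedman-Lane: permute reduced-model residuals
  qz <- qr(Z)
  fit_red <- qr.fitted(qz, Y)
  res_red <- qr.resid(qz, Y)
  null_max <- numeric(config$n_perm)
  for (p in seq_len(config$n_perm)) {
    Yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
    tp <- fit_t(Yp)$t
    cp <- edge_components(pairs, tp > t_thr, n_nodes)
    null_max[p] <- if (length(cp)) max(lengths(cp)) else 0
  }
  p_fwe <- vapply(sizes, function(s) (1 + sum(null_max >= s)) /
                    (1 + config$n_perm), numeric(1))

  t_mat <- sym_from_upper(obs$t, n_nodes, s1$node_ids)
  comp_edges <- lapply(comps, function(idx)
    data.frame(node_i = s1$node_ids[pairs[idx, 1]],
               node_j = s1$node_ids[pairs[idx, 2]],
               t = obs$t[idx], stringsAsFactors = FALSE))
  structure(list(t = t_mat, threshold_t = t_thr, df = obs$df,
                 components = comp_edges, component_sizes = unname(sizes),
                 p_fwe = unname(p_fwe), null_max_size = null_max,
                 config = config),
            class = "nbs_outcome")
}

#' @export
print.nbs_outcome <- function(x, ...) {
  cat(sprintf("NBS (%s): t threshold %.3f (df = %d), %d permutation(s)\n",
              x$config$direction, x$threshold_t, x$df, x$config$n_perm))
  if (!length(x$component_sizes)) {
    cat("  no suprathreshold components\n")
  } else {
    for (i in seq_along(x$component_sizes))
      cat(sprintf("  component %d: %d edge(s), FWE p = %.4f%s\n", i,
                  x$component_sizes[i], x$p_fwe[i],
                  if (x$p_fwe[i] < x$config$alpha) " *" else ""))
  }
  invisible(x)
}

#' QC-FC motion diagnostics
#'
#' Correlates every edge of a connectivity-matrix stack with subjects' mean
#' framewise displacement, the standard benchmark of residual motion
#' contamination after denoising.
#'
#' @param stack list of symmetric matrices or node x node x subject array
#' @param mean_fd per-subject mean framewise displacement
#' @param alpha per-edge uncorrected significance level
#' @return list with \code{r} (per-edge correlations), \code{p},
#'   \code{median_r}, \code{pct_significant} (percentage of edges with
#'   uncorrected p < alpha)
#' @export
qcfc <- function(stack, mean_fd, alpha = 0.05) {
  s <- stack_to_edges(stack)
  n <- nrow(s$Y)
  if (length(mean_fd) != n)
    stop_("'mean_fd' must have one value per subject")
  if (n < 4) stop_("need at least 4 subjects")
  if (stats::sd(mean_fd) < 1e-12) stop_("mean FD has zero variance")
  r <- suppressWarnings(as.vector(stats::cor(mean_fd, s$Y)))
  r[is.na(r)] <- 0
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  list(r = r, p = p, median_r = stats::median(r),
       pct_significant = 100 * mean(p < alpha))
}
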