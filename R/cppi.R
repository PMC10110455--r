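
#' Fisher z transform and its inverse
#'
#' \code{fisher_z} maps correlation coefficients to z values via atanh;
#' \code{fisher_z_inv} maps back via tanh.
#'
#' @param r correlation value(s), |r| < 1
#' @param z Fisher z value(s)
#' @return transformed numeric vector
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop_("|r| must be < 1 for the Fisher transform")
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Regularized Wiener deconvolution against the canonical HRF
#'
#' Estimates the latent neural series from an observed BOLD series by
#' frequency-domain division with Tikhonov regularization:
#' \eqn{\hat{n} = F^{-1}[\bar{H} Y / (|H|^2 + \lambda \max |H|^2)]}.
#'
#' @param y observed series (numeric vector)
#' @param kernel HRF kernel sampled at the series' sampling interval
#' @param lambda regularization as a fraction of the peak spectral power
#' @return deconvolved series of the same length
#' @export
wiener_deconvolve <- function(y, kernel, lambda = 1e-2) {
  Tn <- length(y)
  h <- c(kernel, numeric(max(0, Tn - length(kernel))))[seq_len(Tn)]
  H <- stats::fft(h)
  Y <- stats::fft(y)
  P <- Mod(H)^2
  est <- Conj(H) * Y / (P + lambda * max(P))
  Re(stats::fft(est, inverse = TRUE)) / Tn
}

# PPI term of one node: deconvolved neural estimate x centered psychological
# vector, reconvolved with the HRF
ppi_term <- function(y, psych_c, kernel, deconvolve = TRUE, lambda = 1e-2) {
  neural <- if (deconvolve) wiener_deconvolve(y, kernel, lambda) else y
  x <- neural * psych_c
  stats::convolve(x, rev(kernel), type = "open")[seq_along(x)]
}

# partial correlation of a and b controlling for the columns of Z
partial_cor <- function(a, b, Z) {
  qz <- qr(cbind(1, Z))
  ra <- qr.resid(qz, a)
  rb <- qr.resid(qz, b)
  if (stats::sd(ra) < 1e-12 || stats::sd(rb) < 1e-12) return(NA_real_)
  stats::cor(ra, rb)
}

#' Correlational PPI connectivity matrix
#'
#' Task-conditional connectivity by correlational psychophysiological
#' interaction: for every node, the (Wiener-)deconvolved neural estimate is
#' multiplied with the centered psychological contrast vector and reconvolved
#' with the canonical HRF to form a PPI term. For each node pair, the partial
#' correlation between the two PPI terms is computed controlling for the
#' observed series of both nodes, the convolved task regressor, and the
#' per-volume motion (framewise displacement) series, then Fisher
#' z-transformed. Run matrices are computed separately and averaged.
#'
#' @param runs list of denoised volumes x nodes matrices (one per run), or a
#'   single matrix
#' @param design a \code{\link{simulate_design}} result (shared across runs)
#' @param positive,negative condition labels of the psychological contrast
#' @param motion list of per-volume motion covariate vectors (one per run;
#'   e.g. the framewise displacement series), or NULL to omit
#' @param deconvolve use Wiener deconvolution (\code{FALSE} multiplies the
#'   observed series directly)
#' @param lambda Wiener regularization parameter
#' @param include_cue passed to \code{\link{make_task_regressor}}
#' @return symmetric node x node Fisher-z matrix (class
#'   \code{connectivity_matrix}) with zero diagonal; provenance (contrast,
#'   runs averaged, number of missing entries) in attributes
#' @export
cppi_matrix <- function(runs, design, positive = "fluency",
                        negative = "counting", motion = NULL,
                        deconvolve = TRUE, lambda = 1e-2,
                        include_cue = FALSE) {
  if (is.matrix(runs)) runs <- list(runs)
  if (!is.null(motion) && !is.list(motion)) motion <- list(motion)
  if (!is.null(motion) && length(motion) != length(runs))
    stop_("'motion' must supply one covariate series per run")
  n_nodes <- ncol(runs[[1]])
  if (n_nodes < 2) stop_("need at least 2 nodes")
  node_ids <- colnames(runs[[1]]) %||% paste0("node", seq_len(n_nodes))

  # psychological vectors: centered boxcar for the PPI product, HRF-convolved
  # regressor as a partial-correlation control
  psych_c <- make_task_regressor(design, positive, negative, convolve = FALSE,
                                 include_cue = include_cue)
  task_reg <- make_task_regressor(design, positive, negative, convolve = TRUE,
                                  include_cue = include_cue)
  kernel <- hrf_kernel(design$tr_s)

  zsum <- matrix(0, n_nodes, n_nodes)
  zcnt <- matrix(0, n_nodes, n_nodes)
  for (r in seq_along(runs)) {
    y <- as.matrix(runs[[r]])
    if (nrow(y) != design$n_volumes_retained)
      stop_("run ", r, ": volume count does not match the design")
    y <- sweep(y, 2, colMeans(y))  # the method operates on demeaned residuals
    ppi <- apply(y, 2, ppi_term, psych_c = psych_c, kernel = kernel,
                 deconvolve = deconvolve, lambda = lambda)
    mot <- if (!is.null(motion)) motion[[r]] else NULL
    # project the shared controls (intercept, task regressor, motion) out of
    # both blocks once; the pairwise controls (the two observed node series)
    # are then conditioned out via the joint covariance of
    # (ppi_i, ppi_j, y_i, y_j), which equals residual-based partialling
    qz <- qr(cbind(1, task_reg, mot))
    pr <- qr.resid(qz, ppi)
    yr <- qr.resid(qz, y)
    C_pp <- crossprod(pr)
    C_py <- crossprod(pr, yr)
    C_yy <- crossprod(yr)
    for (i in seq_len(n_nodes - 1)) {
      for (j in (i + 1):n_nodes) {
        S11 <- C_pp[c(i, j), c(i, j)]
        S12 <- C_py[c(i, j), c(i, j)]
        S22 <- C_yy[c(i, j), c(i, j)]
        cond <- tryCatch(S11 - S12 %*% solve(S22, t(S12)),
                         error = function(e) NULL)
        rho <- if (is.null(cond) || any(diag(cond) < 1e-12)) NA_real_ else
          cond[1, 2] / sqrt(cond[1, 1] * cond[2, 2])
        if (!is.na(rho)) {
          z <- fisher_z(max(-1 + 1e-12, min(1 - 1e-12, rho)))
          zsum[i, j] <- zsum[i, j] + z
          zcnt[i, j] <- zcnt[i, j] + 1
        }
      }
    }
  }
  z <- ifelse(zcnt > 0, zsum / zcnt, NA_real_)
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  diag(z) <- 0
  dimnames(z) <- list(node_ids, node_ids)
  n_missing <- sum(is.na(z[upper.tri(z)]))
  if (n_missing > 0)
    warning(sprintf("%d edge(s) undefined (constant PPI term)", n_missing),
            call. = FALSE)
  structure(z, class = c("connectivity_matrix", "matrix", "array"),
            contrast = paste(paste(positive, collapse = "+"), ">",
                             paste(negative, collapse = "+")),
            n_runs = length(runs), n_missing = n_missing,
            deconvolved = deconvolve)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("cPPI connectivity matrix: %d nodes, contrast %s, %d run(s) averaged\n",
              nrow(x), attr(x, "contrast") %||% "?", attr(x, "n_runs") %||% 1L))
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(utils::head(round(m[, seq_len(min(6, ncol(m)))], 3), 6))
  invisible(x)
}

#' Average node series within communities
#'
#' Collapses a volumes x nodes matrix to one mean series per community,
#' enabling the network-level analysis tier.
#'
#' @param series volumes x nodes matrix with node ids as column names
#' @param partition named node-to-community vector covering every node
#' @return volumes x communities matrix (community labels as column names)
#' @export
network_average_series <- function(series, partition) {
  series <- as.matrix(series)
  nodes <- colnames(series)
  if (is.null(nodes)) stop_("'series' must carry node ids as column names")
  check_partition(partition, nodes)
  comms <- unique(partition[nodes])
  out <- sapply(comms, function(cm) {
    members <- nodes[partition[nodes] == cm]
    if (!length(members)) stop_("empty community: ", cm)
    rowMeans(series[, members, drop = FALSE])
  })
  colnames(out) <- comms
  out
}

#' Mean within- and between-network connectivity
#'
#' Averages Fisher-z edges of a connectivity matrix within and between
#' communities, on the full signed matrix (no negative-weight zeroing).
#'
#' @param z symmetric connectivity matrix with node ids
#' @param partition named node-to-community vector
#' @return list with \code{within}, \code{between} (grand means) and
#'   \code{pairs} (community-pair mean matrix)
#' @export
network_fc_summary <- function(z, partition) {
  check_symmetric(z, "z")
  nodes <- rownames(z) %||% names(partition)[seq_len(nrow(z))]
  check_partition(partition, nodes)
  comm <- partition[nodes]
  same <- outer(comm, comm, "==")
  ut <- upper.tri(z)
  comms <- unique(comm)
  pairs <- matrix(NA_real_, length(comms), length(comms),
                  dimnames = list(comms, comms))
  for (a in seq_along(comms)) for (b in a:length(comms)) {
    sel <- ut & outer(comm == comms[a], comm == comms[b], "&")
    if (a != b)
      sel <- sel | (ut & outer(comm == comms[b], comm == comms[a], "&"))
    vals <- z[sel]
    pairs[a, b] <- pairs[b, a] <- mean(vals, na.rm = TRUE)
  }
  list(within = mean(z[ut & same], na.rm = TRUE),
       between = mean(z[ut & !same], na.rm = TRUE),
       pairs = pairs)
}
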