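
#' Build the confound regressor matrix for denoising
#'
#' Assembles the full nuisance design from a per-volume confound table:
#' the 24-parameter motion expansion (6 realignment parameters, their
#' backward-difference temporal derivatives, and the squares of all 12),
#' optionally the global signal, the component (aCompCor) regressors, 18
#' discrete-cosine drift regressors, and one indicator (one-hot) column per
#' volume whose framewise displacement exceeds \code{fd_spike_mm}.
#'
#' @param confounds data frame with columns \code{trans_x..rot_z},
#'   \code{framewise_displacement}, \code{global_signal} (when used), and
#'   \code{a_comp_cor_*}
#' @param use_global_signal include the global signal column?
#' @param n_cosine number of discrete-cosine drift regressors
#' @param fd_spike_mm framewise-displacement censoring threshold (mm)
#' @return numeric matrix (volumes x regressors) with named columns; the
#'   column provenance (class of each regressor) is attached as attribute
#'   \code{"provenance"}
#' @export
build_confound_matrix <- function(confounds, use_global_signal = TRUE,
                                  n_cosine = 18, fd_spike_mm = 0.9) {
  motion_cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  need <- c(motion_cols, "framewise_displacement",
            if (use_global_signal) "global_signal")
  missing <- setdiff(need, names(confounds))
  if (length(missing))
    stop_("confound table lacks column(s): ", paste(missing, collapse = ", "))
  Tn <- nrow(confounds)

  motion <- as.matrix(confounds[, motion_cols])
  deriv <- rbind(0, apply(motion, 2, diff))
  colnames(deriv) <- paste0(motion_cols, "_derivative1")
  quad <- cbind(motion, deriv)^2
  colnames(quad) <- paste0(colnames(cbind(motion, deriv)), "_power2")
  X <- cbind(motion, deriv, quad)
  prov <- rep("motion24", ncol(X))

  if (use_global_signal) {
    X <- cbind(X, global_signal = confounds$global_signal)
    prov <- c(prov, "global_signal")
  }
  cc_cols <- grep("^a_comp_cor", names(confounds), value = TRUE)
  if (length(cc_cols)) {
    X <- cbind(X, as.matrix(confounds[, cc_cols, drop = FALSE]))
    prov <- c(prov, rep("compcor", length(cc_cols)))
  }
  if (n_cosine > 0) {
    t <- seq_len(Tn)
    dct <- sapply(seq_len(n_cosine), function(k)
      sqrt(2 / Tn) * cos(pi * k * (2 * t - 1) / (2 * Tn)))
    colnames(dct) <- sprintf("cosine%02d", seq_len(n_cosine))
    X <- cbind(X, dct)
    prov <- c(prov, rep("cosine", n_cosine))
  }
  spikes <- which(confounds$framewise_displacement > fd_spike_mm)
  if (length(spikes)) {
    S <- matrix(0, Tn, length(spikes))
    S[cbind(spikes, seq_along(spikes))] <- 1
    colnames(S) <- sprintf("motion_outlier%02d", seq_along(spikes))
    X <- cbind(X, S)
    prov <- c(prov, rep("spike", length(spikes)))
  }
  attr(X, "provenance") <- stats::setNames(prov, colnames(X))
  X
}

#' Remove confounds from node time series in a single regression step
#'
#' Projects every node series onto the orthogonal complement of the confound
#' design (plus an intercept) by one joint least-squares fit, then demeans the
#' residuals. Collinear regressor columns are dropped (with a message) before
#' fitting; residuals are orthogonal to every retained regressor.
#'
#' @param series volumes x nodes numeric matrix
#' @param X confound regressor matrix from
#'   \code{\link{build_confound_matrix}}
#' @return residual matrix of the same shape; dropped columns recorded in
#'   attribute \code{"dropped"}
#' @export
denoise <- function(series, X) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  if (nrow(X) != Tn)
    stop_("series and confound matrix differ in volume count")
  X1 <- cbind(`(Intercept)` = 1, X)
  if (ncol(X1) >= Tn)
    stop_(sprintf("more regressors (%d) than volumes (%d)", ncol(X1), Tn))
  qrX <- qr(X1)
  dropped <- character(0)
  if (qrX$rank < ncol(X1)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X1)[-keep]
    message("denoise: dropping collinear regressor(s): ",
            paste(dropped, collapse = ", "))
    qrX <- qr(X1[, keep, drop = FALSE])
  }
  res <- qr.resid(qrX, series)
  res <- sweep(res, 2, colMeans(res))
  sds <- apply(res, 2, stats::sd)
  if (any(sds < 1e-12))
    warning("node series constant after denoising: ",
            paste(colnames(series)[sds < 1e-12], collapse = ", "),
            call. = FALSE)
  attr(res, "dropped") <- dropped
  res
}
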