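
# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible integer seed from a master seed and a label
#'
#' Stable string hash (polynomial rolling hash over UTF-8 bytes, modulo a
#' Mersenne prime below 2^31) so that per-subject random streams are
#' reproducible and independent of generation order.
#'
#' @param seed master integer seed
#' @param ... labels (coerced to character) identifying the stream
#' @return a single integer in [0, 2^31-2]
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(sprintf("'%s' must be a single finite number", name))
  if (integer && x != round(x))
    stop_(sprintf("'%s' must be an integer", name))
  if (x < lower || x > upper)
    stop_(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(x)
}

check_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_(sprintf("'%s' must be a square matrix", name))
  if (max(abs(m - t(m))) > tol)
    stop_(sprintf("'%s' must be symmetric", name))
  invisible(m)
}

# upper-triangle index pairs of an n x n matrix, in the same (column-major)
# order as m[upper.tri(m)]
upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# rebuild a symmetric matrix (zero diagonal) from its upper-triangle vector
sym_from_upper <- function(v, n, node_ids = NULL) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(node_ids)) dimnames(m) <- list(node_ids, node_ids)
  m
}

upper_vec <- function(m) m[upper.tri(m)]
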