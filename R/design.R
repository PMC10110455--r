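
#' Canonical double-gamma hemodynamic response function
#'
#' SPM-convention difference of two gamma densities: response peak at
#' \code{peak} seconds, undershoot peak at \code{undershoot} seconds, with the
#' undershoot scaled down by \code{ratio}. The kernel is normalized to unit
#' peak height; scaling is irrelevant for all correlation-based stages.
#'
#' @param t time points in seconds (>= 0)
#' @param peak delay of the positive response peak (s)
#' @param undershoot delay of the undershoot peak (s)
#' @param ratio positive-to-undershoot amplitude ratio
#' @return numeric vector of HRF values at \code{t}
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  check_number(peak, "peak", lower = 1e-6)
  check_number(undershoot, "undershoot", lower = 1e-6)
  check_number(ratio, "ratio", lower = 1e-6)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  h / max(h)
}

# HRF sampled on a dt grid, truncated at 32 s, normalized to sum 1 so that
# convolution preserves signal scale
hrf_kernel <- function(dt, span_s = 32, peak = 6, undershoot = 16, ratio = 6) {
  k <- hrf_double_gamma(seq(0, span_s, by = dt), peak, undershoot, ratio)
  k / sum(k)
}

#' Simulate a blocked semantic-fluency / counting task design
#'
#' Builds the event timeline of a paced word-retrieval experiment: task blocks
#' of \code{block_s} seconds separated by single rest periods of \code{rest_s}
#' seconds (rests only between consecutive blocks, none after the last). Each
#' block opens with a \code{cue_s}-second visual cue followed by
#' \code{trials_per_block} trials separated by inter-trial jitter drawn
#' uniformly from \code{jitter_s}; cue, trials and jitter all fit inside the
#' block budget. Block conditions alternate between fluency and counting.
#'
#' @param n_fluency_blocks,n_counting_blocks number of blocks per condition
#' @param block_s,rest_s,cue_s block, rest and cue durations in seconds
#' @param trials_per_block trials in each block
#' @param tr_s sampling interval (repetition time) in seconds
#' @param discard initial volumes dropped before analysis
#' @param n_volumes_acquired total volumes collected; defaults to
#'   \code{discard} plus the volumes needed to cover the task timeline
#' @param jitter_s length-2 range of the uniform inter-trial jitter (s)
#' @param seed integer seed for the jitter draws
#' @return an object of class \code{task_design}: list with \code{events}
#'   (onset, duration, trial_type, block, trial), \code{blocks},
#'   \code{total_duration_s}, volume counts and timing parameters
#' @examples
#' d <- simulate_design(10, 10)
#' d$total_duration_s / 60  # 19.4 min
#' @export
simulate_design <- function(n_fluency_blocks, n_counting_blocks,
                            block_s = 43, rest_s = 16, cue_s = 2,
                            trials_per_block = 9, tr_s = 2, discard = 29,
                            n_volumes_acquired = NULL,
                            jitter_s = c(2, 4), seed = 1L) {
  check_number(n_fluency_blocks, "n_fluency_blocks", lower = 0, integer = TRUE)
  check_number(n_counting_blocks, "n_counting_blocks", lower = 0, integer = TRUE)
  if (n_fluency_blocks + n_counting_blocks < 1)
    stop_("at least one block is required")
  check_number(block_s, "block_s", lower = 1e-9)
  check_number(rest_s, "rest_s", lower = 1e-9)
  check_number(cue_s, "cue_s", lower = 0)
  check_number(trials_per_block, "trials_per_block", lower = 1, integer = TRUE)
  check_number(tr_s, "tr_s", lower = 1e-9)
  check_number(discard, "discard", lower = 0, integer = TRUE)
  if (length(jitter_s) != 2L || any(jitter_s < 0) || jitter_s[2] < jitter_s[1])
    stop_("'jitter_s' must be an increasing non-negative range")

  n_blocks <- n_fluency_blocks + n_counting_blocks
  # alternate conditions until one is exhausted, then run out the other
  conditions <- c(rep(c("fluency", "counting"),
                      min(n_fluency_blocks, n_counting_blocks)),
                  rep(if (n_fluency_blocks > n_counting_blocks) "fluency"
                      else "counting",
                      abs(n_fluency_blocks - n_counting_blocks)))

  total_s <- n_blocks * block_s + (n_blocks - 1) * rest_s

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  rows <- vector("list", n_blocks * (trials_per_block + 2L))
  r <- 0L
  block_onsets <- (seq_len(n_blocks) - 1L) * (block_s + rest_s)
  for (b in seq_len(n_blocks)) {
    on <- block_onsets[b]
    r <- r + 1L
    rows[[r]] <- data.frame(onset = on, duration = cue_s, trial_type = "cue",
                            block = b, trial = NA_integer_)
    n_gaps <- trials_per_block - 1L
    jit <- if (n_gaps > 0) stats::runif(n_gaps, jitter_s[1], jitter_s[2]) else numeric(0)
    trial_budget <- block_s - cue_s - sum(jit)
    if (trial_budget <= 0)
      stop_("jitter and cue exceed the block duration; increase 'block_s'")
    trial_dur <- trial_budget / trials_per_block
    t0 <- on + cue_s
    for (k in seq_len(trials_per_block)) {
      r <- r + 1L
      rows[[r]] <- data.frame(onset = t0, duration = trial_dur,
                              trial_type = conditions[b], block = b, trial = k)
      t0 <- t0 + trial_dur + if (k <= n_gaps) jit[k] else 0
    }
    if (b < n_blocks) {
      r <- r + 1L
      rows[[r]] <- data.frame(onset = on + block_s, duration = rest_s,
                              trial_type = "rest", block = NA_integer_,
                              trial = NA_integer_)
    }
  }
  events <- do.call(rbind, rows[seq_len(r)])
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL

  n_task_vols <- ceiling(total_s / tr_s)
  if (is.null(n_volumes_acquired)) n_volumes_acquired <- discard + n_task_vols
  check_number(n_volumes_acquired, "n_volumes_acquired", lower = 1, integer = TRUE)
  n_volumes_acquired <- as.integer(n_volumes_acquired)
  discard <- as.integer(discard)
  n_ret <- n_volumes_acquired - discard
  if (n_ret < 1)
    stop_("'discard' leaves no retained volumes")

  structure(list(
    events = events,
    blocks = data.frame(onset = block_onsets, duration = block_s,
                        condition = conditions, block = seq_len(n_blocks)),
    total_duration_s = total_s,
    tr_s = tr_s,
    cue_s = cue_s,
    n_volumes_acquired = n_volumes_acquired,
    n_volumes_discarded = discard,
    n_volumes_retained = n_ret
  ), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  tab <- table(x$blocks$condition)
  cat(sprintf("Task design: %d blocks (%s), %.1f s total (%.2f min)\n",
              nrow(x$blocks),
              paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = " + "),
              x$total_duration_s, x$total_duration_s / 60))
  cat(sprintf("  TR %.2f s; volumes acquired %d, discarded %d, retained %d\n",
              x$tr_s, x$n_volumes_acquired, x$n_volumes_discarded,
              x$n_volumes_retained))
  invisible(x)
}

# condition label ("fluency"/"counting"/"rest") of each retained volume,
# by block window membership (cue volumes belong to their block)
design_condition_per_volume <- function(design) {
  times <- (seq_len(design$n_volumes_retained) - 1L) * design$tr_s
  cond <- rep("rest", length(times))
  for (b in seq_len(nrow(design$blocks))) {
    w <- times >= design$blocks$onset[b] &
      times < design$blocks$onset[b] + design$blocks$duration[b]
    cond[w] <- design$blocks$condition[b]
  }
  cond
}

#' Psychological (task-contrast) regressor sampled at volume times
#'
#' Builds a boxcar that is +1 over events of the positive conditions and -1
#' over events of the negative conditions, convolves it with the canonical
#' double-gamma HRF on a fine time grid, samples it at the retained volume
#' times, and mean-centers the result.
#'
#' @param design a \code{task_design}
#' @param positive,negative character vectors of condition labels; the
#'   contrast is positive minus negative (e.g. fluency > counting)
#' @param include_cue logical; should each block's cue period carry its
#'   block's condition in the boxcar?
#' @param convolve logical; \code{FALSE} returns the centered boxcar itself
#' @param dt_s fine grid step for the convolution (s)
#' @param hrf_peak,hrf_undershoot,hrf_ratio HRF shape parameters
#' @return numeric vector of length \code{design$n_volumes_retained}
#' @export
make_task_regressor <- function(design, positive, negative = character(0),
                                include_cue = FALSE, convolve = TRUE,
                                dt_s = 0.1, hrf_peak = 6, hrf_undershoot = 16,
                                hrf_ratio = 6) {
  stopifnot(inherits(design, "task_design"))
  known <- unique(c(design$events$trial_type, "fluency", "counting", "rest"))
  bad <- setdiff(c(positive, negative), known)
  if (length(bad))
    stop_("unknown condition(s): ", paste(bad, collapse = ", "))
  ev <- design$events
  if (include_cue) {
    cue <- ev[ev$trial_type == "cue", , drop = FALSE]
    if (nrow(cue)) {
      cue$trial_type <- design$blocks$condition[match(cue$block, design$blocks$block)]
      ev <- rbind(ev[ev$trial_type != "cue", , drop = FALSE], cue)
    }
  }
  # grid covers the full acquisition, not just the task timeline, so the
  # HRF tail after the last block is represented
  span_s <- max(design$total_duration_s,
                design$n_volumes_retained * design$tr_s) + 1e-9
  t_fine <- seq(0, span_s, by = dt_s)
  box <- numeric(length(t_fine))
  add_cond <- function(box, conds, sign) {
    sel <- ev[ev$trial_type %in% conds, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      w <- t_fine >= sel$onset[i] & t_fine < sel$onset[i] + sel$duration[i]
      box[w] <- sign
    }
    box
  }
  box <- add_cond(box, positive, +1)
  box <- add_cond(box, negative, -1)
  x <- if (convolve) {
    k <- hrf_kernel(dt_s, peak = hrf_peak, undershoot = hrf_undershoot,
                    ratio = hrf_ratio)
    stats::convolve(box, rev(k), type = "open")[seq_along(box)]
  } else box
  vol_t <- (seq_len(design$n_volumes_retained) - 1L) * design$tr_s
  idx <- pmin(length(t_fine), pmax(1L, round(vol_t / dt_s) + 1L))
  out <- x[idx]
  out - mean(out)
}

#' Write a BIDS-style events table
#'
#' @param design a \code{task_design}
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
write_events_tsv <- function(design, path) {
  ev <- design$events[, c("onset", "duration", "trial_type")]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
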