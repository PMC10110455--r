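
#' Assign nodes to communities
#'
#' Convenience constructor for a community partition: \code{n_nodes} nodes
#' split as evenly as possible over \code{n_communities} labeled networks.
#'
#' @param n_nodes number of nodes
#' @param n_communities number of communities (networks)
#' @param labels optional community labels (default \code{net1..netK})
#' @return named character vector mapping node id to community label
#' @export
make_partition <- function(n_nodes = 28, n_communities = 7, labels = NULL) {
  check_number(n_nodes, "n_nodes", lower = 1, integer = TRUE)
  check_number(n_communities, "n_communities", lower = 1, integer = TRUE)
  if (n_communities > n_nodes)
    stop_("more communities than nodes")
  labels <- labels %||% paste0("net", seq_len(n_communities))
  if (length(labels) != n_communities)
    stop_("'labels' must have length 'n_communities'")
  p <- labels[rep(seq_len(n_communities), length.out = n_nodes)]
  p <- sort(p)
  names(p) <- sprintf("node%03d", seq_len(n_nodes))
  p
}

check_partition <- function(partition, node_ids = NULL) {
  if (is.null(names(partition)))
    stop_("'partition' must be a named vector (node id -> community)")
  if (anyNA(partition)) stop_("'partition' contains missing labels")
  if (!is.null(node_ids)) {
    missing <- setdiff(node_ids, names(partition))
    if (length(missing))
      stop_("nodes not covered by partition: ", paste(missing, collapse = ", "))
  }
  invisible(partition)
}

# condition-specific latent correlation matrix from block coupling levels;
# 'between' may be a scalar or a symmetric community x community matrix
condition_cor <- function(partition, within, between) {
  comms <- unique(partition)
  n <- length(partition)
  if (is.matrix(between)) {
    if (!all(comms %in% rownames(between)) || !all(comms %in% colnames(between)))
      stop_("'between' matrix must be indexed by community labels")
  } else {
    between <- matrix(between, length(comms), length(comms),
                      dimnames = list(comms, comms))
  }
  if (any(abs(within) >= 1) || any(abs(between) >= 1))
    stop_("coupling levels must lie in (-1, 1)")
  m <- between[partition, partition]
  same <- outer(partition, partition, "==")
  m[same] <- within
  diag(m) <- 1
  dimnames(m) <- list(names(partition), names(partition))
  m
}

# nearest-PSD repair by eigenvalue clipping at zero, rescaled to unit diagonal
repair_psd <- function(m, warn = TRUE) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(m)
  if (warn) warning("coupling matrix not positive semidefinite; ",
                    "clipping negative eigenvalues", call. = FALSE)
  v <- pmax(e$values, 0)
  r <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(r), 1e-12))
  r <- r / outer(d, d)
  dimnames(r) <- dimnames(m)
  (r + t(r)) / 2
}

default_coupling <- function() {
  # study conditions: old = young with within -0.2 / between +0.2 during the
  # fluency (target) condition; identical control and rest coupling
  list(
    young = list(fluency  = list(within = 0.5, between = 0.1),
                 counting = list(within = 0.3, between = 0.1),
                 rest     = list(within = 0.2, between = 0.0)),
    old   = list(fluency  = list(within = 0.3, between = 0.3),
                 counting = list(within = 0.3, between = 0.1),
                 rest     = list(within = 0.2, between = 0.0))
  )
}

#' Specify a synthetic two-group cohort
#'
#' Fixes the generative conditions for a multi-subject ROI time-series
#' simulation: group sizes, the node-to-network partition, condition- and
#' group-specific latent coupling (within- and between-network correlation
#' levels for fluency, counting and rest), observation noise, and motion
#' artifact rate. Latent correlation matrices implied by the coupling levels
#' are verified positive semidefinite and repaired by eigenvalue clipping if
#' needed.
#'
#' @param n_young,n_old subjects per age group (>= 1; \code{n_old = 0} allowed
#'   for single-group datasets)
#' @param partition named node-to-community vector (see
#'   \code{\link{make_partition}})
#' @param coupling nested list \code{coupling[[group]][[condition]]} with
#'   elements \code{within} (scalar) and \code{between} (scalar or community
#'   matrix), all in (-1, 1)
#' @param noise_ar1 AR(1) coefficient of the observation noise, in [0, 1)
#' @param noise_sd innovation standard deviation of the observation noise
#' @param signal_sd standard deviation scale of the latent BOLD signal
#' @param motion_spike_rate expected motion spikes per run (Poisson)
#' @param n_runs runs per subject
#' @param seed master seed; per-subject streams are derived by stable hashing
#' @return an object of class \code{cohort_spec}
#' @export
cohort_spec <- function(n_young = 15, n_old = 15,
                        partition = make_partition(),
                        coupling = default_coupling(),
                        noise_ar1 = 0.3, noise_sd = 1, signal_sd = 1.5,
                        motion_spike_rate = 1, n_runs = 2, seed = 1L) {
  check_number(n_young, "n_young", lower = 1, integer = TRUE)
  check_number(n_old, "n_old", lower = 0, integer = TRUE)
  check_partition(partition)
  check_number(noise_ar1, "noise_ar1", lower = 0, upper = 1 - 1e-9)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(signal_sd, "signal_sd", lower = 1e-12)
  check_number(motion_spike_rate, "motion_spike_rate", lower = 0)
  check_number(n_runs, "n_runs", lower = 1, integer = TRUE)
  for (g in c("young", "old")) {
    if (is.null(coupling[[g]]))
      stop_("'coupling' must have entries for groups young and old")
    for (cond in c("fluency", "counting", "rest")) {
      cc <- coupling[[g]][[cond]]
      if (is.null(cc))
        stop_(sprintf("'coupling$%s' lacks condition '%s'", g, cond))
    }
  }
  # precompute (and verify/repair) the condition correlation matrices
  sigma <- list()
  for (g in c("young", "old")) {
    sigma[[g]] <- list()
    for (cond in c("fluency", "counting", "rest")) {
      cc <- coupling[[g]][[cond]]
      m <- condition_cor(partition, cc$within, cc$between)
      m <- repair_psd(m)
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8)
        stop_(sprintf("coupling for %s/%s not repairable to PSD", g, cond))
      sigma[[g]][[cond]] <- m
    }
  }
  structure(list(
    n_young = n_young, n_old = n_old, partition = partition,
    coupling = coupling, sigma = sigma,
    noise_ar1 = noise_ar1, noise_sd = noise_sd, signal_sd = signal_sd,
    motion_spike_rate = motion_spike_rate, n_runs = n_runs,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Cohort spec: %d young + %d old, %d nodes in %d networks, %d run(s)\n",
    x$n_young, x$n_old, length(x$partition),
    length(unique(x$partition)), x$n_runs))
  cat(sprintf("  AR(1) noise %.2f (sd %.2f), spike rate %.2f/run, seed %d\n",
              x$noise_ar1, x$noise_sd, x$motion_spike_rate, x$seed))
  invisible(x)
}

# draw a latent series with per-volume condition-switching correlation;
# conditions indexes into the sigma list
sim_latent <- function(sigma_list, cond_per_volume) {
  n <- ncol(sigma_list[[1]])
  Tn <- length(cond_per_volume)
  chol_list <- lapply(sigma_list, function(s) chol(s + diag(1e-10, n)))
  z <- matrix(stats::rnorm(Tn * n), Tn, n)
  x <- matrix(0, Tn, n)
  for (cond in names(sigma_list)) {
    w <- which(cond_per_volume == cond)
    if (length(w))
      x[w, ] <- z[w, , drop = FALSE] %*% chol_list[[cond]]
  }
  x
}

# AR(1) noise matrix, columns independent
sim_ar1 <- function(Tn, n, phi, sd) {
  e <- matrix(stats::rnorm(Tn * n, sd = sd), Tn, n)
  if (phi > 0 && Tn > 1) {
    for (t in 2:Tn) e[t, ] <- phi * e[t - 1, ] + e[t, ]
    e <- e * sqrt(1 - phi^2)  # stationary marginal sd = sd
  }
  e
}

#' Simulate one subject-run of ROI time series with confounds
#'
#' Draws a latent multivariate neural process whose instantaneous correlation
#' switches between the condition-specific matrices of the cohort spec
#' (fluency / counting / rest windows of the design), convolves it with the
#' canonical double-gamma HRF, and adds AR(1) observation noise. Motion spikes
#' inject transient global signal offsets and framewise-displacement
#' excursions above 0.9 mm. Output is bit-reproducible given
#' \code{(spec$seed, subject_id, run)}.
#'
#' @param spec a \code{\link{cohort_spec}}
#' @param design a \code{\link{simulate_design}} result
#' @param subject_id subject identifier (character)
#' @param group \code{"young"} or \code{"old"}
#' @param run run index
#' @param keep_latent store the pre-convolution latent draws as attribute
#'   \code{"latent"} of the series matrix (used for generator-truth checks)
#' @return list with \code{series} (volumes x nodes matrix, node ids as
#'   column names), \code{confounds} (per-volume data frame with BIDS-style
#'   columns), \code{subject}, \code{group}, \code{run}, \code{mean_fd}
#' @export
simulate_subject <- function(spec, design, subject_id, group,
                             run = 1L, keep_latent = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "task_design"))
  group <- match.arg(group, c("young", "old"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(spec$seed, subject_id, run))

  nodes <- names(spec$partition)
  n <- length(nodes)
  Tn <- design$n_volumes_retained
  cond <- design_condition_per_volume(design)

  latent <- sim_latent(spec$sigma[[group]], cond) * spec$signal_sd
  # unit-energy kernel: convolution smooths in time but preserves each
  # node's marginal variance, so signal_sd/noise_sd is the effective CNR
  k <- hrf_kernel(design$tr_s)
  k <- k / sqrt(sum(k^2))
  bold <- apply(latent, 2, function(x)
    stats::convolve(x, rev(k), type = "open")[seq_len(Tn)])
  noise <- sim_ar1(Tn, n, spec$noise_ar1, spec$noise_sd)
  y <- bold + noise

  # motion: slow random-walk realignment parameters plus spike jumps
  trans <- apply(matrix(stats::rnorm(Tn * 3, sd = 0.02), Tn, 3), 2, cumsum)
  rot <- apply(matrix(stats::rnorm(Tn * 3, sd = 2e-4), Tn, 3), 2, cumsum)
  n_spikes <- stats::rpois(1, spec$motion_spike_rate)
  spike_vols <- integer(0)
  if (n_spikes > 0 && Tn > 2) {
    spike_vols <- sort(sample(2:Tn, min(n_spikes, Tn - 1)))
    jump <- 0.35 + stats::rexp(length(spike_vols), rate = 4)
    for (i in seq_along(spike_vols)) {
      v <- spike_vols[i]
      trans[v, ] <- trans[v, ] + jump[i]
      # transient global offset in the BOLD signal at the spike volume
      y[v, ] <- y[v, ] + 3 * spec$noise_sd * jump[i]
    }
  }
  # Power-style framewise displacement, rotations on a 50 mm sphere
  dtr <- rbind(0, abs(apply(trans, 2, diff)))
  dro <- rbind(0, abs(apply(rot, 2, diff))) * 50
  fd <- rowSums(dtr) + rowSums(dro)
  fd[1] <- 0

  colnames(y) <- nodes
  gs <- rowMeans(y)
  compcor <- sim_ar1(Tn, 10, 0.5, 1)
  confounds <- data.frame(trans_x = trans[, 1], trans_y = trans[, 2],
                          trans_z = trans[, 3], rot_x = rot[, 1],
                          rot_y = rot[, 2], rot_z = rot[, 3],
                          framewise_displacement = fd, global_signal = gs)
  for (i in 1:10)
    confounds[[sprintf("a_comp_cor_%02d", i - 1)]] <- compcor[, i]

  if (keep_latent) attr(y, "latent") <- latent
  list(series = y, confounds = confounds, subject = subject_id,
       group = group, run = as.integer(run), mean_fd = mean(fd))
}

#' Simulate a full two-group cohort
#'
#' Generates all subject-runs of the spec with group-specific coupling, using
#' per-subject random streams derived from the master seed (generation order
#' does not affect any subject's data).
#'
#' @param spec a \code{\link{cohort_spec}}
#' @param design a \code{\link{simulate_design}} result
#' @param subject_ids optional character ids (default \code{sub01..});
#'   duplicates are an error
#' @param keep_latent passed to \code{\link{simulate_subject}}
#' @return object of class \code{synth_cohort}: list with \code{subjects}
#'   (data frame: subject, group, mean_fd, education), \code{runs} (nested
#'   list \code{runs[[subject]][[run]]}), \code{design}, \code{spec}
#' @export
simulate_cohort <- function(spec, design, subject_ids = NULL,
                            keep_latent = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- spec$n_young + spec$n_old
  groups <- c(rep("young", spec$n_young), rep("old", spec$n_old))
  subject_ids <- subject_ids %||% sprintf("sub%02d", seq_len(n_tot))
  if (length(subject_ids) != n_tot)
    stop_("'subject_ids' must have length n_young + n_old")
  if (anyDuplicated(subject_ids))
    stop_("duplicate subject ids: ",
          paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))

  runs <- stats::setNames(vector("list", n_tot), subject_ids)
  mean_fd <- numeric(n_tot)
  for (i in seq_len(n_tot)) {
    rr <- vector("list", spec$n_runs)
    for (r in seq_len(spec$n_runs))
      rr[[r]] <- simulate_subject(spec, design, subject_ids[i], groups[i],
                                  run = r, keep_latent = keep_latent)
    runs[[i]] <- rr
    mean_fd[i] <- mean(vapply(rr, `[[`, numeric(1), "mean_fd"))
  }
  # education: young adults more educated, as in typical aging cohorts
  edu_seed <- derive_seed(spec$seed, "education")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(edu_seed)
  education <- round(ifelse(groups == "young", stats::rnorm(n_tot, 17, 1.5),
                            stats::rnorm(n_tot, 14, 2)), 1)
  structure(list(
    subjects = data.frame(subject = subject_ids, group = groups,
                          mean_fd = mean_fd, education = education,
                          stringsAsFactors = FALSE),
    runs = runs, design = design, spec = spec
  ), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d young, %d old), %d run(s) each\n",
              nrow(x$subjects), sum(x$subjects$group == "young"),
              sum(x$subjects$group == "old"), x$spec$n_runs))
  invisible(x)
}

#' Write a cohort to disk as TSV/CSV files
#'
#' Time series as TSV (volumes x nodes, node-id header), confounds as
#' BIDS-style TSV, events as TSV, subject table as CSV, and the generative
#' truth (coupling levels and seed) as a JSON sidecar.
#'
#' @param cohort a \code{\link{simulate_cohort}} result
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_events_tsv(cohort$design, file.path(dir, "task_events.tsv"))
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (s in names(cohort$runs)) {
    for (r in seq_along(cohort$runs[[s]])) {
      run <- cohort$runs[[s]][[r]]
      base <- sprintf("%s_run-%d", s, r)
      utils::write.table(run$series, file.path(dir, paste0(base, "_timeseries.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(run$confounds, file.path(dir, paste0(base, "_confounds.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  truth <- list(seed = cohort$spec$seed,
                partition = as.list(cohort$spec$partition),
                coupling = cohort$spec$coupling,
                noise_ar1 = cohort$spec$noise_ar1,
                motion_spike_rate = cohort$spec$motion_spike_rate)
  jsonlite::write_json(truth, file.path(dir, "generative_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
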