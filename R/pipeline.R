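
#' Declarative pipeline configuration
#'
#' Collects every stage parameter with defaults mirroring the reference
#' analysis settings: Jaccard threshold 0.15, 5 mm ROI spheres, FD spike
#' threshold 0.9 mm, 18 cosine drift regressors, NBS cluster-forming p 0.01
#' with FWE alpha 0.025 and 10,000 permutations, 100 participation-coefficient
#' nulls, 15% coverage exclusion, global signal regression on.
#'
#' @param out_dir output directory for stage artifacts
#' @param seed master seed; every stochastic stage consumes a named seed
#'   derived from it
#' @param stages character vector of stages to run, in dependency order,
#'   among \code{simulate}, \code{connectivity}, \code{graph}, \code{nbs},
#'   \code{models}
#' @param n_young,n_old,n_nodes,n_communities,n_runs cohort dimensions
#' @param n_fluency_blocks,n_counting_blocks design dimensions
#' @param coupling generative coupling (see \code{\link{cohort_spec}})
#' @param use_global_signal denoising variant (with/without global signal)
#' @param j_min,roi_radius_mm,coverage_max_missing netmap parameters
#' @param fd_spike_mm,n_cosine denoising parameters
#' @param nbs_threshold_p,nbs_alpha,nbs_n_perm NBS parameters
#' @param pc_n_null participation-coefficient null count
#' @param behavior_link generative behavioral link (see
#'   \code{\link{behavior_link}})
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(out_dir = tempfile("cppigraph_run_"),
                            seed = 1L,
                            stages = c("simulate", "connectivity", "graph",
                                       "nbs", "models"),
                            n_young = 10, n_old = 10, n_nodes = 28,
                            n_communities = 7, n_runs = 2,
                            n_fluency_blocks = 10, n_counting_blocks = 10,
                            coupling = default_coupling(),
                            use_global_signal = TRUE,
                            j_min = 0.15, roi_radius_mm = 5,
                            coverage_max_missing = 0.15,
                            fd_spike_mm = 0.9, n_cosine = 18,
                            nbs_threshold_p = 0.01, nbs_alpha = 0.025,
                            nbs_n_perm = 10000, pc_n_null = 100,
                            behavior_link = cppigraph::behavior_link()) {
  stages <- match.arg(stages, several.ok = TRUE)
  check_number(j_min, "j_min", lower = 0, upper = 1)
  check_number(roi_radius_mm, "roi_radius_mm", lower = 1e-9)
  check_number(coverage_max_missing, "coverage_max_missing", lower = 0, upper = 1)
  check_number(fd_spike_mm, "fd_spike_mm", lower = 0)
  check_number(n_cosine, "n_cosine", lower = 0, integer = TRUE)
  check_number(nbs_threshold_p, "nbs_threshold_p", lower = 1e-12, upper = 1 - 1e-12)
  check_number(nbs_alpha, "nbs_alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_number(nbs_n_perm, "nbs_n_perm", lower = 100, integer = TRUE)
  check_number(pc_n_null, "pc_n_null", lower = 1, integer = TRUE)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
              n_young = n_young, n_old = n_old, n_nodes = n_nodes,
              n_communities = n_communities, n_runs = n_runs,
              n_fluency_blocks = n_fluency_blocks,
              n_counting_blocks = n_counting_blocks,
              coupling = coupling, use_global_signal = use_global_signal,
              j_min = j_min, roi_radius_mm = roi_radius_mm,
              coverage_max_missing = coverage_max_missing,
              fd_spike_mm = fd_spike_mm, n_cosine = n_cosine,
              nbs_threshold_p = nbs_threshold_p, nbs_alpha = nbs_alpha,
              nbs_n_perm = nbs_n_perm, pc_n_null = pc_n_null,
              behavior_link = behavior_link)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read or write a pipeline configuration as JSON
#'
#' Round-trips losslessly: \code{read_config(write_config(cfg, path))}
#' reproduces the configuration.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param path JSON file path
#' @return \code{write_config} returns \code{path} invisibly;
#'   \code{read_config} returns the configuration
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  bl <- unclass(x$behavior_link)
  bl$acc <- as.list(bl$acc)  # keep coefficient names through JSON
  bl$rt <- as.list(bl$rt)
  x$behavior_link <- bl
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bl <- x$behavior_link
  x$behavior_link <- behavior_link(acc = unlist(bl$acc), rt = unlist(bl$rt),
                                   sd_subject = bl$sd_subject,
                                   sd_category = bl$sd_category,
                                   sd_rt = bl$sd_rt)
  # coupling arrives as nested lists; validated later by cohort_spec
  do.call(pipeline_config, x)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order on a synthetic cohort:
#' \code{simulate} (cohort + behavior), \code{connectivity} (confound
#' regression and cPPI per subject), \code{graph} (segregation, OMST, global
#' efficiency, participation coefficients, hubs), \code{nbs} (edge-wise group
#' inference) and \code{models} (age LRTs and brain-behavior models). Tabular
#' outputs are written under \code{config$out_dir} together with a JSON run
#' manifest recording parameters, derived seeds, outputs and content hashes.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param quiet suppress per-stage log messages
#' @return (invisibly) list with \code{results} (per-stage R objects) and
#'   \code{manifest}
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (quiet) stage_log <- function(...) invisible(NULL)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = config$seed, stages = list())
  results <- list()
  outputs <- character(0)

  need_stage <- function(stage, dep) {
    if (is.null(results[[dep]]))
      stop_(sprintf("stage '%s' requires outputs of stage '%s'; enable it first",
                    stage, dep))
  }
  record <- function(stage, params, files) {
    outputs <<- c(outputs, files)
    manifest$stages[[stage]] <<- list(
      parameters = params,
      seed = derive_seed(config$seed, stage),
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(files)), basename(files))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }

  if ("simulate" %in% config$stages) {
    stage_log("simulate", "cohort of %d young + %d old, %d nodes, seed %d",
              config$n_young, config$n_old, config$n_nodes, config$seed)
    design <- simulate_design(config$n_fluency_blocks, config$n_counting_blocks,
                              seed = derive_seed(config$seed, "design"))
    spec <- cohort_spec(n_young = config$n_young, n_old = config$n_old,
                        partition = make_partition(config$n_nodes,
                                                   config$n_communities),
                        coupling = config$coupling, n_runs = config$n_runs,
                        seed = derive_seed(config$seed, "cohort"))
    cohort <- simulate_cohort(spec, design)
    # behavioral measure linked to each subject's generative between-network
    # fluency coupling
    bet <- vapply(cohort$subjects$group, function(g) {
      b <- config$coupling[[g]]$fluency$between
      mean(if (is.matrix(b)) b[upper.tri(b)] else b)
    }, numeric(1))
    behavior <- simulate_behavior(
      cohort$subjects,
      measure = stats::setNames(bet, cohort$subjects$subject),
      link = config$behavior_link,
      seed = derive_seed(config$seed, "behavior"))
    dirs <- file.path(config$out_dir, "cohort")
    write_cohort(cohort, dirs)
    bpath <- file.path(config$out_dir, "behavior.csv")
    utils::write.csv(behavior, bpath, row.names = FALSE)
    results$simulate <- list(cohort = cohort, behavior = behavior,
                             design = design)
    record("simulate", list(n_young = config$n_young, n_old = config$n_old,
                            n_nodes = config$n_nodes, n_runs = config$n_runs),
           c(file.path(dirs, "subjects.csv"), bpath))
  }

  if ("connectivity" %in% config$stages) {
    need_stage("connectivity", "simulate")
    cohort <- results$simulate$cohort
    design <- results$simulate$design
    stage_log("connectivity", "cPPI (%s global signal), %d subjects",
              if (config$use_global_signal) "with" else "without",
              nrow(cohort$subjects))
    mats <- list()
    for (s in cohort$subjects$subject) {
      runs <- lapply(cohort$runs[[s]], function(run) {
        X <- build_confound_matrix(run$confounds,
                                   use_global_signal = config$use_global_signal,
                                   n_cosine = config$n_cosine,
                                   fd_spike_mm = config$fd_spike_mm)
        denoise(run$series, X)
      })
      motion <- lapply(cohort$runs[[s]],
                       function(run) run$confounds$framewise_displacement)
      mats[[s]] <- cppi_matrix(runs, design, motion = motion)
    }
    mat_dir <- file.path(config$out_dir, "connectivity")
    dir.create(mat_dir, showWarnings = FALSE)
    files <- character(0)
    for (s in names(mats)) {
      f <- file.path(mat_dir, paste0(s, "_cppi.tsv"))
      utils::write.table(round(unclass(mats[[s]]), 8), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    results$connectivity <- list(matrices = mats)
    record("connectivity", list(use_global_signal = config$use_global_signal,
                                n_cosine = config$n_cosine,
                                fd_spike_mm = config$fd_spike_mm),
           files[1])
  }

  if ("graph" %in% config$stages) {
    need_stage("graph", "connectivity")
    cohort <- results$simulate$cohort
    mats <- results$connectivity$matrices
    partition <- cohort$spec$partition
    stage_log("graph", "OMST + topology metrics, %d PC nulls", config$pc_n_null)
    rows <- list()
    pc_tables <- list()
    for (s in names(mats)) {
      pos <- zero_negative(unclass(mats[[s]]))
      seg <- system_segregation(pos, partition, "global")
      o <- omst(pos)
      pc <- participation_coefficient(o$adjacency, partition,
                                      n_null = config$pc_n_null,
                                      seed = derive_seed(config$seed, "pc", s))
      grp <- cohort$subjects$group[cohort$subjects$subject == s]
      rows[[s]] <- data.frame(
        subject = s, group = grp,
        mean_fd = cohort$subjects$mean_fd[cohort$subjects$subject == s],
        segregation = seg$segregation,
        global_efficiency = global_efficiency(o$adjacency),
        omst_cost = o$cost, omst_gce = o$gce,
        mean_pc_norm = mean(pc$pc_norm, na.rm = TRUE),
        stringsAsFactors = FALSE)
      pc_tables[[s]] <- cbind(subject = s, group = grp, pc)
    }
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
    pc_all <- do.call(rbind, pc_tables)
    hubs <- define_hubs(stats::setNames(pc_all$pc_norm,
                                        paste(pc_all$subject, pc_all$node)),
                        pc_all$group)
    mfile <- file.path(config$out_dir, "graph_metrics.csv")
    utils::write.csv(metrics, mfile, row.names = FALSE)
    pfile <- file.path(config$out_dir, "participation_coefficients.csv")
    utils::write.csv(pc_all, pfile, row.names = FALSE)
    results$graph <- list(metrics = metrics, pc = pc_all, hubs = hubs)
    record("graph", list(pc_n_null = config$pc_n_null), c(mfile, pfile))
  }

  if ("nbs" %in% config$stages) {
    need_stage("nbs", "connectivity")
    cohort <- results$simulate$cohort
    mats <- results$connectivity$matrices
    if (length(unique(cohort$subjects$group)) < 2)
      stop_("NBS group comparison needs both age groups in the cohort")
    stage_log("nbs", "%d permutations, cluster p %.3f",
              config$nbs_n_perm, config$nbs_threshold_p)
    old_ids <- cohort$subjects$subject[cohort$subjects$group == "old"]
    yng_ids <- cohort$subjects$subject[cohort$subjects$group == "young"]
    covs <- data.frame(mean_fd = c(
      cohort$subjects$mean_fd[match(old_ids, cohort$subjects$subject)],
      cohort$subjects$mean_fd[match(yng_ids, cohort$subjects$subject)]))
    out <- nbs(lapply(old_ids, function(s) unclass(mats[[s]])),
               lapply(yng_ids, function(s) unclass(mats[[s]])),
               nbs_config(threshold_p = config$nbs_threshold_p,
                          alpha = config$nbs_alpha,
                          n_perm = config$nbs_n_perm),
               covariates = covs,
               seed = derive_seed(config$seed, "nbs"))
    nfile <- file.path(config$out_dir, "nbs_components.csv")
    comp_df <- if (length(out$components)) {
      cbind(component = rep(seq_along(out$components),
                            out$component_sizes),
            do.call(rbind, out$components),
            p_fwe = rep(out$p_fwe, out$component_sizes))
    } else data.frame(component = integer(0))
    utils::write.csv(comp_df, nfile, row.names = FALSE)
    results$nbs <- out
    record("nbs", list(n_perm = config$nbs_n_perm,
                       threshold_p = config$nbs_threshold_p,
                       alpha = config$nbs_alpha), nfile)
  }

  if ("models" %in% config$stages) {
    need_stage("models", "graph")
    cohort <- results$simulate$cohort
    behavior <- results$simulate$behavior
    metrics <- results$graph$metrics
    if (length(unique(cohort$subjects$group)) < 2)
      stop_("group models need both age groups in the cohort")
    stage_log("models", "age LRTs + brain-behavior models")
    age_tests <- rbind(
      lrt_network_model(data.frame(subject = metrics$subject,
                                   group = metrics$group,
                                   mean_fd = metrics$mean_fd,
                                   value = metrics$segregation),
                        "segregation"),
      lrt_network_model(data.frame(subject = metrics$subject,
                                   group = metrics$group,
                                   mean_fd = metrics$mean_fd,
                                   value = metrics$global_efficiency),
                        "global_efficiency"))
    meas <- list(
      segregation = stats::setNames(metrics$segregation, metrics$subject),
      global_efficiency = stats::setNames(metrics$global_efficiency,
                                          metrics$subject))
    bb <- behavior_models(behavior, meas, nAGQ = 0L)
    afile <- file.path(config$out_dir, "age_models.csv")
    bfile <- file.path(config$out_dir, "behavior_models.csv")
    utils::write.csv(age_tests, afile, row.names = FALSE)
    utils::write.csv(bb, bfile, row.names = FALSE)
    results$models <- list(age = age_tests, behavior = bb)
    record("models", list(), c(afile, bfile))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(results = results, manifest = manifest,
                 manifest_path = mpath))
}

#' Validate a dataset directory for format conformance
#'
#' Report-only checks of a cohort directory as written by
#' \code{\link{write_cohort}}: TSV column/row consistency between time series
#' and confounds, node-id agreement across subjects, subject cross-references
#' from the subjects table, and events-table schema.
#'
#' @param dir dataset directory
#' @return data frame of violations (file, check, message); zero rows when
#'   fully consistent
#' @export
validate_inputs <- function(dir) {
  violations <- list()
  note <- function(file, check, msg)
    violations[[length(violations) + 1]] <<-
    data.frame(file = file, check = check, message = msg,
               stringsAsFactors = FALSE)

  subj_path <- file.path(dir, "subjects.csv")
  if (!file.exists(subj_path)) {
    note("subjects.csv", "exists", "subjects table missing")
  } else {
    subjects <- utils::read.csv(subj_path, stringsAsFactors = FALSE)
    for (col in c("subject", "group"))
      if (!col %in% names(subjects))
        note("subjects.csv", "schema", paste("missing column", col))
    node_ref <- NULL
    if ("subject" %in% names(subjects)) {
      for (s in subjects$subject) {
        ts_files <- list.files(dir, sprintf("^%s_run-\\d+_timeseries\\.tsv$", s))
        if (!length(ts_files)) {
          note(subj_path, "crossref", paste("no time-series file for", s))
          next
        }
        for (f in ts_files) {
          ts <- utils::read.delim(file.path(dir, f), check.names = FALSE)
          if (is.null(node_ref)) node_ref <- colnames(ts)
          if (!identical(colnames(ts), node_ref))
            note(f, "node_ids", "node ids differ from other subjects")
          cf <- sub("_timeseries", "_confounds", f)
          if (!file.exists(file.path(dir, cf))) {
            note(cf, "exists", "confound table missing")
          } else {
            conf <- utils::read.delim(file.path(dir, cf))
            if (nrow(conf) != nrow(ts))
              note(cf, "rows", sprintf("%d confound rows vs %d volumes",
                                       nrow(conf), nrow(ts)))
            if (!"framewise_displacement" %in% names(conf))
              note(cf, "schema", "missing framewise_displacement")
          }
        }
      }
    }
  }
  ev_path <- file.path(dir, "task_events.tsv")
  if (!file.exists(ev_path)) {
    note("task_events.tsv", "exists", "events table missing")
  } else {
    ev <- utils::read.delim(ev_path)
    for (col in c("onset", "duration", "trial_type"))
      if (!col %in% names(ev))
        note("task_events.tsv", "schema", paste("missing column", col))
    if (all(c("onset") %in% names(ev)) && is.unsorted(ev$onset))
      note("task_events.tsv", "order", "onsets not increasing")
  }
  if (!length(violations))
    return(data.frame(file = character(0), check = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, violations)
  rownames(out) <- NULL
  out
}
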