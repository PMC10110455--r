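
#' Generative link coefficients for behavioral simulation
#'
#' Coefficients of the trial-level generative model. Accuracy is Bernoulli
#' with a logistic link; response time is lognormal. Both linear predictors
#' share the structure intercept + measure + age + measure x age + difficulty
#' (+ task for the counting contrast) + subject and category random
#' intercepts. Age is sum-coded (young = -1, old = +1), difficulty sum-coded
#' (easy = -1, difficult = +1) and the connectivity measure is mean-centered
#' before entering the predictor.
#'
#' @param acc named numeric vector of logit-scale accuracy coefficients
#' @param rt named numeric vector of log-seconds RT coefficients
#' @param sd_subject,sd_category random-intercept standard deviations
#'   (accuracy scale); RT uses half these values
#' @param sd_rt residual sd of log RT
#' @return list of class \code{behavior_link}
#' @export
behavior_link <- function(acc = c(intercept = 1.2, measure = 0, age = 0,
                                  interaction = 0, difficulty = -0.8,
                                  task = 1.5),
                          rt = c(intercept = 0.4, measure = 0, age = 0.15,
                                 interaction = 0, difficulty = 0.15,
                                 task = -0.2),
                          sd_subject = 0.5, sd_category = 0.4, sd_rt = 0.3) {
  need <- c("intercept", "measure", "age", "interaction", "difficulty", "task")
  for (v in list(acc = acc, rt = rt)) {
    if (!all(need %in% names(v)) || !all(is.finite(v)))
      stop_("link coefficients must be finite and named ",
            paste(need, collapse = ", "))
  }
  structure(list(acc = acc, rt = rt, sd_subject = sd_subject,
                 sd_category = sd_category, sd_rt = sd_rt),
            class = "behavior_link")
}

#' Simulate trial-level behavior linked to a connectivity measure
#'
#' Generates a trial table (accuracy and response time) for every subject of
#' a cohort, generatively linked to a per-subject network measure through the
#' coefficients of \code{\link{behavior_link}}. Fluency trials carry one of
#' \code{n_categories} semantic categories (half easy, half difficult) with
#' category random intercepts; counting trials have no category. Response
#' times are drawn for all trials; by convention only correct fluency trials
#' are analyzed downstream.
#'
#' @param subjects data frame with columns \code{subject}, \code{group}, and
#'   (optionally) \code{mean_fd}, \code{education} — e.g.
#'   \code{cohort$subjects} from \code{\link{simulate_cohort}}
#' @param measure named per-subject numeric vector (names = subject ids); the
#'   network measure entering the generative link (mean-centered internally)
#' @param link a \code{\link{behavior_link}}
#' @param n_categories number of fluency categories
#' @param trials_per_category fluency trials per category
#' @param n_counting_trials counting trials per subject
#' @param seed integer seed
#' @return data frame of class \code{behavior_table} with columns subject,
#'   group, task, category, difficulty, trial, accuracy, rt, education,
#'   mean_fd; generative coefficients stored in attribute \code{"link"}
#' @export
simulate_behavior <- function(subjects, measure, link = behavior_link(),
                              n_categories = 20, trials_per_category = 9,
                              n_counting_trials = 45, seed = 1L) {
  stopifnot(inherits(link, "behavior_link"))
  if (inherits(subjects, "synth_cohort")) subjects <- subjects$subjects
  need <- c("subject", "group")
  if (!all(need %in% names(subjects)))
    stop_("'subjects' needs columns ", paste(need, collapse = ", "))
  if (is.null(names(measure)) || !all(subjects$subject %in% names(measure)))
    stop_("'measure' must be named with every subject id")
  check_number(n_categories, "n_categories", lower = 2, integer = TRUE)
  if (n_categories %% 2 != 0) stop_("'n_categories' must be even (easy/difficult split)")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  meas_c <- measure[subjects$subject] - mean(measure[subjects$subject])
  age_s <- ifelse(subjects$group == "old", 1, -1)
  n_sub <- nrow(subjects)
  u_sub_acc <- stats::rnorm(n_sub, 0, link$sd_subject)
  u_sub_rt <- stats::rnorm(n_sub, 0, link$sd_subject / 2)
  cats <- sprintf("cat%02d", seq_len(n_categories))
  difficulty <- rep(c("easy", "difficult"), each = n_categories / 2)
  u_cat_acc <- stats::rnorm(n_categories, 0, link$sd_category)
  u_cat_rt <- stats::rnorm(n_categories, 0, link$sd_category / 2)

  rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    # fluency trials: every category x trial; counting trials: no category
    flu <- data.frame(
      task = "fluency",
      category = rep(cats, each = trials_per_category),
      difficulty = rep(difficulty, each = trials_per_category),
      trial = rep(seq_len(trials_per_category), n_categories),
      cat_idx = rep(seq_len(n_categories), each = trials_per_category))
    cnt <- if (n_counting_trials > 0) data.frame(
      task = "counting", category = NA_character_, difficulty = "easy",
      trial = seq_len(n_counting_trials), cat_idx = NA_integer_) else NULL
    tr <- rbind(flu, cnt)
    diff_s <- ifelse(tr$difficulty == "difficult", 1, -1)
    task_s <- ifelse(tr$task == "counting", 1, -1)
    ucat_a <- ifelse(is.na(tr$cat_idx), 0, u_cat_acc[tr$cat_idx])
    ucat_r <- ifelse(is.na(tr$cat_idx), 0, u_cat_rt[tr$cat_idx])

    eta_acc <- link$acc[["intercept"]] + link$acc[["measure"]] * meas_c[i] +
      link$acc[["age"]] * age_s[i] +
      link$acc[["interaction"]] * meas_c[i] * age_s[i] +
      link$acc[["difficulty"]] * diff_s + link$acc[["task"]] * task_s +
      u_sub_acc[i] + ucat_a
    eta_rt <- link$rt[["intercept"]] + link$rt[["measure"]] * meas_c[i] +
      link$rt[["age"]] * age_s[i] +
      link$rt[["interaction"]] * meas_c[i] * age_s[i] +
      link$rt[["difficulty"]] * diff_s + link$rt[["task"]] * task_s +
      u_sub_rt[i] + ucat_r

    tr$accuracy <- stats::rbinom(nrow(tr), 1, stats::plogis(eta_acc))
    tr$rt <- exp(eta_rt + stats::rnorm(nrow(tr), 0, link$sd_rt))
    tr$subject <- subjects$subject[i]
    tr$group <- subjects$group[i]
    tr$education <- if ("education" %in% names(subjects))
      subjects$education[i] else NA_real_
    tr$mean_fd <- if ("mean_fd" %in% names(subjects))
      subjects$mean_fd[i] else NA_real_
    rows[[i]] <- tr[, c("subject", "group", "task", "category", "difficulty",
                        "trial", "accuracy", "rt", "education", "mean_fd")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "link") <- link
  attr(out, "measure") <- measure
  class(out) <- c("behavior_table", class(out))
  out
}
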