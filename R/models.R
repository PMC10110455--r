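
# sum (deviation) coding for all factors, ANOVA-style
with_sum_contrasts <- function(expr) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  force(expr)
}

lrt_compare <- function(full, reduced) {
  ll_f <- as.numeric(stats::logLik(full))
  ll_r <- as.numeric(stats::logLik(reduced))
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  chisq <- max(0, 2 * (ll_f - ll_r))
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Likelihood-ratio test of an age effect on a network measure
#'
#' Fits \code{value ~ group + mean_fd} with a random intercept per subject
#' (when subjects contribute repeated observations) by maximum likelihood,
#' and compares it against the model without the group term by a
#' likelihood-ratio test. With a single observation per subject the model
#' degrades to a fixed-effects linear regression (with a message). Group is
#' sum-coded.
#'
#' @param data data frame with columns \code{subject}, \code{group},
#'   \code{mean_fd}, \code{value}
#' @param measure_name label carried into the result
#' @return data frame (one row): measure, chisq, df, p, beta_age, se_age,
#'   ci_low, ci_high, model, converged
#' @export
lrt_network_model <- function(data, measure_name = "measure") {
  need <- c("subject", "group", "mean_fd", "value")
  if (!all(need %in% names(data)))
    stop_("'data' needs columns ", paste(need, collapse = ", "))
  if (length(unique(data$group)) < 2)
    stop_("both age groups are required to test a group effect")
  if (stats::sd(data$value) < 1e-12)
    stop_("network measure has zero variance")
  # sum coding with old = +1 (matching the generator's age contrast) when the
  # standard labels are used
  data$group <- if (all(data$group %in% c("young", "old")))
    factor(data$group, levels = c("old", "young")) else factor(data$group)
  data$subject <- factor(data$subject)
  repeated <- any(table(data$subject) > 1)
  if (repeated) {
    # a measure exactly constant within every subject carries no run-level
    # information: the residual variance degenerates, so collapse to one row
    # per subject and test at the subject level
    within_var <- tapply(data$value, data$subject, stats::var)
    if (all(is.na(within_var) | within_var < 1e-24)) {
      data <- data[!duplicated(data$subject), , drop = FALSE]
      repeated <- FALSE
    }
  }
  converged <- TRUE

  with_sum_contrasts({
    if (repeated) {
      full <- withCallingHandlers(
        lme4::lmer(value ~ group + mean_fd + (1 | subject), data = data,
                   REML = FALSE),
        warning = function(w) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        })
      reduced <- suppressWarnings(
        lme4::lmer(value ~ mean_fd + (1 | subject), data = data, REML = FALSE))
      beta <- lme4::fixef(full)[2]
      se <- sqrt(diag(as.matrix(stats::vcov(full))))[2]
      model <- "lmm"
    } else {
      message("single observation per subject; fitting fixed-effects model")
      full <- stats::lm(value ~ group + mean_fd, data = data)
      reduced <- stats::lm(value ~ mean_fd, data = data)
      beta <- stats::coef(full)[2]
      se <- sqrt(diag(stats::vcov(full)))[2]
      model <- "lm"
    }
    lrt <- lrt_compare(full, reduced)
  })
  data.frame(measure = measure_name, chisq = lrt$chisq, df = lrt$df,
             p = lrt$p, beta_age = unname(beta), se_age = unname(se),
             ci_low = unname(beta - 1.96 * se),
             ci_high = unname(beta + 1.96 * se),
             model = model, converged = converged, stringsAsFactors = FALSE)
}

fit_glmer_pair <- function(formula_full, formula_red, data, family, nAGQ) {
  converged <- TRUE
  handler <- function(w) {
    converged <<- FALSE
    invokeRestart("muffleWarning")
  }
  if (identical(family, "binomial")) {
    full <- withCallingHandlers(
      lme4::glmer(formula_full, data = data, family = stats::binomial(),
                  nAGQ = nAGQ), warning = handler)
    red <- suppressWarnings(
      lme4::glmer(formula_red, data = data, family = stats::binomial(),
                  nAGQ = nAGQ))
  } else {
    full <- withCallingHandlers(
      lme4::lmer(formula_full, data = data, REML = FALSE), warning = handler)
    red <- suppressWarnings(
      lme4::lmer(formula_red, data = data, REML = FALSE))
  }
  list(full = full, red = red, converged = converged)
}

#' Brain-behavior mixed models with Holm correction
#'
#' For each network measure, fits the trial-level models of in-scanner
#' performance: a binomial mixed model of accuracy and a linear mixed model
#' of log response time (correct fluency trials only), both with fixed
#' effects measure, age, their interaction, mean FD and education (measure,
#' FD and education mean-centered; categorical predictors sum-coded) and
#' random intercepts for subject and semantic category. The measure x age
#' interaction is tested by a likelihood-ratio test, and p-values are
#' Holm-adjusted across measures within each response family.
#'
#' @param behavior trial table with columns subject, group, task, category,
#'   difficulty, accuracy, rt, education, mean_fd (see
#'   \code{\link{simulate_behavior}})
#' @param measures named list (or data frame) of per-subject measure vectors,
#'   each named by subject id
#' @param responses which response families to fit
#' @param nAGQ integration points for the binomial fits (0 = fastest,
#'   penalized quasi-likelihood-style; 1 = Laplace)
#' @return data frame: response, measure, chisq, df, p, p_holm, estimate
#'   (interaction coefficient; odds ratio for accuracy), ci_low, ci_high,
#'   converged
#' @export
behavior_models <- function(behavior, measures,
                            responses = c("accuracy", "rt"), nAGQ = 1L) {
  need <- c("subject", "group", "task", "category", "difficulty", "accuracy",
            "rt", "education", "mean_fd")
  if (!all(need %in% names(behavior)))
    stop_("'behavior' needs columns ", paste(need, collapse = ", "))
  responses <- match.arg(responses, several.ok = TRUE)
  if (is.data.frame(measures))
    measures <- as.list(measures)
  if (is.null(names(measures)) || !length(measures))
    stop_("'measures' must be a named list of per-subject vectors")

  flu <- behavior[behavior$task == "fluency", , drop = FALSE]
  if (!nrow(flu)) stop_("no fluency trials in the behavior table")
  rt_data <- flu[flu$accuracy == 1 & is.finite(flu$rt) & flu$rt > 0, ,
                 drop = FALSE]
  if ("rt" %in% responses && !nrow(rt_data))
    stop_("no correct fluency trials; RT model undefined")
  acc_by_sub <- tapply(flu$accuracy, flu$subject, mean)
  if (any(acc_by_sub %in% c(0, 1)))
    warning("subject(s) with all-correct or all-incorrect fluency trials; ",
            "possible separability", call. = FALSE)

  prep <- function(d, meas) {
    d$measure_c <- meas[d$subject] - mean(meas[unique(d$subject)])
    # sum coding with old = +1, young = -1
    d$age <- factor(d$group, levels = c("old", "young"))
    d$fd_c <- d$mean_fd - mean(d$mean_fd)
    d$edu_c <- d$education - mean(d$education)
    d$subject <- factor(d$subject)
    d$category <- factor(d$category)
    d
  }

  rows <- list()
  for (resp in responses) {
    for (mn in names(measures)) {
      meas <- measures[[mn]]
      res <- with_sum_contrasts({
        if (resp == "accuracy") {
          d <- prep(flu, meas)
          fits <- fit_glmer_pair(
            accuracy ~ measure_c * age + fd_c + edu_c +
              (1 | subject) + (1 | category),
            accuracy ~ measure_c + age + fd_c + edu_c +
              (1 | subject) + (1 | category),
            d, "binomial", nAGQ)
        } else {
          d <- prep(rt_data, meas)
          d$log_rt <- log(d$rt)
          fits <- fit_glmer_pair(
            log_rt ~ measure_c * age + fd_c + edu_c +
              (1 | subject) + (1 | category),
            log_rt ~ measure_c + age + fd_c + edu_c +
              (1 | subject) + (1 | category),
            d, "gaussian", nAGQ)
        }
        lrt <- lrt_compare(fits$full, fits$red)
        fe <- lme4::fixef(fits$full)
        k <- length(fe)  # interaction is the last coefficient
        se <- sqrt(diag(as.matrix(stats::vcov(fits$full))))[k]
        est <- unname(fe[k]); lo <- est - 1.96 * se; hi <- est + 1.96 * se
        if (resp == "accuracy") {
          est <- exp(est); lo <- exp(lo); hi <- exp(hi)  # odds ratio
        }
        data.frame(response = resp, measure = mn, chisq = lrt$chisq,
                   df = lrt$df, p = lrt$p, p_holm = NA_real_, estimate = est,
                   ci_low = lo, ci_high = hi, converged = fits$converged,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  for (resp in unique(out$response)) {
    sel <- out$response == resp
    out$p_holm[sel] <- stats::p.adjust(out$p[sel], method = "holm")
  }
  rownames(out) <- NULL
  out
}

#' Bonferroni-Holm step-down adjustment
#'
#' Thin wrapper around \code{p.adjust(..., method = "holm")}, kept as the
#' package's single point of multiple-comparison correction.
#'
#' @param p raw p-values
#' @return adjusted p-values (monotone, never below the raw values)
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
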