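#' Stratify subjects by top score quantile
#'
#' Splits subjects into "high" (score at or above the `1 - q` quantile,
#' linear-interpolation quantile, ties going high) and "low" groups --
#' e.g. `q = 0.25` marks the top 25% of scores as high.
#'
#' @param scores per-subject numeric scores, optionally named by
#'   subject id.
#' @param q fraction of subjects in the high group (0 < q < 1).
#' @return list: `group` (character "high"/"low", named like `scores`),
#'   `threshold`, `rule` (human-readable description).
#' @export
stratify_top_quantile <- function(scores, q = 0.25) {
  if (length(scores) < 4L) stop("need at least 4 subjects to stratify")
  if (q <= 0 || q >= 1) stop("'q' must be strictly between 0 and 1")
  if (anyNA(scores)) stop("scores must not contain NA")
  if (min(scores) == max(scores))
    stop("all scores are equal; no stratification possible")
  thr <- unname(stats::quantile(scores, probs = 1 - q, type = 7))
  group <- ifelse(scores >= thr, "high", "low")
  names(group) <- names(scores)
  list(group = group, threshold = thr,
       rule = sprintf("high = score >= %.6g (top %.0f%% by linear-interpolation quantile, ties high)",
                      thr, 100 * q))
}

.check_surv <- function(surv) {
  need <- c("time_days", "event")
  if (!all(need %in% colnames(surv)))
    stop("survival table needs columns ", paste(need, collapse = ", "))
  if (any(surv$time_days < 0)) stop("survival times must be non-negative")
  invisible(surv)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per group; censored subjects leave the risk
#' set after their censoring time. The curve starts at 1 and is
#' non-increasing; with no events it stays identically 1.
#'
#' @param surv data.frame with columns `time_days`, `event` (logical or
#'   0/1; TRUE = death).
#' @param group optional per-subject group labels; `NULL` fits a single
#'   curve.
#' @return data.frame: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, one row per distinct observed time.
#' @export
kaplan_meier <- function(surv, group = NULL) {
  .check_surv(surv)
  if (is.null(group)) group <- rep("all", nrow(surv))
  if (length(group) != nrow(surv))
    stop("'group' must have one entry per subject")
  fit <- survival::survfit(
    survival::Surv(surv$time_days, as.integer(surv$event)) ~ grp,
    data = data.frame(grp = group))
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group), length(s$time))
         else sub("^grp=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor,
             survival = s$surv, stringsAsFactors = FALSE)
}

#' Log-rank test with O/E hazard ratio
#'
#' Mantel-Haenszel log-rank test between two groups with the hazard
#' ratio reported as the observed/expected ratio
#' \eqn{HR = (O_1/E_1)/(O_2/E_2)} (the convention of KM-figure
#' software), with a log-scale confidence interval
#' \eqn{\exp(\log HR \pm z \sqrt{1/E_1 + 1/E_2})} and p-value from the
#' chi-squared(1) statistic.
#'
#' @param surv data.frame with `time_days`, `event`.
#' @param group per-subject labels with exactly two levels.
#' @param numerator which group forms the HR numerator (default
#'   `"high"` when present, else the first sorted level).
#' @param conf_level confidence level of the HR interval.
#' @return list: `chisq`, `p`, `hr`, `ci_low`, `ci_high`, `observed`,
#'   `expected` (both named by group).
#' @export
logrank_test_hr <- function(surv, group, numerator = NULL,
                            conf_level = 0.95) {
  .check_surv(surv)
  levels <- sort(unique(as.character(group)))
  if (length(levels) != 2L) stop("'group' must have exactly two levels")
  if (any(table(group) == 0L)) stop("both groups must be non-empty")
  if (sum(surv$event) < 1L) stop("need at least one event")
  if (is.null(numerator))
    numerator <- if ("high" %in% levels) "high" else levels[1]
  if (!numerator %in% levels) stop("'numerator' must be a group level")
  sd <- survival::survdiff(
    survival::Surv(surv$time_days, as.integer(surv$event)) ~ grp,
    data = data.frame(grp = group))
  obs <- sd$obs; expd <- sd$exp
  names(obs) <- names(expd) <- sub("^grp=", "", names(sd$n))
  denom <- setdiff(levels, numerator)
  hr <- (obs[numerator] / expd[numerator]) / (obs[denom] / expd[denom])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(1 / expd[numerator] + 1 / expd[denom])
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p = unname(p), hr = unname(hr),
       ci_low = unname(hr * exp(-z * se_log)),
       ci_high = unname(hr * exp(z * se_log)),
       observed = obs, expected = expd)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Breslow tie handling by default) of the
#' named covariates, reporting per-covariate coefficients, Wald
#' hazard ratios with confidence intervals and p-values. Non-converged
#' fits and separated covariates (coefficients running to infinity)
#' raise errors instead of returning unstable estimates.
#'
#' @param surv data.frame with `time_days`, `event` and the covariate
#'   columns (binary covariates coded 0/1).
#' @param covariates character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level confidence level for the intervals.
#' @return data.frame: `term`, `coef`, `hr`, `ci_low`, `ci_high`, `se`,
#'   `p`.
#' @export
cox_fit <- function(surv, covariates, ties = c("breslow", "efron"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  .check_surv(surv)
  missing <- setdiff(covariates, colnames(surv))
  if (length(missing))
    stop("covariates absent from table: ", paste(missing, collapse = ", "))
  if (sum(surv$event) < 10L)
    stop("need at least 10 events for a stable Cox fit")
  X <- as.matrix(surv[covariates])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("covariates are collinear")
  f <- stats::as.formula(paste("survival::Surv(time_days, as.integer(event)) ~",
                               paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(f, data = surv, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)) > 15))
    stop("separation detected: a covariate perfectly orders the events")
  s <- summary(fit, conf.int = conf_level)
  data.frame(term = rownames(s$coefficients),
             coef = s$coefficients[, "coef"],
             hr = s$coefficients[, "exp(coef)"],
             ci_low = s$conf.int[, 3],
             ci_high = s$conf.int[, 4],
             se = s$coefficients[, "se(coef)"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
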