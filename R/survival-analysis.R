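#' Kaplan-Meier survival curves
#'
#' Product-limit estimates per group via the `survival` package. Censored
#' times reduce the at-risk count without introducing steps.
#'
#' @param times follow-up times (>= 0)
#' @param events event indicators (1 = observed)
#' @param groups optional group labels (one curve per level; a single
#'   curve if omitted)
#' @return named list of `km_estimate` data.frames with columns `time`
#'   (event times, ascending), `n_risk`, `n_event`, `survival`
#' @export
km_curve <- function(times, events, groups = NULL) {
  if (any(times < 0)) stopf("times must be >= 0")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- as.character(groups)
  out <- lapply(split(seq_along(times), groups), function(idx) {
    if (!length(idx)) stopf("empty group")
    sf <- survival::survfit(survival::Surv(times[idx], events[idx]) ~ 1)
    keep <- sf$n.event > 0
    est <- data.frame(time = sf$time[keep], n_risk = sf$n.risk[keep],
                      n_event = sf$n.event[keep], survival = sf$surv[keep])
    class(est) <- c("km_estimate", "data.frame")
    est
  })
  out
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic on the pooled
#' event-time risk table (via `survival::survdiff`). With no events at
#' all, the statistic is 0 and p = 1 by convention.
#'
#' @param times follow-up times
#' @param events event indicators (1 = observed)
#' @param groups two-level group labels
#' @return list: statistic (chi-square, 1 df), p_value
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stopf("exactly two non-empty groups required")
  if (sum(events) == 0) return(list(statistic = 0, p_value = 1))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chisq <- sd$chisq
  list(statistic = chisq, p_value = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Median-split survival screen of one feature
#'
#' Samples are split at the feature's median (ties go to the low group:
#' high = strictly above the median) and the two groups are compared by
#' log-rank test.
#'
#' @param values named numeric vector (names = sample ids)
#' @param survival a [survival_table()] covering those samples
#' @return list: groups (named "high"/"low" per sample), statistic, p_value
#' @export
median_split_screen <- function(values, survival) {
  if (length(unique(values)) < 2L) stopf("feature is constant; cannot median-split")
  med <- stats::median(values)
  grp <- ifelse(values > med, "high", "low")
  if (length(unique(grp)) < 2L) stopf("median split produced a single group")
  idx <- match(names(values), survival$sample_id)
  if (anyNA(idx)) stopf("survival table does not cover all samples")
  lr <- logrank_test(survival$os_days[idx], survival$event[idx], grp)
  list(groups = grp, statistic = lr$statistic, p_value = lr$p_value)
}

#' Cox proportional-hazards screen of clinical covariates
#'
#' Fits Cox PH models (Efron tie handling) for the requested covariates,
#' either one model per covariate (`univariate`) or a single joint model
#' (`multivariate`). Factor covariates contribute one row per non-reference
#' level. Covariates whose fit fails or whose standard error is not finite
#' are flagged unestimable instead of crashing.
#'
#' @param survival a [survival_table()] with clinical covariate columns
#' @param covariates covariate column names (default: all non-core columns)
#' @param mode "univariate" or "multivariate"
#' @param p_max risk-factor flag threshold, default 0.05
#' @return data.frame: covariate, term, hazard_ratio, ci_lower, ci_upper,
#'   p_value, risk_factor, estimable
#' @export
cox_screen <- function(survival, covariates = NULL,
                       mode = c("univariate", "multivariate"), p_max = 0.05) {
  mode <- match.arg(mode)
  core <- c("sample_id", "os_days", "event")
  covariates <- covariates %||% setdiff(names(survival), core)
  if (sum(survival$event) < 2L) stopf("need >= 2 events")
  surv_obj <- survival::Surv(survival$os_days, survival$event)
  fit_one <- function(fml, data, cov_of_term) {
    fit <- tryCatch(
      survival::coxph(fml, data = data, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(fml, data = data, ties = "efron"))
      })
    if (is.null(fit)) return(NULL)
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    data.frame(covariate = cov_of_term(rownames(co)),
               term = rownames(co),
               hazard_ratio = unname(co[, "exp(coef)"]),
               ci_lower = unname(ci[, "lower .95"]),
               ci_upper = unname(ci[, "upper .95"]),
               p_value = unname(co[, "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  }
  unestimable_row <- function(cov) data.frame(
    covariate = cov, term = cov, hazard_ratio = NA_real_, ci_lower = NA_real_,
    ci_upper = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
  rows <- list()
  if (mode == "univariate") {
    for (cov in covariates) {
      x <- survival[[cov]]
      if (length(unique(x[!is.na(x)])) < 2L) {
        rows[[cov]] <- unestimable_row(cov)
        next
      }
      d <- data.frame(surv_obj = surv_obj, x = x)
      r <- fit_one(surv_obj ~ x, d, function(tm) rep(cov, length(tm)))
      rows[[cov]] <- if (is.null(r)) unestimable_row(cov) else {
        r$term <- sub("^x", cov, r$term)
        r
      }
    }
  } else {
    usable <- covariates[vapply(covariates, function(cv)
      length(unique(survival[[cv]][!is.na(survival[[cv]])])) >= 2L, logical(1L))]
    for (cv in setdiff(covariates, usable)) rows[[cv]] <- unestimable_row(cv)
    if (length(usable)) {
      d <- survival[, usable, drop = FALSE]
      d$surv_obj <- surv_obj
      fml <- stats::as.formula(paste("surv_obj ~", paste(usable, collapse = " + ")))
      cov_of_term <- function(tm) {
        vapply(tm, function(t1) usable[which.max(nchar(usable) * startsWith(t1, usable))],
               character(1L))
      }
      r <- fit_one(fml, d, cov_of_term)
      if (is.null(r)) {
        for (cv in usable) rows[[cv]] <- unestimable_row(cv)
      } else rows[["joint"]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$estimable <- is.finite(out$hazard_ratio) &
    is.finite(out$ci_lower) & is.finite(out$ci_upper)
  out$risk_factor <- out$estimable & !is.na(out$p_value) & out$p_value < p_max
  out
}

#' Stratified biomarker survival screen
#'
#' Splits the cohort by a clinical stratifier and, within each stratum,
#' median-splits every requested biomarker and reports the log-rank
#' p-value. Strata with fewer than `min_stratum` samples are skipped with
#' a warning; an empty stratifier level is an error.
#'
#' @param profile samples-by-features matrix covering the biomarkers
#' @param survival a [survival_table()]
#' @param stratifier name of a covariate column, or a vector/factor of
#'   stratum labels aligned with `survival`
#' @param prb_features biomarker feature ids to screen
#' @param p_max significance threshold, default 0.05
#' @param min_stratum minimum stratum size, default 4
#' @return data.frame: stratum, feature, p_value, significant
#' @export
stratified_prb_screen <- function(profile, survival, stratifier, prb_features,
                                  p_max = 0.05, min_stratum = 4L) {
  strat <- if (is.character(stratifier) && length(stratifier) == 1L) {
    if (!stratifier %in% names(survival)) stopf("no covariate column '%s'", stratifier)
    survival[[stratifier]]
  } else stratifier
  if (!is.factor(strat)) strat <- factor(strat)
  if (any(table(strat) == 0L) || nlevels(strat) < 2L)
    stopf("stratifier must partition samples into >= 2 non-empty strata")
  rows <- list()
  for (lev in levels(strat)) {
    ids <- survival$sample_id[strat == lev]
    ids <- intersect(rownames(profile), ids)
    if (length(ids) < min_stratum) {
      warnf("stratum '%s' has %d sample(s) (< %d); skipped", lev, length(ids), min_stratum)
      next
    }
    sv <- survival[match(ids, survival$sample_id), , drop = FALSE]
    for (f in prb_features) {
      p <- tryCatch(
        median_split_screen(stats::setNames(profile[ids, f], ids), sv)$p_value,
        error = function(e) NA_real_)
      rows[[paste(lev, f)]] <- data.frame(stratum = lev, feature = f,
                                          p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- !is.na(out$p_value) & out$p_value < p_max
  out
}
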