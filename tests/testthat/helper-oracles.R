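# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle re-derives its quantity from first principles and
# never calls the implementation it checks.

labels_df <- function(ids, labs) {
  out <- data.frame(sample_id = ids,
                    label = factor(labs, levels = c("positive", "negative", "excluded")),
                    stringsAsFactors = FALSE)
  class(out) <- c("prognosis_labels", "data.frame")
  out
}

surv_df <- function(ids, os, event) {
  survival_table(data.frame(sample_id = ids, os_days = os, event = event,
                            stringsAsFactors = FALSE))
}

# AUC as the probability a random positive outscores a random negative,
# by exhaustive pair counting with ties worth one half.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Kaplan-Meier by explicit product over risk sets.
km_oracle <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# One-df log-rank by manual hypergeometric risk-table arithmetic.
logrank_oracle <- function(times, events, g) {
  g <- as.character(g)
  ga <- sort(unique(g))[1L]
  ts <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t1 in ts) {
    at <- times >= t1
    n <- sum(at)
    nA <- sum(at & g == ga)
    d <- sum(times == t1 & events == 1)
    O <- O + sum(times == t1 & events == 1 & g == ga)
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(statistic = chi, p_value = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Hand-built logistic MPA model with identity standardization.
lr_model <- function(features, coef, intercept = 0) {
  structure(list(method = "LR", features = features,
                 fit = list(coefficients = c(`(Intercept)` = intercept,
                                             stats::setNames(coef, features))),
                 center = stats::setNames(rep(0, length(features)), features),
                 scale = stats::setNames(rep(1, length(features)), features),
                 seed = 1L),
            class = "mpa_model")
}

# Screening -> per-layer essential features, as run by the pipeline.
essential_by_omics <- function(co, labels) {
  lapply(co$omics, function(m) {
    sel <- select_differential(welch_t_screen(m, labels))
    feats <- sel$feature_id
    if (length(feats) < 2L) return(feats)
    sub <- m$values[feats, , drop = FALSE]
    fm <- fit_efa(sub, choose_n_factors(sub), omics_type = m$omics_type)
    select_essential(normalize_weights(fm))
  })
}

profile_for <- function(co, features) {
  rows <- do.call(rbind, lapply(co$omics, function(m)
    m$values[intersect(rownames(m$values), features), , drop = FALSE]))
  t(rows[features, , drop = FALSE])
}

# Train an LR model on one omics combination and return its AUC on a
# shared test set. The split is computed once on the full essential
# profile (one testing set reused across all combinations); each
# combination refits on its own feature subset.
combo_auc <- function(co, labels, essential, combo, seed, split = NULL) {
  feats <- unique(unlist(essential[combo], use.names = FALSE))
  prof <- profile_for(co, feats)
  sp <- split %||% diverse_subset_split(prof, labels, seed = seed)
  fit <- train_mpa(prof[sp$train, , drop = FALSE], labels, method = "LR", seed = seed)
  pred <- predict_scores(fit, prof[sp$test, , drop = FALSE])
  lab <- labels$label[match(sp$test, labels$sample_id)]
  roc_auc(pred$score, as.character(lab))$auc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
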