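#' Enumerate omics combinations
#'
#' All non-empty subsets of the available omics layers, ordered by size and
#' then lexicographically; four layers give the pipeline's 15 model
#' combinations.
#'
#' @param omics character vector of available omics types
#' @return list of character vectors (each sorted)
#' @export
enumerate_combinations <- function(omics) {
  omics <- sort(unique(omics))
  if (!length(omics)) stopf("need at least one omics type")
  out <- list()
  for (s in seq_along(omics)) {
    cmb <- utils::combn(omics, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Diverse Subset train/test split
#'
#' Greedy farthest-point sampling run independently within the positive and
#' the negative class on z-scored features with Euclidean distance: a
#' seeded-random first pick, then the sample farthest from it, then
#' repeatedly the sample with the largest mean distance to the selected
#' set, until `ceil(train_fraction x class size)` samples are in the
#' training set. Ties break by sample order. Deterministic given the seed.
#'
#' @param profile samples-by-features numeric matrix (rownames = sample ids)
#' @param labels a `prognosis_labels` data.frame (positive/negative used)
#' @param train_fraction fraction of each class placed in the training set
#' @param seed RNG seed for the first pick of each class
#' @return list of class `split_result`: `train`, `test` (sample ids),
#'   `seed`
#' @export
diverse_subset_split <- function(profile, labels, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(is.matrix(profile), !is.null(rownames(profile)))
  Z <- scale(profile)
  Z[!is.finite(Z)] <- 0
  set.seed(seed)
  train <- character(0)
  test <- character(0)
  for (cls in c("positive", "negative")) {
    ids <- rownames(profile)[rownames(profile) %in% labelled_ids(labels, cls)]
    m <- length(ids)
    if (m < 2L) stopf("class '%s' has %d sample(s); need >= 2", cls, m)
    D <- as.matrix(stats::dist(Z[ids, , drop = FALSE]))
    k <- ceiling(train_fraction * m)
    sel <- sample.int(m, 1L)
    while (length(sel) < k) {
      rest <- setdiff(seq_len(m), sel)
      md <- colMeans(D[sel, rest, drop = FALSE])
      sel <- c(sel, rest[which.max(md)])
    }
    train <- c(train, ids[sel])
    test <- c(test, ids[setdiff(seq_len(m), sel)])
  }
  structure(list(train = train, test = test, seed = seed), class = "split_result")
}

MPA_METHODS <- c("LR", "SVM", "NB", "NN", "RF", "LiR")

# L2-penalized logistic regression by iteratively reweighted least squares.
# The intercept is unpenalized; lambda = 1 on the summed log-loss matches
# the common C = 1 convention. Penalization keeps the fit well-defined on
# linearly separable training sets, where the unpenalized MLE diverges.
ridge_logistic <- function(X, y, lambda = 1, maxit = 100L, tol = 1e-10) {
  D <- cbind(`(Intercept)` = 1, X)
  p <- ncol(D)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(drop(D %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(D, y - mu)) - drop(pen %*% beta)
    H <- crossprod(D * w, D) + pen
    step <- drop(solve(H, grad))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coefficients = stats::setNames(beta, colnames(D)))
}

#' Train a multi-omics prognostic (MPA) classifier
#'
#' Fits a binary prognosis classifier on an essential-feature profile.
#' Features are z-scored with training-set statistics only (the constants
#' are stored on the model and reused at prediction time, so no test-set
#' leakage is possible). Stochastic learners (SVM probability model, NN,
#' RF) are seeded.
#'
#' Methods: `LR` L2-penalized logistic regression (IRLS, unpenalized
#' intercept, penalty 1 on the summed log-loss), `SVM` RBF support
#' vector machine with probability outputs (`e1071`), `NB` Gaussian naive
#' Bayes (`e1071`), `NN` single-hidden-layer neural network (`nnet`), `RF`
#' random forest with 100 trees (`randomForest`), `LiR` ordinary least
#' squares on the 0/1 label with scores clipped to \[0,1\].
#'
#' @param profile training samples-by-features matrix (rownames = ids)
#' @param labels a `prognosis_labels` data.frame; only samples labelled
#'   positive or negative and present in `profile` are used
#' @param method one of `"LR"`, `"SVM"`, `"NB"`, `"NN"`, `"RF"`, `"LiR"`
#' @param seed RNG seed for stochastic learners
#' @param nn_size hidden units for `NN` (default 100)
#' @return object of class `mpa_model`
#' @export
train_mpa <- function(profile, labels, method = "LR", seed = 1L, nn_size = 100L) {
  method <- match.arg(method, MPA_METHODS)
  ids <- rownames(profile)
  y <- rep(NA, length(ids))
  y[ids %in% labelled_ids(labels, "positive")] <- 1
  y[ids %in% labelled_ids(labels, "negative")] <- 0
  keep <- !is.na(y)
  X <- profile[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2L) stopf("training set contains a single class")
  zs <- zscore_train(X)
  Z <- zscore_apply(X, zs)
  set.seed(seed)
  fit <- switch(method,
    LR = ridge_logistic(Z, y),
    SVM = e1071::svm(x = Z, y = factor(y, levels = c(0, 1)), probability = TRUE),
    NB = e1071::naiveBayes(x = as.data.frame(Z), y = factor(y, levels = c(0, 1))),
    NN = nnet::nnet(Z, y, size = nn_size, entropy = TRUE, maxit = 200,
                    trace = FALSE, MaxNWts = 100000L, decay = 1e-3),
    RF = randomForest::randomForest(x = Z, y = factor(y, levels = c(0, 1)),
                                    ntree = 100L),
    LiR = stats::lm.fit(cbind(`(Intercept)` = 1, Z), y))
  structure(list(method = method, features = colnames(profile),
                 fit = fit, center = zs$center, scale = zs$scale,
                 seed = seed),
            class = "mpa_model")
}

#' @export
print.mpa_model <- function(x, ...) {
  cat(sprintf("<mpa_model> %s on %d features\n", x$method, length(x$features)))
  invisible(x)
}

#' Predict prognosis scores from an MPA model
#'
#' Returns a probability-like score in \[0,1\] per sample (high = good
#' prognosis / positive class) and the class at the 0.5 threshold. The
#' profile is standardized with the model's stored training constants.
#'
#' @param model an [train_mpa()] model
#' @param profile samples-by-features matrix covering the model's features
#' @return data.frame: sample_id, score, class ("positive"/"negative")
#' @export
predict_scores <- function(model, profile) {
  miss <- setdiff(model$features, colnames(profile))
  if (length(miss)) stopf("profile is missing model feature(s): %s",
                          paste(utils::head(miss, 5L), collapse = ", "))
  X <- profile[, model$features, drop = FALSE]
  Z <- zscore_apply(X, list(center = model$center, scale = model$scale))
  lincoef <- function(co) { co[is.na(co)] <- 0; co }  # collinear columns drop to 0
  score <- switch(model$method,
    LR = {
      eta <- drop(cbind(1, Z) %*% lincoef(model$fit$coefficients))
      stats::plogis(eta)
    },
    SVM = {
      pr <- attr(stats::predict(model$fit, Z, probability = TRUE), "probabilities")
      pr[, "1"]
    },
    NB = stats::predict(model$fit, as.data.frame(Z), type = "raw")[, "1"],
    NN = drop(stats::predict(model$fit, Z)),
    RF = stats::predict(model$fit, Z, type = "prob")[, "1"],
    LiR = pmin(1, pmax(0, drop(cbind(1, Z) %*% lincoef(model$fit$coefficients)))))
  data.frame(sample_id = rownames(profile), score = unname(score),
             class = ifelse(score > 0.5, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC
#'
#' Threshold-sweep ROC via `pROC` with the positive class scoring high;
#' the AUC equals the Mann-Whitney pair-count probability that a random
#' positive outscores a random negative, ties counting one half.
#'
#' @param scores numeric scores
#' @param labels character/factor with values "positive"/"negative"
#' @return list of class `roc_result`: thresholds, sensitivities,
#'   specificities, auc
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(unique(labels[labels %in% c("positive", "negative")])) < 2L)
    stopf("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  structure(list(thresholds = r$thresholds,
                 sensitivities = r$sensitivities,
                 specificities = r$specificities,
                 auc = as.numeric(r$auc)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}
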