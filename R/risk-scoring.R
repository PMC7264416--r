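#' Fit the linear prognosis risk score (PRS)
#'
#' Ordinary least squares of the 0/1 prognosis label (positive = 1) on the
#' biomarker feature values, matching the pipeline's use of linear
#' regression for the final risk score. Feature values are standardized
#' before fitting and the constants stored on the model, so coefficients
#' are on a comparable scale.
#'
#' @param profile samples-by-features matrix restricted to the biomarker
#'   (PRB) features
#' @param labels a `prognosis_labels` data.frame
#' @param standardize standardize features before fitting (default TRUE)
#' @return object of class `prs_model`: features, coefficients, intercept,
#'   threshold (NA until [choose_threshold()] is applied), center, scale
#' @export
fit_prs <- function(profile, labels, standardize = TRUE) {
  ids <- rownames(profile)
  y <- rep(NA_real_, length(ids))
  y[ids %in% labelled_ids(labels, "positive")] <- 1
  y[ids %in% labelled_ids(labels, "negative")] <- 0
  keep <- !is.na(y)
  X <- profile[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2L) stopf("both prognosis classes must be present")
  if (standardize) {
    zs <- zscore_train(X)
    Xf <- zscore_apply(X, zs)
  } else {
    zs <- list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
    Xf <- X
  }
  D <- cbind(`(Intercept)` = 1, Xf)
  if (qr(D)$rank < ncol(D)) stopf("rank-deficient design: collinear or constant feature(s)")
  fit <- stats::lm.fit(D, y)
  co <- fit$coefficients
  prs_model(features = colnames(profile), coefficients = unname(co[-1L]),
            intercept = unname(co[1L]), center = zs$center, scale = zs$scale)
}

#' Construct a PRS model from explicit coefficients
#'
#' @param features ordered feature names
#' @param coefficients one coefficient per feature
#' @param intercept model intercept
#' @param threshold decision threshold (optional)
#' @param center,scale per-feature standardization constants applied before
#'   scoring (defaults: none)
#' @return object of class `prs_model`
#' @export
prs_model <- function(features, coefficients, intercept, threshold = NA_real_,
                      center = NULL, scale = NULL) {
  if (length(features) != length(coefficients))
    stopf("coefficient count (%d) must equal feature count (%d)",
          length(coefficients), length(features))
  structure(list(features = features,
                 coefficients = stats::setNames(coefficients, features),
                 intercept = intercept, threshold = threshold,
                 center = stats::setNames(center %||% rep(0, length(features)), features),
                 scale = stats::setNames(scale %||% rep(1, length(features)), features)),
            class = "prs_model")
}

#' The published 13-biomarker PRS
#'
#' The colon-adenocarcinoma prognosis risk score over the 13 prognosis
#' risk biomarkers (EPB41, PSMA1, FGFR3, MRAS, LEP, C7orf46, LOC285000,
#' LBP, ZNF35, SLC30A3, LECT2, RNF7, DYNC1I1), with its printed
#' coefficients, intercept 0.325 and decision threshold 0.254. Scores are
#' computed directly on the supplied feature values (no standardization
#' constants are published).
#'
#' @return a [prs_model()]
#' @export
published_prs <- function() {
  prs_model(
    features = c("EPB41", "PSMA1", "FGFR3", "MRAS", "LEP", "C7orf46",
                 "LOC285000", "LBP", "ZNF35", "SLC30A3", "LECT2", "RNF7",
                 "DYNC1I1"),
    coefficients = c(-1.021, -0.364, -0.046, -0.113, -0.013, -0.219,
                     -0.379, -0.085, -0.539, -0.150, -0.057, -0.404, -0.143),
    intercept = 0.325, threshold = 0.254)
}

#' Score samples with a PRS model
#'
#' `intercept + sum(coefficient * standardized value)` per sample.
#'
#' @param model a [prs_model()]
#' @param x named numeric vector (one sample) or samples-by-features matrix
#' @return numeric vector of scores
#' @export
score_prs <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) stopf("missing feature(s): %s", paste(miss, collapse = ", "))
  X <- x[, model$features, drop = FALSE]
  Z <- zscore_apply(X, list(center = model$center, scale = model$scale))
  drop(model$intercept + Z %*% model$coefficients)
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> %d features, intercept %.3f, threshold %s\n",
              length(x$features), x$intercept,
              if (is.na(x$threshold)) "unset" else format(x$threshold)))
  invisible(x)
}

#' Choose a decision threshold by Youden's J
#'
#' Maximizes J = sensitivity + specificity - 1 over the midpoints of the
#' sorted unique scores (a sample is called positive when its score is
#' strictly above the threshold). Ties resolve to the lowest optimal
#' threshold. With only one distinct score, J = 0.
#'
#' @param scores numeric scores (higher = more positive)
#' @param labels values "positive"/"negative"
#' @return list: threshold, sensitivity, specificity, youden_j
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  if (!length(pos) || !length(neg)) stopf("both classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) >= 2L) (u[-length(u)] + u[-1L]) / 2 else u
  sens <- vapply(cand, function(t) mean(pos > t), numeric(1L))
  spec <- vapply(cand, function(t) mean(neg <= t), numeric(1L))
  j <- sens + spec - 1
  best <- which(j == max(j))[1L]   # candidates ascend, so first max = lowest threshold
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden_j = j[best])
}
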