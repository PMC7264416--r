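#' Choose the number of factors by the Kaiser criterion
#'
#' Number of eigenvalues of the feature correlation matrix strictly greater
#' than 1, floored at 1. Constant features are dropped with a warning
#' before the eigendecomposition.
#'
#' @param matrix an [omics_matrix()] or plain features-by-samples matrix
#'   (typically the differential-feature submatrix)
#' @return positive integer factor count
#' @export
choose_n_factors <- function(matrix) {
  v <- if (inherits(matrix, "omics_matrix")) matrix$values else matrix
  v <- drop_constant_features(v)
  if (nrow(v) < 2L) stopf("need >= 2 non-constant features")
  R <- stats::cor(t(v))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  max(1L, sum(ev > 1))
}

drop_constant_features <- function(v) {
  sds <- apply(v, 1L, stats::sd)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warnf("dropping %d constant feature(s) before factor analysis: %s",
          sum(const), paste(utils::head(rownames(v)[const], 5L), collapse = ", "))
    v <- v[!const, , drop = FALSE]
  }
  v
}

# Minimum-residual (minres) factor extraction: optimise the uniquenesses so
# that the rank-k eigen-approximation of the reduced correlation matrix
# minimises the off-diagonal residual sum of squares. Deterministic start
# from squared multiple correlations.
efa_extract_minres <- function(R, k, maxit = 1000L) {
  p <- ncol(R)
  Rinv <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-6, p)))
  smc <- 1 - 1 / diag(Rinv)
  start <- pmin(pmax(1 - smc, 0.005), 1)
  loadings_for <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), nrow = k)
  }
  obj <- function(psi) {
    L <- loadings_for(psi)
    res <- R - L %*% t(L)
    diag(res) <- 0
    sum(res^2)
  }
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = 0.005, upper = 1,
                      control = list(maxit = maxit))
  if (fit$convergence != 0)
    stopf("minres extraction failed to converge (%d function evaluations): %s",
          fit$counts[[1L]], fit$message %||% "")
  L <- loadings_for(fit$par)
  # sign convention: largest-magnitude loading per factor positive
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Fit an exploratory factor model to one omics layer
#'
#' Minres extraction on the feature correlation matrix, varimax rotation
#' (skipped for a single factor), and Thurstone regression-method factor
#' scores. Deterministic: uniquenesses start from squared multiple
#' correlations and the optimiser is L-BFGS-B.
#'
#' @param matrix an [omics_matrix()] or features-by-samples matrix holding
#'   the differential features of one layer
#' @param n_factors number of factors (see [choose_n_factors()])
#' @param omics_type optional tag recorded on the model
#' @return object of class `factor_model`: `weights` (feature x factor
#'   loadings), `scores` (sample x factor), `n_factors`, `rotation`,
#'   `omics_type`.
#' @export
fit_efa <- function(matrix, n_factors, omics_type = NULL) {
  v <- if (inherits(matrix, "omics_matrix")) matrix$values else matrix
  if (is.null(omics_type) && inherits(matrix, "omics_matrix"))
    omics_type <- matrix$omics_type
  v <- drop_constant_features(v)
  p <- nrow(v); n <- ncol(v)
  if (p < 2L) stopf("need >= 2 non-constant features")
  if (n_factors < 1L || n_factors > min(p, n))
    stopf("n_factors must lie in [1, min(n_features, n_samples)]")
  X <- t(v)                      # samples x features
  R <- stats::cor(X)
  L <- efa_extract_minres(R, n_factors)
  rotation <- "none"
  if (n_factors >= 2L) {
    rot <- stats::varimax(L, normalize = FALSE)
    L <- unclass(rot$loadings)
    rotation <- "varimax"
  }
  dimnames(L) <- list(rownames(v), paste0("F", seq_len(n_factors)))
  Z <- scale(X)
  Z[!is.finite(Z)] <- 0
  Rinv <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-6, p)))
  S <- Z %*% Rinv %*% L          # regression-method scores
  dimnames(S) <- list(colnames(v), colnames(L))
  structure(list(omics_type = omics_type, n_factors = n_factors,
                 weights = L, scores = S, rotation = rotation),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %s: %d features, %d factors (%s)\n",
              x$omics_type %||% "?", nrow(x$weights), x$n_factors, x$rotation))
  invisible(x)
}

#' Normalize a factor weight (loading) matrix to \[0,1\]
#'
#' Loadings are taken in absolute value (weight as importance, not
#' direction) and min-max scaled column-wise. A constant column maps to
#' 0.5 everywhere, with a warning.
#'
#' @param weights feature-by-factor loading matrix (or a `factor_model`)
#' @return matrix of the same shape with values in \[0,1\]
#' @export
normalize_weights <- function(weights) {
  if (inherits(weights, "factor_model")) weights <- weights$weights
  W <- abs(weights)
  for (j in seq_len(ncol(W))) {
    rng <- range(W[, j])
    if (diff(rng) == 0) {
      warnf("constant weight column %d: normalized to 0.5", j)
      W[, j] <- 0.5
    } else {
      W[, j] <- (W[, j] - rng[1L]) / diff(rng)
    }
  }
  W
}

#' Select the essential feature per factor
#'
#' For each factor column of a normalized weight matrix, the feature with
#' the maximal weight (ties broken lexicographically by feature id);
#' duplicates across factors are collapsed, preserving factor order.
#'
#' @param normalized_weights output of [normalize_weights()]
#' @return character vector of essential feature ids (length <= n factors)
#' @export
select_essential <- function(normalized_weights) {
  W <- normalized_weights
  picks <- vapply(seq_len(ncol(W)), function(j) {
    cand <- rownames(W)[W[, j] == max(W[, j])]
    sort(cand)[1L]
  }, character(1L))
  unique(picks)
}

#' Combine per-omics factor scores with log OS and cluster samples
#'
#' Column-binds the factor score matrices of the supplied models (samples
#' must be identical and ordered), appends `log10(os_days + 1)`, z-scores
#' all columns and runs average-linkage hierarchical clustering on the
#' Euclidean sample distances.
#'
#' @param models list of [fit_efa()] models sharing aligned samples
#' @param survival a [survival_table()] covering those samples
#' @return list: `matrix` (sample x (factors + log_os)), `order` (sample
#'   ids in dendrogram leaf order), `merge` (hclust merge list), `hclust`
#' @export
combine_scores <- function(models, survival) {
  sc <- lapply(models, function(m) m$scores)
  ids <- rownames(sc[[1L]])
  for (m in sc) {
    if (!identical(rownames(m), ids)) stopf("factor models do not share an aligned sample set")
  }
  for (i in seq_along(sc)) {
    colnames(sc[[i]]) <- paste0(names(models)[i] %||% paste0("m", i), ".",
                                colnames(sc[[i]]))
  }
  M <- do.call(cbind, sc)
  os <- survival$os_days[match(ids, survival$sample_id)]
  if (anyNA(os)) stopf("survival table does not cover all factor-model samples")
  M <- cbind(M, log_os = log10(os + 1))
  Z <- scale(M)
  Z[!is.finite(Z)] <- 0
  hc <- stats::hclust(stats::dist(Z), method = "average")
  list(matrix = M, order = ids[hc$order], merge = hc$merge, hclust = hc)
}
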