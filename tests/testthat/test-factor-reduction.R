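# Build a features-by-samples matrix from a loading matrix: X = L F + e.
factor_fixture <- function(loadings, n, seed) {
  set.seed(seed)
  k <- ncol(loadings)
  p <- nrow(loadings)
  F <- matrix(rnorm(n * k), k, n)
  uniq <- sqrt(pmax(1 - rowSums(loadings^2), 0))
  X <- loadings %*% F + uniq * matrix(rnorm(p * n), p, n)
  dimnames(X) <- list(paste0("f", seq_len(p)), paste0("s", seq_len(n)))
  X
}

test_that("Kaiser criterion counts eigenvalues above one, floored at one", {
  # exactly uncorrelated features (zero-sum orthogonal contrasts) ->
  # correlation = identity -> floor of 1
  X <- t(contr.helmert(8)[, 1:4])
  dimnames(X) <- list(paste0("f", 1:4), paste0("s", 1:8))
  expect_identical(choose_n_factors(X), 1L)

  # two perfectly correlated pairs, independent across pairs: ev = {2,2,0,0}
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50)
  X2 <- rbind(f1 = a, f2 = a, f3 = b, f4 = b)
  colnames(X2) <- paste0("s", 1:50)
  expect_identical(choose_n_factors(X2), 2L)

  # single pair at exact sample correlation 0.8: ev = {1.8, 0.2} -> 1
  x <- scale(rnorm(60))[, 1]
  e <- scale(residuals(lm(rnorm(60) ~ x)))[, 1]  # exactly orthogonal to x
  y <- 0.8 * x + 0.6 * e
  X3 <- rbind(f1 = x, f2 = y)
  colnames(X3) <- paste0("s", 1:60)
  expect_equal(cor(x, y), 0.8, tolerance = 1e-12)
  expect_identical(choose_n_factors(X3), 1L)

  # constant features are dropped with a warning
  X4 <- rbind(X2, f5 = rep(1, 50))
  expect_warning(k <- choose_n_factors(X4), "constant")
  expect_identical(k, 2L)
  expect_error(choose_n_factors(X2[1, , drop = FALSE]), ">= 2")
})

test_that("minres + varimax recovers a planted two-factor loading structure", {
  L_true <- cbind(c(0.9, 0.9, 0, 0), c(0, 0, 0.9, 0.9))
  X <- factor_fixture(L_true, 500, seed = 42)
  fm <- fit_efa(X, 2)
  W <- abs(fm$weights)
  # match columns by which recovered factor loads the first block
  ord <- if (mean(W[1:2, 1]) > mean(W[1:2, 2])) 1:2 else 2:1
  expect_lt(max(abs(W[, ord] - abs(L_true))), 0.15)
  # regression scores are centred
  expect_lt(max(abs(colMeans(fm$scores))), 1e-8)
  # communalities bounded by one
  expect_lte(max(rowSums(fm$weights^2)), 1 + 1e-8)
})

test_that("varimax rotation preserves per-feature communalities", {
  L_true <- cbind(c(0.8, 0.7, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.7))
  X <- factor_fixture(L_true, 300, seed = 5)
  R <- cor(t(X))
  L0 <- coadmark:::efa_extract_minres(R, 2)
  L1 <- unclass(varimax(L0, normalize = FALSE)$loadings)
  expect_equal(rowSums(L0^2), rowSums(L1^2), tolerance = 1e-8)
})

test_that("weight normalization is column-wise min-max on absolute loadings", {
  W <- matrix(c(0.2, 0.8, 0.5), 3, 1, dimnames = list(paste0("f", 1:3), "F1"))
  expect_equal(unname(normalize_weights(W)[, 1]), c(0, 1, 0.5))
  W2 <- matrix(c(-0.8, 0.2), 2, 1, dimnames = list(c("f1", "f2"), "F1"))
  expect_equal(unname(normalize_weights(W2)[, 1]), c(1, 0))
  W3 <- matrix(c(0.3, 0.3), 2, 1, dimnames = list(c("f1", "f2"), "F1"))
  expect_warning(nw <- normalize_weights(W3), "constant")
  expect_equal(unname(nw[, 1]), c(0.5, 0.5))
})

test_that("essential features are the per-factor argmax, deduplicated, tie-broken", {
  W <- matrix(c(0.1, 0.9, 0.3, 0.2,
                0.8, 0.0, 0.1, 0.2), 4, 2,
              dimnames = list(paste0("f", c(3, 7, 1, 2)), c("F1", "F2")))
  expect_identical(select_essential(W), c("f7", "f3"))
  # both factors argmax the same feature -> deduplicated
  W2 <- matrix(c(0.9, 0.1, 0.9, 0.2), 2, 2,
               dimnames = list(c("f3", "f9"), c("F1", "F2")))
  expect_identical(select_essential(W2), "f3")
  # exact tie -> lexicographically smaller id
  W3 <- matrix(c(0.9, 0.9), 2, 1, dimnames = list(c("fb", "fa"), "F1"))
  expect_identical(select_essential(W3), "fa")
  # invariance to row order
  W4 <- W[c(3, 1, 4, 2), , drop = FALSE]
  expect_identical(sort(select_essential(W4)), sort(select_essential(W)))
})

test_that("essential selection recovers the strongest planted loadings", {
  # three indicators per factor keep the within-block loading ordering
  # identified (with only two, minres constrains just their product)
  L_true <- cbind(c(0.9, 0.7, 0.5, 0, 0, 0), c(0, 0, 0, 0.9, 0.7, 0.5))
  hits <- 0
  for (seed in 1:50) {
    X <- factor_fixture(L_true, 300, seed = seed)
    fm <- fit_efa(X, 2)
    ess <- select_essential(normalize_weights(fm))
    if (setequal(ess, c("f1", "f4"))) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("combined factor scores take the expected width and cluster structure", {
  ids <- sprintf("s%03d", 1:40)
  mk <- function(k, seed) {
    set.seed(seed)
    structure(list(scores = matrix(rnorm(40 * k), 40, k,
                                   dimnames = list(ids, paste0("F", 1:k))),
                   n_factors = k), class = "factor_model")
  }
  models <- list(gene = mk(19, 1), exon = mk(45, 2),
                 methylation = mk(39, 3), mutation = mk(37, 4))
  sv <- surv_df(ids, rexp(40, 1e-3), rbinom(40, 1, 0.8))
  cb <- combine_scores(models, sv)
  expect_identical(ncol(cb$matrix), 19L + 45L + 39L + 37L + 1L)
  expect_identical(colnames(cb$matrix)[ncol(cb$matrix)], "log_os")

  # one model, one factor: the top split of the dendrogram is an interval
  # of the score ordering
  m1 <- list(a = structure(list(scores = matrix(c(5, 1, 9, 3, 7), 5, 1,
                                dimnames = list(ids[1:5], "F1"))),
                           class = "factor_model"))
  cb1 <- combine_scores(m1, sv[1:5, ])
  cut1 <- cutree(cb1$hclust, 2)
  grp_sorted <- cut1[order(m1$a$scores[, 1])]
  expect_identical(length(rle(as.integer(grp_sorted))$lengths), 2L)

  # two planted, well-separated sample clusters split at the top
  set.seed(8)
  grp <- rep(c(0, 1), each = 20)
  sc <- matrix(rnorm(40 * 3, mean = 6 * grp), 40, 3,
               dimnames = list(ids, paste0("F", 1:3)))
  m2 <- list(x = structure(list(scores = sc), class = "factor_model"))
  cb2 <- combine_scores(m2, sv)
  cut <- cutree(cb2$hclust, 2)
  expect_identical(length(unique(tapply(grp, cut, mean))), 2L)
  expect_true(all(tapply(grp, cut, function(g) length(unique(g))) == 1))

  expect_error(combine_scores(list(m1$a, models$gene), sv), "aligned sample set")
})

test_that("essential-feature union is bounded by the total factor count", {
  co <- generate_cohort(cohort_config(
    n_samples = 120L,
    n_features_per_omics = c(gene = 80L, exon = 80L),
    n_planted_per_omics = c(gene = 6L, exon = 6L), seed = 12))
  lab <- dichotomize_by_os(co$survival)
  total_factors <- 0
  union <- character(0)
  for (ot in names(co$omics)) {
    sel <- select_differential(welch_t_screen(co$omics[[ot]], lab))
    sub <- co$omics[[ot]]$values[sel$feature_id, , drop = FALSE]
    k <- choose_n_factors(sub)
    fm <- fit_efa(sub, k)
    total_factors <- total_factors + k
    union <- union(union, select_essential(normalize_weights(fm)))
  }
  expect_lte(length(union), total_factors)
})

test_that("degenerate factor inputs are rejected or repaired", {
  X <- factor_fixture(cbind(c(0.9, 0.8, 0.7)), 100, seed = 2)
  expect_error(fit_efa(X, 5), "n_factors")
  Xc <- rbind(X, f4 = rep(2, 100))
  expect_warning(fm <- fit_efa(Xc, 1), "constant")
  expect_identical(nrow(fm$weights), 3L)
})
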