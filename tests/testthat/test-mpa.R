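test_that("omics combinations enumerate all non-empty subsets in canonical order", {
  c4 <- enumerate_combinations(c("gene", "exon", "methylation", "mutation"))
  expect_length(c4, 15L)
  expect_identical(lengths(c4), c(rep(1L, 4), rep(2L, 6), rep(3L, 4), 4L))
  expect_identical(c4[[1]], "exon")  # lexicographic within size
  expect_length(enumerate_combinations(c("a", "b")), 3L)
  # brute force over bitmasks for three omics
  omics <- c("x", "y", "z")
  brute <- list()
  for (mask in 1:7) brute[[mask]] <- omics[bitwAnd(mask, 2^(0:2)) > 0]
  c3 <- enumerate_combinations(omics)
  expect_length(c3, 7L)
  expect_setequal(vapply(c3, paste, "", collapse = "+"),
                  vapply(brute, function(s) paste(sort(s), collapse = "+"), ""))
})

# Independent re-derivation of the per-class greedy farthest-point rule.
split_oracle <- function(profile, labels, train_fraction, seed) {
  Z <- scale(profile)
  Z[!is.finite(Z)] <- 0
  set.seed(seed)
  train <- character(0)
  for (cls in c("positive", "negative")) {
    ids <- rownames(profile)[rownames(profile) %in%
                               labels$sample_id[labels$label == cls]]
    m <- length(ids)
    D <- as.matrix(dist(Z[ids, , drop = FALSE]))
    sel <- sample.int(m, 1L)
    while (length(sel) < ceiling(train_fraction * m)) {
      best <- NA; best_d <- -Inf
      for (j in setdiff(seq_len(m), sel)) {
        dj <- mean(D[sel, j])
        if (dj > best_d) { best_d <- dj; best <- j }
      }
      sel <- c(sel, best)
    }
    train <- c(train, ids[sel])
  }
  train
}

test_that("diverse-subset split matches a brute-force greedy oracle", {
  for (seed in 1:5) {
    set.seed(100 + seed)
    n <- 12
    prof <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:3)))
    lab <- labels_df(rownames(prof), rep(c("positive", "negative"), each = 6))
    sp <- diverse_subset_split(prof, lab, seed = seed)
    expect_setequal(sp$train, split_oracle(prof, lab, 2 / 3, seed))
    # partition invariants
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), rownames(prof))
  }
})

test_that("greedy selection always keeps the farthest extreme of a 1-D class", {
  # class values {0, 1, 10}: whatever the random first pick, the point at 10
  # is always selected (it is the farthest from both others)
  prof <- matrix(c(0, 1, 10, 5, 6), 5, 1,
                 dimnames = list(c("a", "b", "c", "d", "e"), "f1"))
  lab <- labels_df(rownames(prof), c(rep("positive", 3), rep("negative", 2)))
  for (seed in 1:10) {
    sp <- diverse_subset_split(prof, lab, seed = seed)
    pos_train <- intersect(sp$train, c("a", "b", "c"))
    expect_length(pos_train, 2L)        # ceil(2/3 * 3)
    expect_true("c" %in% pos_train)
    if ("a" %in% pos_train) expect_identical(sort(pos_train), c("a", "c"))
  }
  # ceiling rule on a 4-sample class: ceil(8/3) = 3
  prof2 <- matrix(rnorm(8), 8, 1, dimnames = list(letters[1:8], "f1"))
  lab2 <- labels_df(letters[1:8], rep(c("positive", "negative"), each = 4))
  sp2 <- diverse_subset_split(prof2, lab2, seed = 1)
  expect_length(intersect(sp2$train, letters[1:4]), 3L)
  expect_error(diverse_subset_split(prof2[1:5, , drop = FALSE],
                                    labels_df(letters[1:5],
                                              c(rep("positive", 4), "negative"))),
               "need >= 2")
})

sep_fixture <- function(n = 40, seed = 1) {
  set.seed(seed)
  half <- n / 2
  X <- rbind(matrix(rnorm(half * 2, 2, 0.5), half, 2),
             matrix(rnorm(half * 2, -2, 0.5), half, 2))
  dimnames(X) <- list(sprintf("s%02d", 1:n), c("f1", "f2"))
  list(profile = X,
       labels = labels_df(rownames(X), rep(c("positive", "negative"), each = half)))
}

test_that("every classifier separates an easy two-cluster toy", {
  fx <- sep_fixture()
  for (method in c("LR", "SVM", "NB", "NN", "RF", "LiR")) {
    fit <- train_mpa(fx$profile, fx$labels, method = method, seed = 1)
    pred <- predict_scores(fit, fx$profile)
    expect_true(all(pred$score >= 0 & pred$score <= 1))
    acc <- mean(pred$class == as.character(fx$labels$label))
    expect_gte(acc, if (method == "LR") 1 else 0.9)
  }
  expect_error(train_mpa(fx$profile[1:20, ],
                         labels_df(rownames(fx$profile)[1:20], rep("positive", 20))),
               "single class")
})

test_that("predictions are deterministic and reuse training constants only", {
  fx <- sep_fixture(seed = 3)
  fit <- train_mpa(fx$profile[1:30, ], fx$labels, method = "LR", seed = 1)
  # standardization constants come from the training rows alone
  expect_equal(unname(fit$center), unname(colMeans(fx$profile[1:30, ])))
  p1 <- predict_scores(fit, fx$profile[31:40, ])
  p2 <- predict_scores(fit, fx$profile[31:40, ])
  expect_identical(p1, p2)
  dup <- fx$profile[c(31, 31), , drop = FALSE]
  rownames(dup) <- c("x1", "x2")
  pd <- predict_scores(fit, dup)
  expect_equal(pd$score[1], pd$score[2])
  expect_error(predict_scores(fit, fx$profile[, 1, drop = FALSE]), "f2")
})

test_that("linear-regression scores reproduce the closed-form OLS fit", {
  prof <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "f1"))
  lab <- labels_df(c("a", "b"), c("negative", "positive"))
  fit <- train_mpa(prof, lab, method = "LiR")
  pred <- predict_scores(fit, prof)
  expect_equal(pred$score, c(0, 1), tolerance = 1e-12)  # perfect 2-point fit
  expect_identical(pred$class, c("negative", "positive"))
})

test_that("shuffled labels yield chance-level test AUC", {
  aucs <- numeric(20)
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("s%03d", 1:n), paste0("f", 1:4)))
    lab <- labels_df(rownames(X), sample(rep(c("positive", "negative"), each = n / 2)))
    sp <- diverse_subset_split(X, lab, seed = seed)
    fit <- train_mpa(X[sp$train, ], lab, method = "LR", seed = seed)
    pred <- predict_scores(fit, X[sp$test, ])
    aucs[seed] <- roc_auc(pred$score,
                          as.character(lab$label[match(sp$test, lab$sample_id)]))$auc
  }
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("AUC equals the Mann-Whitney pair count, including ties", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c("positive", "positive", "negative", "negative"))
  expect_identical(r$auc, 1)
  r2 <- roc_auc(c(0.9, 0.5, 0.4, 0.2), c("positive", "negative", "positive", "negative"))
  expect_equal(r2$auc, 0.75)
  set.seed(4)
  for (i in 1:10) {
    n <- sample(6:50, 1)
    scores <- round(runif(n), 1)  # deliberate ties
    labs <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    expect_equal(roc_auc(scores, labs)$auc, auc_oracle(scores, labs),
                 tolerance = 1e-9)
    expect_equal(roc_auc(scores, labs)$auc + roc_auc(-scores, labs)$auc, 1,
                 tolerance = 1e-9)
  }
  expect_error(roc_auc(c(0.1, 0.2), c("positive", "positive")), "both classes")
})
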