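#' Dichotomize samples into prognosis groups by overall survival
#'
#' Samples surviving beyond the threshold are labelled `positive` (good
#' prognosis, high OS); samples with an observed death at or before the
#' threshold are `negative` (poor prognosis); samples censored before the
#' threshold are `excluded` because their 5-year status is unknowable.
#'
#' @param survival a [survival_table()]
#' @param threshold_days OS dichotomisation point, default 1825 (5 years)
#' @return data.frame of class `prognosis_labels` with columns `sample_id`
#'   and `label` (factor: positive/negative/excluded); the threshold is
#'   stored as attribute `threshold_days`.
#' @export
dichotomize_by_os <- function(survival, threshold_days = 1825) {
  lab <- ifelse(survival$os_days > threshold_days, "positive",
                ifelse(survival$event == 1, "negative", "excluded"))
  out <- data.frame(sample_id = survival$sample_id,
                    label = factor(lab, levels = c("positive", "negative", "excluded")),
                    stringsAsFactors = FALSE)
  attr(out, "threshold_days") <- threshold_days
  class(out) <- c("prognosis_labels", "data.frame")
  out
}

labelled_ids <- function(labels, which) {
  labels$sample_id[labels$label == which]
}

#' Welch t screen of one omics layer
#'
#' Two-sided unequal-variance (Welch) t-test per feature between the
#' positive (high-OS) and negative (low-OS) groups, plus the fold change
#' `mean(negative) / mean(positive)` with an epsilon guard
#' (eps = 1e-8 x grand mean of the matrix) so that zero-mean sparse
#' features stay finite. Features identical across both groups get p = 1
#' and FC = 1. Vectorised over features.
#'
#' @param matrix an [omics_matrix()]
#' @param labels a [dichotomize_by_os()] result covering the matrix samples
#' @return data.frame: feature_id, p_value, fold_change, mean_positive,
#'   mean_negative (one row per feature, input order)
#' @export
welch_t_screen <- function(matrix, labels) {
  stopifnot(inherits(matrix, "omics_matrix"))
  pos <- intersect(sample_ids(matrix), labelled_ids(labels, "positive"))
  neg <- intersect(sample_ids(matrix), labelled_ids(labels, "negative"))
  if (length(pos) < 2L || length(neg) < 2L)
    stopf("need >= 2 samples per prognosis class (positive: %d, negative: %d)",
          length(pos), length(neg))
  xp <- matrix$values[, pos, drop = FALSE]
  xn <- matrix$values[, neg, drop = FALSE]
  np <- ncol(xp); nn <- ncol(xn)
  mp <- rowMeans(xp); mn <- rowMeans(xn)
  vp <- rowSums((xp - mp)^2) / (np - 1L)
  vn <- rowSums((xn - mn)^2) / (nn - 1L)
  se2 <- vp / np + vn / nn
  tstat <- (mn - mp) / sqrt(se2)
  df <- se2^2 / ((vp / np)^2 / (np - 1L) + (vn / nn)^2 / (nn - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1  # zero variance in both groups, equal means
  eps <- 1e-8 * mean(matrix$values)
  fc <- (mn + eps) / (mp + eps)
  fc[mp + eps == 0 & mn + eps == 0] <- 1
  data.frame(feature_id = rownames(matrix$values), p_value = p,
             fold_change = fc, mean_positive = mp, mean_negative = mn,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select prognosis-differential features
#'
#' Applies the screening gates: keep the `top_n` features by ascending
#' p-value (stable tie-break by feature id), then require `p < p_max` and
#' a fold change above `fc_hi` or below `fc_lo`. Output is ordered by
#' ascending p and marks every input row's `passed` status.
#'
#' @param results a [welch_t_screen()] data.frame for one omics layer
#' @param p_max p-value gate, default 0.01
#' @param fc_hi,fc_lo fold-change gates, defaults 1.5 and 2/3
#' @param top_n ascending-p prefilter size, default 1000
#' @return data.frame of the kept rows (ascending p) with column `passed`
#'   (all TRUE); the full annotated table is attached as attribute `"all"`.
#' @export
select_differential <- function(results, p_max = 0.01, fc_hi = 1.5,
                                fc_lo = 2 / 3, top_n = 1000L) {
  ord <- order(results$p_value, results$feature_id)
  res <- results[ord, , drop = FALSE]
  in_top <- seq_len(nrow(res)) <= top_n
  gate <- res$p_value < p_max & (res$fold_change > fc_hi | res$fold_change < fc_lo)
  res$passed <- in_top & gate
  kept <- res[res$passed, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "all") <- res
  kept
}

#' Two-group validation test (Wilcoxon + fold change)
#'
#' Used to confirm biomarkers on an external two-condition dataset (e.g.
#' tumour vs normal single-cell expression): two-sided Wilcoxon rank-sum
#' p-value, case/control mean fold change with an epsilon guard, and the
#' significance flags `p < p_max` and `|log2 FC| > abs_log2fc_min`.
#'
#' @param case_values,control_values numeric vectors (>= 1 value each)
#' @param p_max p-value flag threshold, default 0.05
#' @param abs_log2fc_min absolute log2 fold-change flag threshold, default 1
#'   (i.e. |FC| > 2)
#' @return list: p_value, fold_change, rank_sum (of the case group),
#'   significant_p, significant_fc
#' @export
two_group_validation <- function(case_values, control_values,
                                 p_max = 0.05, abs_log2fc_min = 1) {
  if (!length(case_values) || !length(control_values))
    stopf("both groups need at least one value")
  pooled <- c(case_values, control_values)
  if (length(unique(pooled)) == 1L) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(case_values, control_values, exact = NULL)$p.value)
  }
  r <- rank(pooled)
  rank_sum <- sum(r[seq_along(case_values)])
  eps <- 1e-8 * mean(abs(pooled))
  mc <- mean(case_values); mk <- mean(control_values)
  fc <- if (mc + eps == 0 && mk + eps == 0) 1 else (mc + eps) / (mk + eps)
  list(p_value = p, fold_change = fc, rank_sum = rank_sum,
       significant_p = p < p_max,
       significant_fc = abs(log2(fc)) > abs_log2fc_min)
}
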