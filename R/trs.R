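#' Eligible true-negative samples for regulation simulation
#'
#' Samples that are both label-negative (observed poor prognosis) and
#' predicted negative by the model — the confusion-matrix true negatives.
#' Only these are candidates for in-silico down-regulation.
#'
#' @param model an [train_mpa()] model
#' @param profile samples-by-features matrix of the test set
#' @param labels a `prognosis_labels` data.frame
#' @return character vector of sample ids (possibly empty)
#' @export
eligible_true_negatives <- function(model, profile, labels) {
  pred <- predict_scores(model, profile)
  neg <- labelled_ids(labels, "negative")
  pred$sample_id[pred$class == "negative" & pred$sample_id %in% neg]
}

#' Clamp values for down-regulation
#'
#' The per-feature minimum over all label-positive (good-prognosis)
#' samples: the target level a feature is down-regulated to. For a binary
#' mutation feature this is 0 whenever any positive sample lacks the
#' mutation, so regulation amounts to mutation removal.
#'
#' @param features feature ids
#' @param profile samples-by-features matrix covering positives
#' @param positive_ids ids of the label-positive samples
#' @return named numeric vector of clamp values
#' @export
clamp_values <- function(features, profile, positive_ids) {
  miss <- setdiff(features, colnames(profile))
  if (length(miss)) stopf("feature(s) absent from profile: %s",
                          paste(miss, collapse = ", "))
  pos <- intersect(rownames(profile), positive_ids)
  if (!length(pos)) stopf("no positive samples to derive clamp values from")
  apply(profile[pos, features, drop = FALSE], 2L, min)
}

#' Simulate down-regulation of one or two features
#'
#' Substitutes the clamp values into the eligible samples' profiles,
#' re-standardizes with the model's stored training constants and
#' re-predicts. A sample "flips" when its new prediction is positive
#' (good prognosis). The original profile is untouched.
#'
#' @param model an [train_mpa()] model
#' @param profile samples-by-features matrix containing the eligible samples
#' @param eligible ids of true-negative samples to perturb
#' @param features one or two feature ids to clamp
#' @param clamp named vector of clamp values (see [clamp_values()]); looked
#'   up by feature id
#' @return list of class `flip_result`: features, clamp, flipped (ids),
#'   n_flipped
#' @export
simulate_regulation <- function(model, profile, eligible, features, clamp) {
  if (length(features) < 1L || length(features) > 2L)
    stopf("regulation specs cover one or two features")
  if (!length(eligible))
    return(structure(list(features = features, clamp = clamp[features],
                          flipped = character(0), n_flipped = 0L),
                     class = "flip_result"))
  P <- profile[eligible, , drop = FALSE]
  for (f in features) P[, f] <- clamp[[f]]
  pred <- predict_scores(model, P)
  flipped <- pred$sample_id[pred$class == "positive"]
  structure(list(features = features, clamp = clamp[features],
                 flipped = flipped, n_flipped = length(flipped)),
            class = "flip_result")
}

#' Scan all single features and feature pairs
#'
#' Runs [simulate_regulation()] for every single feature and every
#' unordered pair from `features` (n + n(n-1)/2 specs in total) against
#' the eligible true-negative samples.
#'
#' @param model an [train_mpa()] model
#' @param profile samples-by-features matrix (must include the eligible
#'   samples and all label-positive samples used for clamping)
#' @param eligible ids from [eligible_true_negatives()]
#' @param features feature ids to scan (length >= 1)
#' @param positive_ids label-positive sample ids used for clamp values
#' @return data.frame of class `trs_scan`: feature1, feature2 (NA for
#'   singles), n_flipped, flipped (semicolon-joined ids)
#' @export
scan_trs <- function(model, profile, eligible, features, positive_ids) {
  if (!length(features)) stopf("need at least one feature")
  clamp <- clamp_values(features, profile, positive_ids)
  specs <- c(lapply(features, function(f) f),
             if (length(features) >= 2L)
               utils::combn(features, 2L, simplify = FALSE))
  rows <- lapply(specs, function(fs) {
    fr <- simulate_regulation(model, profile, eligible, fs, clamp)
    data.frame(feature1 = fs[1L],
               feature2 = if (length(fs) == 2L) fs[2L] else NA_character_,
               n_flipped = fr$n_flipped,
               flipped = paste(fr$flipped, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trs_scan", "data.frame")
  out
}

#' Build the flip network from a TRS scan
#'
#' Nodes are features involved in at least one flipping single or pair
#' (node size = number of distinct patients affected by that feature);
#' edges are pairs with at least one flip, weighted by flip count. The
#' per-feature pair-participation count (number of flipping pairs the
#' feature belongs to) ranks the TRS-essential features.
#'
#' @param results a [scan_trs()] data.frame
#' @return list of class `flip_network`: `nodes` (feature, n_affected),
#'   `edges` (feature1, feature2, weight), `participation` (feature,
#'   n_pairs, ranked by descending participation then feature id)
#' @export
build_flip_network <- function(results) {
  flips <- results[results$n_flipped > 0, , drop = FALSE]
  singles <- flips[is.na(flips$feature2), , drop = FALSE]
  pairs <- flips[!is.na(flips$feature2), , drop = FALSE]
  feats <- unique(c(singles$feature1, pairs$feature1, pairs$feature2))
  affected <- vapply(feats, function(f) {
    rows <- flips$feature1 == f | (!is.na(flips$feature2) & flips$feature2 == f)
    ids <- unlist(strsplit(flips$flipped[rows], ";", fixed = TRUE))
    length(unique(ids[nzchar(ids)]))
  }, integer(1L))
  nodes <- data.frame(feature = feats, n_affected = unname(affected),
                      stringsAsFactors = FALSE)
  edges <- data.frame(feature1 = pairs$feature1, feature2 = pairs$feature2,
                      weight = pairs$n_flipped, stringsAsFactors = FALSE)
  part_feats <- sort(unique(c(pairs$feature1, pairs$feature2)))
  part <- vapply(part_feats, function(f)
    sum(pairs$feature1 == f | pairs$feature2 == f), integer(1L))
  participation <- data.frame(feature = part_feats, n_pairs = unname(part),
                              stringsAsFactors = FALSE)
  participation <- participation[order(-participation$n_pairs,
                                       participation$feature), , drop = FALSE]
  rownames(participation) <- NULL
  structure(list(nodes = nodes, edges = edges, participation = participation),
            class = "flip_network")
}

#' @export
print.flip_network <- function(x, ...) {
  cat(sprintf("<flip_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
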