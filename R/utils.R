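`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x)

#' Train-set standardization constants
#'
#' Column means and standard deviations of a samples-by-features matrix;
#' zero-variance columns get scale 1 so the transform stays total.
#' @keywords internal
zscore_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' @keywords internal
zscore_apply <- function(X, zs) {
  sweep(sweep(X, 2L, zs$center, "-"), 2L, zs$scale, "/")
}
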