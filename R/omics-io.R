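#' Recognised omics layer types
#'
#' The four layers handled by the pipeline: gene expression and exon
#' expression (non-negative, log-scale), DNA methylation (beta values in
#' \[0,1\]) and somatic mutation (binary 0/1 matrix).
#' @export
OMICS_TYPES <- c("gene", "exon", "methylation", "mutation")

#' Construct an omics matrix
#'
#' An `omics_matrix` holds one omics layer as a features-by-samples numeric
#' matrix together with its omics-type tag. The constructor enforces the
#' layer's value-domain contract: expression values must be non-negative,
#' methylation beta values must lie in \[0,1\], mutation values must be 0/1,
#' and feature/sample identifiers must be unique and complete.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param omics_type one of `"gene"`, `"exon"`, `"methylation"`, `"mutation"`.
#' @return an object of class `omics_matrix` with elements `values` and
#'   `omics_type`; `feature_ids()`/`sample_ids()` accessors read the dimnames.
#' @export
omics_matrix <- function(values, omics_type) {
  omics_type <- match.arg(omics_type, OMICS_TYPES)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must carry feature ids as rownames and sample ids as colnames")
  x <- structure(list(values = values, omics_type = omics_type),
                 class = "omics_matrix")
  validate_omics_matrix(x)
  x
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d features x %d samples\n",
              x$omics_type, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname omics_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

validate_omics_matrix <- function(x) {
  v <- x$values
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup)) stopf("duplicate feature id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(v)[duplicated(colnames(v))]
  if (length(dup)) stopf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(v)) stopf("missing values present after load; impute before construction")
  bad <- switch(x$omics_type,
    gene = , exon = which(v < 0),
    methylation = which(v < 0 | v > 1),
    mutation = which(!(v %in% c(0, 1))))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(v))
    stopf("value %g out of domain for omics type '%s' at feature '%s', sample '%s'",
          v[bad[1L]], x$omics_type, rownames(v)[i[1L]], colnames(v)[i[2L]])
  }
  invisible(x)
}

#' Read an omics matrix from a TSV file
#'
#' Expects a tab-separated file with feature ids in the first column and
#' sample ids in the header. Missing values in continuous layers are imputed
#' with the feature-wise median (a message reports the count); missing
#' mutation calls are treated as 0. Row and column order are preserved.
#'
#' @param path path to a TSV file
#' @param omics_type omics layer tag, see [OMICS_TYPES]
#' @return an [omics_matrix()]
#' @export
read_matrix <- function(path, omics_type) {
  omics_type <- match.arg(omics_type, OMICS_TYPES)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("'%s' has no sample columns", path)
  feats <- as.character(df[[1L]])
  v <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- feats
  n_na <- sum(is.na(v))
  if (n_na > 0) {
    if (omics_type == "mutation") {
      v[is.na(v)] <- 0
    } else {
      med <- apply(v, 1L, stats::median, na.rm = TRUE)
      idx <- which(is.na(v), arr.ind = TRUE)
      v[idx] <- med[idx[, 1L]]
    }
    message(sprintf("read_matrix: imputed %d missing value(s) in '%s'", n_na, basename(path)))
  }
  omics_matrix(v, omics_type)
}

#' Write an omics matrix to a TSV file
#'
#' Inverse of [read_matrix()]; round-trips losslessly to within 1e-9
#' (exactly, for mutation matrices).
#' @param x an [omics_matrix()]
#' @param path output path
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a survival table
#'
#' Per-sample overall survival in days, an event flag (1 = death observed,
#' 0 = censored) and optional clinical covariate columns.
#'
#' @param df data.frame with at least `sample_id`, `os_days`, `event`
#' @return the validated data.frame with class `survival_table`
#' @export
survival_table <- function(df) {
  need <- c("sample_id", "os_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("survival table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in survival table")
  if (any(df$os_days < 0 | !is.finite(df$os_days))) stopf("os_days must be finite and >= 0")
  if (!all(df$event %in% c(0, 1))) stopf("event must be 0/1")
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read / write a survival table (TSV with header)
#' @param path TSV path
#' @return [survival_table()]
#' @export
read_survival_table <- function(path) {
  survival_table(utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
}

#' @rdname read_survival_table
#' @param x a `survival_table`
#' @export
write_survival_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-to-gene-symbol annotation map
#'
#' Two-column TSV (feature id, gene symbol); many features may map to one
#' symbol. Returns a named character vector feature -> symbol.
#' @param path TSV path
#' @export
read_annotation_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("annotation map needs two columns")
  sym <- as.character(df[[2L]])
  if (any(!nzchar(sym))) stopf("annotation map contains empty symbol(s)")
  stats::setNames(sym, as.character(df[[1L]]))
}

#' Read / write a protein-protein interaction edge list
#'
#' Two-column TSV of gene-symbol pairs; treated as undirected.
#' @param path TSV path
#' @export
read_ppi_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("edge list needs two columns")
  data.frame(from = as.character(df[[1L]]), to = as.character(df[[2L]]),
             stringsAsFactors = FALSE)
}

#' @rdname read_ppi_edges
#' @param edges data.frame with columns `from`, `to`
#' @export
write_ppi_edges <- function(edges, path) {
  utils::write.table(edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict omics layers and survival to their shared samples
#'
#' Computes the intersection of sample ids across all supplied layers and
#' the survival table and returns every object restricted to that shared
#' set, in the order of the first matrix. Idempotent.
#'
#' @param matrices list of [omics_matrix()] objects (at least one)
#' @param survival a [survival_table()]
#' @return list with `matrices` (same names), `survival`, and `samples`
#'   (the shared ordered id vector)
#' @export
align_samples <- function(matrices, survival) {
  if (!length(matrices)) stopf("need at least one omics matrix")
  lapply(matrices, function(m) stopifnot(inherits(m, "omics_matrix")))
  shared <- Reduce(intersect, lapply(matrices, sample_ids))
  shared <- intersect(shared, survival$sample_id)
  ord <- sample_ids(matrices[[1L]])
  shared <- ord[ord %in% shared]
  if (!length(shared)) stopf("no samples shared across all omics layers and the survival table")
  mats <- lapply(matrices, function(m) {
    m$values <- m$values[, shared, drop = FALSE]
    m
  })
  surv <- survival[match(shared, survival$sample_id), , drop = FALSE]
  rownames(surv) <- NULL
  list(matrices = mats, survival = survival_table(surv), samples = shared)
}
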