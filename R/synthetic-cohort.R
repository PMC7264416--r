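#' Configuration for a synthetic multi-omics cohort
#'
#' Defines the study conditions a generated cohort emulates: a two-group
#' prognosis structure split at 5 years of overall survival, planted
#' differential features whose values are higher in poor-prognosis samples,
#' mutation features absent from every good-prognosis sample, and survival
#' times whose hazard rises with a latent risk built from the planted
#' features.
#'
#' Defaults (chosen once as the package's study conditions): 200 samples;
#' 300/300/300/150 features for gene/exon/methylation/mutation with
#' 10/10/10/8 planted; standardized effect size 1.5; mutation probability
#' 0.3 in poor-prognosis samples; baseline hazard 5e-4 per day (median OS
#' near the 1825-day dichotomisation point); log-hazard 2.5 per SD of latent
#' risk, strong enough that the OS-derived prognosis labels realise the
#' planted between-group effect size (the generator's contract) while the
#' survival draw still attenuates it; 20% administrative censoring.
#'
#' @param n_samples number of samples
#' @param n_features_per_omics named vector/list, omics type -> feature count
#' @param n_planted_per_omics named vector/list, omics type -> number of
#'   planted prognosis-associated features (must not exceed the feature count)
#' @param effect_size standardized mean shift (Cohen's d, on the generative
#'   latent scale) of planted continuous features, poor-prognosis group higher
#' @param mutation_rate_negative probability of a planted mutation in a
#'   poor-prognosis sample
#' @param baseline_hazard per-day exponential hazard at zero latent risk
#' @param risk_coefficient log-hazard increase per unit (SD) of latent risk
#' @param censor_rate probability a sample is subject to administrative
#'   censoring at a uniform time before maximum follow-up
#' @param seed integer RNG seed
#' @return a list of class `cohort_config`
#' @export
cohort_config <- function(n_samples = 200L,
                          n_features_per_omics = c(gene = 300L, exon = 300L,
                                                   methylation = 300L, mutation = 150L),
                          n_planted_per_omics = c(gene = 10L, exon = 10L,
                                                  methylation = 10L, mutation = 8L),
                          effect_size = 1.5,
                          mutation_rate_negative = 0.3,
                          baseline_hazard = 5e-4,
                          risk_coefficient = 2.5,
                          censor_rate = 0.2,
                          seed = 1L) {
  cfg <- structure(list(
    n_samples = n_samples,
    n_features_per_omics = unlist(n_features_per_omics),
    n_planted_per_omics = unlist(n_planted_per_omics),
    effect_size = effect_size,
    mutation_rate_negative = mutation_rate_negative,
    baseline_hazard = baseline_hazard,
    risk_coefficient = risk_coefficient,
    censor_rate = censor_rate,
    seed = seed), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is_count(cfg$n_samples) || cfg$n_samples < 2)
    stopf("invalid 'n_samples': must be an integer >= 2")
  nf <- cfg$n_features_per_omics
  if (!length(nf) || is.null(names(nf)) || !all(names(nf) %in% OMICS_TYPES))
    stopf("invalid 'n_features_per_omics': names must be omics types")
  if (any(nf < 1)) stopf("invalid 'n_features_per_omics': counts must be positive")
  np <- cfg$n_planted_per_omics
  np <- np[names(np) %in% names(nf)]
  if (any(np < 0)) stopf("invalid 'n_planted_per_omics': counts must be non-negative")
  for (k in names(np))
    if (np[[k]] > nf[[k]])
      stopf("invalid 'n_planted_per_omics': %d planted > %d features for omics '%s'",
            np[[k]], nf[[k]], k)
  for (fld in c("mutation_rate_negative", "censor_rate")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || v < 0 || v > 1) stopf("invalid '%s': must lie in [0,1]", fld)
  }
  if (!is.numeric(cfg$effect_size) || !is.finite(cfg$effect_size))
    stopf("invalid 'effect_size'")
  if (!is.numeric(cfg$baseline_hazard) || cfg$baseline_hazard <= 0)
    stopf("invalid 'baseline_hazard': must be > 0")
  if (!is.numeric(cfg$risk_coefficient) || !is.finite(cfg$risk_coefficient))
    stopf("invalid 'risk_coefficient'")
  if (!is_count(cfg$seed)) stopf("invalid 'seed': must be an integer")
  invisible(cfg)
}

# Deterministic feature-id schemes per layer.
synthetic_feature_ids <- function(omics_type, p) {
  switch(omics_type,
    gene = sprintf("GENE%04d", seq_len(p)),
    exon = sprintf("chr%d:%d-%d:%s", (seq_len(p) - 1L) %% 22L + 1L,
                   1e6L + seq_len(p) * 1000L, 1e6L + seq_len(p) * 1000L + 150L,
                   ifelse(seq_len(p) %% 2L == 0L, "+", "-")),
    methylation = sprintf("cg%08d", seq_len(p)),
    mutation = sprintf("MUT%04d", p = seq_len(p)))
}

# One continuous expression layer: i.i.d. log-normal noise, planted rows
# shifted by d standard deviations on the log scale in the poor group.
r_expression_layer <- function(p, np, n, grp, d) {
  meanlog <- stats::runif(p, 0, 3)
  sdlog <- 0.5
  shift <- matrix(0, p, n)
  if (np > 0) shift[seq_len(np), grp == 1L] <- d * sdlog
  v <- matrix(stats::rlnorm(p * n, meanlog = rep(meanlog, n), sdlog = sdlog), p, n)
  v * exp(shift)
}

# Methylation on the logit scale, inverse-transformed to keep beta in [0,1].
# Planted baselines are drawn from the lowly methylated range so that the
# planted logit shift is visible as a beta-scale fold change.
r_methylation_layer <- function(p, np, n, grp, d) {
  mu <- stats::runif(p, -2, 2)
  if (np > 0) mu[seq_len(np)] <- stats::runif(np, -2, -0.5)
  s <- 0.8
  shift <- matrix(0, p, n)
  if (np > 0) shift[seq_len(np), grp == 1L] <- d * s
  z <- matrix(stats::rnorm(p * n, mean = rep(mu, n), sd = s), p, n) + shift
  stats::plogis(z)
}

r_mutation_layer <- function(p, np, n, grp, rate_neg, background = 0.05) {
  v <- matrix(stats::rbinom(p * n, 1L, background), p, n)
  if (np > 0) {
    for (i in seq_len(np)) {
      v[i, ] <- ifelse(grp == 1L, stats::rbinom(n, 1L, rate_neg), 0L)
    }
  }
  v
}

#' Generate a seeded synthetic multi-omics cohort
#'
#' Produces one [omics_matrix()] per configured layer, a [survival_table()]
#' with eleven clinical covariates, the list of planted feature ids per
#' layer, and the per-sample latent risk. Deterministic given the config
#' seed.
#'
#' Generation order: a provisional poor-prognosis indicator is drawn per
#' sample; planted features are shifted against it; the latent risk is the
#' standardized sum of z-scored planted feature values; overall survival is
#' drawn from an exponential model with hazard
#' `baseline_hazard * exp(risk_coefficient * latent_risk)` plus independent
#' administrative censoring. Because the final prognosis label is recomputed
#' from the drawn OS (> 1825 days), planted effects are realistically
#' attenuated rather than perfectly separating the groups. Planted mutation
#' features are then zeroed in every final good-prognosis sample, so their
#' sum over that group is exactly 0.
#'
#' @param config a [cohort_config()]
#' @return list of class `synthetic_cohort`: `omics` (named list of
#'   matrices), `survival`, `planted_truth`, `latent_risk`, `annotation`
#'   (feature -> synthetic gene symbol; planted features share symbols
#'   across layers), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  grp <- stats::rbinom(n, 1L, 0.5)  # provisional poor-prognosis indicator

  omics <- list()
  planted <- list()
  planted_rows <- list()
  for (ot in names(config$n_features_per_omics)) {
    p <- as.integer(config$n_features_per_omics[[ot]])
    np <- as.integer(config$n_planted_per_omics[ot] %||% 0L)
    if (is.na(np)) np <- 0L
    v <- switch(ot,
      gene = , exon = r_expression_layer(p, np, n, grp, config$effect_size),
      methylation = r_methylation_layer(p, np, n, grp, config$effect_size),
      mutation = r_mutation_layer(p, np, n, grp, config$mutation_rate_negative))
    rownames(v) <- synthetic_feature_ids(ot, p)
    colnames(v) <- ids
    omics[[ot]] <- omics_matrix(v, ot)
    planted[[ot]] <- rownames(v)[seq_len(np)]
    if (np > 0) planted_rows[[ot]] <- v[seq_len(np), , drop = FALSE]
  }

  # Latent risk: standardized sum of z-scored planted feature values.
  if (length(planted_rows)) {
    P <- do.call(rbind, planted_rows)
    Z <- t(scale(t(P)))
    Z[!is.finite(Z)] <- 0
    raw <- colSums(Z)
    s <- stats::sd(raw)
    latent <- if (is.finite(s) && s > 0) (raw - mean(raw)) / s else rep(0, n)
  } else {
    latent <- rep(0, n)
  }
  names(latent) <- ids

  rate <- config$baseline_hazard * exp(config$risk_coefficient * latent)
  t_event <- stats::rexp(n, rate)
  cens <- stats::runif(n) < config$censor_rate
  c_time <- stats::runif(n, 0, max(t_event))
  os <- ifelse(cens & c_time < t_event, c_time, t_event)
  event <- as.integer(!(cens & c_time < t_event))

  # Enforce mutation exclusivity in the final good-prognosis group.
  good <- os > 1825
  if (!is.null(omics$mutation) && length(planted$mutation)) {
    omics$mutation$values[planted$mutation, good] <- 0
  }

  surv <- survival_table(data.frame(
    sample_id = ids, os_days = os, event = event,
    age = round(stats::rnorm(n, 65, 10)),
    gender = sample(c("male", "female"), n, replace = TRUE),
    weight = round(stats::rnorm(n, 80, 15), 1),
    histological_type = sample(c("adenocarcinoma", "mucinous"), n,
                               replace = TRUE, prob = c(0.85, 0.15)),
    history_of_colon_polyps = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.3, 0.7)),
    person_neoplasm_cancer_status = sample(c("with tumor", "tumor free"), n, replace = TRUE),
    lymphatic_invasion = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.4, 0.6)),
    pathologic_stage = sample(c("i", "ii", "iii", "iv"), n, replace = TRUE),
    pathologic_t_stage = sample(c("t1", "t2", "t3", "t4"), n, replace = TRUE),
    venous_invasion = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.25, 0.75)),
    n_first_degree_relatives_with_cancer = stats::rpois(n, 0.3),
    stringsAsFactors = FALSE))

  # Annotation: planted feature j of every layer shares a symbol (so symbol
  # unions across omics are genuinely redundant); other features map 1:1.
  ann <- character(0)
  for (ot in names(omics)) {
    f <- feature_ids(omics[[ot]])
    np <- length(planted[[ot]])
    sym <- sprintf("SYM_%s_%04d", toupper(substr(ot, 1, 2)), seq_along(f))
    if (np > 0) sym[seq_len(np)] <- sprintf("SYMPL%04d", seq_len(np))
    ann <- c(ann, stats::setNames(sym, f))
  }

  structure(list(omics = omics, survival = surv, planted_truth = planted,
                 latent_risk = latent, annotation = ann, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples; layers: %s\n",
              x$config$n_samples,
              paste(sprintf("%s(%d)", names(x$omics),
                            vapply(x$omics, function(m) nrow(m$values), 1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' One `<omics>.tsv` matrix per layer, `survival.tsv`, `annotation.tsv`
#' and `planted_truth.tsv`.
#' @param cohort a [generate_cohort()] result
#' @param dir output directory (created if needed)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ot in names(cohort$omics))
    write_matrix(cohort$omics[[ot]], file.path(dir, paste0(ot, ".tsv")))
  write_survival_table(cohort$survival, file.path(dir, "survival.tsv"))
  utils::write.table(
    data.frame(feature_id = names(cohort$annotation), symbol = cohort$annotation),
    file.path(dir, "annotation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- data.frame(
    omics = rep(names(cohort$planted_truth), lengths(cohort$planted_truth)),
    feature_id = unlist(cohort$planted_truth, use.names = FALSE))
  utils::write.table(pt, file.path(dir, "planted_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a synthetic undirected PPI edge list with designated hubs
#'
#' The first `n_hubs` symbols are wired to at least `hub_degree` distinct
#' partners; optionally `n_extra_edges` random background edges are added.
#' The result is self-loop-free and duplicate-free (undirected).
#'
#' @param gene_symbols character vector of node names
#' @param n_hubs number of designated hub symbols (taken from the front)
#' @param hub_degree minimum degree guaranteed for each hub
#' @param seed RNG seed
#' @param n_extra_edges additional random edges beyond the hub spokes
#' @return data.frame with columns `from`, `to`
#' @export
generate_ppi_edges <- function(gene_symbols, n_hubs, hub_degree, seed = 1L,
                               n_extra_edges = 0L) {
  m <- length(gene_symbols)
  if (n_hubs > m) stopf("n_hubs exceeds number of symbols")
  if (n_hubs > 0 && hub_degree > m - 1L)
    stopf("hub_degree %d impossible with %d symbols", hub_degree, m)
  set.seed(seed)
  ed <- list()
  for (h in seq_len(n_hubs)) {
    partners <- sample(setdiff(gene_symbols, gene_symbols[h]), hub_degree)
    ed[[length(ed) + 1L]] <- data.frame(from = gene_symbols[h], to = partners,
                                        stringsAsFactors = FALSE)
  }
  k <- 0L
  while (k < n_extra_edges && m >= 2L) {
    pair <- sample(gene_symbols, 2L)
    ed[[length(ed) + 1L]] <- data.frame(from = pair[1L], to = pair[2L],
                                        stringsAsFactors = FALSE)
    k <- k + 1L
  }
  if (!length(ed)) return(data.frame(from = character(0), to = character(0),
                                     stringsAsFactors = FALSE))
  e <- do.call(rbind, ed)
  key <- ifelse(e$from < e$to, paste(e$from, e$to), paste(e$to, e$from))
  e <- e[!duplicated(key) & e$from != e$to, , drop = FALSE]
  rownames(e) <- NULL
  e
}
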