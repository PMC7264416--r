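#' Pipeline configuration
#'
#' Collects the inputs and thresholds for an end-to-end run. Either an
#' in-memory [generate_cohort()] object or on-disk TSV paths per omics
#' layer plus a survival table may be supplied.
#'
#' @param cohort optional `synthetic_cohort` (used directly if given)
#' @param omics_paths named list omics type -> TSV path (if no cohort)
#' @param survival_path survival table TSV path (if no cohort)
#' @param annotation optional feature -> symbol named vector
#' @param ppi_edges optional edge list data.frame (`from`, `to`)
#' @param os_threshold_days OS dichotomisation point, default 1825
#' @param p_max,fc_hi,fc_lo,top_n screening gates (defaults 0.01, 1.5,
#'   2/3, 1000)
#' @param min_degree PPI hub threshold, default 5
#' @param method MPA classifier tag, default "LR"
#' @param n_prb number of top TRS-ranked biomarkers fed to the risk score,
#'   default 13
#' @param seed RNG seed for split and stochastic learners
#' @param outdir output directory (default: a fresh temporary directory)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(cohort = NULL, omics_paths = NULL,
                            survival_path = NULL, annotation = NULL,
                            ppi_edges = NULL, os_threshold_days = 1825,
                            p_max = 0.01, fc_hi = 1.5, fc_lo = 2 / 3,
                            top_n = 1000L, min_degree = 5L, method = "LR",
                            n_prb = 13L, seed = 1L,
                            outdir = tempfile("coadmark_run_")) {
  cfg <- structure(list(cohort = cohort, omics_paths = omics_paths,
                        survival_path = survival_path, annotation = annotation,
                        ppi_edges = ppi_edges,
                        os_threshold_days = os_threshold_days, p_max = p_max,
                        fc_hi = fc_hi, fc_lo = fc_lo, top_n = top_n,
                        min_degree = min_degree, method = method,
                        n_prb = n_prb, seed = seed, outdir = outdir),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  for (fld in c("os_threshold_days", "p_max", "fc_hi", "fc_lo", "top_n", "min_degree"))
    if (!is.numeric(cfg[[fld]]) || cfg[[fld]] <= 0)
      stopf("invalid '%s': must be a positive number", fld)
  if (!(cfg$fc_lo < 1 && 1 < cfg$fc_hi))
    stopf("fold-change gates must satisfy fc_lo < 1 < fc_hi (got %g, %g)",
          cfg$fc_lo, cfg$fc_hi)
  if (cfg$p_max >= 1) stopf("invalid 'p_max': must be < 1")
  match.arg(cfg$method, MPA_METHODS)
  if (is.null(cfg$cohort) && (is.null(cfg$omics_paths) || is.null(cfg$survival_path)))
    stopf("supply either 'cohort' or 'omics_paths' + 'survival_path'")
  invisible(cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full prognostic pipeline
#'
#' Executes the stages in order — screening, factor reduction, MPA model
#' training/evaluation, target regulation simulation, risk scoring,
#' survival analysis, network annotation — writes every stage output as
#' TSV under the configured output directory and records a machine-readable
#' JSON manifest (seeds, thresholds, per-stage row counts).
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with all stage results plus `manifest` and
#'   `outdir`
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("coadmark")),
                   seed = config$seed, method = config$method,
                   thresholds = list(os_days = config$os_threshold_days,
                                     p_max = config$p_max, fc_hi = config$fc_hi,
                                     fc_lo = config$fc_lo, top_n = config$top_n,
                                     min_degree = config$min_degree),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # -- load & align ---------------------------------------------------------
  al <- run_stage("load", {
    if (!is.null(config$cohort)) {
      align_samples(config$cohort$omics, config$cohort$survival)
    } else {
      mats <- lapply(names(config$omics_paths), function(ot)
        read_matrix(config$omics_paths[[ot]], ot))
      names(mats) <- names(config$omics_paths)
      align_samples(mats, read_survival_table(config$survival_path))
    }
  })
  annotation <- config$annotation %||% config$cohort$annotation

  # -- screening ------------------------------------------------------------
  labels <- run_stage("screening", dichotomize_by_os(al$survival, config$os_threshold_days))
  differential <- run_stage("screening", {
    lapply(al$matrices, function(m) {
      res <- welch_t_screen(m, labels)
      select_differential(res, p_max = config$p_max, fc_hi = config$fc_hi,
                          fc_lo = config$fc_lo, top_n = config$top_n)
    })
  })
  for (ot in names(differential))
    utils::write.table(differential[[ot]],
                       file.path(config$outdir, sprintf("differential_%s.tsv", ot)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  note("screening", n_differential = vapply(differential, nrow, 1L),
       n_labelled = sum(labels$label != "excluded"))

  # -- factor reduction -----------------------------------------------------
  fr <- run_stage("factor_reduction", {
    models <- list()
    essential <- list()
    for (ot in names(al$matrices)) {
      feats <- differential[[ot]]$feature_id
      if (length(feats) < 2L) {
        essential[[ot]] <- feats   # nothing to reduce
        next
      }
      sub <- al$matrices[[ot]]$values[feats, , drop = FALSE]
      k <- choose_n_factors(sub)
      fm <- fit_efa(sub, k, omics_type = ot)
      models[[ot]] <- fm
      essential[[ot]] <- select_essential(normalize_weights(fm))
      utils::write.table(
        data.frame(feature_id = rownames(fm$weights), fm$weights),
        file.path(config$outdir, sprintf("factor_weights_%s.tsv", ot)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = rownames(fm$scores), fm$scores),
        file.path(config$outdir, sprintf("factor_scores_%s.tsv", ot)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    comb <- if (length(models)) combine_scores(models, al$survival) else NULL
    if (!is.null(comb))
      writeLines(comb$order, file.path(config$outdir, "cluster_order.txt"))
    list(models = models, essential = essential, combined = comb)
  })
  essential_union <- unique(unlist(fr$essential, use.names = FALSE))
  if (length(essential_union) < 2L)
    stopf("pipeline stage 'factor_reduction' failed: fewer than 2 essential features")
  note("factor_reduction",
       n_factors = vapply(fr$models, function(m) m$n_factors, 1L),
       n_essential = vapply(fr$essential, length, 1L),
       n_essential_union = length(essential_union))

  # essential-feature profile: samples x features across layers
  profile <- run_stage("factor_reduction", {
    rows <- do.call(rbind, lapply(names(al$matrices), function(ot) {
      feats <- intersect(fr$essential[[ot]], rownames(al$matrices[[ot]]$values))
      al$matrices[[ot]]$values[feats, , drop = FALSE]
    }))
    t(rows[essential_union, , drop = FALSE])
  })

  # -- mpa ------------------------------------------------------------------
  mpa <- run_stage("mpa", {
    split <- diverse_subset_split(profile, labels, seed = config$seed)
    model <- train_mpa(profile[split$train, , drop = FALSE], labels,
                       method = config$method, seed = config$seed)
    pred <- predict_scores(model, profile[split$test, , drop = FALSE])
    test_labels <- labels$label[match(split$test, labels$sample_id)]
    roc <- roc_auc(pred$score, as.character(test_labels))
    utils::write.table(pred, file.path(config$outdir, "mpa_test_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(split = split, model = model, predictions = pred, roc = roc)
  })
  note("mpa", n_train = length(mpa$split$train), n_test = length(mpa$split$test),
       auc = mpa$roc$auc)

  # -- trs ------------------------------------------------------------------
  trs <- run_stage("trs", {
    eligible <- eligible_true_negatives(mpa$model,
                                        profile[mpa$split$test, , drop = FALSE],
                                        labels)
    scan <- scan_trs(mpa$model, profile, eligible, essential_union,
                     positive_ids = labelled_ids(labels, "positive"))
    net <- build_flip_network(scan)
    utils::write.table(scan, file.path(config$outdir, "trs_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$nodes, file.path(config$outdir, "flip_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$edges, file.path(config$outdir, "flip_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(eligible = eligible, scan = scan, network = net)
  })
  note("trs", n_eligible = length(trs$eligible), n_specs = nrow(trs$scan),
       n_flipping_specs = sum(trs$scan$n_flipped > 0))

  # -- risk scoring ---------------------------------------------------------
  prs <- run_stage("risk_scoring", {
    ranked <- trs$network$participation$feature
    prb <- utils::head(unique(c(ranked, essential_union)), config$n_prb)
    model <- fit_prs(profile[, prb, drop = FALSE], labels)
    lab_ids <- labels$sample_id[labels$label %in% c("positive", "negative")]
    lab_ids <- intersect(rownames(profile), lab_ids)
    scores <- score_prs(model, profile[lab_ids, , drop = FALSE])
    thr <- choose_threshold(scores, labels$label[match(lab_ids, labels$sample_id)])
    model$threshold <- thr$threshold
    utils::write.table(
      data.frame(feature = model$features, coefficient = model$coefficients),
      file.path(config$outdir, "prs_coefficients.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(model = model, scores = scores, threshold = thr, features = prb)
  })
  note("risk_scoring", n_prb = length(prs$features),
       threshold = prs$threshold$threshold, youden_j = prs$threshold$youden_j)

  # -- survival analysis ----------------------------------------------------
  sa <- run_stage("survival_analysis", {
    idx <- match(mpa$predictions$sample_id, al$survival$sample_id)
    km <- km_curve(al$survival$os_days[idx], al$survival$event[idx],
                   mpa$predictions$class)
    lr <- if (length(unique(mpa$predictions$class)) == 2L)
      logrank_test(al$survival$os_days[idx], al$survival$event[idx],
                   mpa$predictions$class) else list(statistic = NA, p_value = NA)
    cox <- cox_screen(al$survival, mode = "univariate")
    utils::write.table(cox, file.path(config$outdir, "cox_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(km = km, logrank = lr, cox = cox)
  })
  note("survival_analysis", logrank_p = sa$logrank$p_value,
       n_cox_rows = nrow(sa$cox))

  # -- network annotation ---------------------------------------------------
  net <- run_stage("network_annotation", {
    mapped <- if (!is.null(annotation))
      map_to_symbols(fr$essential, annotation)
    else list(symbols = essential_union,
              provenance = data.frame(symbol = character(0), omics = character(0)),
              unmapped = data.frame(omics = character(0), feature_id = character(0)))
    edges <- config$ppi_edges %||%
      data.frame(from = character(0), to = character(0))
    degrees <- compute_degrees(mapped$symbols, edges, config$min_degree)
    hubs <- hub_filter(degrees, config$min_degree)
    utils::write.table(degrees, file.path(config$outdir, "ppi_degrees.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(mapped = mapped, degrees = degrees, hubs = hubs)
  })
  note("network_annotation", n_symbols = length(net$mapped$symbols),
       n_hubs = length(net$hubs))

  manifest$n_stages_completed <- length(manifest$stages)
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(aligned = al, labels = labels, differential = differential,
                 factors = fr, profile = profile, mpa = mpa, trs = trs,
                 prs = prs, survival = sa, network = net,
                 manifest = manifest, outdir = config$outdir))
}
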