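#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end analysis: input locations (or a
#' synthetic-cohort configuration), the discretization pair, transform
#' registry, FDR level, number of spiked random predictors, null-simulation
#' settings and seeds.
#'
#' @param sim_config a [cohort_sim_config()] used when no external tables
#'   are supplied.
#' @param blood_csv,visits_csv,features_csv optional input CSV paths
#'   (override the synthetic cohort).
#' @param extraction an [extraction_config()].
#' @param registry transform registry.
#' @param fdr_level FDR level for the screens.
#' @param n_random spiked random predictors in the screens.
#' @param null_config a [null_sim_config()].
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim_config = cohort_sim_config(),
                            blood_csv = NULL, visits_csv = NULL,
                            features_csv = NULL,
                            extraction = extraction_config(),
                            registry = default_transform_registry(),
                            fdr_level = 0.05, n_random = 100,
                            null_config = null_sim_config(n_datasets = 500),
                            seed = 1) {
  structure(list(sim_config = sim_config, blood_csv = blood_csv,
                 visits_csv = visits_csv, features_csv = features_csv,
                 extraction = extraction, registry = registry,
                 fdr_level = fdr_level, n_random = n_random,
                 null_config = null_config, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes assemble -> screen (with and without volume adjustment) ->
#' selection (LASSO and stepwise) -> top-5 PCA signature -> Monte-Carlo
#' null reference test -> association triangle, writing every artifact
#' into `out_dir`: the two screening tables, the selection results
#' (JSON), the frozen signature (JSON), the null-test scatter (CSV) and
#' summary (JSON), the association report summary (JSON), and a manifest
#' recording seeds and configuration. Any stage error halts with a
#' stage-tagged message; artifacts written before the failure remain.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  dat <- stage("assemble", {
    if (!is.null(cfg$blood_csv)) {
      tabs <- read_tables(cfg$blood_csv, cfg$visits_csv)
      feats <- if (!is.null(cfg$features_csv))
        read.csv(cfg$features_csv, stringsAsFactors = FALSE) else NULL
      if (!is.null(feats)) feats$date <- .parse_dates(feats$date,
                                                      "features")
      cohort <- assemble_cohort(tabs$blood, tabs$visits, feats)
      list(cohort = cohort,
           feature_names = setdiff(names(feats),
                                   c("patient_id", "date")))
    } else {
      g <- generate_cohort(cfg$sim_config)
      list(cohort = g$cohort,
           feature_names = setdiff(colnames(cfg$sim_config$feature_cov),
                                   character(0)))
    }
  })
  cohort <- dat$cohort
  feature_names <- dat$feature_names
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)

  screen_raw <- stage("screen", screen_features(
    cohort, feature_names, cfg$registry, n_random = cfg$n_random,
    adjust_volume = FALSE, fdr_level = cfg$fdr_level, seed = cfg$seed))
  write_screen_csv(screen_raw, file.path(out_dir, "screen_unadjusted.csv"))

  feature_names_nv <- setdiff(feature_names, "Volume")
  screen_adj <- stage("screen_volume", screen_features(
    cohort, feature_names_nv, cfg$registry, n_random = cfg$n_random,
    adjust_volume = TRUE, fdr_level = cfg$fdr_level, seed = cfg$seed))
  write_screen_csv(screen_adj, file.path(out_dir,
                                         "screen_volume_adjusted.csv"))

  sel <- stage("select", {
    Z <- .standardized_features(cohort, feature_names, cfg$registry)
    rnd <- spike_random_features(ncol(Z), cohort$patient_id, icc = 0,
                                 seed = cfg$seed + 17)
    rnd <- scale(as.matrix(rnd))
    Xall <- cbind(Z, rnd)
    path <- lasso_mlm_path(cohort$log_maf, Xall, cohort$patient_id)
    las <- select_lambda_by_random_entry(path, colnames(rnd))
    stp <- stepwise_r2(cohort$log_maf, Xall, cohort$patient_id,
                       colnames(rnd))
    list(lasso = las, stepwise = stp)
  })
  jsonlite::write_json(
    list(lasso = list(selected = sel$lasso$selected,
                      stopping = sel$lasso$stopping,
                      lambda = sel$lasso$lambda),
         stepwise = list(selected = sel$stepwise$selected,
                         stopping = sel$stepwise$stopping,
                         r2 = sel$stepwise$r2)),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)

  sig <- stage("signature", {
    top5 <- pick_top5(screen_adj)
    fit_pca_signature(cohort, top5, response = abs(cohort$log_maf),
                      registry = cfg$registry)
  })
  write_signature_json(sig, file.path(out_dir, "signature.json"))

  nulltest <- stage("nulltest", null_reference_test(
    cohort, setdiff(feature_names, "Volume"), cfg$null_config,
    builder = "five-features", registry = cfg$registry))
  write_nullsim_csv(nulltest, file.path(out_dir, "nullsim_scatter.csv"))
  jsonlite::write_json(
    list(p_r2 = nulltest$p_r2, p_lrt = nulltest$p_lrt,
         real_r2 = unname(nulltest$real["r2"]),
         real_lrt = unname(nulltest$real["lrt"])),
    file.path(out_dir, "nullsim_summary.json"), auto_unbox = TRUE,
    digits = NA)

  assoc <- stage("associate", association_triangle(cohort, sig))
  assoc_json <- lapply(assoc$models, function(m) {
    if (is.null(m)) return(NULL)
    list(label = m$label, chosen_degree = m$chosen_degree,
         marginal_r2_linear = unname(m$marginal_r2["linear"]),
         marginal_r2_quadratic = unname(m$marginal_r2["quadratic"]),
         near_independent = m$near_independent)
  })
  jsonlite::write_json(assoc_json, file.path(out_dir, "association.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "ctradiomics",
    version = as.character(utils::packageVersion("ctradiomics")),
    seed = cfg$seed, sim_seed = cfg$sim_config$seed,
    null_seed = cfg$null_config$seed,
    fdr_level = cfg$fdr_level, n_random = cfg$n_random,
    n_null_datasets = cfg$null_config$n_datasets,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, screen = screen_raw,
                 screen_volume = screen_adj, selection = sel,
                 signature = sig, nulltest = nulltest,
                 association = assoc, manifest = manifest,
                 out_dir = out_dir))
}

# Transform + z-score the named feature columns.
.standardized_features <- function(cohort, feature_names, registry) {
  Z <- vapply(feature_names, function(nm) {
    sp <- .registry_spec(registry, nm)
    sp$zscore <- TRUE; sp$mean <- NA_real_; sp$sd <- NA_real_
    apply_transform(cohort[[nm]], sp, nm)$values
  }, numeric(nrow(cohort)))
  colnames(Z) <- feature_names
  Z
}
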