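#' Token exclusion report
#'
#' @param n_recorded,n_excluded token counts (0 <= excluded <= recorded).
#' @return List with `pct_excluded` (percentage, one decimal) and
#'   `n_retained`.
#' @export
exclusion_report <- function(n_recorded, n_excluded) {
  if (n_recorded < 0 || n_excluded < 0) stop("counts must be non-negative")
  if (n_excluded > n_recorded) stop("cannot exclude more tokens than recorded")
  list(pct_excluded = round(100 * n_excluded / n_recorded, 1),
       n_retained = n_recorded - n_excluded)
}

#' Run the full measure-evaluation pipeline
#'
#' Orchestrates the four analysis strands over a dataset (supplied or
#' simulated): per-token measure extraction; per-speaker MDS ordination
#' with stress summary; the 64-pair Procrustes residual sweep; the 64-pair
#' speaker-held-out classification sweep with optional mixed-logistic error
#' model; and the within-speaker-scaled correlation analyses.  All
#' artifacts are written as CSV under `out_dir` together with a JSON run
#' manifest (configuration hash, seeds, row counts), and reruns with the
#' same inputs are byte-identical.
#'
#' @param dataset a [tongue_dataset()]; if `NULL`, a cohort is simulated
#'   from `config`.
#' @param config a [cohort_config()] used when `dataset` is `NULL`.
#' @param out_dir output directory (created if needed).
#' @param mds_variant `"nonmetric"` or `"classical"`.
#' @param n_reps classification resampling replicates (default 100).
#' @param error_model_reps replicates (out of `n_reps`) whose trials feed
#'   the error model; 0 skips the model.
#' @param allow_reflection,symmetric Procrustes options.
#' @param seed master seed for ordination restarts and classification
#'   splits.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_all <- function(dataset = NULL, config = cohort_config(),
                    out_dir = tempfile("tonguespace_run_"),
                    mds_variant = "nonmetric", n_reps = 100L,
                    error_model_reps = 5L, allow_reflection = TRUE,
                    symmetric = TRUE, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if (is.null(dataset)) {
    sim <- stage("simulate", generate_cohort(config))
    dataset <- sim$dataset
    truth <- sim$truth
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  n_tokens <- length(dataset$contours)

  measures <- stage("measures", measure_table(dataset))
  write_measures(measures, file.path(out_dir, "measures.csv"))

  ords <- stage("ordinate",
                ordinate_speakers(dataset, variant = mds_variant,
                                  seed = seed))
  ord_tab <- dplyr::bind_rows(lapply(ords, function(o)
    tibble::tibble(speaker = o$speaker, token = o$tokens,
                   MDS1 = o$coords[, 1], MDS2 = o$coords[, 2],
                   stress = o$stress)))
  utils::write.csv(ord_tab, file.path(out_dir, "ordination.csv"),
                   row.names = FALSE)
  stress <- stress_summary(ords)
  utils::write.csv(stress, file.path(out_dir, "stress_summary.csv"),
                   row.names = FALSE)

  sweep_ss <- stage("sweep-procrustes",
                    combo_sweep(measures, ords,
                                allow_reflection = allow_reflection,
                                symmetric = symmetric))
  utils::write.csv(as.data.frame(sweep_ss),
                   file.path(out_dir, "procrustes_sweep.csv"),
                   row.names = FALSE)

  scaled <- stage("scale", scale_within_speaker(measures))
  keep_trials <- error_model_reps > 0L
  sweep_acc <- stage("sweep-lda",
                     sweep_accuracy(scaled, n_reps = n_reps, seed = seed,
                                    keep_trials = keep_trials))
  utils::write.csv(as.data.frame(sweep_acc),
                   file.path(out_dir, "lda_accuracy.csv"),
                   row.names = FALSE)

  emod <- NULL
  if (keep_trials) {
    trials <- attr(sweep_acc, "trials")
    trials <- trials[trials$replicate <= error_model_reps, ]
    emod <- stage("error-model", fit_error_model(trials))
    utils::write.csv(
      tibble::tibble(term = names(emod$coefficients),
                     estimate = unname(emod$coefficients)),
      file.path(out_dir, "error_model.csv"), row.names = FALSE)
  }

  mm <- stage("correlate-means", speaker_item_means(scaled))
  corr <- stage("correlate", correlation_table(mm))
  utils::write.csv(as.data.frame(round(corr$r, 6)),
                   file.path(out_dir, "correlation_matrix.csv"))
  fcorr <- NULL
  if (!is.null(dataset$formants)) {
    fsc <- scale_within_speaker(
      dplyr::inner_join(
        dataset$formants,
        tibble::tibble(speaker = vapply(dataset$contours, `[[`, "", "speaker"),
                       token = vapply(dataset$contours, `[[`, "", "token"),
                       vowel = vapply(dataset$contours, `[[`, "", "vowel")),
        by = c("speaker", "token")),
      cols = c("f1_hz", "f2_hz"))
    fmeans <- speaker_item_means(fsc, vars = c("f1_hz", "f2_hz"))
    fcorr <- stage("correlate-formants", formant_correlations(mm, fmeans))
    utils::write.csv(fcorr$f1, file.path(out_dir, "formant_f1.csv"),
                     row.names = FALSE)
    utils::write.csv(fcorr$f2, file.path(out_dir, "formant_f2.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tonguespace")),
    seed = seed, mds_variant = mds_variant, n_reps = n_reps,
    error_model_reps = error_model_reps,
    allow_reflection = allow_reflection, symmetric = symmetric,
    simulated = !is.null(truth),
    config_hash = if (!is.null(truth)) config_hash(config) else NULL,
    n_tokens = n_tokens,
    n_speakers = length(ords),
    n_measure_rows = nrow(measures),
    n_degenerate = sum(measures$degenerate),
    stress_median = stress$median,
    stress_upper_quartile = stress$upper_quartile)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(dataset = dataset, truth = truth, measures = measures,
                 ordinations = ords, stress = stress,
                 procrustes = sweep_ss, accuracy = sweep_acc,
                 error_model = emod, correlations = corr,
                 formant_correlations = fcorr,
                 out_dir = out_dir, manifest = manifest))
}

# md5 of the serialised configuration (text serialisation for stability)
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(unclass(config), file = tf)
  unname(tools::md5sum(tf))
}
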