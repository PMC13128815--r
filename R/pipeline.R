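#' Windowing + normalization for one trial
#'
#' Segments an aligned bundle with the model configuration's window length
#' and stride, then z-scores the predictor channels.  When `stats` is
#' `NULL` the statistics are fitted on this trial (training use); pass the
#' training statistics when preparing test trials.
#'
#' @param bundle A `recording_bundle`.
#' @param cfg A [model_config()].
#' @param stats Optional `norm_stats` from the training trial.
#' @return List with `ws` (normalized `window_set`) and `stats`.
#' @export
prepare_windows <- function(bundle, cfg, stats = NULL) {
  ws <- segment_windows(bundle, cfg$window_len, cfg$stride,
                        label = cfg$label)
  if (is.null(stats)) stats <- fit_normalizer(ws)
  list(ws = apply_normalizer(ws, stats), stats = stats)
}

#' Train on one trial and evaluate on held-out trials
#'
#' The canonical per-subject protocol: fit the normalizer and the model on
#' the training bundle, then score every test bundle with the training
#' statistics.
#'
#' @param train_bundle Training `recording_bundle`.
#' @param test_bundles Named list of test `recording_bundle`s.
#' @param cfg A [model_config()].
#' @param verbose Print epoch losses.
#' @return List with `model` (trained, with `loss_history`), `report`
#'   (an `evaluation_report`), `stats`.
#' @export
run_experiment <- function(train_bundle, test_bundles, cfg,
                           verbose = FALSE) {
  prep <- prepare_windows(train_bundle, cfg)
  model <- build_variant(cfg, n_channels = dim(prep$ws$windows)[3])
  model <- train_model(model, prep$ws, verbose = verbose)
  test_ws <- lapply(test_bundles, function(b)
    prepare_windows(b, cfg, stats = prep$stats)$ws)
  list(model = model, report = evaluate_model(model, test_ws),
       stats = prep$stats)
}

#' Ablation ladder over model variants
#'
#' Trains the requested variants on identical data for each seed and
#' aggregates the test metrics per variant, target and metric with mean
#' and standard deviation across seeds.
#'
#' @param train_bundle,test_bundles As in [run_experiment()].
#' @param cfg Base [model_config()]; the `variant` and `seed` fields are
#'   overridden per run.
#' @param variants Character vector of variants (default all five).
#' @param seeds Integer vector of seeds.
#' @return A data.frame with columns `variant`, `target`, `metric`,
#'   `mean`, `sd`, `n_seeds`.
#' @export
run_ablation <- function(train_bundle, test_bundles, cfg,
                         variants = c("I", "II", "III", "IV", "V"),
                         seeds = cfg$seed) {
  rows <- list()
  for (v in variants) {
    per_seed <- lapply(seeds, function(s) {
      cfg_v <- cfg; cfg_v$variant <- v; cfg_v$seed <- as.integer(s)
      attr(run_experiment(train_bundle, test_bundles, cfg_v)$report,
           "aggregates")
    })
    targets <- per_seed[[1]]$target
    for (tg in targets)
      for (met in c("vaf", "rmse", "r2")) {
        vals <- vapply(per_seed, function(a)
          a[a$target == tg, paste0(met, "_mean")], 0)
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, target = tg, metric = met,
          mean = mean(vals),
          sd = if (length(vals) > 1L) stats::sd(vals) else 0,
          n_seeds = length(vals), stringsAsFactors = FALSE)
      }
  }
  do.call(rbind, rows)
}
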