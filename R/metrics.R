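#' Root mean square error
#'
#' `sqrt(mean((p - p_hat)^2))`, in the units of the inputs (N·m for
#' moments).
#'
#' @param p Actual values.
#' @param p_hat Predicted values, same length.
#' @return Nonnegative scalar.
#' @export
rmse <- function(p, p_hat) {
  if (length(p) != length(p_hat) || length(p) == 0L)
    stop("rmse: inputs must have equal nonzero length", call. = FALSE)
  sqrt(mean((p - p_hat)^2))
}

#' Coefficient of determination
#'
#' `1 - sum((p - p_hat)^2) / sum((p - mean(p))^2)`.
#'
#' @inheritParams rmse
#' @return Scalar <= 1.
#' @export
r_squared <- function(p, p_hat) {
  if (length(p) != length(p_hat) || length(p) < 2L)
    stop("r_squared: inputs must have equal length >= 2", call. = FALSE)
  den <- sum((p - mean(p))^2)
  if (den <= 0)
    stop("r_squared: actual values are constant (zero variance)",
         call. = FALSE)
  1 - sum((p - p_hat)^2) / den
}

#' Variance accounted for
#'
#' `1 - var(p_hat - p) / var(p)` with the population variance (divisor N).
#' Because the variance of the residual ignores its mean, VAF is invariant
#' to a constant prediction offset, unlike R²; the two coincide exactly
#' when the residual has zero mean.
#'
#' @inheritParams rmse
#' @return Scalar <= 1.
#' @export
vaf <- function(p, p_hat) {
  if (length(p) != length(p_hat) || length(p) < 2L)
    stop("vaf: inputs must have equal length >= 2", call. = FALSE)
  pvar <- function(x) mean((x - mean(x))^2)
  den <- pvar(p)
  if (den <= 0)
    stop("vaf: actual values are constant (zero variance)", call. = FALSE)
  1 - pvar(p_hat - p) / den
}

# round half away from zero to `digits` decimals (base round() is
# round-half-even, which would print 20.25 -> 20.2)
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Body mass index
#'
#' `mass / (height/100)^2`, rounded half-away-from-zero to one decimal.
#'
#' @param mass Body mass in kg (> 0).
#' @param height Height in cm (> 0).
#' @return BMI value rounded to one decimal.
#' @export
bmi <- function(mass, height) {
  if (any(mass <= 0) || any(height <= 0))
    stop("mass and height must be positive", call. = FALSE)
  round_half_up(mass / (height / 100)^2, 1L)
}

#' BMI weight category
#'
#' Classifies a (1-decimal) BMI value: below 18.5 underweight, 18.5-24.9
#' normal weight, 25-29.9 overweight, 30 and above obese.
#'
#' @param value BMI value(s) as returned by [bmi()].
#' @return Character vector of categories.
#' @export
bmi_category <- function(value) {
  cut(value, breaks = c(-Inf, 18.5 - 1e-9, 25 - 1e-9, 30 - 1e-9, Inf),
      labels = c("Underweight", "Normal weight", "Overweight", "Obese"),
      right = FALSE) |> as.character()
}

#' Train/test split protocols
#'
#' Two schemes mirror the published protocols: for treadmill gait the
#' lowest trial id (lexicographic order) trains and the remaining trials
#' test (`first_trial_train_rest_test`); for level-ground and ramp gait a
#' chronological 80/20 split of a single trace is used (`fraction_80_20`,
#' no shuffling, since gait data are autocorrelated).
#'
#' @param scheme `"first_trial_train_rest_test"` or `"fraction_80_20"`.
#' @param trial_ids Ordered character vector of trial ids (first scheme
#'   needs at least 2).
#' @return A `split_protocol` list; for the first scheme it carries
#'   `train_ids` and `test_ids`.
#' @export
split_protocol <- function(scheme = c("first_trial_train_rest_test",
                                      "fraction_80_20"),
                           trial_ids = character()) {
  scheme <- match.arg(scheme)
  out <- list(scheme = scheme, trial_ids = trial_ids)
  if (scheme == "first_trial_train_rest_test") {
    if (length(trial_ids) < 2L)
      stop("first_trial_train_rest_test needs at least 2 trials",
           call. = FALSE)
    ord <- sort(trial_ids)
    out$train_ids <- ord[1L]
    out$test_ids <- ord[-1L]
  } else {
    out$train_fraction <- 0.8
  }
  structure(out, class = "split_protocol")
}

#' Chronological fraction split of a window set
#'
#' @param ws A `window_set`.
#' @param train_fraction Fraction of windows (in time order) used for
#'   training (default 0.8).
#' @return List with `train` and `test` window sets.
#' @export
split_windows_fraction <- function(ws, train_fraction = 0.8) {
  stopifnot(inherits(ws, "window_set"))
  n <- dim(ws$windows)[1]
  n_train <- floor(n * train_fraction)
  if (n_train < 1L || n_train >= n)
    stop("fraction split leaves an empty train or test set", call. = FALSE)
  take <- function(i) {
    out <- ws
    out$windows <- ws$windows[i, , , drop = FALSE]
    out$targets <- ws$targets[i, , drop = FALSE]
    out
  }
  list(train = take(seq_len(n_train)),
       test = take((n_train + 1L):n))
}

#' Evaluate a trained model on test trials
#'
#' Computes RMSE, R² and VAF per test trial and target, then aggregates
#' with mean and sample standard deviation (divisor n-1; 0 by convention
#' for a single test trial) across trials.
#'
#' @param model A trained `lstam_model`.
#' @param test_trials Named list of normalized `window_set`s, one per test
#'   trial.
#' @return An `evaluation_report`: data.frame with columns `trial`,
#'   `target`, `rmse`, `r2`, `vaf`, with the aggregate mean/sd table in
#'   attribute `aggregates` and the seed in attribute `seed`.
#' @export
evaluate_model <- function(model, test_trials) {
  stopifnot(inherits(model, "lstam_model"), is.list(test_trials),
            length(test_trials) >= 1L)
  if (is.null(names(test_trials)) || any(!nzchar(names(test_trials))))
    names(test_trials) <- sprintf("trial%02d", seq_along(test_trials))
  rows <- list()
  for (tr in names(test_trials)) {
    ws <- test_trials[[tr]]
    pred <- predict(model, ws)
    tn <- ws$target_names
    if (is.null(tn)) tn <- sprintf("target%d", seq_len(ncol(pred)))
    for (k in seq_len(ncol(pred)))
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr, target = tn[k],
        rmse = rmse(ws$targets[, k], pred[, k]),
        r2 = r_squared(ws$targets[, k], pred[, k]),
        vaf = vaf(ws$targets[, k], pred[, k]),
        stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(rep, rep$target), function(d)
    data.frame(target = d$target[1],
               rmse_mean = mean(d$rmse),
               rmse_sd = if (nrow(d) > 1L) stats::sd(d$rmse) else 0,
               r2_mean = mean(d$r2),
               r2_sd = if (nrow(d) > 1L) stats::sd(d$r2) else 0,
               vaf_mean = mean(d$vaf),
               vaf_sd = if (nrow(d) > 1L) stats::sd(d$vaf) else 0,
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(rep, aggregates = agg, seed = model$cfg$seed,
            class = c("evaluation_report", "data.frame"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Per-trial metrics:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("\nAggregates (mean ± sd across test trials):\n")
  a <- attr(x, "aggregates")
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-10s VAF %.3f ± %.3f  RMSE %.3f ± %.3f  R2 %.3f ± %.3f\n",
                a$target[i], a$vaf_mean[i], a$vaf_sd[i],
                a$rmse_mean[i], a$rmse_sd[i], a$r2_mean[i], a$r2_sd[i]))
  invisible(x)
}
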