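#' Channel descriptor
#'
#' Describes one column of a multichannel biosignal recording: its name, its
#' role in the regression (predictor EMG envelope, predictor joint angle, or
#' target joint moment), and free-text units.
#'
#' @param name Nonempty channel name, e.g. `"gluteus_medius"`.
#' @param kind One of `"emg"`, `"angle"`, `"moment"`.
#' @param units Free-text units string (e.g. `"mV"`, `"deg"`, `"N·m"`).
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, kind = c("emg", "angle", "moment"),
                         units = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("channel name must be a nonempty string", call. = FALSE)
  kind <- match.arg(kind)
  structure(list(name = name, kind = kind, units = units),
            class = "channel_spec")
}

#' Multichannel uniformly sampled biosignal recording
#'
#' Bundles a numeric sample matrix (time in rows, channels in columns) with
#' per-channel metadata and a sampling rate.  Rows containing any
#' non-finite value are dropped at construction time; the number of dropped
#' rows is kept in the `dropped` attribute and reported via [message()].
#'
#' @param samples Numeric matrix, `n_time x n_channels`.
#' @param channels List of [channel_spec()] objects, one per column.
#' @param rate Sampling frequency in Hz (> 0).
#' @param subject_id,trial_id Optional identifier strings.
#' @return An object of class `signal_recording` with fields `samples`,
#'   `channels`, `rate`, `subject_id`, `trial_id`.
#' @export
signal_recording <- function(samples, channels, rate,
                             subject_id = "", trial_id = "") {
  if (!is.matrix(samples)) samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.list(channels) || !all(vapply(channels, inherits, TRUE,
                                        "channel_spec")))
    stop("channels must be a list of channel_spec objects", call. = FALSE)
  if (ncol(samples) != length(channels))
    stop("samples must have exactly one column per channel", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)", call. = FALSE)
  keep <- rowSums(!is.finite(samples)) == 0L
  dropped <- sum(!keep)
  if (dropped > 0L) {
    samples <- samples[keep, , drop = FALSE]
    message(sprintf("signal_recording: dropped %d row(s) with non-finite values",
                    dropped))
  }
  if (nrow(samples) < 1L)
    stop("recording has zero usable rows after dropping non-finite rows",
         call. = FALSE)
  colnames(samples) <- vapply(channels, `[[`, "", "name")
  structure(list(samples = samples, channels = channels, rate = rate,
                 subject_id = subject_id, trial_id = trial_id,
                 dropped = dropped),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  kinds <- vapply(x$channels, `[[`, "", "kind")
  cat(sprintf("<signal_recording> %d samples x %d channels @ %g Hz\n",
              nrow(x$samples), length(x$channels), x$rate))
  cat(sprintf("  channels: %s\n",
              paste(sprintf("%s[%s]", colnames(x$samples), kinds),
                    collapse = ", ")))
  if (nzchar(x$subject_id) || nzchar(x$trial_id))
    cat(sprintf("  subject: %s  trial: %s\n", x$subject_id, x$trial_id))
  invisible(x)
}

channel_kinds <- function(rec) vapply(rec$channels, `[[`, "", "kind")

#' Read a delimited-table recording
#'
#' Reads a CSV file with a header row and assembles a [signal_recording()]
#' from the mapped columns, in the order given by `channel_map`.  Rows with
#' any non-finite value in a mapped column are dropped and counted.
#'
#' @param path Path to a CSV file.
#' @param channel_map Named list mapping column names to [channel_spec()]
#'   objects; the output channel order follows the order of this list.
#' @param rate Sampling frequency in Hz of the stored signal.
#' @param subject_id,trial_id Optional identifiers attached to the result.
#' @return A [signal_recording()].
#' @export
read_table_recording <- function(path, channel_map, rate,
                                 subject_id = "", trial_id = "") {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  missing_cols <- setdiff(names(channel_map), names(tab))
  if (length(missing_cols) > 0L)
    stop(sprintf("column(s) missing from %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  mat <- as.matrix(tab[, names(channel_map), drop = FALSE])
  storage.mode(mat) <- "double"
  if (nrow(mat) == 0L || all(rowSums(!is.finite(mat)) > 0L))
    stop(sprintf("no usable rows in %s", path), call. = FALSE)
  signal_recording(mat, unname(channel_map), rate,
                   subject_id = subject_id, trial_id = trial_id)
}

#' Write a recording as a CSV fixture
#'
#' Emits the same CSV dialect [read_table_recording()] consumes (comma
#' separated, `.` decimal mark, `\n` line endings, header row), with values
#' printed at 15 significant digits so that a write/read round trip
#' preserves samples to well below 1e-9.
#'
#' @param rec A [signal_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(colnames(rec$samples), collapse = ",")
  body <- apply(rec$samples, 1L, function(row)
    paste(formatC(row, digits = 15, format = "g"), collapse = ","))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Decimate a recording by sample dropping
#'
#' Keeps every k-th sample, where `k = step_ms * rate / 1000`, starting at
#' sample 1 (phase 0).  This is pure sample dropping: no anti-alias filter
#' is applied unless `lowpass = TRUE`, in which case a length-k moving
#' average is applied before dropping.
#'
#' @param rec A [signal_recording()].
#' @param step_ms New sample period in milliseconds; must correspond to an
#'   integer decimation factor.
#' @param lowpass Apply a length-k moving-average filter before dropping
#'   samples (default `FALSE`).
#' @return A [signal_recording()] at `1000 / step_ms` Hz.
#' @export
decimate <- function(rec, step_ms, lowpass = FALSE) {
  stopifnot(inherits(rec, "signal_recording"))
  if (!is.numeric(step_ms) || length(step_ms) != 1L || step_ms <= 0)
    stop("step_ms must be a positive scalar", call. = FALSE)
  k <- step_ms * rec$rate / 1000
  if (abs(k - round(k)) > 1e-9 || round(k) < 1)
    stop(sprintf("step_ms %g is not an integer multiple of the sample period (%g ms)",
                 step_ms, 1000 / rec$rate), call. = FALSE)
  k <- as.integer(round(k))
  samples <- rec$samples
  if (lowpass && k > 1L) {
    kern <- rep(1 / k, k)
    samples <- apply(samples, 2L, function(x)
      stats::filter(x, kern, sides = 1)[seq_along(x)])
    samples[seq_len(k - 1L), ] <- rec$samples[seq_len(k - 1L), ]
  }
  idx <- seq.int(1L, nrow(samples), by = k)
  signal_recording(samples[idx, , drop = FALSE], rec$channels,
                   rate = 1000 / step_ms,
                   subject_id = rec$subject_id, trial_id = rec$trial_id)
}

decimate_by_factor <- function(rec, k) {
  decimate(rec, step_ms = 1000 * k / rec$rate)
}

#' Align predictor and target recordings into a bundle
#'
#' Brings two recordings to a common rate (the faster one is decimated by
#' the integer rate ratio) and truncates both to the common length.
#'
#' @param predictors [signal_recording()] holding EMG and angle channels.
#' @param targets [signal_recording()] holding moment channels.
#' @return A `recording_bundle` with fields `predictors`, `targets`,
#'   `aligned` (always `TRUE` on success).
#' @export
align_bundle <- function(predictors, targets) {
  stopifnot(inherits(predictors, "signal_recording"),
            inherits(targets, "signal_recording"))
  if (predictors$rate != targets$rate) {
    ratio <- max(predictors$rate, targets$rate) /
      min(predictors$rate, targets$rate)
    if (abs(ratio - round(ratio)) > 1e-9)
      stop(sprintf("rates %g and %g Hz differ by a non-integer factor",
                   predictors$rate, targets$rate), call. = FALSE)
    ratio <- as.integer(round(ratio))
    if (predictors$rate > targets$rate)
      predictors <- decimate_by_factor(predictors, ratio)
    else
      targets <- decimate_by_factor(targets, ratio)
  }
  n <- min(nrow(predictors$samples), nrow(targets$samples))
  trunc_rec <- function(rec) {
    if (nrow(rec$samples) == n) return(rec)
    signal_recording(rec$samples[seq_len(n), , drop = FALSE], rec$channels,
                     rec$rate, rec$subject_id, rec$trial_id)
  }
  structure(list(predictors = trunc_rec(predictors),
                 targets = trunc_rec(targets), aligned = TRUE),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> aligned=%s, %d samples @ %g Hz, %d predictor / %d target channel(s)\n",
              x$aligned, nrow(x$predictors$samples), x$predictors$rate,
              length(x$predictors$channels), length(x$targets$channels)))
  invisible(x)
}

#' Load a nested subject/date/mode/sensor table directory
#'
#' Walks a directory tree organised as `subject/date/mode/sensor/*.csv`
#' (the layout used by public gait biomechanics repositories that store
#' per-trial tables) and reads every file matching the glob into a list of
#' recordings, one per trial file.  Tables for the same trial are expected
#' to live in one file per sensor group.
#'
#' @param root Root directory.
#' @param channel_map As in [read_table_recording()].
#' @param rate Sampling frequency of the stored tables (Hz).
#' @param subject,date,mode,sensor Glob components (default `"*"`).
#' @return Named list of [signal_recording()]s, names are paths relative to
#'   `root`.
#' @export
read_nested_recordings <- function(root, channel_map, rate,
                                   subject = "*", date = "*",
                                   mode = "*", sensor = "*") {
  if (!dir.exists(root))
    stop(sprintf("directory not found: %s", root), call. = FALSE)
  files <- Sys.glob(file.path(root, subject, date, mode, sensor, "*.csv"))
  if (length(files) == 0L)
    stop("no CSV files matched the subject/date/mode/sensor glob",
         call. = FALSE)
  out <- lapply(files, function(f) {
    parts <- strsplit(sub(paste0("^", root, "/?"), "", f), "/")[[1]]
    read_table_recording(f, channel_map, rate,
                         subject_id = parts[1],
                         trial_id = sub("\\.csv$", "", basename(f)))
  })
  names(out) <- sub(paste0("^", normalizePath(root), "/?"), "",
                    normalizePath(files))
  out
}
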