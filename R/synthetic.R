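#' Synthetic gait-signal configuration
#'
#' Describes a stated world of quasi-periodic gait at ~1 Hz: four
#' burst-like nonnegative EMG envelopes phase-locked to the gait cycle
#' (gluteus medius, semitendinosus, biceps femoris, rectus femoris), two
#' smooth two-harmonic joint angles (hip adduction, hip flexion), and two
#' moments (Hip FE, Hip AA) produced by a known mapping: a linear angle
#' term, an electromechanically delayed muscle-pair envelope difference,
#' and a small quadratic angle term.  Defaults are clean (no noise, no
#' spikes); corruption is opt-in via `noise_sigma` / `spike_rate`.
#'
#' @param duration_s Trace length in seconds.
#' @param rate Sampling frequency in Hz (default 200).
#' @param gait_freq Mean gait cycle frequency in Hz (default 1.0).
#' @param gait_jitter Relative per-cycle frequency jitter (default 0.03).
#' @param activation_centers Gait-phase centers in `[0, 1)` of the four
#'   muscle activation bursts.
#' @param activation_widths Phase widths of the bursts.
#' @param angle_harmonics List of two `amp` / `phase` pairs per angle
#'   (two harmonics of the gait cycle each); amplitudes in degrees.
#' @param moment_map Named list (one entry per moment) with fields
#'   `angle` (source angle name), `a` (linear angle gain, N·m/deg),
#'   `b` (envelope-difference gain, N·m), `q` (quadratic angle gain,
#'   N·m/deg²), `emg_pos`, `emg_neg` (muscle pair).
#' @param delay_ms Electromechanical delay of the envelope term in
#'   milliseconds (default 50 ms = 10 samples at 200 Hz).
#' @param noise_sigma Relative high-frequency noise level on the
#'   predictors (and, scaled by 0.1, observation noise on the moments).
#' @param spike_rate Transient spike artifacts per second on the
#'   predictors.
#' @param seed Integer seed; all randomness flows from it through fixed
#'   per-channel substream offsets.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(duration_s = 16, rate = 200, gait_freq = 1.0,
                             gait_jitter = 0.03,
                             activation_centers = c(gluteus_medius = 0.05,
                                                    semitendinosus = 0.85,
                                                    biceps_femoris = 0.90,
                                                    rectus_femoris = 0.35),
                             activation_widths = rep(0.08, 4),
                             angle_harmonics = list(
                               hip_adduction = list(amp = c(6, 2),
                                                    phase = c(0.0, 0.9)),
                               hip_flexion = list(amp = c(18, 6),
                                                  phase = c(-0.4, 0.7))),
                             moment_map = list(
                               hip_fe = list(angle = "hip_flexion",
                                             a = 0.35, b = 8, q = 0.01,
                                             emg_pos = "biceps_femoris",
                                             emg_neg = "rectus_femoris"),
                               hip_aa = list(angle = "hip_adduction",
                                             a = 0.5, b = 6, q = 0.02,
                                             emg_pos = "gluteus_medius",
                                             emg_neg = "semitendinosus")),
                             delay_ms = 50, noise_sigma = 0,
                             spike_rate = 0, seed = 1L) {
  if (duration_s <= 0 || rate <= 0 || gait_freq <= 0)
    stop("duration_s, rate and gait_freq must be positive", call. = FALSE)
  if (noise_sigma < 0 || spike_rate < 0)
    stop("noise_sigma and spike_rate must be >= 0", call. = FALSE)
  if (length(activation_centers) != 4L || length(activation_widths) != 4L)
    stop("exactly four muscle activation centers/widths are expected",
         call. = FALSE)
  structure(list(duration_s = duration_s, rate = rate,
                 gait_freq = gait_freq, gait_jitter = gait_jitter,
                 activation_centers = activation_centers,
                 activation_widths = activation_widths,
                 angle_harmonics = angle_harmonics,
                 moment_map = moment_map, delay_ms = delay_ms,
                 noise_sigma = noise_sigma, spike_rate = spike_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# wrapped distance on the unit circle of phase
phase_dist <- function(phi, center) {
  d <- abs(phi %% 1 - center)
  pmin(d, 1 - d)
}

# Piecewise-linear gait phase: cycle c has its own frequency
# gait_freq * (1 + jitter_c); phase is a deterministic function of absolute
# time given the jitter draws, so sample grids at different rates agree.
make_phase_fun <- function(cfg) {
  set.seed(cfg$seed)
  n_cycles <- ceiling(cfg$duration_s * cfg$gait_freq *
                        (1 + cfg$gait_jitter)) + 3L
  jit <- stats::runif(n_cycles, -cfg$gait_jitter, cfg$gait_jitter)
  durs <- 1 / (cfg$gait_freq * (1 + jit))
  bounds <- c(0, cumsum(durs))
  function(t) {
    cyc <- pmin(pmax(findInterval(t, bounds), 1L), n_cycles)
    neg <- t < 0                       # extrapolate before t=0 with cycle 1
    cyc[neg] <- 1L
    (cyc - 1) + (t - bounds[cyc]) / durs[cyc]
  }
}

envelope_at <- function(cfg, phi) {
  sapply(seq_along(cfg$activation_centers), function(m)
    exp(-0.5 * (phase_dist(phi, cfg$activation_centers[m]) /
                  cfg$activation_widths[m])^2))
}

angles_at <- function(cfg, phi) {
  sapply(cfg$angle_harmonics, function(h)
    h$amp[1] * sin(2 * pi * phi + h$phase[1]) +
      h$amp[2] * sin(4 * pi * phi + h$phase[2]))
}

moments_from_components <- function(cfg, angles, env_delayed) {
  muscles <- names(cfg$activation_centers)
  sapply(cfg$moment_map, function(mm) {
    ang <- angles[, mm$angle]
    dpair <- env_delayed[, match(mm$emg_pos, muscles)] -
      env_delayed[, match(mm$emg_neg, muscles)]
    mm$a * ang + mm$b * dpair + mm$q * ang^2
  })
}

#' Generate a synthetic gait recording bundle
#'
#' Produces a noisy predictor/target bundle, a clean (noise- and
#' artifact-free) copy, and the deterministic ground-truth components
#' (gait phase, activation envelopes, angles, clean moments) from which
#' the known moment mapping can be replayed exactly.  EMG channels are the
#' activation envelope times a rectified seeded Gaussian broadband
#' carrier; they are everywhere nonnegative in the clean copy.  With
#' `noise_sigma = 0` and `spike_rate = 0` the noisy and clean bundles are
#' identical.
#'
#' @param cfg A [synthetic_config()].
#' @return A `synthetic_recording` list: `bundle` (possibly corrupted),
#'   `clean` (clean bundle), `components` (list with `time`, `phase`,
#'   `envelopes`, `envelopes_delayed`, `angles`, `moments_clean`), `cfg`.
#' @export
generate_gait <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- round(cfg$duration_s * cfg$rate)
  t <- (seq_len(n) - 1) / cfg$rate
  phase_fun <- make_phase_fun(cfg)
  phi <- phase_fun(t)
  env <- envelope_at(cfg, phi)
  env_del <- envelope_at(cfg, phase_fun(t - cfg$delay_ms / 1000))
  ang <- angles_at(cfg, phi)
  mom <- moments_from_components(cfg, ang, env_del)
  muscles <- names(cfg$activation_centers)
  colnames(env) <- colnames(env_del) <- muscles
  # rectified broadband carriers, one seeded substream per muscle
  emg <- matrix(0, n, 4L)
  for (m in seq_len(4L)) {
    set.seed(cfg$seed + 100L + m)
    emg[, m] <- env[, m] * abs(stats::rnorm(n))
  }
  # seeded observation noise on the moments, one substream per target
  mom_obs <- mom
  if (cfg$noise_sigma > 0) {
    for (k in seq_len(ncol(mom))) {
      set.seed(cfg$seed + 200L + k)
      mom_obs[, k] <- mom[, k] +
        stats::rnorm(n, sd = 0.1 * cfg$noise_sigma * stats::sd(mom[, k]))
    }
  }
  pred_channels <- c(lapply(muscles, channel_spec, kind = "emg",
                            units = "mV"),
                     lapply(names(cfg$angle_harmonics), channel_spec,
                            kind = "angle", units = "deg"))
  targ_channels <- lapply(names(cfg$moment_map), channel_spec,
                          kind = "moment", units = "N·m")
  pred_clean <- signal_recording(cbind(emg, ang), pred_channels, cfg$rate,
                                 trial_id = "synthetic")
  targ <- signal_recording(mom_obs, targ_channels, cfg$rate,
                           trial_id = "synthetic")
  pred_noisy <- if (cfg$noise_sigma > 0 || cfg$spike_rate > 0)
    corrupt_recording(pred_clean, cfg$noise_sigma, cfg$spike_rate,
                      seed = cfg$seed + 300L,
                      cutoff_hz = 10 * cfg$gait_freq)
  else pred_clean
  targ_clean <- signal_recording(mom, targ_channels, cfg$rate,
                                 trial_id = "synthetic")
  structure(list(bundle = align_bundle(pred_noisy, targ),
                 clean = align_bundle(pred_clean, targ_clean),
                 components = list(time = t, phase = phi, envelopes = env,
                                   envelopes_delayed = env_del,
                                   angles = ang, moments_clean = mom),
                 cfg = cfg),
            class = "synthetic_recording")
}

#' Corrupt a recording with high-frequency noise and spike artifacts
#'
#' Adds (a) band-limited Gaussian noise restricted to frequencies at or
#' above `cutoff_hz` (10x the gait frequency by default, i.e. half of
#' `gait_freq * 20`), scaled to `noise_sigma` times each channel's
#' standard deviation, and (b) Poisson-placed single-sample spikes of
#' amplitude 5x the channel standard deviation.  Intended for predictor
#' channels; targets are never corrupted by [generate_gait()].
#'
#' @param rec A [signal_recording()].
#' @param noise_sigma Relative noise level (0 disables).
#' @param spike_rate Expected spikes per second (0 disables).
#' @param seed Integer seed.
#' @param cutoff_hz High-pass cutoff of the noise band in Hz.
#' @return The corrupted [signal_recording()].
#' @export
corrupt_recording <- function(rec, noise_sigma, spike_rate, seed,
                              cutoff_hz = 10) {
  stopifnot(inherits(rec, "signal_recording"))
  if (noise_sigma == 0 && spike_rate == 0) return(rec)
  n <- nrow(rec$samples)
  duration <- n / rec$rate
  freqs <- (seq_len(n) - 1) * rec$rate / n
  keep_bin <- pmin(freqs, rec$rate - freqs) >= cutoff_hz
  samples <- rec$samples
  set.seed(seed)
  for (ch in seq_len(ncol(samples))) {
    sdv <- stats::sd(samples[, ch])
    if (noise_sigma > 0 && any(keep_bin)) {
      w <- stats::rnorm(n)
      W <- stats::fft(w)
      W[!keep_bin] <- 0
      hp <- Re(stats::fft(W, inverse = TRUE)) / n
      hp <- hp / stats::sd(hp)
      samples[, ch] <- samples[, ch] + noise_sigma * sdv * hp
    }
    if (spike_rate > 0) {
      n_spk <- stats::rpois(1L, spike_rate * duration)
      if (n_spk > 0) {
        pos <- sample.int(n, n_spk, replace = TRUE)
        samples[pos, ch] <- samples[pos, ch] + 5 * sdv
      }
    }
  }
  signal_recording(samples, rec$channels, rec$rate, rec$subject_id,
                   rec$trial_id)
}

#' Replay the known moment mapping (idealized oracle)
#'
#' Recomputes the moments from the clean ground-truth components with the
#' configured mapping — the idealized regressor that knows the generating
#' equations.  Used to certify that the mapping is learnable and the
#' metric wiring is sound (VAF >= 0.99 against the stored targets on clean
#' data).
#'
#' @param gen A `synthetic_recording` from [generate_gait()].
#' @return Matrix `(n_time, n_moments)` of oracle moment predictions.
#' @export
oracle_moments <- function(gen) {
  stopifnot(inherits(gen, "synthetic_recording"))
  moments_from_components(gen$cfg, gen$components$angles,
                          gen$components$envelopes_delayed)
}

#' Write a synthetic bundle as CSV fixtures with a JSON sidecar
#'
#' Emits `predictors.csv`, `targets.csv`, `predictors_clean.csv`,
#' `targets_clean.csv` in the package CSV dialect plus `ground_truth.json`
#' recording the full generator configuration (mapping coefficients, seed,
#' rates).
#'
#' @param gen A `synthetic_recording`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixture <- function(gen, dir) {
  stopifnot(inherits(gen, "synthetic_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_recording_csv(gen$bundle$predictors,
                      file.path(dir, "predictors.csv"))
  write_recording_csv(gen$bundle$targets, file.path(dir, "targets.csv"))
  write_recording_csv(gen$clean$predictors,
                      file.path(dir, "predictors_clean.csv"))
  write_recording_csv(gen$clean$targets,
                      file.path(dir, "targets_clean.csv"))
  jsonlite::write_json(unclass(gen$cfg),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
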