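# Ground-truthed synthetic data: microstate-structured EEG,
# heartbeat-locked (BCG-like) artifact trains, periodic gradient-like
# artifacts, carbon-wire-loop channels, and twin-session cohorts with
# known true reliability. Every generator is a pure function of
# (config, seed).

#' Synthetic-data configuration
#'
#' Defaults describe a 32-channel, 250 Hz recording with four microstate
#' generators of 80 ms mean dwell time, a ~1 Hz heartbeat with 50 ms RR
#' jitter, and BCG components delayed 0.21 s after the R-peak (so the
#' artifact falls inside a -0.2/+0.5 s epoch around the peak).
#'
#' @param n_channels number of EEG channels (default 32).
#' @param rate sampling rate in Hz (default 250).
#' @param duration_s recording length in seconds (default 60).
#' @param k_templates number of microstate generators, 2-8 (default 4).
#' @param mean_state_duration_ms mean microstate dwell time, scalar or one
#'   value per template (default 80).
#' @param state_duration_cv coefficient of variation of the gamma dwell
#'   distribution (default 0.4; 0 gives constant dwells).
#' @param signal_amp_uv mean GFP amplitude of the microstate signal
#'   (default 10).
#' @param noise_sd_uv sensor-noise standard deviation (default 2).
#' @param heart_rate_hz mean heartbeat rate (default 1.0).
#' @param rr_jitter_sd_s SD of the RR-interval jitter in s (default 0.05).
#' @param n_bcg_components number of BCG spatial components (default 3).
#' @param bcg_snr BCG-to-signal RMS amplitude ratio; 0 disables the
#'   artifact (default 0).
#' @param bcg_delay_s delay of the BCG waveform after the R-peak
#'   (default 0.21).
#' @param ga_period_s period of the gradient-like artifact in s, or
#'   `NULL` for none.
#' @param ga_amplitude_uv gradient-artifact amplitude (default 200).
#' @param cwl_coupling coupling gain of motion artifact into EEG (adds two
#'   CWL channels tracking the motion source), or `NULL` for none.
#' @param seed RNG seed (mandatory).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_channels = 32L, rate = 250, duration_s = 60,
                         k_templates = 4L, mean_state_duration_ms = 80,
                         state_duration_cv = 0.4, signal_amp_uv = 10,
                         noise_sd_uv = 2, heart_rate_hz = 1.0,
                         rr_jitter_sd_s = 0.05, n_bcg_components = 3L,
                         bcg_snr = 0, bcg_delay_s = 0.21,
                         ga_period_s = NULL, ga_amplitude_uv = 200,
                         cwl_coupling = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(rate > 0, duration_s > 0, k_templates >= 2, k_templates <= 8,
            all(mean_state_duration_ms > 0), heart_rate_hz > 0)
  structure(as.list(environment()), class = "synth_config")
}

# quasi-uniform sensor positions on the upper hemisphere (deterministic)
hemisphere_positions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - i / n)             # polar angle, top half only
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta),
        z = cos(phi))
}

#' Generate smooth microstate template maps
#'
#' Smooth, average-referenced, unit-GFP maps built from random
#' combinations of linear and quadratic functions of the sensor
#' positions; rejection-sampled until all pairwise absolute correlations
#' are below 0.5.
#'
#' @param n_channels number of channels (k must be < n_channels).
#' @param k number of maps.
#' @param seed RNG seed.
#' @param positions optional channels x 3 position matrix (default:
#'   deterministic hemisphere layout).
#' @return k x n_channels matrix of maps.
#' @export
make_templates <- function(n_channels, k, seed, positions = NULL) {
  if (k > n_channels - 1L) stop("k must be at most n_channels - 1")
  if (is.null(positions)) positions <- hemisphere_positions(n_channels)
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  basis <- cbind(x, y, z, x * y, x * z, y * z, x^2 - y^2, 2 * z^2 - x^2 - y^2)
  with_seed(seed, {
    for (attempt in seq_len(500L)) {
      coef <- matrix(stats::rnorm(8L * k), nrow = 8L)
      maps <- t(basis %*% coef)
      maps <- maps - rowMeans(maps)
      maps <- maps / sqrt(rowMeans(maps^2))
      cc <- abs(stats::cor(t(maps)))
      if (max(cc[upper.tri(cc)]) < 0.5) return(maps)
    }
    stop("could not sample ", k, " maps with pairwise |corr| < 0.5")
  })
}

#' Simulate a microstate label sequence
#'
#' Semi-Markov chain: per-visit dwell times are gamma distributed with
#' the configured mean and CV; the next state is uniform over the other
#' k - 1 templates (no self-transitions).
#'
#' @param cfg a [synth_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return Integer vector of per-sample template indices.
#' @export
simulate_state_sequence <- function(cfg, seed = cfg$seed) {
  n <- as.integer(round(cfg$duration_s * cfg$rate))
  k <- cfg$k_templates
  mu <- rep(cfg$mean_state_duration_ms, length.out = k) / 1000 * cfg$rate
  cv <- cfg$state_duration_cv
  with_seed(seed, {
    lab <- integer(n)
    pos <- 1L
    state <- sample.int(k, 1L)
    while (pos <= n) {
      d <- if (cv <= 0) mu[state]
           else stats::rgamma(1L, shape = 1 / cv^2, scale = mu[state] * cv^2)
      d <- max(1L, as.integer(round(d)))
      lab[pos:min(n, pos + d - 1L)] <- state
      pos <- pos + d
      nxt <- sample.int(k - 1L, 1L)
      state <- setdiff(seq_len(k), state)[nxt]
    }
    lab
  })
}

# Rectified low-pass noise: a plausible GFP envelope. The 20 Hz
# bandwidth yields peaks every ~25 ms, the rate seen for band-limited
# (2-20 Hz) EEG, so every microstate visit contains GFP peaks.
gfp_envelope <- function(n, rate, mean_amp) {
  lp <- signal::butter(2, min(0.45, 20 / (rate / 2)), type = "low")
  e <- abs(signal::filtfilt(lp, stats::rnorm(n)))
  e * (mean_amp / mean(e))
}

bcg_waveform <- function(T_samp, rate, f_hz, tau_s) {
  t <- (seq_len(T_samp) - 1L) / rate
  sin(2 * pi * f_hz * t) * exp(-t / tau_s)
}

#' Simulate one recording with ground truth
#'
#' EEG = dwell-labeled template topographies modulated by a rectified
#' low-pass GFP envelope, plus white sensor noise; optionally plus a
#' heartbeat-locked BCG train (fixed random spatial patterns times
#' stereotyped damped-oscillation waveforms, delayed `bcg_delay_s` after
#' each jittered R-peak and scaled to `bcg_snr` times the signal RMS),
#' a periodic gradient-like artifact with volume-trigger events, and
#' carbon-wire-loop channels tracking a motion source that also leaks
#' into the EEG.
#'
#' @param cfg a [synth_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @param template_seed seed of the template maps (default `seed`); a
#'   cohort shares one template set by fixing this across subjects.
#' @return List with `recording` (events: `"R"` = R-peaks, `"V"` = volume
#'   triggers) and `truth` (state labels, R-peak samples, BCG patterns
#'   and waveforms, template maps, positions).
#' @export
simulate_recording <- function(cfg, seed = cfg$seed,
                               template_seed = seed) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- as.integer(round(cfg$duration_s * cfg$rate))
  C <- cfg$n_channels
  positions <- hemisphere_positions(C)
  templates <- make_templates(C, cfg$k_templates, seed = template_seed,
                              positions = positions)
  lab <- simulate_state_sequence(cfg, seed = seed + 1L)
  out <- with_seed(seed + 2L, {
    env <- gfp_envelope(n, cfg$rate, cfg$signal_amp_uv)
    eeg <- t(templates[lab, , drop = FALSE]) *
      rep(env, each = C)                                  # C x n
    sig_rms <- sqrt(mean(eeg^2))
    eeg <- eeg + matrix(stats::rnorm(C * n, sd = cfg$noise_sd_uv), C, n)

    # heartbeat train with jittered RR intervals
    rr <- numeric(0); t_cur <- stats::runif(1, 0.2, 1 / cfg$heart_rate_hz)
    while (t_cur < cfg$duration_s) {
      rr <- c(rr, t_cur)
      t_cur <- t_cur + max(0.35, 1 / cfg$heart_rate_hz +
                             stats::rnorm(1, sd = cfg$rr_jitter_sd_s))
    }
    r_peaks <- as.integer(round(rr * cfg$rate)) + 1L
    r_peaks <- r_peaks[r_peaks >= 1L & r_peaks <= n]

    bcg_patterns <- NULL; bcg_wave <- NULL
    if (cfg$bcg_snr > 0 && cfg$n_bcg_components > 0) {
      nb <- cfg$n_bcg_components
      # artifact topographies follow the field/head geometry, which is
      # broadly stereotyped: tie them to the template seed so a cohort
      # shares them (amplitude and beat timing stay subject-specific)
      bcg_patterns <- with_seed(template_seed + 500L,
                                matrix(stats::rnorm(nb * C), nb, C))
      bcg_patterns <- bcg_patterns - rowMeans(bcg_patterns)
      bcg_patterns <- bcg_patterns / sqrt(rowMeans(bcg_patterns^2))
      # the artifact spans most of the cardiac cycle, like real BCG
      Tw <- as.integer(round(0.85 * cfg$rate))
      bcg_wave <- t(vapply(seq_len(nb), function(i)
        bcg_waveform(Tw, cfg$rate, f_hz = 2 + 2 * i, tau_s = 0.3),
        numeric(Tw)))
      src <- matrix(0, nb, n)
      d <- as.integer(round(cfg$bcg_delay_s * cfg$rate))
      for (p in r_peaks) {
        i0 <- p + d
        if (i0 >= 1L && i0 + Tw - 1L <= n) {
          amp <- 1 + 0.1 * stats::rnorm(nb)   # slight beat-to-beat variation
          src[, i0:(i0 + Tw - 1L)] <- src[, i0:(i0 + Tw - 1L)] +
            amp * bcg_wave
        }
      }
      bcg <- t(bcg_patterns) %*% src
      bcg <- bcg * (cfg$bcg_snr * sig_rms / max(sqrt(mean(bcg^2)), 1e-12))
      eeg <- eeg + bcg
    }

    v_trig <- integer(0)
    if (!is.null(cfg$ga_period_s)) {
      per <- as.integer(round(cfg$ga_period_s * cfg$rate))
      v_trig <- seq(1L, n - per + 1L, by = per)
      ga_shape <- cfg$ga_amplitude_uv *
        (2 * ((seq_len(per) - 1) / per) - 1)              # sawtooth
      ga_pat <- stats::rnorm(C); ga_pat <- 1 + 0.2 * ga_pat / max(abs(ga_pat))
      for (s in v_trig)
        eeg[, s:(s + per - 1L)] <- eeg[, s:(s + per - 1L)] +
          outer(ga_pat, ga_shape)
    }

    ch_names <- paste0("E", seq_len(C))
    ch_types <- rep("eeg", C)
    data <- eeg
    if (!is.null(cfg$cwl_coupling)) {
      lp <- signal::butter(2, min(0.45, 8 / (cfg$rate / 2)), type = "low")
      motion <- signal::filtfilt(lp, stats::rnorm(n)) * 20
      m_pat <- stats::rnorm(C); m_pat <- m_pat / sqrt(mean(m_pat^2))
      data <- data + cfg$cwl_coupling * outer(m_pat, motion)
      cwl <- rbind(motion + stats::rnorm(n, sd = 0.5),
                   c(0, motion[-n]) + stats::rnorm(n, sd = 0.5))
      data <- rbind(data, cwl)
      ch_names <- c(ch_names, "CWL1", "CWL2")
      ch_types <- c(ch_types, "cwl", "cwl")
      positions_full <- rbind(positions, matrix(0, 2, 3))
    } else positions_full <- positions

    ev <- data.frame(
      sample = c(r_peaks, v_trig),
      label = c(rep("R", length(r_peaks)), rep("V", length(v_trig))))
    rec <- recording(data, rate = cfg$rate, ch_names = ch_names,
                     ch_types = ch_types, events = ev,
                     positions = positions_full,
                     log = sprintf("simulate_recording(seed=%d)", seed))
    list(recording = rec,
         truth = list(state_labels = lab, r_peaks = r_peaks,
                      bcg_patterns = bcg_patterns, bcg_waveforms = bcg_wave,
                      template_maps = templates, positions = positions,
                      seed = seed))
  })
  out
}

#' Simulate a twin-session cohort with known true reliability
#'
#' Per-template subject effects on the mean dwell time are drawn as
#' `mu_subj = mu_pop + N(0, sigma_b^2)` and per-session values as
#' `mu_sess = mu_subj + N(0, sigma_w^2)`, with the variance split chosen
#' so `sigma_b^2 / (sigma_b^2 + sigma_w^2) = icc_target`. Each session is
#' then simulated independently given its dwell means; all subjects share
#' one template set (same generator seed).
#'
#' @param cfg a [synth_config()] (its `mean_state_duration_ms` is the
#'   population mean; its `seed` seeds the cohort).
#' @param n_subjects number of subjects.
#' @param icc_target true intraclass correlation in `[0, 1)`.
#' @param n_sessions sessions per subject (default 2).
#' @param sigma_total_ms total SD of the per-type dwell means across
#'   subject-sessions (default 20).
#' @param bcg_snr_sessions optional per-session BCG amplitude ratios
#'   (default: `cfg$bcg_snr` for all sessions).
#' @return List with `sessions` (list of lists of
#'   [simulate_recording()] results, `sessions[[s]][[subject]]`) and
#'   `truth` (per-subject, per-session dwell-mean matrices).
#' @export
simulate_cohort <- function(cfg, n_subjects, icc_target, n_sessions = 2L,
                            sigma_total_ms = 20,
                            bcg_snr_sessions = NULL) {
  stopifnot(inherits(cfg, "synth_config"),
            icc_target >= 0, icc_target < 1)
  if (is.null(bcg_snr_sessions))
    bcg_snr_sessions <- rep(cfg$bcg_snr, n_sessions)
  k <- cfg$k_templates
  sb <- sqrt(icc_target) * sigma_total_ms
  sw <- sqrt(1 - icc_target) * sigma_total_ms
  mu_pop <- rep(cfg$mean_state_duration_ms, length.out = k)
  eff <- with_seed(cfg$seed, {
    subj <- matrix(stats::rnorm(n_subjects * k, sd = sb), n_subjects, k)
    sess <- array(stats::rnorm(n_subjects * k * n_sessions, sd = sw),
                  dim = c(n_subjects, k, n_sessions))
    # heartbeat/artifact strength differs between people
    snr_mult <- stats::runif(n_subjects, 0.6, 1.4)
    list(subj = subj, sess = sess, snr_mult = snr_mult)
  })
  mu <- array(0, dim = c(n_subjects, k, n_sessions))
  for (s in seq_len(n_sessions))
    mu[, , s] <- pmax(30, rep(mu_pop, each = n_subjects) +
                        eff$subj + eff$sess[, , s])
  sessions <- lapply(seq_len(n_sessions), function(s) {
    lapply(seq_len(n_subjects), function(i) {
      cfg_i <- cfg
      cfg_i$mean_state_duration_ms <- mu[i, , s]
      cfg_i$bcg_snr <- bcg_snr_sessions[s] * eff$snr_mult[i]
      simulate_recording(cfg_i, seed = cfg$seed + 1000L * s + 10L * i,
                         template_seed = cfg$seed)
    })
  })
  list(sessions = sessions,
       truth = list(dwell_means = mu, icc_target = icc_target,
                    sigma_between = sb, sigma_within = sw))
}
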