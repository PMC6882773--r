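# Synthetic paired neural/audio sessions with a known, tunable coupling
# between a latent articulatory trajectory, the audio it drives, and the
# high-gamma band amplitude of each neural channel.  Makes every stage of
# the decoder and evaluation stack testable without patient data.

.DEFAULT_INVENTORY <- c(
  "bat", "bed", "big", "bog", "bud", "cat", "cod", "cup", "dig", "dog",
  "fan", "fig", "gut", "hat", "hid", "hop", "jam", "kit", "lap", "mud")

# Region-wise readout strength of the latent trajectory: ventral motor
# cortex carries the most articulatory information, premotor intermediate,
# inferior frontal least, other channels almost none.
.REGION_GAIN <- c(M1v = 1.0, PMv = 0.6, IFG = 0.3, OTHER = 0.1)

#' Configuration for a synthetic session
#'
#' Defaults emulate the reference recording setup: a 64-channel grid at
#' 2 kHz over IFG/PMv/M1v with some channels outside the regions of
#' interest, 48 kHz audio, one mostly-CVC word every 2 s, and a word
#' inventory in which every label recurs so that repeated words are
#' acoustically similar across tokens.
#'
#' @param n_words number of word tokens to produce.
#' @param n_channels total neural channels; must equal `sum(region_plan)`.
#' @param neural_rate neural sampling rate, Hz.
#' @param audio_rate audio sampling rate, Hz.
#' @param word_period word pacing in seconds (one word per period).
#' @param word_inventory labels cycled over tokens.
#' @param coupling latent-to-neural coupling strength in `[0, 1]`: 0 means
#'   the neural data carry no speech information, 1 full modulation.
#' @param noise_sd standard deviation of additive broadband neural noise.
#' @param region_plan named channel counts per region.
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @return object of class `b2s_simconfig`.
#' @export
sim_config <- function(n_words = 30,
                       n_channels = 64,
                       neural_rate = 2000,
                       audio_rate = 48000,
                       word_period = 2.0,
                       word_inventory = .DEFAULT_INVENTORY,
                       coupling = 1.0,
                       noise_sd = 0.3,
                       region_plan = c(IFG = 12, PMv = 20, M1v = 18,
                                       OTHER = 14),
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "b2s_simconfig")
  if (cfg$coupling < 0 || cfg$coupling > 1) stop("coupling must be in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_words < 1) stop("n_words must be >= 1")
  if (sum(cfg$region_plan) != cfg$n_channels)
    stop("region_plan counts (", sum(cfg$region_plan),
         ") must sum to n_channels (", cfg$n_channels, ")")
  if (!all(names(cfg$region_plan) %in% REGIONS))
    stop("region_plan names must be among ", paste(REGIONS, collapse = ", "))
  cfg
}

#' Latent articulatory trajectory of a word
#'
#' Four smooth latent dimensions (two formant tracks, a voicing amplitude
#' and a pitch track) built from a short low-order random Fourier series
#' at 200 Hz.  The shape is a deterministic function of `(label, seed)`
#' only, so repeated tokens of the same word are acoustically similar —
#' the property cross-validated decoding relies on.
#'
#' @param label word label.
#' @param duration trajectory duration in seconds.
#' @param seed base seed; the label is hashed into it.
#' @return matrix (time x 4) sampled at 200 Hz.
#' @export
word_trajectory <- function(label, duration, seed = 1) {
  stopifnot(duration > 0)
  n <- max(2L, round(duration * 200))
  u <- seq(0, 1, length.out = n)
  .with_seed(.subseed(seed, paste0("word:", label)), {
    traj <- vapply(1:4, function(d) {
      x <- numeric(n)
      for (h in 1:3) {
        amp <- rnorm(1, sd = 1 / h)
        phs <- runif(1, 0, 2 * pi)
        x <- x + amp * cos(pi * h * u + phs)
      }
      x
    }, numeric(n))
    traj
  })
}

# Raised-cosine on/off amplitude ramp over a token.
.word_envelope <- function(n, ramp_frac = 0.15) {
  r <- max(2L, round(n * ramp_frac))
  env <- rep(1, n)
  env[1:r] <- 0.5 - 0.5 * cos(pi * (0:(r - 1)) / (r - 1))
  env[(n - r + 1):n] <- rev(env[1:r])
  env
}

# Formant-style token audio at `rate` from a latent trajectory: three
# frequency-modulated partials (pitch + two formants) under a voicing
# envelope.  Not intelligible speech; word-specific, repeatable
# spectrotemporal structure is all the evaluation needs.
.synth_token_audio <- function(traj, duration, rate) {
  n <- round(duration * rate)
  up <- function(v) stats::approx(seq_along(v), v, n = n)$y
  f0 <- 120 + 25 * tanh(up(traj[, 4]))
  f1 <- 500 + 250 * tanh(up(traj[, 1]))
  f2 <- 1500 + 700 * tanh(up(traj[, 2]))
  amp <- (0.55 + 0.35 * tanh(up(traj[, 3]))) * .word_envelope(n)
  ph <- function(f) 2 * pi * cumsum(f) / rate
  x <- amp * (0.5 * sin(ph(f0)) + 0.8 * sin(ph(f1)) + 0.5 * sin(ph(f2)))
  0.45 * x / max(abs(x))
}

#' Generate a paired synthetic neural/audio session
#'
#' Audio: each word token is synthesized by a small formant-style
#' generator driven by that word's latent trajectory ([word_trajectory()]),
#' with silence between words.  Neural: each channel is 70–170 Hz
#' band-limited noise whose amplitude is modulated by a channel-specific
#' linear readout of the same latent trajectory, scaled by `coupling`,
#' plus independent broadband noise of sd `noise_sd` and a slow linear
#' drift.  M1v channels receive the strongest readout weights, PMv
#' intermediate, IFG weakest.  The whole construction is a deterministic
#' function of the config, including the seed.
#'
#' @param config a `b2s_simconfig` from [sim_config()].
#' @return a validated `b2s_session`.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "b2s_simconfig"))
  cfg <- config
  dur <- cfg$n_words * cfg$word_period
  n_na <- round(dur * cfg$audio_rate)
  n_nn <- round(dur * cfg$neural_rate)

  .with_seed(.subseed(cfg$seed, "session"), {
    labels <- sample(rep(cfg$word_inventory, length.out = cfg$n_words))
    word_dur <- pmin(0.64, pmax(0.52, 0.58 + rnorm(cfg$n_words, sd = 0.02)))
    onsets <- (seq_len(cfg$n_words) - 1) * cfg$word_period + 0.55 +
      runif(cfg$n_words, -0.04, 0.04)
    words <- data.frame(label = labels, onset = onsets,
                        offset = onsets + word_dur)

    # per-token latent trajectories (word-specific shape + small jitter)
    trajs <- lapply(seq_len(cfg$n_words), function(i) {
      tr <- word_trajectory(labels[i], word_dur[i], cfg$seed)
      tr * (1 + matrix(rnorm(4, sd = 0.05), nrow(tr), 4, byrow = TRUE))
    })

    # ---- audio track -------------------------------------------------
    audio <- numeric(n_na)
    for (i in seq_len(cfg$n_words)) {
      tok <- .synth_token_audio(trajs[[i]], word_dur[i], cfg$audio_rate)
      a <- round(onsets[i] * cfg$audio_rate) + 1L
      audio[a:(a + length(tok) - 1L)] <- tok
    }
    audio <- audio + rnorm(n_na, sd = 2e-4)   # mic noise floor

    # ---- session-long latent at the neural rate ----------------------
    Z <- matrix(0, 4, n_nn)
    for (i in seq_len(cfg$n_words)) {
      a <- round(onsets[i] * cfg$neural_rate) + 1L
      b <- min(n_nn, a + round(word_dur[i] * cfg$neural_rate) - 1L)
      env <- .word_envelope(b - a + 1L)
      for (d in 1:4)
        Z[d, a:b] <- env * stats::approx(seq_len(nrow(trajs[[i]])),
                                         trajs[[i]][, d], n = b - a + 1L)$y
    }

    # ---- neural channels ---------------------------------------------
    plan <- cfg$region_plan
    regions <- rep(names(plan), times = plan)
    ch_names <- unlist(lapply(names(plan), function(r)
      sprintf("%s_%d", r, seq_len(plan[[r]]))), use.names = FALSE)
    bp <- signal::butter(4, c(70, 170) / (cfg$neural_rate / 2), "pass")
    active <- colSums(abs(Z)) > 0
    neural <- matrix(0, cfg$n_channels, n_nn)
    tt <- seq_len(n_nn) / n_nn
    for (ch in seq_len(cfg$n_channels)) {
      w <- rnorm(4); w <- w / sqrt(sum(w^2))
      readout <- drop(w %*% Z)
      s_act <- sd(readout[active])
      if (is.finite(s_act) && s_act > 0)
        readout <- readout / s_act * 0.5 * .REGION_GAIN[[regions[ch]]]
      env <- pmax(0.05, 1 + cfg$coupling * readout)
      carrier <- signal::filtfilt(bp, rnorm(n_nn))
      neural[ch, ] <- carrier * env + rnorm(n_nn, sd = cfg$noise_sd) +
        0.3 * tt                                 # slow drift, removed by detrend
    }
    rownames(neural) <- ch_names

    session(neural, cfg$neural_rate, audio, cfg$audio_rate,
            channels = data.frame(name = ch_names, region = regions),
            words = words,
            session_id = sprintf("sim-seed%d-c%g", cfg$seed, cfg$coupling))
  })
}
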