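# 2-D Gaussian topography over montage positions, unit-normalized
.topo <- function(montage, cx, cy, s) {
  g <- exp(-((montage$x - cx)^2 + (montage$y - cy)^2) / (2 * s^2))
  g / sqrt(sum(g^2))
}

#' Forward model mapping latent signals to scalp channels
#'
#' Defines unit-normalized spatial weight vectors for each simulated component:
#' opposite-polarity posterior-midline C1 patterns for upper- vs lower-field
#' stimulation (with a slight topographic shift between them, so their
#' difference has a positive and a negative pole), a centroparietal pattern for
#' the accumulation signal (CPP), left/right occipital patterns for
#' lateralized alpha, a frontal pattern for blinks, and the 1/f background
#' noise spectrum.
#'
#' @param montage a [make_montage()] layout.
#' @param noise_spectrum_exponent 1/f slope of background noise power.
#' @param noise_theta relative amplitude of the ongoing mid-band (theta)
#'   component of the background spectrum, a Gaussian bump at 6 Hz. Real EEG
#'   carries substantial ongoing rhythmic power between the screening bands;
#'   without it the drift/muscle band-power ratios are unstable.
#' @param noise_rms background noise RMS per channel (uV).
#' @param artifact_injection list of per-trial injection probabilities and
#'   amplitudes for blink/drift/muscle artifacts (used when
#'   `simulate_eeg(..., artifacts = TRUE)`).
#' @return object of class `forward_model`.
#' @export
forward_model <- function(montage = make_montage(),
                          noise_spectrum_exponent = 1,
                          noise_theta = 0.6,
                          noise_rms = 5,
                          artifact_injection = list(
                            blink_prob = 0.06, blink_amp = 150,
                            drift_prob = 0.04, drift_amp = 30,
                            muscle_prob = 0.04, muscle_amp = 12)) {
  gA <- .topo(montage, 0.05, -0.62, 0.22)   # inferior posterior midline
  gB <- .topo(montage, -0.05, -0.30, 0.25)  # superior posterior midline
  c1_lower <- gA - 0.45 * gB
  c1_upper <- -(0.85 * gA - 0.35 * gB)      # opposite polarity, shifted
  norm1 <- function(v) v / sqrt(sum(v^2))
  fm <- list(
    montage = montage,
    c1_topography_upper = norm1(c1_upper),
    c1_topography_lower = norm1(c1_lower),
    cpp_topography      = .topo(montage, 0, -0.25, 0.28),
    alpha_topography_left  = .topo(montage, -0.5, -0.55, 0.25),
    alpha_topography_right = .topo(montage,  0.5, -0.55, 0.25),
    blink_topography    = .topo(montage, 0, 0.9, 0.35),
    vep_topography      = .topo(montage, 0, -0.5, 0.4),
    noise_spectrum_exponent = noise_spectrum_exponent,
    noise_theta = noise_theta,
    noise_rms = noise_rms,
    artifact_injection = artifact_injection)
  if (sum(fm$c1_topography_upper * fm$c1_topography_lower) >= 0)
    .fail("C1 topographies must have negative inner product")
  class(fm) <- "forward_model"
  fm
}

# EEG background noise, n series of length len (columns), unit variance:
# 1/f^a plus an ongoing mid-band (theta) bump, synthesized by spectrally
# shaping white noise (circular)
pink_noise <- function(len, n, exponent, fs, theta = 0) {
  nf <- len %/% 2L
  f <- seq_len(nf) * fs / len
  amp <- f^(-exponent / 2) + theta * exp(-(f - 6)^2 / 8)
  shape <- c(0, amp, rev(amp[seq_len(len - nf - 1L)]))  # zero DC, Hermitian
  w <- stats::mvfft(matrix(stats::rnorm(len * n), len, n))
  x <- Re(stats::mvfft(w * shape, inverse = TRUE)) / len
  x / sqrt(sum(shape^2) / len)
}

# raised-cosine bump centred at c, half-width w (ms)
.bump <- function(t, c, w) ifelse(abs(t - c) < w, 0.5 * (1 + cos(pi * (t - c) / w)), 0)

#' Simulate multichannel EEG epochs for a trial table
#'
#' Generates target-locked epochs containing, per trial: (i) a C1 transient at
#' 80-90 ms whose signed source amplitude is the generative `c1_true` (stimulus
#' contrast difference plus the early-evidence noise shared with the decision,
#' i.e. choice probability by construction); (ii) a centroparietal ramp whose
#' slope is evidence-dependent from `params$late_latency` onward and which
#' peaks at the response; (iii) pre-target 10 Hz alpha whose amplitude is
#' lower over the hemisphere contralateral to the upcoming choice; (iv) a
#' choice-history modulation of C1 amplitude congruent with the previous
#' choice; (v) 1/f background noise; and optionally injected blink / drift /
#' muscle artifacts with ground-truth labels.
#'
#' @param fm a [forward_model()].
#' @param trials a trial table from [simulate_behaviour()] (needs `target`,
#'   `choice`, `rt_ms`, `c1_true`, `evidence_upper`; `prev_choice` for the
#'   history modulation).
#' @param params the [observer_params()] used to generate `trials` (latencies).
#' @param fs sampling rate, >= 256 Hz (default 512).
#' @param span epoch span in ms, half-open (default c(-600, 400)).
#' @param c1_scale uV of scalp C1 (bipolar source units) per unit `c1_true`.
#' @param cpp_slope_base,cpp_slope_gain CPP source slope (uV/ms):
#'   `base + gain * |evidence|` after the late latency.
#' @param alpha_amp,alpha_lat_gain pre-target alpha amplitude (uV) and its
#'   choice-predictive lateralized reduction.
#' @param vep_scale scaling of the common (target-evoked, choice-independent)
#'   P1/N1 complex; 0 removes it.
#' @param history_c1_gain uV of C1 modulation congruent with previous choice.
#' @param artifacts logical; inject artifacts with ground-truth labels.
#' @param seed integer seed.
#' @return an [epoch_set()]; `$meta$ground_truth` holds injected per-trial
#'   source amplitudes, the vEOG trace matrix (`veog`), per-trial gaze
#'   summaries, and the artifact label table.
#' @export
simulate_eeg <- function(fm, trials, params = observer_params(), fs = 512,
                         span = c(-600, 400), c1_scale = 1,
                         cpp_slope_base = 0.015, cpp_slope_gain = 0.25,
                         alpha_amp = 4, alpha_lat_gain = 1.5,
                         history_c1_gain = 0.15, vep_scale = 1,
                         artifacts = FALSE, seed = 1L) {
  stopifnot(inherits(fm, "forward_model"))
  if (fs < 256) .fail("fs must be >= 256 Hz")
  if (is.null(trials$rt_ms)) .fail("trials and stimuli misaligned: no rt_ms")
  set.seed(seed)
  n_tr <- nrow(trials); n_ch <- nrow(fm$montage)
  n_sp <- as.integer(round((span[2L] - span[1L]) * fs / 1000))
  off0 <- as.integer(round(span[1L] * fs / 1000))
  t_ms <- (off0 + seq_len(n_sp) - 1L) * 1000 / fs   # sample 0 = target onset
  labels <- fm$montage$label

  k_c1 <- .bump(t_ms, 85, 14)                       # C1 transient
  # stored topographies are unit-L2; for injection each is rescaled so the
  # peak channel carries weight 1, making amplitude parameters mean uV at the
  # peak electrode independent of montage size
  pk <- function(v) v / max(abs(v))
  topo_c1_diff <- pk(fm$c1_topography_lower - fm$c1_topography_upper)
  vep <- vep_scale * (2.5 * .bump(t_ms, 120, 30) - 2 * .bump(t_ms, 175, 35)) # common P1/N1

  prev_sign <- ifelse(is.na(trials$prev_choice), 0,
                      ifelse(trials$prev_choice == "upper", 1, -1))
  # history modulation is C1-congruent with the previous choice: an upper
  # previous choice pushes C1 in the upper-target (negative) direction
  c1_src <- c1_scale * trials$c1_true - history_c1_gain * prev_sign
  sat <- params$evidence_saturation %||% Inf
  ev_eff <- if (is.finite(sat)) sat * tanh(trials$evidence_upper / sat)
            else trials$evidence_upper
  slope <- cpp_slope_base + cpp_slope_gain * abs(ev_eff) *
    exp(rnorm(n_tr, 0, 0.1))
  choice_up <- trials$choice == "upper"

  x <- array(0, dim = c(n_tr, n_ch, n_sp))
  alpha_env <- ifelse(t_ms < 0, 1, pmax(0.3, 1 - t_ms / 250))
  topo_vep <- pk(fm$vep_topography); topo_cpp <- pk(fm$cpp_topography)
  topo_aL <- pk(fm$alpha_topography_left); topo_aR <- pk(fm$alpha_topography_right)
  vep_mat <- outer(topo_vep, vep)              # constant across trials
  c1_mat  <- outer(topo_c1_diff, k_c1)         # scaled per trial
  # batch the background-noise synthesis (FFTs amortize over trials)
  chunk <- 8L
  noise_at <- chunk                            # forces generation on first use
  noise_buf <- NULL
  for (i in seq_len(n_tr)) {
    m <- vep_mat + c1_src[i] * c1_mat
    ramp_t <- pmin(pmax(t_ms - params$late_latency, 0),
                   max(trials$rt_ms[i] - params$late_latency, 0))
    decay <- pmax(0, 1 - pmax(t_ms - trials$rt_ms[i], 0) / 150)
    m <- m + outer(topo_cpp, slope[i] * ramp_t * decay)
    phL <- stats::runif(1, 0, 2 * pi); phR <- stats::runif(1, 0, 2 * pi)
    aL <- alpha_amp - alpha_lat_gain * (!choice_up[i]) + stats::rnorm(1, 0, 0.3)
    aR <- alpha_amp - alpha_lat_gain * ( choice_up[i]) + stats::rnorm(1, 0, 0.3)
    osc <- alpha_env * sin(2 * pi * 10 * t_ms / 1000 + phL)
    oscR <- alpha_env * sin(2 * pi * 10 * t_ms / 1000 + phR)
    m <- m + outer(topo_aL, max(aL, 0) * osc) +
             outer(topo_aR, max(aR, 0) * oscR)
    if (noise_at == chunk) {
      noise_buf <- pink_noise(n_sp, n_ch * chunk, fm$noise_spectrum_exponent,
                              fs, fm$noise_theta %||% 0)
      noise_at <- 0L
    }
    cols <- (noise_at * n_ch + 1L):((noise_at + 1L) * n_ch)
    noise_at <- noise_at + 1L
    m <- m + t(noise_buf[, cols, drop = FALSE]) * fm$noise_rms
    x[i, , ] <- m
  }

  veog <- matrix(rnorm(n_tr * n_sp, 0, 3), n_tr, n_sp)
  gaze <- data.frame(trial = seq_len(n_tr),
                     saccade = rep(FALSE, n_tr),
                     gaze_dev_deg = abs(rnorm(n_tr, 0.15, 0.1)))
  art <- NULL
  if (artifacts) {
    aj <- fm$artifact_injection
    rows <- list()
    for (i in seq_len(n_tr)) {
      if (stats::runif(1) < aj$blink_prob) {
        c0 <- stats::runif(1, span[1L] + 120, span[2L] - 120)
        blink <- aj$blink_amp * .bump(t_ms, c0, 90)
        veog[i, ] <- veog[i, ] + blink
        x[i, , ] <- x[i, , ] + outer(pk(fm$blink_topography), 0.6 * blink)
        rows[[length(rows) + 1L]] <- data.frame(trial = i, channel = NA_character_,
          type = "blink", t_start_ms = c0 - 90, t_end_ms = c0 + 90)
      }
      if (stats::runif(1) < aj$drift_prob) {
        ch <- sample(n_ch, 1L)
        x[i, ch, ] <- x[i, ch, ] + aj$drift_amp *
          sin(2 * pi * stats::runif(1, 0.4, 1.2) * (t_ms - span[1L]) / 1000 +
              stats::runif(1, 0, 2 * pi))
        rows[[length(rows) + 1L]] <- data.frame(trial = i, channel = labels[ch],
          type = "drift", t_start_ms = span[1L], t_end_ms = span[2L])
      }
      if (stats::runif(1) < aj$muscle_prob) {
        ch <- sample(n_ch, 1L)
        f0 <- stats::runif(1, 22, 38)
        burst <- aj$muscle_amp * sin(2 * pi * f0 * t_ms / 1000 +
                                     stats::runif(1, 0, 2 * pi))
        x[i, ch, ] <- x[i, ch, ] + burst
        rows[[length(rows) + 1L]] <- data.frame(trial = i, channel = labels[ch],
          type = "muscle", t_start_ms = span[1L], t_end_ms = span[2L])
      }
    }
    art <- if (length(rows)) do.call(rbind, rows) else
      data.frame(trial = integer(0), channel = character(0), type = character(0),
                 t_start_ms = numeric(0), t_end_ms = numeric(0))
  }
  epoch_set(x, t_ms, fs, labels, align = "target",
            meta = list(seed = seed,
                        ground_truth = list(c1_source = c1_src, cpp_slope = slope,
                                            veog = veog, gaze = gaze,
                                            artifacts = art)))
}

#' Trial-level covariate generator with RT-band-limited C1-choice coupling
#'
#' A fast generator used to calibrate and validate the sliding-RT-window
#' machinery without synthesizing full EEG. For each of `n_participants`
#' simulated observers it draws response times, targets, previous choices and a
#' single-trial C1 amplitude (stimulus-driven plus noise), then generates
#' choices from a logistic model in which the C1 contributes *only* when the
#' trial's RT falls inside `band_ms`. Under `coupling = 0` the C1 is
#' conditionally independent of choice given the stimulus (a null
#' configuration).
#'
#' @param n_participants,trials_each sample sizes.
#' @param band_ms numeric length 2: RT band (ms) where the C1-choice coupling
#'   is active (default c(250, 380)).
#' @param coupling log-odds of an upper choice per SD of C1 inside the band
#'   (negative = choice-congruent C1, matching the physiological direction:
#'   more negative C1 for upper choices).
#' @param dc differential contrast (drives both the C1 and accuracy).
#' @param accuracy_band_ms RT band outside which accuracy is at chance
#'   (default c(200, Inf): above-chance accuracy only for RT > 200 ms).
#' @param acc_gain log-odds of a correct choice inside `accuracy_band_ms`.
#' @param seed integer seed.
#' @return a trial table with `participant`, `target`, `choice`, `rt_ms`,
#'   `correct`, `prev_choice`, `c1`, `deadline_ms`, `excluded`.
#' @export
simulate_windowed_coupling <- function(n_participants = 18L, trials_each = 1200L,
                                       band_ms = c(250, 380), coupling = -1,
                                       dc = 0.02, accuracy_band_ms = c(200, Inf),
                                       acc_gain = 0.5, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    n <- trials_each
    target <- sample(c("upper", "lower"), n, replace = TRUE)
    tsign <- ifelse(target == "upper", 1, -1)
    # RT: mixture of the two deadline regimes' distributions
    dl <- sample(c(400, 600), n, replace = TRUE)
    rt <- pmin(dl + 40, pmax(120, rnorm(n, ifelse(dl == 400, 260, 330), 75)))
    c1 <- -tsign * 2 * dc * 5 + rnorm(n, 0, 0.5)   # stimulus part + noise
    c1z <- (c1 - mean(c1)) / stats::sd(c1)
    in_band <- rt >= band_ms[1L] & rt <= band_ms[2L]
    in_acc <- rt >= accuracy_band_ms[1L] & rt <= accuracy_band_ms[2L]
    lp <- acc_gain * tsign * in_acc + coupling * c1z * in_band
    choice <- ifelse(stats::runif(n) < stats::plogis(lp), "upper", "lower")
    out[[p]] <- data.frame(participant = p, trial = seq_len(n), target = target,
                           choice = choice, rt_ms = rt,
                           correct = as.integer(choice == target),
                           prev_choice = c(NA_character_, choice[-n]),
                           c1 = c1, deadline_ms = dl, excluded = FALSE,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("trial_table", "data.frame")
  res
}
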