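#' Parameters of the two-stage accumulator observer
#'
#' The data-generating decision process is a bounded accumulator with two
#' evidence stages: a transient early sample delivered once at `early_latency`
#' (the stage whose noise is shared with the simulated C1, producing choice
#' probability by construction) and a sustained drift that switches on at
#' `late_latency`. The decision bound collapses linearly so that a response is
#' forced as the deadline approaches, and a Gaussian motor delay separates
#' bound crossing from the recorded response time. A start-point bias toward
#' switching away from the previous choice produces a choice-history effect
#' concentrated at fast response times.
#'
#' @param early_latency,late_latency ms; arrival of the transient early sample
#'   and onset of sustained evidence.
#' @param early_noise_sd,late_noise_sd evidence-noise SDs, in units of
#'   fractional contrast difference (the early one is trial-unique and shared
#'   with the C1; the late one is a per-trial drift perturbation).
#' @param evidence_saturation soft cap on the effective contrast-difference
#'   evidence, `sat * tanh(ev / sat)`: cortical contrast responses saturate,
#'   so the easy (dc = 0.30) blocks produce strong but not arbitrarily large
#'   evidence, keeping their response times in a realistic range.
#' @param shared_noise_gain coupling of the early evidence noise into simulated
#'   C1 amplitude (0 removes choice probability from the C1).
#' @param early_gain,late_gain accumulator units per unit contrast difference
#'   (late_gain per second).
#' @param diffusion_sd within-trial accumulator diffusion (units/sqrt(s)).
#' @param start_sd SD of Gaussian start-point variability (accumulator units);
#'   the source of fast guesses (chance-level fastest responses) and of errors
#'   being faster than correct responses.
#' @param bound decision bound at time 0 (accumulator units).
#' @param urgency_slope fractional collapse rate: the bound reaches zero at
#'   `(deadline - motor_delay_mean) / urgency_slope` ms.
#' @param motor_delay_mean,motor_delay_sd ms.
#' @param history_bias start-point offset away from the previous choice
#'   (accumulator units).
#' @param c1_gain scaling of stimulus contrast difference into C1 amplitude
#'   (uV per unit lower-minus-upper contrast).
#' @param seed integer seed.
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(early_latency = 80, late_latency = 150,
                            early_noise_sd = 0.06, late_noise_sd = 0.05,
                            evidence_saturation = 0.12,
                            shared_noise_gain = 25, early_gain = 2.2,
                            late_gain = 8, diffusion_sd = 0.5, start_sd = 0.65,
                            bound = 1, urgency_slope = 1,
                            motor_delay_mean = 100, motor_delay_sd = 20,
                            history_bias = 0.12, c1_gain = 12, seed = 1L) {
  p <- list(early_latency = early_latency, late_latency = late_latency,
            early_noise_sd = early_noise_sd, late_noise_sd = late_noise_sd,
            evidence_saturation = evidence_saturation,
            shared_noise_gain = shared_noise_gain, early_gain = early_gain,
            late_gain = late_gain, diffusion_sd = diffusion_sd,
            start_sd = start_sd, bound = bound, urgency_slope = urgency_slope,
            motor_delay_mean = motor_delay_mean, motor_delay_sd = motor_delay_sd,
            history_bias = history_bias, c1_gain = c1_gain,
            seed = as.integer(seed))
  if (p$early_latency < 0 || p$late_latency < 0) .fail("latencies must be >= 0")
  if (p$early_noise_sd < 0 || p$late_noise_sd < 0) .fail("noise SDs must be >= 0")
  class(p) <- "observer_params"
  p
}

#' Simulate choices and response times for a trial sequence
#'
#' Runs the two-stage accumulator (see [observer_params()]) over a sequence of
#' stimuli, sequentially so that the previous simulated choice feeds the
#' start-point switching bias.
#'
#' @param params an [observer_params()].
#' @param stimuli data.frame with at least columns `target` ("upper"/"lower")
#'   and `evidence_upper` (signed mean-contrast difference, upper minus lower),
#'   e.g. from [generate_session()].
#' @param deadline response deadline in ms (scalar, or taken per-trial from a
#'   `deadline_ms` column in `stimuli`).
#' @param dt_ms simulation step (default 2 ms).
#' @param seed integer seed; defaults to `params$seed`.
#' @return a trial table data.frame: `trial`, `target`, `choice`, `rt_ms`,
#'   `correct`, `prev_choice`, `deadline_ms`, plus the generative ground truth
#'   `eps_early` (shared early noise) and `c1_true` (noiseless C1 amplitude in
#'   uV, positive for lower-favouring evidence), with all columns of `stimuli`
#'   carried through.
#' @export
simulate_behaviour <- function(params, stimuli, deadline = NULL, dt_ms = 2,
                               seed = params$seed) {
  stopifnot(inherits(params, "observer_params"), nrow(stimuli) >= 1L)
  set.seed(seed)
  n <- nrow(stimuli)
  dl <- if (!is.null(deadline)) rep(deadline, length.out = n)
        else if (!is.null(stimuli$deadline_ms)) stimuli$deadline_ms
        else .fail("no deadline given and stimuli has no deadline_ms column")
  if (!all(dl %in% c(400, 600)))
    warning("deadlines outside the study's {400, 600} ms regimes")
  sat <- p_sat <- params$evidence_saturation %||% Inf
  ev <- if (is.finite(sat)) sat * tanh(stimuli$evidence_upper / sat)
        else stimuli$evidence_upper
  dt_s <- dt_ms / 1000
  eps_early <- rnorm(n, 0, params$early_noise_sd)
  eta_late  <- rnorm(n, 0, params$late_noise_sd)
  start_pt  <- rnorm(n, 0, params$start_sd)
  motor     <- pmax(50, rnorm(n, params$motor_delay_mean, params$motor_delay_sd))
  collapse_at <- pmax(dt_ms, (dl - params$motor_delay_mean) / params$urgency_slope)

  choice_sign <- integer(n); t_dec <- numeric(n); prev <- integer(n)
  prev_sign <- 0L
  # accumulate in blocks of trials is impossible (sequential history), but the
  # time loop is short; vectorise over time inside each trial instead
  t_grid <- seq(dt_ms, 700, by = dt_ms)
  nT <- length(t_grid)
  early_step <- which(t_grid >= params$early_latency)[1L]
  late_from  <- which(t_grid >= params$late_latency)[1L]
  for (i in seq_len(n)) {
    prev[i] <- prev_sign
    drift <- numeric(nT)
    if (!is.na(late_from))
      drift[late_from:nT] <- params$late_gain * (ev[i] + eta_late[i]) * dt_s
    noise <- rnorm(nT, 0, params$diffusion_sd * sqrt(dt_s))
    inc <- drift + noise
    if (!is.na(early_step))
      inc[early_step] <- inc[early_step] + params$early_gain * (ev[i] + eps_early[i])
    a <- start_pt[i] - params$history_bias * prev_sign + cumsum(inc)
    b <- params$bound * pmax(0, 1 - t_grid / collapse_at[i])
    hit <- which(abs(a) >= b)
    j <- hit[1L]   # bound reaches 0 before 700 ms, so a crossing always exists
    s <- sign(a[j])
    if (s == 0) s <- sample(c(-1L, 1L), 1L)
    choice_sign[i] <- s
    t_dec[i] <- t_grid[j]
    prev_sign <- s
  }
  choice <- ifelse(choice_sign > 0, "upper", "lower")
  rt <- t_dec + motor
  out <- cbind(stimuli, data.frame(
    choice = choice, rt_ms = rt,
    correct = as.integer(choice == stimuli$target),
    prev_choice = ifelse(prev == 0L, NA_character_,
                         ifelse(prev > 0, "upper", "lower")),
    eps_early = eps_early,
    stringsAsFactors = FALSE))
  # C1 ground truth: tracks lower-minus-upper contrast plus the shared early
  # noise (scaled by shared_noise_gain); positive = lower-favouring.
  out$c1_true <- params$c1_gain * (-ev) - params$shared_noise_gain * eps_early
  if (is.null(out$trial)) out$trial <- seq_len(n)
  if (is.null(out$deadline_ms)) out$deadline_ms <- dl
  out$excluded <- FALSE
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Block score under the study's payoff scheme
#'
#' 10 points for every correct, timely response; minus 7 points for all other
#' trials (errors or late responses).
#'
#' @param trials a trial table with `correct`, `rt_ms`, `deadline_ms`.
#' @return integer score.
#' @export
block_score <- function(trials) {
  timely_correct <- trials$correct == 1L & trials$rt_ms <= trials$deadline_ms
  sum(ifelse(timely_correct, 10L, -7L))
}

#' Automated difficulty titration
#'
#' Iteratively adjusts the differential contrast `dc` (on accuracy error, in
#' log steps with a decreasing stochastic-approximation gain) and the `bias`
#' term (on choice-rate imbalance) over simulated blocks, then averages the
#' settled half of the run, emulating the experimenter-in-the-loop titration
#' that fixed task difficulty at ~55% correct.
#'
#' @param params an [observer_params()].
#' @param target_accuracy fraction in (0.5, 1); default 0.55.
#' @param block_size trials per titration block.
#' @param max_blocks number of titration blocks; if the settled-half accuracy
#'   misses the target by more than `tol`, a warning is raised and the
#'   averaged parameters are still returned.
#' @param deadline ms; blocks cycle through the given regimes (default both
#'   400 and 600, so the target is the overall accuracy across regimes).
#' @param dc0,bias0 starting values.
#' @param tol convergence tolerance on the settled-half accuracy.
#' @param seed integer seed.
#' @return list with `dc`, `bias`, `accuracy` (settled-half estimate),
#'   `converged`, and a per-block `history` data.frame including the block
#'   `score`.
#' @export
titrate_difficulty <- function(params, target_accuracy = 0.55,
                               block_size = 240L, max_blocks = 24L,
                               deadline = c(400, 600), dc0 = 0.03, bias0 = 0,
                               tol = 0.015, seed = params$seed) {
  if (target_accuracy <= 0.5 || target_accuracy >= 1)
    .fail("target_accuracy must be in (0.5, 1)")
  dc <- dc0; bias <- bias0
  hist <- list()
  for (b in seq_len(max_blocks)) {
    dl <- deadline[(b - 1L) %% length(deadline) + 1L]
    cfg <- stimulus_config(dc = dc, bias = bias)
    stim <- generate_session(cfg, deadlines = dl, n_blocks = 1L,
                             block_size = block_size, easy_block_size = 0L,
                             seed = stage_seed(seed, paste0("titrate", b)))
    stim <- stim[stim$block_type == "hard", ]
    tt <- simulate_behaviour(params, stim, deadline = dl,
                             seed = stage_seed(seed, paste0("titrate-beh", b)))
    acc <- mean(tt$correct)
    p_up <- mean(tt$choice == "upper")
    hist[[b]] <- data.frame(block = b, dc = dc, bias = bias, accuracy = acc,
                            p_upper = p_up, score = block_score(tt))
    # stochastic-approximation step with decreasing gain, so the staircase
    # settles at the target instead of stopping on a lucky block
    gain <- 3 / (1 + 0.1 * b)
    dc <- max(1e-4, min(0.15, dc * exp(-gain * (acc - target_accuracy))))
    bias <- max(-0.05, min(0.05, bias - 0.1 * (p_up - 0.5) * dc / 0.05))
  }
  hist <- do.call(rbind, hist)
  # the staircase sweeps a range of dc values; interpolate the target through
  # a psychometric fit of block accuracy on log dc (weighting blocks by size)
  dc_hat <- tryCatch({
    fit <- stats::glm(cbind(round(accuracy * block_size),
                            round((1 - accuracy) * block_size)) ~ log(dc),
                      family = stats::binomial(), data = hist)
    co <- stats::coef(fit)
    cand <- exp((stats::qlogis(target_accuracy) - co[1L]) / co[2L])
    if (!is.finite(cand) || co[2L] <= 0) NA_real_ else
      min(max(cand, 0.5 * min(hist$dc)), 2 * max(hist$dc))
  }, error = function(e) NA_real_)
  if (is.na(dc_hat)) dc_hat <- exp(mean(log(utils::tail(hist$dc, max_blocks %/% 2))))
  bias_hat <- mean(utils::tail(hist$bias, max_blocks %/% 2))
  # confirmation run at the interpolated parameters
  acc_conf <- numeric(length(deadline))
  for (k in seq_along(deadline)) {
    cfg <- stimulus_config(dc = dc_hat, bias = bias_hat)
    stim <- generate_session(cfg, deadlines = deadline[k], n_blocks = 1L,
                             block_size = 600L, easy_block_size = 0L,
                             seed = stage_seed(seed, paste0("titrate-conf", k)))
    stim <- stim[stim$block_type == "hard", ]
    tc <- simulate_behaviour(params, stim, deadline = deadline[k],
                             seed = stage_seed(seed, paste0("titrate-confbeh", k)))
    acc_conf[k] <- mean(tc$correct)
  }
  acc_hat <- mean(acc_conf)
  converged <- abs(acc_hat - target_accuracy) < tol
  if (!converged)
    warning(sprintf("titration did not converge in %d blocks; returning best-so-far",
                    max_blocks))
  list(dc = unname(dc_hat), bias = bias_hat, accuracy = acc_hat,
       converged = converged, history = hist)
}

#' Transient-readout simulation: choice probability as a function of RT
#'
#' A minimal model of a decision fed by a transient early evidence sample plus
#' later accumulating evidence, used to motivate the prediction that readout of
#' a transient sensory signal produces choice probability confined to an
#' intermediate RT band: before the sample arrives there is nothing to read
#' out, and at long RTs its contribution is diluted by accumulated late
#' evidence.
#'
#' Zero-signal trials are simulated; choice probability is the area under the
#' ROC of the early sample split by choice, per RT bin.
#'
#' @param readout_weight_early weight of the transient sample in the decision.
#' @param dilution_rate growth rate of late-evidence variance (per 100 ms).
#' @param n_trials number of trials (>= 1000).
#' @param seed integer seed.
#' @param early_latency_ms,late_latency_ms information arrival times.
#' @param motor_delay_ms added to decision time to give RT.
#' @param bin_width_ms RT bin width for the CP curve.
#' @return data.frame `rt_lo`, `rt_hi`, `n`, `cp`.
#' @export
simulate_transient_readout <- function(readout_weight_early = 1,
                                       dilution_rate = 1.2,
                                       n_trials = 20000L, seed = 1L,
                                       early_latency_ms = 80,
                                       late_latency_ms = 150,
                                       motor_delay_ms = 100,
                                       bin_width_ms = 50) {
  if (n_trials < 1000L) .fail("n_trials must be >= 1000")
  set.seed(seed)
  t_dec <- runif(n_trials, 20, 520)
  x_e <- rnorm(n_trials)
  late_sd <- dilution_rate * sqrt(pmax(0, t_dec - late_latency_ms) / 100)
  d <- readout_weight_early * x_e * (t_dec >= early_latency_ms) +
       rnorm(n_trials, 0, 1e-9 + late_sd) + rnorm(n_trials, 0, 0.05)
  choice <- d > 0
  rt <- t_dec + motor_delay_ms
  breaks <- seq(floor(min(rt) / bin_width_ms) * bin_width_ms,
                ceiling(max(rt) / bin_width_ms) * bin_width_ms, by = bin_width_ms)
  bin <- cut(rt, breaks, right = FALSE)
  cp <- vapply(levels(bin), function(lv) {
    i <- bin == lv
    a <- x_e[i & choice]; b <- x_e[i & !choice]
    if (length(a) < 5L || length(b) < 5L) return(NA_real_)
    # AUC via rank sum
    r <- rank(c(a, b))
    (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
      (length(a) * length(b))
  }, numeric(1L))
  data.frame(rt_lo = breaks[-length(breaks)], rt_hi = breaks[-1L],
             n = as.integer(table(bin)), cp = cp, row.names = NULL)
}
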