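# Shared fixtures, built in code at load time. Kept small: everything heavier
# is generated inside the tests that need it.

mini_montage <- make_montage(16)
mini_fm <- forward_model(mini_montage)

# observer with all noise sources off: deterministic evidence readout
noiseless_params <- function(...) {
  observer_params(early_noise_sd = 0, late_noise_sd = 0, diffusion_sd = 1e-6,
                  start_sd = 0, history_bias = 0, motor_delay_sd = 0, ...)
}

# a small hard-block trial sequence + behaviour, reused across tests
small_session <- generate_session(stimulus_config(dc = 0.05), deadlines = 600,
                                  n_blocks = 1L, block_size = 80L,
                                  easy_block_size = 60L, seed = 301)
small_trials <- simulate_behaviour(observer_params(), small_session, seed = 302)

# independent IRLS-free logistic oracle is stats::glm (used in several files)
glm_oracle <- function(X, y) {
  fit <- stats::glm(y ~ X, family = stats::binomial())
  unname(stats::coef(fit))
}

# brute-force significance-run oracle: enumerate all runs + the empty run,
# scoring agreement by direct counting, with the same tie-break rules
run_oracle <- function(sig) {
  x <- as.logical(sig); n <- length(x)
  best <- list(start = NA_integer_, end = NA_integer_, agreement = sum(!x))
  best_len <- 0L; best_s <- Inf
  for (s in seq_len(n)) for (e in s:n) {
    inside <- rep(FALSE, n); inside[s:e] <- TRUE
    agree <- sum(x[inside]) + sum(!x[!inside])
    len <- e - s + 1L
    if (agree > best$agreement ||
        (agree == best$agreement && (len > best_len ||
                                     (len == best_len && s < best_s)))) {
      best <- list(start = s, end = e, agreement = agree)
      best_len <- len; best_s <- s
    }
  }
  best
}
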