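# build a response-locked epoch_set directly from per-trial waveforms
.resp_epochs <- function(waves, labels = "cpz") {
  n_sp <- ncol(waves)
  t_ms <- (as.integer(round(-600 * 512 / 1000)) + seq_len(n_sp) - 1L) * 1000 / 512
  epoch_set(array(waves, dim = c(nrow(waves), 1L, n_sp)), t_ms, 512, labels,
            align = "response")
}

test_that("slope series is exact on linear ramps and null on identical conditions", {
  n_sp <- 358L
  ramp <- seq_len(n_sp) / 512 * 1000 * 0.01      # 1 uV per 100 ms
  waves <- matrix(rep(ramp, each = 12L), 12L, n_sp, byrow = FALSE)
  e <- .resp_epochs(waves)
  tt <- data.frame(participant = rep(1:6, each = 2L),
                   block_type = rep(c("hard", "easy"), 6L),
                   rt_ms = rep(300, 12L))
  ss <- slope_series(e, tt, "cpz")
  expect_equal(as.vector(ss$slopes), rep(0.01, length(ss$slopes)),
               tolerance = 1e-9)
  # identical conditions: no significant paired differences anywhere
  expect_false(any(!is.na(ss$p) & ss$p < 0.05))
})

test_that("the onset rule takes the first window continuously significant to the peak", {
  centers <- seq(-500, 50, by = 10)
  peak <- 0
  p <- rep(0.5, length(centers))
  pk <- which.min(abs(centers - peak))
  # pattern: ns, s, ns, then s through the peak -> onset at the second s-block
  p[10] <- 0.01
  p[12:pk] <- 0.01
  onset <- c1readout:::.cpp_onset_from_p(p, centers, peak, 0.05)
  expect_equal(onset, centers[12])
  # all significant -> first window
  expect_equal(c1readout:::.cpp_onset_from_p(rep(0.01, length(centers)),
                                             centers, peak, 0.05), centers[1L])
  # nothing significant -> NA
  expect_true(is.na(c1readout:::.cpp_onset_from_p(rep(0.5, length(centers)),
                                                  centers, peak, 0.05)))
})

test_that("CPP electrode selection finds the injected channel", {
  p <- observer_params()
  fm <- forward_model(mini_montage, noise_rms = 0)
  sess <- generate_session(stimulus_config(dc = 0.05), deadlines = 600,
                           n_blocks = 1L, block_size = 40L,
                           easy_block_size = 0L, seed = 101)
  tt <- simulate_behaviour(p, sess, seed = 102)
  # CPP as the only injected component
  e <- simulate_eeg(fm, tt, p, alpha_amp = 0, vep_scale = 0, c1_scale = 0,
                    history_c1_gain = 0, seed = 103)
  rl <- response_lock(e, tt$rt_ms)
  ch <- select_cpp_electrode(rl)
  pool <- montage_pool(mini_montage, "centroparietal")
  # the layout is left/right symmetric, so the topography maximum can be tied
  peak_lbls <- mini_montage$label[fm$cpp_topography >= max(fm$cpp_topography) - 1e-12]
  expect_true(ch %in% peak_lbls)
  expect_true(ch %in% pool)
  # pool of one returns that channel; flat data ties break to the first
  expect_equal(select_cpp_electrode(rl, pool = ch), ch)
  rl0 <- rl; rl0$data[] <- 0
  expect_message(ch0 <- select_cpp_electrode(rl0, pool = c("A2", "A3")), "tie")
  expect_equal(ch0, "A2")
})

# synthetic participant-average waveforms with a known divergence time:
# easy slope exceeds hard from (150 - rt) ms response-locked
.divergence_waves <- function(n_part, rt_mean, diverge_ms = 150, noise = 0.002,
                              seed = 1) {
  set.seed(seed)
  n_sp <- 358L
  t_ms <- (as.integer(round(-600 * 512 / 1000)) + seq_len(n_sp) - 1L) * 1000 / 512
  mk <- function(slope, onset_rl) {
    w <- pmax(0, t_ms - onset_rl) * slope
    w + cumsum(stats::rnorm(n_sp, 0, noise))
  }
  waves <- matrix(0, 2L * n_part, n_sp)
  tt <- data.frame(participant = rep(seq_len(n_part), each = 2L),
                   block_type = rep(c("hard", "easy"), n_part),
                   rt_ms = rep(rt_mean, 2L * n_part))
  for (i in seq_len(nrow(tt))) {
    onset_rl <- diverge_ms - rt_mean
    sl <- if (tt$block_type[i] == "easy") 0.02 else 0.008
    base <- 0.008       # shared pre-divergence buildup
    w <- pmax(0, t_ms - (-rt_mean)) * base +
         pmax(0, t_ms - onset_rl) * (sl - base)
    waves[i, ] <- w + cumsum(stats::rnorm(n_sp, 0, noise))
  }
  list(e = .resp_epochs(waves), tt = tt, t_ms = t_ms)
}

test_that("CPP onset estimation recovers a known divergence time", {
  z <- .divergence_waves(n_part = 14L, rt_mean = 350, diverge_ms = 150,
                         seed = 111)
  ss <- slope_series(z$e, z$tt, "cpz")
  est <- estimate_cpp_onset(ss, n_boot = 300L, seed = 112)
  expect_false(is.na(est$median_ms))
  expect_lt(abs(est$stimulus_locked_median_ms - 150), 20)
  # invariance to a constant baseline shift
  z2 <- z; z2$e$data <- z2$e$data + 7.5
  est2 <- estimate_cpp_onset(slope_series(z2$e, z2$tt, "cpz"),
                             n_boot = 300L, seed = 112)
  expect_equal(est2$median_ms, est$median_ms)
})

test_that("stimulus-locked onset error stays within 20 ms across many datasets", {
  errs <- vapply(1:50, function(i) {
    z <- .divergence_waves(n_part = 10L, rt_mean = 340, diverge_ms = 150,
                           noise = 0.004, seed = 200 + i)
    ss <- slope_series(z$e, z$tt, "cpz")
    est <- estimate_cpp_onset(ss, n_boot = 120L, seed = 300 + i)
    abs(est$stimulus_locked_median_ms - 150)
  }, numeric(1L))
  expect_lte(stats::median(errs, na.rm = TRUE), 20)
})

test_that("pooled onset averages the available estimates", {
  po <- pooled_onset(list(159, 141, 148))
  expect_equal(round(po$pooled_ms), 149)
  expect_equal(round(po$delay_from_c1_ms), 69)   # ~70 ms from an 80 ms C1
  expect_equal(pooled_onset(list(140, 140, 140))$pooled_ms, 140)
  # missing estimates: pooled over the rest, flagged
  po2 <- pooled_onset(list(150, NA_real_, 160))
  expect_true(po2$incomplete)
  expect_equal(po2$pooled_ms, 155)
  expect_equal(po2$n_used, 2L)
})
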