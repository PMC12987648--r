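test_that("average re-referencing zeroes the scalp mean", {
  x <- rbind(c(1, 1), c(-1, -1))
  expect_equal(rereference_average(x), x)
  x2 <- x + 5
  expect_equal(rereference_average(x2), x)
  set.seed(1)
  r <- matrix(rnorm(40 * 100), 40, 100)
  rr <- rereference_average(r)
  expect_equal(max(abs(colMeans(rr))), 0, tolerance = 1e-12)
  # external channels excluded from the mean but still re-referenced
  rr2 <- rereference_average(r, scalp = 1:30)
  expect_equal(max(abs(colMeans(rr2[1:30, ]))), 0, tolerance = 1e-12)
})

test_that("epoch extraction follows the half-open sample convention", {
  fs <- 512
  x <- matrix(0, 2, 5000)
  ev <- c(1000L, 2500L)
  x[1L, ev + 1L] <- 7     # impulse exactly at each event sample
  e <- extract_epochs(x, ev, fs = fs, span = c(-600, 400))
  expect_equal(dim(e$data), c(2L, 2L, 512L))
  # span start snaps to the nearest sample; the event sample is exactly t = 0
  expect_equal(e$time_ms[1L], round(-600 * 512 / 1000) * 1000 / 512)
  expect_true(0 %in% e$time_ms)
  # the impulse lands at time-axis 0
  i0 <- which(e$time_ms == 0)
  expect_equal(e$data[1L, 1L, i0], 7)
  expect_equal(e$data[2L, 1L, i0], 7)
  # response-locked span [-600, 100) -> 358 samples
  e2 <- extract_epochs(x, ev, fs = fs, span = c(-600, 100), align = "response")
  expect_equal(dim(e2$data)[3L], 358L)
  # events too close to the edge are dropped with a message
  expect_message(e3 <- extract_epochs(x, c(10L, 2500L), fs = fs),
                 "too close")
  expect_equal(dim(e3$data)[1L], 1L)
})

test_that("baseline correction is exact and idempotent", {
  e <- epoch_set(array(5, dim = c(3, 2, 512)),
                 -600 + (0:511) * 1000 / 512, 512, c("a", "b"))
  b1 <- baseline_correct(e)
  expect_true(all(b1$data == 0))
  set.seed(2)
  e$data <- array(rnorm(3 * 2 * 512), dim = c(3, 2, 512))
  b1 <- baseline_correct(e)
  idx <- which(e$time_ms >= -50 & e$time_ms <= 30)
  expect_equal(max(abs(apply(b1$data[, , idx], c(1, 2), mean))), 0,
               tolerance = 1e-12)
  b2 <- baseline_correct(b1)
  expect_equal(b1$data, b2$data, tolerance = 1e-12)
})

test_that("artifact screening applies the fixed thresholds", {
  t_ms <- -600 + (0:511) * 1000 / 512
  mk <- function(m) epoch_set(array(m, dim = c(1, 1, 512)), t_ms, 512, "ch1")
  # flat epoch with one 60 uV sample -> absolute flag on that channel
  v <- numeric(512); v[300] <- 60
  rep1 <- suppressWarnings(screen_artifacts(mk(v)))
  expect_true(any(rep1$flags$flag == "absolute"))
  # 45 uV baseline range -> baseline_range flag
  v2 <- numeric(512); v2[t_ms >= -50 & t_ms <= 30][1:2] <- c(22, -23)
  rep2 <- suppressWarnings(screen_artifacts(mk(v2)))
  expect_true("baseline_range" %in% rep2$flags$flag)
  # drift: 1 Hz at 10 uV over 5 Hz at 1 uV; periodogram oracle says ratio 100
  t_s <- (0:511) / 512
  drift <- 10 * sin(2 * pi * 1 * t_s) + 1 * sin(2 * pi * 5 * t_s)
  p <- Mod(stats::fft(drift))^2 / 512
  f <- (0:511) * 512 / 512
  oracle_ratio <- sum(p[f < 3][1:3]) / sum(p[f >= 3 & f < 7])
  expect_gt(oracle_ratio, 5)
  rep3 <- suppressWarnings(screen_artifacts(mk(drift)))
  expect_true("drift" %in% rep3$flags$flag)
  # muscle: 30 Hz burst over weak mid band
  mus <- 8 * sin(2 * pi * 30 * t_s) + 1 * sin(2 * pi * 5 * t_s)
  rep4 <- suppressWarnings(screen_artifacts(mk(mus)))
  expect_true("muscle" %in% rep4$flags$flag)
})

test_that("blink segments are padded and stimulus-overlapping blinks reject", {
  t_ms <- -600 + (0:511) * 1000 / 512
  e <- epoch_set(array(0, dim = c(2, 1, 512)), t_ms, 512, "ch1")
  veog <- matrix(0, 2, 512)
  veog[1L, t_ms >= 200 & t_ms < 260] <- 50      # step at 200 ms, 60 ms long
  veog[2L, t_ms >= -20 & t_ms < 60] <- 50       # overlaps stimulus onset
  rep <- screen_artifacts(e, veog = veog,
                          gaze = data.frame(saccade = c(FALSE, FALSE),
                                            gaze_dev_deg = c(0.1, 0.1)))
  bl <- rep$flags[rep$flags$flag == "blink" & rep$flags$trial == 1L, ]
  expect_equal(nrow(bl), 1L)
  expect_lt(abs(bl$t_start_ms - 150), 3)        # 50 ms pad before
  expect_gt(bl$t_end_ms, 300)                   # 50 ms pad after the segment
  expect_false(rep$full_reject[1L])
  expect_true(rep$full_reject[2L])
  expect_equal(rep$trial_loss, 0.5)
})

test_that("gaze rules and missing vEOG behave as specified", {
  t_ms <- -600 + (0:511) * 1000 / 512
  e <- epoch_set(array(0, dim = c(3, 1, 512)), t_ms, 512, "ch1")
  expect_warning(screen_artifacts(e), "vEOG")
  rep <- suppressWarnings(
    screen_artifacts(e, gaze = data.frame(saccade = c(TRUE, FALSE, FALSE),
                                          gaze_dev_deg = c(0.1, 1.5, 0.2))))
  expect_equal(rep$full_reject, c(TRUE, TRUE, FALSE))
  expect_gte(rep$trial_loss, 0); expect_lte(rep$trial_loss, 1)
})

test_that("screening recovers injected artifacts with high sensitivity/specificity", {
  p <- observer_params()
  sess <- generate_session(stimulus_config(dc = 0.05), deadlines = 600,
                           n_blocks = 2L, block_size = 60L,
                           easy_block_size = 0L, seed = 61)
  tt <- simulate_behaviour(p, sess, seed = 62)
  e <- simulate_eeg(mini_fm, tt, p, artifacts = TRUE, seed = 63)
  gt <- e$meta$ground_truth
  e <- baseline_correct(rereference_average(e))
  rep <- screen_artifacts(e, veog = gt$veog, gaze = gt$gaze,
                          # drift/muscle sit on single channels; relax nothing
                          thresholds = list())
  inj <- gt$artifacts
  expect_gt(nrow(inj), 5L)
  hit <- logical(nrow(inj))
  for (i in seq_len(nrow(inj))) {
    fl <- rep$flags
    hit[i] <- if (inj$type[i] == "blink") {
      any(fl$flag == "blink" & fl$trial == inj$trial[i])
    } else {
      any(fl$flag == inj$type[i] & fl$trial == inj$trial[i] &
            fl$channel == inj$channel[i])
    }
  }
  expect_gte(mean(hit), 0.95)
  # specificity: clean trial-channels carry no drift/muscle/absolute flags
  clean_trials <- setdiff(seq_len(nrow(tt)), inj$trial)
  fl <- rep$flags[rep$flags$flag %in% c("drift", "muscle", "absolute"), ]
  fp <- sum(fl$trial %in% clean_trials)
  total_clean <- length(clean_trials) * length(e$labels)
  expect_gte(1 - fp / total_clean, 0.95)
})

test_that("channel interpolation replaces a channel with its neighbourhood", {
  m <- mini_montage
  e <- epoch_set(array(rnorm(2 * 16 * 64), dim = c(2, 16, 64)),
                 (0:63) * 1000 / 512, 512, m$label)
  bad <- m$label[5L]
  e2 <- interpolate_channels(e, m, bad)
  nb <- c1readout:::montage_neighbours(m, bad, 4L)
  # interpolated trace is a convex combination of neighbours
  for (tr in 1:2) {
    v <- e2$data[tr, 5L, ]
    rng <- apply(e$data[tr, match(nb, m$label), ], 2L, range)
    expect_true(all(v >= rng[1L, ] - 1e-9 & v <= rng[2L, ] + 1e-9))
  }
  # other channels untouched
  expect_equal(e2$data[, -5L, ], e$data[, -5L, ])
})
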