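# noiseless easy-block epochs shared by the C1 electrode tests: both the EEG
# background and the observer's shared early-evidence noise (which feeds C1
# amplitude by design) are switched off
.mk_easy <- function(noise = 0, n_trials = 40L, seed = 71) {
  p <- observer_params(early_noise_sd = 0)
  fm <- forward_model(mini_montage, noise_rms = noise)
  sess <- generate_session(stimulus_config(dc = 0.05), deadlines = 600,
                           n_blocks = 1L, block_size = 2L,
                           easy_block_size = n_trials, seed = seed)
  sess <- sess[sess$block_type == "easy", ]
  tt <- simulate_behaviour(p, sess, seed = seed + 1L)
  e <- simulate_eeg(fm, tt, p, alpha_amp = 0, alpha_lat_gain = 0, seed = seed + 2L)
  list(e = baseline_correct(e), tt = tt, fm = fm)
}

test_that("C1 electrode selection recovers the forward-model poles", {
  z <- .mk_easy(noise = 0)
  m <- select_c1_electrodes(z$e, z$tt, k_per_pole = 3L)
  d <- z$fm$c1_topography_lower - z$fm$c1_topography_upper
  names(d) <- mini_montage$label
  pool <- montage_pool(mini_montage, "posterior")
  dp <- sort(d[pool], decreasing = TRUE)
  expect_setequal(m$pos_electrodes, names(dp)[1:3])
  expect_setequal(m$neg_electrodes, names(rev(dp))[1:3])
  expect_length(select_c1_electrodes(z$e, z$tt, k_per_pole = 1L)$pos_electrodes, 1L)
})

test_that("identical responses for both fields give a no-C1 error", {
  z <- .mk_easy(noise = 0)
  z$e$data[] <- 1   # no target-dependent difference anywhere
  expect_error(select_c1_electrodes(z$e, z$tt), "no sign-opposed C1 poles")
})

test_that("the bipolar C1 measure is exact arithmetic and linear", {
  t_ms <- (-307:204) * 1000 / 512
  dat <- array(0, dim = c(2, 4, length(t_ms)))
  dat[, 1, ] <- 2; dat[, 2, ] <- 2    # positive pole, +2 uV
  dat[, 3, ] <- -1; dat[, 4, ] <- -1  # negative pole, -1 uV
  e <- epoch_set(dat, t_ms, 512, c("p1", "p2", "n1", "n2"))
  m <- structure(list(pos_electrodes = c("p1", "p2"),
                      neg_electrodes = c("n1", "n2"), window = c(80, 90)),
                 class = "c1_montage")
  expect_equal(measure_c1(e, m), c(3, 3))
  e0 <- e; e0$data[] <- 0
  expect_equal(measure_c1(e0, m), c(0, 0))
  e2 <- e; e2$data <- e$data * 2.5
  expect_equal(measure_c1(e2, m), 2.5 * measure_c1(e, m))
})

test_that("noiseless lower-target trials give positive C1 sign", {
  z <- .mk_easy(noise = 0)
  m <- select_c1_electrodes(z$e, z$tt)
  c1 <- measure_c1(z$e, m)
  expect_true(all(c1[z$tt$target == "lower"] > 0))
  expect_true(all(c1[z$tt$target == "upper"] < 0))
})

test_that("artifact-flagged montage channels yield missing C1 values", {
  z <- .mk_easy(noise = 0, n_trials = 6L)
  m <- select_c1_electrodes(z$e, z$tt, k_per_pole = 2L)
  flags <- data.frame(trial = 1L, channel = c(m$pos_electrodes),
                      flag = "absolute", t_start_ms = -600, t_end_ms = 400)
  rep <- structure(list(flags = flags, full_reject = rep(FALSE, 6L),
                        trial_loss = 0, n_trials = 6L),
                   class = "artifact_report")
  c1 <- measure_c1(z$e, m, rep)
  expect_true(is.na(c1[1L]))
  expect_false(anyNA(c1[-1L]))
})

test_that("STFT normalization returns sinusoid amplitude at bin frequencies", {
  fs <- 512
  t_ms <- (-307:204) * 1000 / fs
  n_win <- 205L
  f_bin <- fs / n_win * 4          # an exact bin frequency (~9.99 Hz)
  sig <- sin(2 * pi * f_bin * t_ms / 1000)
  e <- epoch_set(array(rep(sig, each = 1), dim = c(1, 1, length(t_ms))),
                 t_ms, fs, "ch1")
  tf <- stft_epochs(e)
  expect_equal(length(tf$freqs_hz), 12L)                 # bins <= 30 Hz
  expect_equal(diff(tf$freqs_hz)[1L], fs / 205, tolerance = 1e-9)
  k <- which.min(abs(tf$freqs_hz - f_bin))
  expect_equal(max(tf$magnitudes[1, 1, k, ]), 1.0, tolerance = 0.01)
  # zero signal -> all magnitudes zero; linear amplitude scaling
  e0 <- e; e0$data[] <- 0
  expect_true(all(stft_epochs(e0)$magnitudes == 0))
  e3 <- e; e3$data <- e$data * 3
  expect_equal(stft_epochs(e3)$magnitudes, tf$magnitudes * 3, tolerance = 1e-9)
})

test_that("covariate extraction averages electrodes x window (x band)", {
  t_ms <- (-307:204) * 1000 / 512
  dat <- array(0, dim = c(2, 3, length(t_ms)))
  i_t <- which.min(abs(t_ms - 100))
  dat[1, 2, i_t] <- 4
  e <- epoch_set(dat, t_ms, 512, c("a", "b", "c"))
  sg <- choice_signal("probe", "b", t_ms[i_t], t_ms[i_t])
  v <- extract_covariates(e, NULL, list(sg))
  expect_equal(v[, "probe"], c(4, 0))
  # fully flagged window -> missing
  rep <- structure(list(flags = data.frame(trial = 2L, channel = "b",
                                           flag = "drift", t_start_ms = -600,
                                           t_end_ms = 400),
                        full_reject = c(FALSE, FALSE), trial_loss = 0,
                        n_trials = 2L), class = "artifact_report")
  v2 <- extract_covariates(e, NULL, list(sg), report = rep)
  expect_true(is.na(v2[2L, "probe"]))
  # contralateral-minus-ipsilateral contrast via the negative electrode set
  sgl <- choice_signal("lat", "a", t_ms[i_t], t_ms[i_t], electrodes_neg = "b")
  v3 <- extract_covariates(e, NULL, list(sgl))
  expect_equal(unname(v3[1L, "lat"]), 0 - 4)
})

test_that("choice-signal search recovers an injected lateralized alpha signal", {
  p <- observer_params()
  mont <- make_montage()         # full layout: occipital sites needed
  fm <- forward_model(mont, noise_rms = 2)
  parts <- list()
  for (pp in 1:6) {
    sess <- generate_session(stimulus_config(dc = 0.05), deadlines = 600,
                             n_blocks = 1L, block_size = 50L,
                             easy_block_size = 0L, seed = 80 + pp)
    tt <- simulate_behaviour(p, sess, seed = 90 + pp)
    tt$participant <- pp
    e <- simulate_eeg(fm, tt, p, alpha_amp = 4, alpha_lat_gain = 2.5,
                      seed = 100 + pp)
    parts[[pp]] <- list(tt = tt, e = baseline_correct(e))
  }
  tt <- do.call(rbind, lapply(parts, `[[`, "tt"))
  dat <- do.call(c1readout:::abind3, lapply(parts, function(z) z$e$data))
  e <- epoch_set(dat, parts[[1]]$e$time_ms, 512, parts[[1]]$e$labels)
  tf <- stft_epochs(e)
  sigs <- search_choice_signals(tf, tt)
  expect_gt(length(sigs), 0L)
  # at least one recovered signal overlaps the injected pre-target 10 Hz band
  # on occipital electrodes
  occ <- c(montage_pool(mont, "occipital_left"),
           montage_pool(mont, "occipital_right"))
  hit <- vapply(sigs, function(s)
    s$f_lo_hz <= 10 && s$f_hi_hz >= 7.5 && s$t_start_ms < 0 &&
      length(intersect(s$electrodes, occ)) > 0, logical(1L))
  expect_true(any(hit))
  # zero-noise, zero-effect data -> empty list
  e0 <- e; e0$data <- array(0, dim = dim(e$data))
  expect_length(search_choice_signals(stft_epochs(e0), tt), 0L)
})

test_that("time-domain search is translation-equivariant in time", {
  set.seed(7)
  n_tr <- 120L; n_p <- 4L
  t_ms <- (-307:204) * 1000 / 512
  mk <- function(shift_samples) {
    dat <- array(rnorm(n_tr * 4 * length(t_ms), 0, 0.4),
                 dim = c(n_tr, 4, length(t_ms)))
    choice <- rep(c("upper", "lower"), n_tr / 2)
    i0 <- which.min(abs(t_ms - 100)) + shift_samples
    for (i in which(choice == "upper"))
      dat[i, 1:2, i0:(i0 + 10)] <- dat[i, 1:2, i0:(i0 + 10)] + 1.2
    list(e = epoch_set(dat, t_ms, 512, c("a", "b", "c", "d")),
         tt = data.frame(participant = rep(1:n_p, each = n_tr / n_p),
                         choice = choice))
  }
  set.seed(11); z0 <- mk(0L)
  set.seed(11); z1 <- mk(26L)     # ~50.8 ms shift
  s0 <- search_choice_signals(z0$e, z0$tt)
  s1 <- search_choice_signals(z1$e, z1$tt)
  expect_gt(length(s0), 0L); expect_gt(length(s1), 0L)
  d0 <- s0[[1L]]$t_start_ms; d1 <- s1[[1L]]$t_start_ms
  expect_equal(d1 - d0, 26 * 1000 / 512, tolerance = 4)   # within 2 samples
})
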