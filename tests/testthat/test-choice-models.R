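.mk_cov_trials <- function(n = 400L, seed = 1L, n_cov = 14L) {
  set.seed(seed)
  tt <- data.frame(participant = rep(1:4, each = n / 4L),
                   target = sample(c("upper", "lower"), n, TRUE),
                   choice = sample(c("upper", "lower"), n, TRUE),
                   rt_ms = runif(n, 150, 590),
                   prev_choice = sample(c("upper", "lower"), n, TRUE),
                   excluded = FALSE)
  tt$correct <- as.integer(tt$choice == tt$target)
  cv <- matrix(rnorm(n * n_cov), n,
               dimnames = list(NULL, c("c1", paste0("sig", seq_len(n_cov - 1L)))))
  list(tt = tt, cv = cv)
}

test_that("design construction: coding, z-scoring and the 48-regressor count", {
  z <- .mk_cov_trials()
  d <- build_design(z$tt, z$cv, rt_interactions = "quadratic")
  # 14 continuous + target + prev_choice = 16 predictors x 3 = 48 regressors
  expect_equal(ncol(d$X), 48L)
  d0 <- build_design(z$tt, z$cv, rt_interactions = "none")
  expect_equal(ncol(d0$X), 16L)
  expect_true(all(d0$X[, "target"] %in% c(0, 1)))
  expect_equal(mean(d0$X[, "c1"]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(d0$X[, "c1"]), 1, tolerance = 1e-10)
  # RT in seconds in interaction columns
  expect_equal(d$X[, "c1:rt"], d$X[, "c1"] * (z$tt$rt_ms[d$rows] / 1000))
  # RT > 600 ms trials excluded
  z$tt$rt_ms[1L] <- 650
  d2 <- build_design(z$tt, z$cv, rt_interactions = "none")
  expect_false(1L %in% d2$rows)
  # constant predictor dropped with a warning
  cv3 <- z$cv; cv3[, "sig3"] <- 2
  expect_warning(build_design(z$tt, cv3), "constant predictor")
})

test_that("logistic fitting recovers known coefficients and matches glm", {
  set.seed(10)
  n <- 20000L
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1L, stats::plogis(0.2 + 1 * X[, 1L] - 0.5 * X[, 2L]))
  f <- fit_logistic(X, y)
  expect_true(f$converged)
  b <- f$table$beta; se <- f$table$se
  expect_lt(abs(b[2L] - 1), 3 * se[2L])
  expect_lt(abs(b[3L] - (-0.5)), 3 * se[3L])
  # oracle agreement to 1e-6 on small fixed data
  Xs <- X[1:400, ]; ys <- y[1:400]
  expect_lt(max(abs(fit_logistic(Xs, ys)$table$beta - glm_oracle(Xs, ys))), 1e-6)
  expect_error(fit_logistic(X, rep(1, n)), "constant")
})

test_that("null predictors are calibrated at the nominal level", {
  set.seed(20)
  hits <- vapply(1:500, function(i) {
    X <- cbind(x = rnorm(250))
    y <- rbinom(250, 1L, 0.5)
    abs(fit_logistic(X, y)$table$t[2L]) < 2
  }, logical(1L))
  expect_gte(mean(hits), 0.94)
})

test_that("perfect separation is flagged, not fatal", {
  X <- cbind(x = c(rep(-1, 20), rep(1, 20)))
  y <- c(rep(0L, 20), rep(1L, 20))
  expect_warning(f <- fit_logistic(X, y), "separation")
  expect_false(f$converged)
  expect_true(all(is.finite(f$table$beta)))
})

test_that("random intercepts are recovered via the Laplace fit", {
  set.seed(30)
  n_g <- 12L; n_per <- 250L
  g <- rep(seq_len(n_g), each = n_per)
  u <- rnorm(n_g, 0, 0.8)[g]
  x <- rnorm(n_g * n_per)
  y <- rbinom(n_g * n_per, 1L, stats::plogis(u + 0.7 * x))
  f <- fit_logistic(cbind(x = x), y, random_intercepts = TRUE, groups = g)
  b <- f$table$beta[f$table$term == "x"]
  se <- f$table$se[f$table$term == "x"]
  expect_lt(abs(b - 0.7), 3 * se)
})

test_that("quadratic vertex converts coefficient triplets to ms", {
  v <- quadratic_vertex(0.56, -3.68, 5.32)
  expect_equal(round(v$rt_ms), 346)
  expect_equal(v$extremum, "minimum")
  expect_equal(quadratic_vertex(3, 0, 2)$rt_ms, 0)
  # constructed vertex at 250 ms: beta_lin = -2 a v with v = 0.25, a = 1
  expect_equal(quadratic_vertex(0, -2 * 1 * 0.25, 1)$rt_ms, 250)
  # invariant to common positive rescaling
  expect_equal(quadratic_vertex(1.12, -7.36, 10.64)$rt_ms, v$rt_ms)
  expect_error(quadratic_vertex(1, 1, 0), "undefined")
})

test_that("sliding RT windows form the stated 81-window grid", {
  tt <- simulate_windowed_coupling(n_participants = 4L, trials_each = 500L,
                                   seed = 41)
  ws <- sliding_rt_models(tt, cbind(c1 = tt$c1))
  expect_s3_class(ws, "window_series")
  expect_equal(sort(unique(ws$center_pct)), 10:90)
  expect_equal(length(unique(ws$center_pct)), 81L)
  wt <- window_term(ws, "c1")
  expect_length(wt$sig, 81L)
  expect_true(all(diff(wt$center_ms) >= 0))
  # C1 reporting sign is flipped relative to the fitted coefficient
  raw <- ws[ws$term == "c1", ]
  expect_equal(raw$beta_report, -raw$beta)
})

test_that("sliding windows localize an RT-band-limited coupling", {
  tt <- simulate_windowed_coupling(n_participants = 8L, trials_each = 900L,
                                   band_ms = c(250, 380), coupling = -1,
                                   seed = 42)
  ws <- sliding_rt_models(tt, cbind(c1 = tt$c1))
  wt <- window_term(ws, "c1")
  run <- fit_significance_run(wt$sig)
  expect_false(is.na(run$start))
  lat <- run_to_latencies(run, wt$beta, wt$center_ms)
  rt <- tt$rt_ms[included_trials(tt)]
  width_on <- diff(stats::quantile(rt, c(max(0.01, (run$start + 9 - 10) / 100),
                                         (run$start + 9 + 10) / 100)))
  width_off <- diff(stats::quantile(rt, c((run$end + 9 - 10) / 100,
                                          min(0.99, (run$end + 9 + 10) / 100))))
  expect_lt(abs(lat$onset_ms - 250), width_on)
  expect_lt(abs(lat$offset_ms - 380), width_off)
  # the run's windows overlap the injected band
  expect_lt(wt$center_ms[run$start], 380)
  expect_gt(wt$center_ms[run$end], 250)
})

test_that("null coupling yields nominal-level significant windows", {
  rates <- vapply(1:60, function(i) {
    tt <- simulate_windowed_coupling(n_participants = 3L, trials_each = 500L,
                                     coupling = 0, seed = 500 + i)
    ws <- sliding_rt_models(tt, cbind(c1 = tt$c1))
    wt <- window_term(ws, "c1")
    mean(wt$sig)
  }, numeric(1L))
  # mean false-positive rate near alpha (windows overlap, so per-replicate
  # counts are highly correlated; the mean over replicates is the yield)
  expect_lt(mean(rates), 0.10)
})

test_that("collinearity pruning removes the fewest columns and guards C1", {
  set.seed(50)
  n <- 500L
  base <- matrix(rnorm(n * 4L), n)
  X <- cbind(c1 = base[, 1L], a = base[, 2L], b = base[, 3L], d = base[, 4L],
             a2 = base[, 2L] + rnorm(n, 0, 0.1),
             b2 = base[, 3L] + rnorm(n, 0, 0.1))
  res <- collinearity_prune(X, 0.5)
  expect_setequal(res$dropped %in% c("a", "a2", "b", "b2"), TRUE)
  expect_equal(length(res$dropped), 2L)
  # brute-force oracle: no single-column removal can achieve the threshold
  ok1 <- vapply(colnames(X), function(cn) {
    R <- abs(stats::cor(X[, setdiff(colnames(X), cn)])); diag(R) <- 0
    max(R) <= 0.5
  }, logical(1L))
  expect_false(any(ok1))
  # duplicated column: exactly one removed
  X2 <- cbind(c1 = base[, 1L], a = base[, 2L], a_dup = base[, 2L])
  expect_equal(length(collinearity_prune(X2, 0.5)$dropped), 1L)
  # already satisfying: nothing removed
  base_named <- base; colnames(base_named) <- paste0("v", 1:4)
  expect_length(collinearity_prune(base_named, 0.99)$dropped, 0L)
  # protected blocking pair errors
  X3 <- cbind(c1 = base[, 1L], c1b = base[, 1L] + rnorm(n, 0, 0.05))
  expect_error(collinearity_prune(X3, 0.5, protect = c("c1", "c1b")),
               "blocking pair")
})

.mk_c1dv <- function(mod_gain, n_per = 700L, seed = 1L) {
  set.seed(seed)
  n <- n_per * 8L
  tt <- data.frame(participant = rep(1:8, each = n_per),
                   target = sample(c("upper", "lower"), n, TRUE),
                   choice = sample(c("upper", "lower"), n, TRUE),
                   prev_choice = sample(c("upper", "lower"), n, TRUE),
                   rt_ms = runif(n, 150, 590), excluded = FALSE)
  tt$correct <- as.integer(tt$choice == tt$target)
  band <- tt$rt_ms > 250 & tt$rt_ms < 400
  # C1 tracks target location; previous choice modulates it congruently
  # (upper prev choice -> more negative C1) only inside an interior RT band
  c1 <- -2 * (tt$target == "upper") + 1 -
    mod_gain * band * ifelse(tt$prev_choice == "upper", 1, -1) + rnorm(n, 0, 1)
  list(tt = tt, c1 = c1)
}

test_that("C1-as-dependent-variable model recovers an RT-banded history effect", {
  z <- .mk_c1dv(mod_gain = 0.5, seed = 61)
  f <- fit_c1_dv_model(z$tt, NULL, z$c1)
  tb <- f$table
  p_quad <- tb$p[tb$term == "prev_choice:rt2"]
  expect_lt(p_quad, 0.05)
  # refitting without current choice leaves the history modulation essentially
  # unchanged: compare the fitted prev-choice RT profile (the individual
  # quadratic coefficients are collinear and poorly conditioned one by one)
  f2 <- fit_c1_dv_model(z$tt, NULL, z$c1, drop_current_choice = TRUE)
  prof <- function(tb) {
    b <- tb$beta[match(c("prev_choice", "prev_choice:rt", "prev_choice:rt2"),
                       tb$term)]
    rt <- seq(0.2, 0.55, by = 0.05)
    b[1L] + b[2L] * rt + b[3L] * rt^2
  }
  expect_lt(max(abs(prof(tb) - prof(f2$table))), 0.1)
})

test_that("C1 history model is null-calibrated without a modulation", {
  set.seed(62)
  p_at_alpha <- vapply(1:200, function(i) {
    z <- .mk_c1dv(mod_gain = 0, n_per = 60L, seed = 600 + i)
    f <- fit_c1_dv_model(z$tt, NULL, z$c1)
    f$table$p[f$table$term == "prev_choice:rt2"] < 0.05
  }, logical(1L))
  expect_lt(mean(p_at_alpha), 0.09)
  expect_gt(mean(p_at_alpha), 0.005)
})

test_that("behavioural models capture the accuracy-RT and history structure", {
  sess <- generate_session(stimulus_config(dc = 0.02), deadlines = c(400, 600),
                           n_blocks = 5L, block_size = 1000L,
                           easy_block_size = 0L, seed = 71)
  tt <- simulate_behaviour(observer_params(), sess, seed = 72)
  fits <- fit_behavioural_models(tt)
  acc <- fits$accuracy_rt$table
  expect_lt(acc$beta[acc$term == "rt2"], 0)               # concave
  expect_lt(acc$p[acc$term == "rt2"], 0.05)
  # switching bias: previous upper choice predicts a lower choice now
  h <- fits$history$table
  expect_lt(h$beta[h$term == "prev_choice"], 0)
  # 600 ms deadline slows responses
  rtd <- fits$rt_deadline$table
  expect_gt(rtd$beta[rtd$term == "deadline"], 0)
  expect_true(is.list(fits$rt_variability) || is.null(fits$rt_variability))
})

test_that("a deadline-invariant observer gives a null deadline effect", {
  set.seed(80)
  hits <- vapply(1:200, function(i) {
    n <- 400L
    tt <- data.frame(participant = 1L,
                     target = sample(c("upper", "lower"), n, TRUE),
                     choice = NA_character_, rt_ms = runif(n, 150, 590),
                     prev_choice = sample(c("upper", "lower"), n, TRUE),
                     deadline_ms = sample(c(400, 600), n, TRUE),
                     excluded = FALSE)
    tt$correct <- rbinom(n, 1L, 0.55)       # same accuracy in both regimes
    tt$choice <- ifelse(tt$correct == 1L, tt$target,
                        ifelse(tt$target == "upper", "lower", "upper"))
    f <- fit_behavioural_models(tt)$accuracy_rt
    f$table$p[f$table$term == "deadline"] < 0.05
  }, logical(1L))
  expect_lt(mean(hits), 0.10)
})
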