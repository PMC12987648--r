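#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], optionally
#' overridden from a YAML file and/or a named list. Study-scale values are the
#' defaults; tests use reduced smoke configurations.
#'
#' @param yaml optional path to a YAML file with overrides.
#' @param overrides optional named list of overrides (applied last).
#' @return named list of class `run_config` with a `config_hash` attribute.
#' @export
run_config <- function(yaml = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1L,
    n_participants = 18L,
    deadlines = c(400, 600),
    n_blocks = 10L, block_size = 120L,
    easy_block_size = 160L, easy_dc = 0.30,
    dc = 0.02, bias = 0,
    titrate = FALSE, target_accuracy = 0.55,
    n_channels = 128L,
    fs = 512,
    artifacts = FALSE,
    k_per_pole = 4L,
    signal_search = FALSE,
    random_intercepts = FALSE,
    n_boot = 500L,
    n_shuffles = 20L,
    decode = FALSE,
    out_dir = NULL,
    log = TRUE)
  if (!is.null(yaml)) cfg <- utils::modifyList(cfg, yaml::read_yaml(yaml))
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  # the hash fingerprints the analysis parameters; where results are written
  # and how chatty the run is are not part of the analysis identity
  hashed <- cfg[setdiff(names(cfg), c("out_dir", "log"))]
  attr(cfg, "config_hash") <- fnv1a32(jsonlite::toJSON(hashed, auto_unbox = TRUE,
                                                       digits = NA))
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

.stage <- function(name, cfg, expr) {
  if (isTRUE(cfg$log)) message(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> preprocess -> C1 measurement (-> signal search) ->
#' choice models -> sliding windows (-> bootstrap onsets) -> CPP (-> decoding)
#' and, when `cfg$out_dir` is set, writes trial tables (CSV), the window
#' series (TSV), coefficient tables (TSV) and onset estimates (JSON), each run
#' stamped with the seed and config hash.
#'
#' @param cfg a [run_config()].
#' @return named list of stage results (`trials`, `c1`, `choice_model`,
#'   `vertex_ms`, `window_series`, `onsets`, `cpp`, `decode`, `config`).
#' @export
run_pipeline <- function(cfg = run_config()) {
  seed <- cfg$seed
  params <- observer_params(seed = stage_seed(seed, "observer"))

  sim <- .stage("simulate", cfg, {
    dc <- cfg$dc; bias <- cfg$bias
    if (isTRUE(cfg$titrate)) {
      tr <- titrate_difficulty(params, cfg$target_accuracy,
                               seed = stage_seed(seed, "titrate"))
      dc <- tr$dc; bias <- tr$bias
    }
    scfg <- stimulus_config(dc = dc, bias = bias)
    fm <- forward_model(make_montage(cfg$n_channels))
    per <- vector("list", cfg$n_participants)
    for (p in seq_len(cfg$n_participants)) {
      st <- generate_session(scfg, deadlines = cfg$deadlines,
                             n_blocks = cfg$n_blocks, block_size = cfg$block_size,
                             easy_block_size = cfg$easy_block_size,
                             easy_dc = cfg$easy_dc,
                             seed = stage_seed(seed, paste0("stim", p)))
      tt <- simulate_behaviour(params, st,
                               seed = stage_seed(seed, paste0("beh", p)))
      tt$participant <- p
      # simulate a span long enough for response-locking under the 600 ms
      # deadline; target-locked analyses use the standard [-600, 400) crop
      ee <- simulate_eeg(fm, tt, params, fs = cfg$fs, span = c(-600, 700),
                         artifacts = isTRUE(cfg$artifacts),
                         seed = stage_seed(seed, paste0("eeg", p)))
      per[[p]] <- list(trials = tt, epochs_long = ee)
    }
    list(per = per, fm = fm)
  })

  pre <- .stage("preprocess", cfg, {
    for (p in seq_along(sim$per)) {
      el <- sim$per[[p]]$epochs_long
      gt <- el$meta$ground_truth
      el <- baseline_correct(rereference_average(el))
      keep_sp <- which(el$time_ms < 400)
      e <- epoch_set(el$data[, , keep_sp, drop = FALSE], el$time_ms[keep_sp],
                     el$fs, el$labels, el$align, el$meta)
      rep <- screen_artifacts(e, veog = gt$veog[, keep_sp, drop = FALSE],
                              gaze = gt$gaze)
      sim$per[[p]]$epochs <- e
      sim$per[[p]]$epochs_long <- el
      sim$per[[p]]$report <- rep
      sim$per[[p]]$trials$excluded <- rep$full_reject
    }
    sim$per
  })

  feat <- .stage("features", cfg, {
    for (p in seq_along(pre)) {
      tt <- pre[[p]]$trials
      easy <- tt$block_type == "easy"
      cm <- select_c1_electrodes(subset_epochs(pre[[p]]$epochs, trials = which(easy)),
                                 tt[easy, ], k_per_pole = cfg$k_per_pole)
      pre[[p]]$c1_montage <- cm
      pre[[p]]$c1 <- measure_c1(pre[[p]]$epochs, cm, pre[[p]]$report)
    }
    pre
  })

  trials <- do.call(rbind, lapply(feat, `[[`, "trials"))
  c1_all <- unlist(lapply(feat, `[[`, "c1"))
  hard <- trials$block_type == "hard"

  signals <- list()
  if (isTRUE(cfg$signal_search)) {
    signals <- .stage("signal-search", cfg, {
      # group-level time-domain search on the hard trials
      es <- lapply(feat, function(z)
        subset_epochs(z$epochs, trials = which(z$trials$block_type == "hard")))
      dat <- do.call(abind3, lapply(es, `[[`, "data"))
      pooled <- epoch_set(dat, es[[1L]]$time_ms, es[[1L]]$fs, es[[1L]]$labels)
      search_choice_signals(pooled, trials[hard, ])
    })
  }

  cm_res <- .stage("choice-model", cfg, {
    tt <- trials[hard, ]
    cv <- cbind(c1 = c1_all[hard])
    if (length(signals)) {
      es <- lapply(feat, function(z)
        subset_epochs(z$epochs, trials = which(z$trials$block_type == "hard")))
      dat <- do.call(abind3, lapply(es, `[[`, "data"))
      pooled <- epoch_set(dat, es[[1L]]$time_ms, es[[1L]]$fs, es[[1L]]$labels)
      cv <- cbind(cv, extract_covariates(pooled, NULL, signals))
    }
    d <- build_design(tt, cv, rt_interactions = "quadratic")
    fit <- fit_logistic(d$X, d$y, random_intercepts = isTRUE(cfg$random_intercepts),
                        groups = d$groups)
    b <- fit$table$beta[match(c("c1", "c1:rt", "c1:rt2"), fit$table$term)]
    vx <- if (!anyNA(b) && b[3L] != 0) quadratic_vertex(b[1L], b[2L], b[3L])$rt_ms
          else NA_real_
    list(fit = fit, vertex_ms = vx, covariates = cv, design = d)
  })

  ws <- .stage("sliding-windows", cfg, {
    sliding_rt_models(trials[hard, ], cm_res$covariates)
  })

  onsets <- NULL
  if (cfg$n_boot > 0L) {
    onsets <- .stage("onsets", cfg, {
      bootstrap_onsets(trials[hard, ], cm_res$covariates,
                       list(c1_window_model, accuracy_intercept_model),
                       n_boot = cfg$n_boot, seed = stage_seed(seed, "onsets"))
    })
  } else if (isTRUE(cfg$log)) message("[onsets] skipped (n_boot = 0)")

  cpp <- .stage("cpp", cfg, {
    use <- trials$block_type %in% c("hard", "easy") & trials$rt_ms <= 600
    resp <- list(); tts <- list()
    for (p in seq_along(feat)) {
      sel <- which(feat[[p]]$trials$block_type %in% c("hard", "easy") &
                     feat[[p]]$trials$rt_ms <= 600)
      rl <- response_lock(subset_epochs(feat[[p]]$epochs_long, trials = sel),
                          feat[[p]]$trials$rt_ms[sel])
      resp[[p]] <- rl
      tts[[p]] <- feat[[p]]$trials[sel, ][rl$meta$kept, ]
    }
    dat <- do.call(abind3, lapply(resp, `[[`, "data"))
    pooled <- epoch_set(dat, resp[[1L]]$time_ms, resp[[1L]]$fs,
                        resp[[1L]]$labels, align = "response")
    ttp <- do.call(rbind, tts)
    ch <- select_cpp_electrode(pooled)
    ss <- slope_series(pooled, ttp, ch)
    est <- estimate_cpp_onset(ss, n_boot = max(100L, cfg$n_boot),
                              seed = stage_seed(seed, "cpp"))
    list(channel = ch, series = ss, onset = est)
  })

  dec <- NULL
  if (isTRUE(cfg$decode)) {
    dec <- .stage("decode", cfg, {
      es <- lapply(feat, function(z)
        subset_epochs(z$epochs, trials = which(z$trials$block_type == "hard")))
      dat <- do.call(abind3, lapply(es, `[[`, "data"))
      pooled <- epoch_set(dat, es[[1L]]$time_ms, es[[1L]]$fs, es[[1L]]$labels)
      lda_timecourse(pooled, trials[hard, ], n_shuffles = cfg$n_shuffles,
                     seed = stage_seed(seed, "decode"))
    })
  }

  res <- list(trials = trials, c1 = c1_all, signals = signals,
              choice_model = cm_res$fit, vertex_ms = cm_res$vertex_ms,
              window_series = ws, onsets = onsets, cpp = cpp, decode = dec,
              config = cfg)
  if (!is.null(cfg$out_dir)) .stage("report", cfg, write_report(res, cfg))
  res
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  n1 <- sum(vapply(parts, function(a) dim(a)[1L], integer(1L)))
  out <- array(0, dim = c(n1, d[2L], d[3L]))
  at <- 0L
  for (a in parts) {
    k <- dim(a)[1L]
    out[(at + 1L):(at + k), , ] <- a
    at <- at + k
  }
  out
}

# write TSV/CSV/JSON artifacts for a pipeline result
write_report <- function(res, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- attr(cfg, "config_hash")
  stamp <- function(df) { df$config_hash <- hash; df$seed <- cfg$seed; df }
  write_trial_table(stamp(cbind(res$trials, c1 = res$c1)),
                    file.path(cfg$out_dir, "trials.csv"))
  utils::write.table(stamp(as.data.frame(res$window_series)),
                     file.path(cfg$out_dir, "window_series.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(stamp(res$choice_model$table),
                     file.path(cfg$out_dir, "choice_model.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$onsets))
    write_onset_estimate(res$onsets, file.path(cfg$out_dir, "onsets.json"))
  if (length(res$signals))
    write_choice_signals(res$signals, file.path(cfg$out_dir, "signals.json"))
  summary <- list(config_hash = hash, seed = cfg$seed,
                  vertex_ms = res$vertex_ms,
                  accuracy = mean(res$trials$correct[res$trials$block_type == "hard"]),
                  cpp_onset_stimulus_locked_ms = res$cpp$onset$stimulus_locked_median_ms)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
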