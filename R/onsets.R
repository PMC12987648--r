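#' Fit the unbroken significance-run model to a test-outcome sequence
#'
#' Models an ordered sequence of per-window significant/non-significant test
#' outcomes as a single contiguous run of significant windows with
#' non-significant windows before and after, choosing the run that maximizes
#' agreement with the observed flags. The empty run competes on equal footing.
#' Ties are broken in favour of higher agreement, then longer runs, then
#' earlier starts.
#'
#' Implementation: agreement(s, e) = (# zeros overall) + sum over the run of
#' (2 flag - 1), so the best run maximizes a prefix-sum difference; all O(n^2)
#' (start, end) pairs are scored through prefix sums.
#'
#' @param sig logical (or 0/1) vector of test outcomes.
#' @return list with `start`, `end` (1-based indices, both `NA` for the empty
#'   run) and `agreement`.
#' @export
fit_significance_run <- function(sig) {
  x <- as.integer(as.logical(sig))
  n <- length(x)
  if (n == 0L) .fail("empty sequence")
  zeros <- sum(x == 0L)
  pref <- c(0L, cumsum(2L * x - 1L))
  best <- list(start = NA_integer_, end = NA_integer_, agreement = zeros,
               len = 0L, s = Inf)
  for (s in seq_len(n)) for (e in s:n) {
    a <- zeros + pref[e + 1L] - pref[s]
    len <- e - s + 1L
    if (a > best$agreement ||
        (a == best$agreement && (len > best$len ||
                                 (len == best$len && s < best$s)))) {
      best <- list(start = s, end = e, agreement = a, len = len, s = s)
    }
  }
  list(start = best$start, end = best$end, agreement = best$agreement)
}

#' Convert a significance run to onset/offset latencies
#'
#' The onset is the linearly interpolated zero crossing of the coefficient
#' series between consecutive window centres, taking the crossing nearest
#' before (or at) the run start; the offset is the crossing nearest after the
#' run end. Where no crossing exists in range, the run-edge window centre is
#' used.
#'
#' @param run a [fit_significance_run()] result (non-empty).
#' @param beta coefficient values per window.
#' @param centers_ms window centres in ms.
#' @return list with `onset_ms`, `offset_ms`.
#' @export
run_to_latencies <- function(run, beta, centers_ms) {
  if (is.na(run$start)) .fail("empty run has no latencies")
  n <- length(beta)
  cross <- function(j) { # zero crossing between centres j and j+1
    b0 <- beta[j]; b1 <- beta[j + 1L]
    centers_ms[j] + (0 - b0) / (b1 - b0) * (centers_ms[j + 1L] - centers_ms[j])
  }
  onset <- centers_ms[run$start]
  if (run$start > 1L) {
    for (j in (run$start - 1L):1L) {
      if (!is.na(beta[j]) && !is.na(beta[j + 1L]) &&
          sign(beta[j]) != sign(beta[j + 1L]) && beta[j] != beta[j + 1L]) {
        onset <- cross(j); break
      }
    }
  }
  offset <- centers_ms[run$end]
  if (run$end < n) {
    for (j in run$end:(n - 1L)) {
      if (!is.na(beta[j]) && !is.na(beta[j + 1L]) &&
          sign(beta[j]) != sign(beta[j + 1L]) && beta[j] != beta[j + 1L]) {
        offset <- cross(j); break
      }
    }
  }
  list(onset_ms = onset, offset_ms = offset)
}

# window model functions -------------------------------------------------

#' Per-window model functions for bootstrap onset estimation
#'
#' `c1_window_model` runs the sliding covariate choice model and returns the
#' C1 term's significance sequence; `accuracy_intercept_model` fits an
#' intercept-only logistic model of correctness per RT window (significant =
#' accuracy above chance).
#'
#' @param trials a trial table.
#' @param covariates covariate matrix (C1 in column `c1`), ignored by the
#'   accuracy model.
#' @param centers,width window grid (percentile points).
#' @param alpha significance level.
#' @return list with `sig`, `beta`, `center_ms` per window.
#' @export
c1_window_model <- function(trials, covariates, centers = 10:90, width = 20,
                            alpha = 0.05) {
  ws <- sliding_rt_models(trials, covariates, centers = centers, width = width,
                          alpha = alpha)
  window_term(ws, "c1")
}

#' @rdname c1_window_model
#' @export
accuracy_intercept_model <- function(trials, covariates = NULL,
                                     centers = 10:90, width = 20,
                                     alpha = 0.05) {
  keep <- included_trials(trials)
  rt <- trials$rt_ms[keep]; correct <- trials$correct[keep]
  pr <- stats::ecdf(rt)(rt) * 100
  half <- width / 2
  sig <- logical(length(centers)); beta <- cms <- numeric(length(centers))
  for (i in seq_along(centers)) {
    cc <- centers[i]
    sel <- pr >= cc - half & pr <= cc + half
    k <- sum(correct[sel]); m <- sum(sel)
    b <- stats::qlogis(pmin(pmax(k / m, 1e-6), 1 - 1e-6))
    se <- sqrt(1 / pmax(k, 0.5) + 1 / pmax(m - k, 0.5))
    pv <- 2 * stats::pnorm(-abs(b / se))
    sig[i] <- pv < alpha && b > 0          # above chance
    beta[i] <- b
    cms[i] <- stats::median(rt[pr >= cc - 0.5 & pr <= cc + 0.5])
    if (!is.finite(cms[i])) cms[i] <- stats::quantile(rt, cc / 100, names = FALSE)
  }
  list(sig = sig, beta = beta, center_pct = centers, center_ms = cms)
}

#' Bootstrap onset/offset estimation over participants
#'
#' Re-samples participants with replacement `n_boot` times; in each sample the
#' window series is rebuilt from scratch (windows re-derived from the sample's
#' pooled RT distribution), the significance-run model fitted, and run edges
#' converted to latencies. Samples with an empty run contribute no latency and
#' are counted. Two model functions can be evaluated on identical samples for
#' paired difference CIs.
#'
#' @param trials a trial table with a `participant` column (>= 2 unique).
#' @param covariates covariate matrix aligned to `trials` (or NULL).
#' @param model_fn a window model function ([c1_window_model()] or
#'   [accuracy_intercept_model()]); or a list of two such functions for paired
#'   evaluation.
#' @param n_boot number of bootstrap samples (>= 100; the study-scale default
#'   is 10000, scaled-down analyses use 500).
#' @param seed integer seed.
#' @param centers,width,alpha window grid.
#' @return object of class `onset_estimate`: list with `onset` / `offset`
#'   (each: `samples`, `median_ms`, `ci` 2.5/97.5 percentiles), `n_empty`,
#'   `n_boot`, `seed`, and (paired mode) `difference` on onsets.
#' @export
bootstrap_onsets <- function(trials, covariates = NULL, model_fn,
                             n_boot = 500L, seed = 1L,
                             centers = 10:90, width = 20, alpha = 0.05) {
  parts <- unique(trials$participant)
  if (length(parts) < 2L) .fail("need >= 2 participants to bootstrap")
  if (n_boot < 100L) .fail("n_boot must be >= 100")
  paired <- is.list(model_fn)
  fns <- if (paired) model_fn else list(model_fn)
  set.seed(seed)
  draws <- matrix(sample(parts, n_boot * length(parts), replace = TRUE),
                  n_boot, length(parts))
  res <- lapply(fns, function(f)
    list(onset = rep(NA_real_, n_boot), offset = rep(NA_real_, n_boot)))
  idx_by_part <- split(seq_len(nrow(trials)), trials$participant)
  n_skip <- 0L
  for (b in seq_len(n_boot)) {
    rows <- unlist(idx_by_part[as.character(draws[b, ])], use.names = FALSE)
    tb <- trials[rows, , drop = FALSE]
    cb <- if (is.null(covariates)) NULL else covariates[rows, , drop = FALSE]
    for (k in seq_along(fns)) {
      wm <- tryCatch(fns[[k]](tb, cb, centers = centers, width = width,
                              alpha = alpha),
                     error = function(e) NULL)
      if (is.null(wm)) { n_skip <- n_skip + 1L; next }
      run <- fit_significance_run(wm$sig)
      if (is.na(run$start)) next
      lat <- run_to_latencies(run, wm$beta, wm$center_ms)
      res[[k]]$onset[b] <- lat$onset_ms
      res[[k]]$offset[b] <- lat$offset_ms
    }
  }
  summarise <- function(v) list(samples = v,
                                median_ms = stats::median(v, na.rm = TRUE),
                                ci = stats::quantile(v, c(0.025, 0.975),
                                                     na.rm = TRUE, names = FALSE))
  out <- list(onset = summarise(res[[1L]]$onset),
              offset = summarise(res[[1L]]$offset),
              n_empty = sum(is.na(res[[1L]]$onset)),
              n_skipped = n_skip, n_boot = n_boot, seed = seed)
  if (paired) {
    d <- res[[1L]]$onset - res[[2L]]$onset
    out$second <- list(onset = summarise(res[[2L]]$onset),
                       offset = summarise(res[[2L]]$offset))
    out$difference <- summarise(d)
  }
  class(out) <- "onset_estimate"
  out
}

#' @export
print.onset_estimate <- function(x, ...) {
  cat(sprintf("<onset_estimate> %d bootstrap samples (%d empty)\n",
              x$n_boot, x$n_empty))
  cat(sprintf("  onset  %0.f ms  [%.0f, %.0f]\n", x$onset$median_ms,
              x$onset$ci[1L], x$onset$ci[2L]))
  cat(sprintf("  offset %0.f ms  [%.0f, %.0f]\n", x$offset$median_ms,
              x$offset$ci[1L], x$offset$ci[2L]))
  if (!is.null(x$difference))
    cat(sprintf("  onset difference %0.f ms  [%.0f, %.0f]\n",
                x$difference$median_ms, x$difference$ci[1L], x$difference$ci[2L]))
  invisible(x)
}

#' Serialize an onset estimate to JSON
#'
#' @param est an `onset_estimate`.
#' @param path JSON file path.
#' @export
write_onset_estimate <- function(est, path) {
  jsonlite::write_json(list(median_ms = est$onset$median_ms,
                            ci_lo = est$onset$ci[1L], ci_hi = est$onset$ci[2L],
                            offset_median_ms = est$offset$median_ms,
                            offset_ci_lo = est$offset$ci[1L],
                            offset_ci_hi = est$offset$ci[2L],
                            n_boot = est$n_boot, n_empty = est$n_empty,
                            seed = est$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
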