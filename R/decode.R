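# shrinkage-regularized linear discriminant: pooled covariance shrunk toward
# a scaled identity, S* = (1 - lambda) S + lambda mean(diag(S)) I
.slda_train <- function(X, y, lambda) {
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  Xc <- rbind(sweep(X[y == 1L, , drop = FALSE], 2L, m1),
              sweep(X[y == 0L, , drop = FALSE], 2L, m0))
  S <- crossprod(Xc) / max(1L, nrow(Xc) - 2L)
  Sh <- (1 - lambda) * S + lambda * mean(diag(S)) * diag(ncol(X))
  w <- tryCatch(solve(Sh, m1 - m0), error = function(e) NULL)
  if (is.null(w)) return(NULL)
  list(w = w, c = sum(w * (m1 + m0)) / 2)
}

.slda_acc <- function(X, y, lambda) {
  fit <- .slda_train(X, y, lambda)
  if (is.null(fit)) return(NA_real_)
  pred <- as.numeric(X %*% fit$w > fit$c)
  mean(pred == y)
}

#' Time-resolved linear discriminant decoding of choice
#'
#' Per participant and per 10 ms window, fits a shrinkage-regularized linear
#' discriminant on per-channel mean amplitudes and evaluates it on the same
#' trials (the train-equals-test protocol of the original analysis, so
#' absolute accuracies are inflated by overfitting). Chance is estimated
#' empirically by refitting after shuffling choice labels, averaged over
#' `n_shuffles` shuffles; real vs shuffled accuracy is compared per window by
#' a paired t-test across participants.
#'
#' @param e target-locked [epoch_set()].
#' @param trials trial table aligned to `e` (needs `participant`, `choice`).
#' @param n_shuffles label shuffles per participant/window (default 100).
#' @param seed integer seed.
#' @param window_ms decoding window length (default 10).
#' @param lambda covariance shrinkage intensity in [0, 1] (default 0.2).
#' @param alpha significance level for the group comparison.
#' @return object of class `decoding_timecourse`: list with `centers_ms`,
#'   `acc_real` / `acc_shuffled` (participant x window), `sig` (per window),
#'   `participants`, `skipped`.
#' @export
lda_timecourse <- function(e, trials, n_shuffles = 100L, seed = 1L,
                           window_ms = 10, lambda = 0.2, alpha = 0.05) {
  stopifnot(nrow(trials) == dim(e$data)[1L])
  set.seed(seed)
  fs <- e$fs
  n_win <- max(2L, as.integer(round(window_ms * fs / 1000)))
  starts <- seq(1L, dim(e$data)[3L] - n_win + 1L, by = n_win)
  centers <- vapply(starts, function(s) mean(e$time_ms[s:(s + n_win - 1L)]),
                    numeric(1L))
  parts <- sort(unique(trials$participant))
  skipped <- character(0)
  accs <- accs_sh <- matrix(NA_real_, length(parts), length(starts))
  for (pi in seq_along(parts)) {
    sel <- which(trials$participant == parts[pi] & !is.na(trials$choice))
    y <- as.integer(trials$choice[sel] == "upper")
    if (min(sum(y == 1L), sum(y == 0L)) < 2L) {
      skipped <- c(skipped, as.character(parts[pi]))
      message(sprintf("participant %s skipped (a choice class has < 2 trials)",
                      parts[pi]))
      next
    }
    for (w in seq_along(starts)) {
      idx <- starts[w]:(starts[w] + n_win - 1L)
      X <- apply(e$data[sel, , idx, drop = FALSE], c(1L, 2L), mean)
      accs[pi, w] <- .slda_acc(X, y, lambda)
      sh <- vapply(seq_len(n_shuffles), function(k)
        .slda_acc(X, sample(y), lambda), numeric(1L))
      accs_sh[pi, w] <- mean(sh, na.rm = TRUE)
    }
  }
  sig <- rep(FALSE, length(starts))
  for (w in seq_along(starts)) {
    d <- accs[, w] - accs_sh[, w]
    d <- d[is.finite(d)]
    if (length(d) >= 2L && stats::sd(d) > 0)
      sig[w] <- stats::t.test(d, alternative = "greater")$p.value < alpha
  }
  structure(list(centers_ms = centers, acc_real = accs, acc_shuffled = accs_sh,
                 sig = sig, participants = parts, skipped = skipped,
                 n_shuffles = n_shuffles, seed = seed),
            class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> %d windows, %d participants (%d skipped), %d shuffles\n",
              length(x$centers_ms), nrow(x$acc_real), length(x$skipped),
              x$n_shuffles))
  cat(sprintf("  peak real accuracy %.1f%% at %.0f ms\n",
              100 * max(colMeans(x$acc_real), na.rm = TRUE),
              x$centers_ms[which.max(colMeans(x$acc_real))]))
  invisible(x)
}
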