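#' Select C1 measurement electrodes from an easy block
#'
#' Averages epochs in the C1 window (default 80-90 ms) separately per target
#' location, subtracts them, and picks the `k` electrodes at each pole of the
#' difference topography from a posterior pool. Pole assignment follows the
#' field-inversion convention: the `pos` pole is the set whose bipolar
#' difference deflects positive for lower-field targets.
#'
#' @param easy_epochs [epoch_set()] from an easy (high differential contrast)
#'   block, target-locked and baseline-corrected.
#' @param trials trial table aligned to `easy_epochs` (needs `target`).
#' @param k_per_pole electrodes per pole (default 4).
#' @param window C1 window in ms (endpoints inclusive; default c(80, 90)).
#' @param pool character vector of candidate labels; default the posterior
#'   half of the montage implied by `montage`.
#' @param montage montage used to build the default pool.
#' @return object of class `c1_montage`: list with `pos_electrodes`,
#'   `neg_electrodes`, `window`.
#' @export
select_c1_electrodes <- function(easy_epochs, trials, k_per_pole = 4L,
                                 window = c(80, 90), pool = NULL,
                                 montage = NULL) {
  stopifnot(nrow(trials) == dim(easy_epochs$data)[1L])
  if (!all(c("upper", "lower") %in% trials$target))
    .fail("easy block must contain both target locations")
  if (is.null(pool)) {
    if (is.null(montage)) montage <- make_montage(length(easy_epochs$labels))
    pool <- intersect(montage_pool(montage, "posterior"), easy_epochs$labels)
  }
  idx <- window_index(easy_epochs$time_ms, window[1L], window[2L], closed = TRUE)
  win_mean <- apply(easy_epochs$data[, , idx, drop = FALSE], c(1L, 2L), mean)
  topo_up <- colMeans(win_mean[trials$target == "upper", , drop = FALSE])
  topo_lo <- colMeans(win_mean[trials$target == "lower", , drop = FALSE])
  d <- topo_lo - topo_up                    # positive pole = lower-favouring
  names(d) <- easy_epochs$labels
  d <- d[pool]
  if (max(d) <= 0 || min(d) >= 0 || all(abs(d) < 1e-12))
    .fail("no sign-opposed C1 poles found in the posterior pool (no identifiable C1)")
  ord <- order(d, decreasing = TRUE)
  m <- list(pos_electrodes = names(d)[ord[seq_len(k_per_pole)]],
            neg_electrodes = names(d)[rev(ord)[seq_len(k_per_pole)]],
            window = window)
  if (length(intersect(m$pos_electrodes, m$neg_electrodes)))
    .fail("C1 poles overlap; decrease k_per_pole")
  class(m) <- "c1_montage"
  m
}

#' Measure the C1 as a single scalar per trial
#'
#' Bipolar measure: mean over the positive-pole electrodes minus mean over the
#' negative-pole electrodes, averaged over the C1 window. Electrodes flagged
#' for the trial over the window are dropped from their pole; if a whole pole
#' (or both) is flagged the trial's value is `NA`.
#'
#' @param e target-locked, baseline-corrected [epoch_set()].
#' @param m a [select_c1_electrodes()] montage.
#' @param report optional `artifact_report` used to drop flagged electrodes.
#' @return numeric vector (µV), one value per trial.
#' @export
measure_c1 <- function(e, m, report = NULL) {
  idx <- window_index(e$time_ms, m$window[1L], m$window[2L], closed = TRUE)
  pos <- chan_index(e, m$pos_electrodes); neg <- chan_index(e, m$neg_electrodes)
  n_tr <- dim(e$data)[1L]
  out <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    usable <- function(ci) {
      keep <- if (is.null(report)) rep(TRUE, length(ci)) else
        !vapply(e$labels[ci], function(lb)
          is_flagged(report, i, lb, m$window[1L], m$window[2L]), logical(1L))
      ci[keep]
    }
    p <- usable(pos); q <- usable(neg)
    out[i] <- if (length(p) == 0L || length(q) == 0L) NA_real_ else
      mean(e$data[i, p, idx]) - mean(e$data[i, q, idx])
  }
  out
}

#' Short-time Fourier transform of epochs
#'
#' Sliding rectangular windows (default 400 ms, rounded to 205 samples at
#' 512 Hz) at 25 ms step intervals, each snapped to the nearest sample.
#' Magnitudes are normalized by half the window length in samples, so a
#' sinusoid at an exact bin frequency returns its amplitude. Analysis
#' frequencies are all non-zero bins up to `max_freq_hz`.
#'
#' @param e an [epoch_set()].
#' @param window_ms,step_ms STFT window and hop (ms).
#' @param max_freq_hz highest analysis frequency (default 30).
#' @return object of class `tf_representation`: list with `magnitudes`
#'   (trials x channels x freqs x times, µV), `freqs_hz`, `times_ms` (window
#'   centres), `window_ms`, `step_ms`.
#' @export
stft_epochs <- function(e, window_ms = 400, step_ms = 25, max_freq_hz = 30) {
  fs <- e$fs
  n_win <- as.integer(round(window_ms * fs / 1000))
  nd <- dim(e$data)
  if (n_win >= nd[3L]) .fail("epoch shorter than the STFT window")
  f_all <- seq_len(n_win - 1L) * fs / n_win
  fi <- which(f_all <= max_freq_hz)
  freqs <- f_all[fi]
  # window centres on the 25 ms grid (relative to epoch start), snapped
  t0 <- e$time_ms[1L]
  half_ms <- (n_win - 1L) / 2 * 1000 / fs
  cand <- seq(ceiling((t0 + half_ms) / step_ms) * step_ms,
              e$time_ms[nd[3L]] - half_ms, by = step_ms)
  starts <- vapply(cand, function(cm)
    as.integer(round((cm - half_ms - t0) * fs / 1000)), integer(1L))
  keep <- starts >= 0L & (starts + n_win) <= nd[3L]
  starts <- starts[keep]; cand <- cand[keep]
  mags <- array(0, dim = c(nd[1L], nd[2L], length(fi), length(starts)))
  for (i in seq_len(nd[1L])) for (c in seq_len(nd[2L])) {
    v <- e$data[i, c, ]
    for (w in seq_along(starts)) {
      seg <- v[(starts[w] + 1L):(starts[w] + n_win)]
      sp <- stats::fft(seg)
      mags[i, c, , w] <- Mod(sp[fi + 1L]) / (n_win / 2)
    }
  }
  structure(list(magnitudes = mags, freqs_hz = freqs, times_ms = cand,
                 window_ms = window_ms, step_ms = step_ms,
                 labels = e$labels),
            class = "tf_representation")
}

#' Definition of a choice-predictive signal
#'
#' @param name signal name.
#' @param electrodes electrode labels averaged (sign +1).
#' @param t_start_ms,t_end_ms time window (ms).
#' @param f_lo_hz,f_hi_hz frequency band (NA for time-domain signals).
#' @param polarity +1 if amplitude is larger for upper choices, -1 otherwise.
#' @param electrodes_neg optional second electrode set entering with sign -1
#'   (for contralateral-minus-ipsilateral contrasts).
#' @return object of class `choice_signal`.
#' @export
choice_signal <- function(name, electrodes, t_start_ms, t_end_ms,
                          f_lo_hz = NA_real_, f_hi_hz = NA_real_,
                          polarity = 1, electrodes_neg = character(0)) {
  structure(list(name = name, electrodes = electrodes,
                 electrodes_neg = electrodes_neg,
                 t_start_ms = t_start_ms, t_end_ms = t_end_ms,
                 f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz, polarity = polarity),
            class = "choice_signal")
}

#' Search for choice-predictive signals
#'
#' Operationalizes the comprehensive (deliberately liberal) search: per
#' participant, activity is averaged by choice outcome and subtracted
#' (upper-chosen minus lower-chosen); a group-level t-test across participants
#' is computed per channel and time (and frequency, for time-frequency input);
#' candidate clusters are contiguous runs of time points where at least
#' `min_electrodes` channels pass `p < alpha` (uncorrected) for at least
#' `min_duration_ms`; in the time-frequency domain, clusters at adjacent
#' frequencies whose time windows and electrode sets mostly overlap (Jaccard
#' >= 0.5) are merged. Candidates are retained if the group t-test on their
#' aggregated covariate passes `alpha`.
#'
#' @param x an [epoch_set()] or a [stft_epochs()] `tf_representation`.
#' @param trials trial table (needs `choice` and `participant`).
#' @param alpha uncorrected threshold (default 0.05).
#' @param min_duration_ms minimum cluster duration (default 20).
#' @param min_electrodes minimum simultaneous electrodes (default 2).
#' @return list of [choice_signal()] definitions (possibly empty).
#' @export
search_choice_signals <- function(x, trials, alpha = 0.05,
                                  min_duration_ms = 20, min_electrodes = 2L) {
  if (!all(c("upper", "lower") %in% trials$choice))
    .fail("both choice outcomes must be present")
  parts <- unique(trials$participant)
  if (length(parts) < 2L) .fail("need >= 2 participants for the group test")
  if (inherits(x, "epoch_set")) {
    diffs <- lapply(parts, function(p) {
      i <- trials$participant == p
      up <- apply(x$data[i & trials$choice == "upper", , , drop = FALSE], c(2L, 3L), mean)
      lo <- apply(x$data[i & trials$choice == "lower", , , drop = FALSE], c(2L, 3L), mean)
      up - lo
    })
    arr <- simplify2array(diffs)               # chan x time x participant
    tm <- apply(arr, c(1L, 2L), mean)
    ts <- apply(arr, c(1L, 2L), stats::sd) / sqrt(length(parts))
    tmat <- tm / pmax(ts, 1e-12)
    crit <- stats::qt(1 - alpha / 2, df = length(parts) - 1L)
    sig <- abs(tmat) > crit                    # chan x time
    cl <- .time_clusters(sig, x$time_ms, min_duration_ms, min_electrodes)
    out <- list()
    for (ci in cl) {
      # a topography with both a positive and a negative pole yields separate
      # signals per pole (aggregating across poles would cancel)
      for (side in c(1, -1)) {
        ch <- ci$channels[sign(rowMeans(tm[ci$channels, ci$ti, drop = FALSE])) == side]
        if (length(ch) == 0L) next
        sg <- choice_signal(sprintf("td_%g_%gms%s", round(ci$t0), round(ci$t1),
                                    if (side > 0) "" else "_neg"),
                            x$labels[ch], ci$t0, ci$t1, polarity = side)
        if (.signal_passes(sg, x, NULL, trials, parts, alpha)) out <- c(out, list(sg))
      }
    }
    return(out)
  }
  # time-frequency input
  tf <- x
  nfreq <- length(tf$freqs_hz)
  per_freq <- vector("list", nfreq)
  for (k in seq_len(nfreq)) {
    diffs <- lapply(parts, function(p) {
      i <- trials$participant == p
      up <- apply(tf$magnitudes[i & trials$choice == "upper", , k, , drop = FALSE], c(2L, 4L), mean)
      lo <- apply(tf$magnitudes[i & trials$choice == "lower", , k, , drop = FALSE], c(2L, 4L), mean)
      up - lo
    })
    arr <- simplify2array(diffs)
    tm <- apply(arr, c(1L, 2L), mean)
    ts <- apply(arr, c(1L, 2L), stats::sd) / sqrt(length(parts))
    tmat <- tm / pmax(ts, 1e-12)
    crit <- stats::qt(1 - alpha / 2, df = length(parts) - 1L)
    sig <- abs(tmat) > crit
    cl <- .time_clusters(sig, tf$times_ms, min_duration_ms, min_electrodes,
                         step_ms = tf$step_ms)
    per_freq[[k]] <- lapply(cl, function(ci)
      list(ti = ci$ti, t0 = ci$t0, t1 = ci$t1, channels = ci$channels,
           f_lo = tf$freqs_hz[k], f_hi = tf$freqs_hz[k], k = k,
           pol = sign(mean(tm[ci$channels, ci$ti]))))
  }
  merged <- .merge_adjacent_freqs(per_freq)
  out <- list()
  for (ci in merged) {
    # channel-wise sign of the choice difference over the merged band/window
    fi <- which(tf$freqs_hz >= ci$f_lo & tf$freqs_hz <= ci$f_hi)
    ti <- which(tf$times_ms >= ci$t0 & tf$times_ms <= ci$t1)
    up <- apply(tf$magnitudes[trials$choice == "upper", ci$channels, fi, ti,
                              drop = FALSE], 2L, mean)
    lo <- apply(tf$magnitudes[trials$choice == "lower", ci$channels, fi, ti,
                              drop = FALSE], 2L, mean)
    d_ch <- up - lo
    for (side in c(1, -1)) {
      ch <- ci$channels[sign(d_ch) == side]
      if (length(ch) == 0L) next
      sg <- choice_signal(sprintf("tf_%g_%ghz_%gms%s", round(ci$f_lo, 1),
                                  round(ci$f_hi, 1), round(ci$t0),
                                  if (side > 0) "" else "_neg"),
                          tf$labels[ch], ci$t0, ci$t1,
                          f_lo_hz = ci$f_lo, f_hi_hz = ci$f_hi, polarity = side)
      if (.signal_passes(sg, NULL, tf, trials, parts, alpha)) out <- c(out, list(sg))
    }
  }
  out
}

# contiguous time clusters from a chan x time significance matrix
.time_clusters <- function(sig, times, min_duration_ms, min_electrodes,
                           step_ms = NULL) {
  counts <- colSums(sig)
  active <- counts >= min_electrodes
  if (!any(active)) return(list())
  r <- rle(active); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  for (j in which(r$values)) {
    ti <- starts[j]:ends[j]
    dur <- times[ends[j]] - times[starts[j]] + (step_ms %||% diff(times[1:2]))
    if (dur < min_duration_ms) next
    ch <- which(rowMeans(sig[, ti, drop = FALSE]) >= 0.5)
    if (length(ch) < min_electrodes) next
    out[[length(out) + 1L]] <- list(ti = ti, t0 = times[starts[j]],
                                    t1 = times[ends[j]], channels = ch)
  }
  out
}

# merge clusters at adjacent frequencies with Jaccard >= 0.5 overlap in both
# time window and electrode set
.merge_adjacent_freqs <- function(per_freq) {
  pool <- do.call(c, per_freq)
  if (length(pool) == 0L) return(list())
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  merged <- list()
  used <- rep(FALSE, length(pool))
  ks <- vapply(pool, function(z) z$k, numeric(1L))
  for (i in order(ks)) {
    if (used[i]) next
    cur <- pool[[i]]; used[i] <- TRUE
    repeat {
      grew <- FALSE
      for (j in seq_along(pool)) {
        if (used[j]) next
        cand <- pool[[j]]
        if (abs(cand$k - cur$k) > 1) next
        t_a <- seq(cur$t0, cur$t1, by = 1); t_b <- seq(cand$t0, cand$t1, by = 1)
        if (jacc(t_a, t_b) >= 0.5 && jacc(cur$channels, cand$channels) >= 0.5) {
          cur$t0 <- min(cur$t0, cand$t0); cur$t1 <- max(cur$t1, cand$t1)
          cur$channels <- union(cur$channels, cand$channels)
          cur$f_lo <- min(cur$f_lo, cand$f_lo); cur$f_hi <- max(cur$f_hi, cand$f_hi)
          cur$k <- max(cur$k, cand$k)
          used[j] <- TRUE; grew <- TRUE
        }
      }
      if (!grew) break
    }
    merged[[length(merged) + 1L]] <- cur
  }
  merged
}

# group-level retention test on the aggregated covariate
.signal_passes <- function(sg, e, tf, trials, parts, alpha) {
  v <- extract_covariates(e, tf, list(sg))[, 1L]
  dd <- vapply(parts, function(p) {
    i <- trials$participant == p & !is.na(v)
    mean(v[i & trials$choice == "upper"]) - mean(v[i & trials$choice == "lower"])
  }, numeric(1L))
  dd <- dd[is.finite(dd)]
  if (length(dd) < 2L) return(FALSE)
  stats::t.test(dd)$p.value < alpha
}

#' Extract per-trial covariate values for signal definitions
#'
#' For each signal, the mean amplitude (time domain) or mean STFT magnitude
#' (time-frequency domain) over its electrodes x window (x band); electrodes
#' in `electrodes_neg` enter with negative sign. Trials whose window is fully
#' artifact-flagged for all of a signal's electrodes are `NA`.
#'
#' @param e an [epoch_set()] (or NULL if only TF signals are requested).
#' @param tf a `tf_representation` (or NULL).
#' @param signals list of [choice_signal()].
#' @param report optional `artifact_report`.
#' @return numeric matrix, trials x signals (named columns).
#' @export
extract_covariates <- function(e, tf, signals, report = NULL) {
  n_tr <- if (!is.null(e)) dim(e$data)[1L] else dim(tf$magnitudes)[1L]
  out <- matrix(NA_real_, n_tr, length(signals),
                dimnames = list(NULL, vapply(signals, `[[`, "", "name")))
  for (s in seq_along(signals)) {
    sg <- signals[[s]]
    td <- is.na(sg$f_lo_hz)
    if (td && is.null(e)) .fail("time-domain signal '%s' but no epochs given", sg$name)
    if (!td && is.null(tf)) .fail("TF signal '%s' but no tf representation given", sg$name)
    labels <- if (td) e$labels else tf$labels
    ci <- match(sg$electrodes, labels)
    ni <- match(sg$electrodes_neg, labels)
    if (anyNA(c(ci, ni))) .fail("signal '%s' references unknown electrodes", sg$name)
    for (i in seq_len(n_tr)) {
      keep <- if (is.null(report)) rep(TRUE, length(ci)) else
        !vapply(labels[ci], function(lb)
          is_flagged(report, i, lb, sg$t_start_ms, sg$t_end_ms), logical(1L))
      if (!any(keep)) { out[i, s] <- NA_real_; next }
      if (td) {
        ti <- window_index(e$time_ms, sg$t_start_ms, sg$t_end_ms, closed = TRUE)
        val <- mean(e$data[i, ci[keep], ti])
        if (length(ni)) val <- val - mean(e$data[i, ni, ti])
      } else {
        ti <- which(tf$times_ms >= sg$t_start_ms & tf$times_ms <= sg$t_end_ms)
        fi <- which(tf$freqs_hz >= sg$f_lo_hz & tf$freqs_hz <= sg$f_hi_hz)
        val <- mean(tf$magnitudes[i, ci[keep], fi, ti])
        if (length(ni)) val <- val - mean(tf$magnitudes[i, ni, fi, ti])
      }
      out[i, s] <- val
    }
  }
  out
}

#' Serialize / read choice-signal definitions as JSON
#'
#' @param signals list of [choice_signal()].
#' @param path JSON file path.
#' @return `read_choice_signals`: list of `choice_signal`.
#' @export
write_choice_signals <- function(signals, path) {
  jsonlite::write_json(lapply(signals, unclass), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_choice_signals
#' @export
read_choice_signals <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(z)
    choice_signal(z$name, unlist(z$electrodes), z$t_start_ms, z$t_end_ms,
                  z$f_lo_hz %||% NA_real_, z$f_hi_hz %||% NA_real_,
                  z$polarity %||% 1, unlist(z$electrodes_neg) %||% character(0)))
}
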