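#' Stimulus configuration for the differential-contrast grating task
#'
#' Two 9 x 9 arrays of gratings (one per visual quadrant) share a mean contrast
#' of `base_contrast`; on each trial one array (the target) is incremented and
#' the other decremented by the differential contrast `dc`, optionally adjusted
#' by a signed `bias` term that makes the task easier or harder depending on
#' target direction. Within each array, per-grating jitter deviations are drawn
#' from a fixed multiset that sums exactly to zero, so the array means - and
#' hence the physical evidence - are identical on every trial.
#'
#' @param base_contrast mean grating contrast over both arrays (default 0.60).
#' @param dc fractional differential contrast added to the target array and
#'   subtracted from the other (default 0.02).
#' @param bias signed contrast term: for an upper target the effective
#'   increment is `dc + bias`, for a lower target `dc - bias`, applied
#'   symmetrically so the grand mean stays at `base_contrast`.
#' @param jitter_values the within-array deviation values; default 9 equally
#'   spaced values spanning +/-0.20 in 0.05 steps, each used 9 times per array.
#' @param clip if `TRUE`, grating contrasts that land outside \[0, 1\] are
#'   clipped to the displayable range instead of raising an error. Needed for
#'   the high-contrast easy blocks (dc = 0.30), where base + dc + jitter can
#'   exceed 1; with clipping, array means are recomputed from the clipped
#'   gratings, so the exact mean-conservation invariants hold only for
#'   non-clipping configurations.
#' @return an object of class `stimulus_config`.
#' @export
stimulus_config <- function(base_contrast = 0.60, dc = 0.02, bias = 0,
                            jitter_values = seq(-0.20, 0.20, by = 0.05),
                            clip = FALSE) {
  if (length(jitter_values) != 9L || abs(sum(jitter_values)) > 1e-12)
    .fail("jitter_values must be 9 values summing to 0")
  cfg <- list(base_contrast = base_contrast, dc = dc, bias = bias,
              jitter_values = jitter_values, grid = c(9L, 9L), clip = clip)
  class(cfg) <- "stimulus_config"
  # worst-case contrast must stay within [0, 1] unless clipping is allowed
  worst_hi <- base_contrast + abs(dc) + abs(bias) + max(jitter_values)
  worst_lo <- base_contrast - abs(dc) - abs(bias) + min(jitter_values)
  if (!clip && (worst_hi > 1 || worst_lo < 0))
    .fail("contrast out of [0,1]: base=%.2f dc=%.3f bias=%.3f with jitter +/-%.2f",
          base_contrast, dc, bias, max(jitter_values))
  cfg
}

#' Generate the contrast matrices for one trial
#'
#' Each array is a 9 (eccentricity) x 9 (polar angle) grid. Each column of the
#' grid receives a random permutation of the full jitter multiset, so every
#' polar-angle arm carries the complete deviation distribution and per-array
#' jitter residuals sum exactly to zero.
#'
#' @param cfg a [stimulus_config()].
#' @param target `"upper"` or `"lower"`: which array carries the contrast
#'   increment.
#' @param rng_seed optional integer seed for the jitter shuffles.
#' @return list with 9 x 9 matrices `upper` and `lower`, plus `mean_upper`,
#'   `mean_lower` and the signed evidence `evidence_upper = mean_upper -
#'   mean_lower`.
#' @export
generate_stimulus_trial <- function(cfg, target = c("upper", "lower"),
                                    rng_seed = NULL) {
  stopifnot(inherits(cfg, "stimulus_config"))
  target <- match.arg(target)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  adj <- cfg$dc + if (target == "upper") cfg$bias else -cfg$bias
  mu_target <- cfg$base_contrast + adj
  mu_other  <- cfg$base_contrast - adj
  jit <- function() {
    m <- vapply(1:9, function(j) sample(cfg$jitter_values), numeric(9L))
    m  # rows = eccentricity, cols = polar angle; each col a permutation
  }
  up <- (if (target == "upper") mu_target else mu_other) + jit()
  lo <- (if (target == "lower") mu_target else mu_other) + jit()
  if (isTRUE(cfg$clip)) {
    up <- pmin(1, pmax(0, up)); lo <- pmin(1, pmax(0, lo))
  } else if (min(up, lo) < 0 || max(up, lo) > 1) .fail("contrast out of [0,1]")
  list(upper = up, lower = lo,
       mean_upper = mean(up), mean_lower = mean(lo),
       evidence_upper = mean(up) - mean(lo), target = target)
}

#' Default session trial structure
#'
#' Reproduces the study's session layout at a configurable scale: per deadline,
#' `n_blocks` blocks of `block_size` trials with targets balanced within block
#' (so the default 10 x 120 yields 600 trials per combination of target
#' location and deadline), preceded per session by an easy block (dc = 0.30,
#' bias 0) and a target-only block, each of `easy_block_size` trials.
#'
#' @param cfg a [stimulus_config()] holding the titrated `dc` and `bias` used
#'   in the hard blocks.
#' @param deadlines vector of response deadlines in ms (one session each).
#' @param n_blocks,block_size hard-block structure per deadline.
#' @param easy_block_size trials in each of the easy and target-only blocks.
#' @param easy_dc differential contrast in the easy block.
#' @param seed integer seed controlling target order and jitter.
#' @return a data.frame with one row per trial: `session`, `block`,
#'   `block_type` ("hard", "easy", "single"), `deadline_ms`, `target`,
#'   `evidence_upper`, `dc`, `bias`.
#' @export
generate_session <- function(cfg = stimulus_config(),
                             deadlines = c(400, 600),
                             n_blocks = 10L, block_size = 120L,
                             easy_block_size = 160L, easy_dc = 0.30,
                             seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (s in seq_along(deadlines)) {
    dl <- deadlines[s]
    easy_cfg <- stimulus_config(cfg$base_contrast, dc = easy_dc, bias = 0,
                                jitter_values = cfg$jitter_values, clip = TRUE)
    specs <- c(list(list(type = "easy", n = easy_block_size, cfg = easy_cfg),
                    list(type = "single", n = easy_block_size, cfg = easy_cfg)),
               replicate(n_blocks, list(type = "hard", n = block_size, cfg = cfg),
                         simplify = FALSE))
    for (b in seq_along(specs)) {
      sp <- specs[[b]]
      n <- sp$n
      if (n == 0L) next
      targets <- sample(rep(c("upper", "lower"), each = n %/% 2L))
      if (n %% 2L) targets <- c(targets, sample(c("upper", "lower"), 1L))
      ev <- vapply(targets, function(tg) {
        generate_stimulus_trial(sp$cfg, tg)$evidence_upper
      }, numeric(1L), USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        session = s, block = b, block_type = sp$type, deadline_ms = dl,
        target = targets, evidence_upper = ev,
        dc = sp$cfg$dc, bias = sp$cfg$bias, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$trial <- seq_len(nrow(out))
  out
}
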