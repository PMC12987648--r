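#' Simplified EEG montage with 2-D electrode positions
#'
#' Builds a schematic scalp layout: electrodes are placed on concentric rings
#' of a unit disk viewed from above (nose up, +y anterior, +x right). Labels
#' follow a Biosemi-like A/B/C/D banking. Real electrode geometry is not needed
#' by any analysis in this package; positions only define electrode *pools*
#' (posterior, centroparietal, left/right occipital) and nearest-neighbour
#' relations for channel interpolation.
#'
#' @param n_channels number of scalp channels: 128 (default), or any smaller
#'   number for reduced test montages (electrodes are taken ring by ring).
#' @return an object of class `montage`: a data.frame with columns `label`,
#'   `x`, `y`, plus attributes used by pool helpers.
#' @export
make_montage <- function(n_channels = 128) {
  stopifnot(n_channels >= 4, n_channels <= 128)
  # ring radii and counts summing to 128
  counts <- c(1L, 6L, 12L, 18L, 22L, 24L, 22L, 23L)
  radii  <- c(0, 0.14, 0.28, 0.42, 0.56, 0.70, 0.84, 0.97)
  xs <- ys <- numeric(0)
  for (i in seq_along(counts)) {
    k <- counts[i]
    if (k == 1L) { xs <- c(xs, 0); ys <- c(ys, 0); next }
    # start angle staggers rings; angle 90 deg = anterior
    th <- pi / 2 + 2 * pi * (seq_len(k) - 1L) / k + (i %% 2) * pi / k
    xs <- c(xs, radii[i] * cos(th)); ys <- c(ys, radii[i] * sin(th))
  }
  bank <- rep(c("A", "B", "C", "D"), each = 32L)
  labels <- paste0(bank, rep(1:32, times = 4L))
  m <- data.frame(label = labels[seq_len(n_channels)],
                  x = xs[seq_len(n_channels)], y = ys[seq_len(n_channels)],
                  stringsAsFactors = FALSE)
  class(m) <- c("montage", "data.frame")
  m
}

#' Electrode pools defined on montage geometry
#'
#' @param montage a [make_montage()] layout.
#' @param pool one of `"posterior"` (below the horizontal midline; the C1
#'   search pool), `"centroparietal"` (midline, slightly posterior; the CPP
#'   pool), `"occipital_left"`, `"occipital_right"`.
#' @return character vector of electrode labels.
#' @export
montage_pool <- function(montage, pool = c("posterior", "centroparietal",
                                           "occipital_left", "occipital_right")) {
  pool <- match.arg(pool)
  sel <- switch(pool,
    posterior       = montage$y < 0,
    centroparietal  = abs(montage$x) < 0.25 & montage$y < 0.05 & montage$y > -0.5,
    occipital_left  = montage$x < -0.2 & montage$y < -0.35,
    occipital_right = montage$x >  0.2 & montage$y < -0.35)
  out <- montage$label[sel]
  if (length(out) == 0L) .fail("montage pool '%s' is empty for this layout", pool)
  out
}

# k nearest scalp neighbours of a channel (by 2-D distance), excluding itself
montage_neighbours <- function(montage, label, k = 4L) {
  i <- match(label, montage$label)
  if (is.na(i)) .fail("unknown channel label '%s'", label)
  d <- sqrt((montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2)
  d[i] <- Inf
  montage$label[order(d)[seq_len(min(k, nrow(montage) - 1L))]]
}
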