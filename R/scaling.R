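#' Log-affine scaling transform for platelet counts
#'
#' Platelet counts are approximately log-normal, so network inputs and
#' outputs live on a log scale. The transform maps `log(count)` affinely so
#' that the degree-four thrombocytopenia threshold (25e9 cells/l) and a
#' typical untreated baseline (300e9 cells/l) land on architecture-specific
#' anchors: `[-0.5, 0.5]` for the GRU variant and `[-1, 1.5]` for the
#' feed-forward variant.
#'
#' @param architecture `"gru"` or `"fnn"`.
#' @param lower_count,upper_count anchor counts in 1e9 cells/l.
#' @return An object of class `scaling_transform`.
#' @examples
#' tr <- scaling_transform("gru")
#' scale_count(25, tr)   # -0.5
#' scale_count(300, tr)  #  0.5
#' @export
scaling_transform <- function(architecture = c("gru", "fnn"),
                              lower_count = 25, upper_count = 300) {
  architecture <- match.arg(architecture)
  stopifnot(lower_count > 0, upper_count > lower_count)
  anchors <- switch(architecture,
    gru = c(-0.5, 0.5),
    fnn = c(-1, 1.5)
  )
  structure(
    list(
      architecture = architecture,
      lower_count = lower_count, upper_count = upper_count,
      target_low = anchors[1], target_high = anchors[2],
      # slope of scaled units per log-count unit
      slope = (anchors[2] - anchors[1]) / (log(upper_count) - log(lower_count))
    ),
    class = "scaling_transform"
  )
}

#' Scale platelet counts to network units
#'
#' @param count platelet counts, 1e9 cells/l, strictly positive.
#' @param transform a [scaling_transform()].
#' @return Scaled values (log-transform followed by the anchored affine map).
#' @export
scale_count <- function(count, transform) {
  if (any(!is.finite(count)) || any(count <= 0)) {
    stop("platelet counts must be positive and finite")
  }
  transform$target_low +
    (log(count) - log(transform$lower_count)) * transform$slope
}

#' Map scaled network values back to platelet counts
#'
#' @param scaled values in network units.
#' @inheritParams scale_count
#' @return Counts in 1e9 cells/l.
#' @export
inverse_scale <- function(scaled, transform) {
  exp(log(transform$lower_count) +
    (scaled - transform$target_low) / transform$slope)
}

#' Exponential smoothing of a prediction sequence
#'
#' First-order exponential smoothing used as a low-pass filter on the
#' network output: `s[1] = raw[1]`, `s[i] = alpha*raw[i] + (1-alpha)*s[i-1]`.
#' `alpha = 1` leaves the sequence untouched; `alpha = 0` holds the first
#' value. In the NARX models `alpha` is a trainable parameter; the
#' unsmoothed sequence stays in the autoregressive feedback loop.
#'
#' @param raw numeric sequence.
#' @param alpha smoothing factor in `[0, 1]`.
#' @return Smoothed sequence of the same length.
#' @export
exponential_smooth <- function(raw, alpha) {
  if (length(raw) == 0L) stop("'raw' must be non-empty")
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("'alpha' must lie in [0, 1]")
  }
  out <- numeric(length(raw))
  out[1] <- raw[1]
  if (length(raw) > 1L) {
    for (i in 2:length(raw)) {
      out[i] <- alpha * raw[i] + (1 - alpha) * out[i - 1]
    }
  }
  out
}
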