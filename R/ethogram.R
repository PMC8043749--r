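#' Per-frame grooming probability stream
#'
#' Lightweight container for one stream of per-frame grooming probabilities,
#' e.g. the output of one classifier model or one test-time augmentation of a
#' model. Frame indexing is 0-based throughout the package: frame 0 is the
#' first video frame.
#'
#' @param probs numeric vector of per-frame grooming probabilities in \[0, 1\].
#' @param fps frames per second of the source video (default 30).
#' @return An object of class `prediction_series`.
#' @examples
#' ps <- prediction_series(c(0.1, 0.8, 0.9), fps = 30)
#' @export
prediction_series <- function(probs, fps = 30) {
  probs <- as.numeric(probs)
  .assert(length(probs) >= 1, "probs must have length >= 1")
  .assert(all(is.finite(probs)) && all(probs >= 0) && all(probs <= 1),
          "probs must lie in [0, 1]")
  .assert(is.numeric(fps) && length(fps) == 1 && fps > 0, "fps must be > 0")
  structure(list(probs = probs, fps = fps), class = "prediction_series")
}

#' Binary grooming ethogram
#'
#' A frame-by-frame record of grooming (1) versus not grooming (0).
#'
#' @param labels vector coercible to 0/1; 1 = grooming.
#' @param fps frames per second.
#' @return An object of class `ethogram`.
#' @export
ethogram <- function(labels, fps = 30) {
  labels <- as.integer(labels)
  .assert(length(labels) >= 1, "labels must have length >= 1")
  .assert(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  .assert(is.numeric(fps) && length(fps) == 1 && fps > 0, "fps must be > 0")
  structure(list(labels = labels, fps = fps), class = "ethogram")
}

#' Ellipse-fit tracking data
#'
#' Per-frame centroid position and fitted ellipse axes from a tracker. The
#' ratio of minor to major axis (W/L) captures body-shape change: during
#' grooming it fluctuates, while a resting mouse in a grooming-like posture is
#' nearly static.
#'
#' @param x,y per-frame centroid coordinates (any consistent length unit).
#' @param W per-frame ellipse minor axis (same unit).
#' @param L per-frame ellipse major axis; must satisfy `W <= L`.
#' @param fps frames per second.
#' @return An object of class `ellipse_track`.
#' @export
ellipse_track <- function(x, y, W, L, fps = 30) {
  n <- length(x)
  .assert(length(y) == n && length(W) == n && length(L) == n,
          "x, y, W, L must have equal length")
  .assert(all(W > 0) && all(L > 0), "W and L must be positive")
  .assert(all(W <= L + 1e-12), "W must not exceed L")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 W = as.numeric(W), L = as.numeric(L), fps = fps),
            class = "ellipse_track")
}

#' @export
print.ethogram <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<ethogram> %d frames @ %g fps (%.1f s), %.1f%% grooming\n",
              n, x$fps, n / x$fps, 100 * mean(x$labels)))
  invisible(x)
}

#' @export
print.prediction_series <- function(x, ...) {
  cat(sprintf("<prediction_series> %d frames @ %g fps, mean prob %.3f\n",
              length(x$probs), x$fps, mean(x$probs)))
  invisible(x)
}

#' Merge several prediction streams into a consensus stream
#'
#' Combines per-frame probabilities across streams (e.g. the 32 predictions
#' from 4 models x 8 rotations/reflections). `mean` averages the
#' probabilities, `max` takes the per-frame maximum, and `vote` takes the
#' per-frame median; with an even number of streams `vote` uses the lower
#' median, which is deterministic and conservative toward not-grooming.
#'
#' @param streams non-empty list of [prediction_series] of equal length and fps.
#' @param mode one of `"mean"`, `"max"`, `"vote"`.
#' @return A consensus [prediction_series].
#' @export
merge_predictions <- function(streams, mode = c("mean", "max", "vote")) {
  mode <- match.arg(mode)
  .assert(is.list(streams) && length(streams) >= 1, "streams must be a non-empty list")
  lens <- vapply(streams, function(s) length(s$probs), integer(1))
  .assert(length(unique(lens)) == 1, "all streams must have the same length")
  fps <- vapply(streams, function(s) s$fps, numeric(1))
  .assert(length(unique(fps)) == 1, "all streams must share fps")
  P <- do.call(rbind, lapply(streams, function(s) s$probs))
  out <- switch(mode,
    mean = colMeans(P),
    max  = apply(P, 2, max),
    # lower median: k-th smallest of n values with k = ceiling(n/2)
    vote = apply(P, 2, function(v) sort(v)[ceiling(length(v) / 2)])
  )
  prediction_series(out, fps = fps[1])
}

#' Temporal smoothing of a prediction stream
#'
#' Centered rolling mean over `window` frames (default 46, the optimal
#' smoothing window for frame-level grooming classification at 30 fps). Near
#' the sequence ends the mean is taken over the available frames only, so the
#' output has the same length as the input and no padded values are invented.
#'
#' @param series a [prediction_series].
#' @param window window size in frames, `>= 1`.
#' @return A smoothed [prediction_series].
#' @export
smooth_predictions <- function(series, window = 46) {
  .assert(inherits(series, "prediction_series"), "series must be a prediction_series")
  .assert(length(window) == 1 && window >= 1, "window must be >= 1")
  prediction_series(.roll_mean(series$probs, as.integer(window)), fps = series$fps)
}

#' Threshold a probability stream into a binary ethogram
#'
#' A frame is called grooming when its probability is greater than or equal to
#' `threshold`.
#'
#' @param series a [prediction_series].
#' @param threshold operating point in (0, 1); default 0.5.
#' @return An [ethogram].
#' @export
binarize <- function(series, threshold = 0.5) {
  .assert(inherits(series, "prediction_series"), "series must be a prediction_series")
  .assert(length(threshold) == 1 && threshold > 0 && threshold < 1,
          "threshold must lie strictly inside (0, 1)")
  ethogram(as.integer(series$probs >= threshold), fps = series$fps)
}

#' Resting-posture mask from ellipse shape change
#'
#' A mouse resting in a hunched, grooming-like posture can fool a frame-level
#' classifier. Grooming motion makes the ellipse shape ratio W/L fluctuate
#' (standard deviation typically above 2.5e-4), whereas at rest it is nearly
#' constant (below 2e-5). Frames where the rolling standard deviation of W/L
#' over a centered `window` is strictly below `std_threshold` are flagged as
#' resting; [apply_resting_mask()] forces those frames to not-grooming.
#'
#' @param track an [ellipse_track].
#' @param window odd window length in frames (default 31).
#' @param std_threshold W/L standard-deviation cutoff (default 5e-5).
#' @return Logical vector, `TRUE` where the animal is judged to be resting.
#' @export
resting_mask <- function(track, window = 31, std_threshold = 5e-5) {
  .assert(inherits(track, "ellipse_track"), "track must be an ellipse_track")
  .assert(window %% 2 == 1, "window must be odd")
  ratio <- track$W / track$L
  .roll_sd(ratio, as.integer(window)) < std_threshold
}

#' @rdname resting_mask
#' @param eth an [ethogram] the same length as the mask.
#' @param mask logical vector from [resting_mask()].
#' @export
apply_resting_mask <- function(eth, mask) {
  .assert(inherits(eth, "ethogram"), "eth must be an ethogram")
  .assert(length(mask) == length(eth$labels), "mask length must match ethogram")
  labels <- eth$labels
  labels[mask] <- 0L
  ethogram(labels, fps = eth$fps)
}
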