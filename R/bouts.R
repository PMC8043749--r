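#' Segment an ethogram into grooming bouts
#'
#' A grooming bout is continuous time spent grooming, exceeding `min_bout_s`
#' seconds, in which brief pauses are tolerated: two grooming runs are merged
#' when the gap between them is shorter than `max_pause_s` seconds *and* the
#' animal does not locomote during the gap — its cumulative centroid path
#' length over the gap does not exceed `locomotion_factor` times its average
#' body length (mean major ellipse axis over the whole video). Merging is
#' applied first; a merged segment qualifies as a bout when its groomed time
#' (grooming frames only, excluding pauses) strictly exceeds `min_bout_s`.
#' Un-joined grooming segments at or below `min_bout_s` are discarded.
#'
#' @param eth an [ethogram].
#' @param track an [ellipse_track] of the same length, or `NULL`, in which
#'   case every gap is treated as motion-free.
#' @param min_bout_s minimum groomed seconds for a bout (strict; default 3).
#' @param max_pause_s longest mergeable pause in seconds (strict; default 10).
#' @param locomotion_factor pause path-length budget in body lengths (default 2).
#' @return A `bout_table`: data frame with 0-based half-open frame interval
#'   (`start`, `end`), `groomed_s`, `span_s`, and `n_pauses` per bout.
#' @export
segment_bouts <- function(eth, track = NULL, min_bout_s = 3, max_pause_s = 10,
                          locomotion_factor = 2) {
  .assert(inherits(eth, "ethogram"), "eth must be an ethogram")
  fps <- eth$fps
  lab <- eth$labels
  if (!is.null(track)) {
    .assert(inherits(track, "ellipse_track"), "track must be an ellipse_track")
    .assert(length(track$x) == length(lab), "track length must match ethogram")
  }
  runs <- .runs_of(lab == 1L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      groomed_s = numeric(0), span_s = numeric(0),
                      n_pauses = integer(0))
  class(empty) <- c("bout_table", "data.frame")
  if (nrow(runs) == 0) return(empty)

  body_len <- if (is.null(track)) NA_real_ else mean(track$L)
  # path length of centroid motion across gap [g0, g1): includes the steps
  # entering each gap frame
  gap_path <- function(g0, g1) {
    if (is.null(track) || g1 <= g0) return(0)
    idx <- seq.int(g0 + 1L, g1)            # 1-based frame indices g0..g1-1
    prev <- pmax(idx - 1L, 1L)
    sum(sqrt((track$x[idx] - track$x[prev])^2 + (track$y[idx] - track$y[prev])^2))
  }

  # greedy left-to-right merging of consecutive grooming runs
  seg_start <- runs[1, "start"]; seg_end <- runs[1, "end"]
  groomed <- runs[1, "end"] - runs[1, "start"]
  pauses <- 0L
  out <- list()
  flush <- function() {
    if (groomed / fps > min_bout_s)
      out[[length(out) + 1L]] <<- data.frame(
        start = seg_start, end = seg_end,
        groomed_s = groomed / fps, span_s = (seg_end - seg_start) / fps,
        n_pauses = pauses)
  }
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap_frames <- runs[i, "start"] - seg_end
      mergeable <- (gap_frames / fps) < max_pause_s &&
        (is.null(track) ||
           gap_path(seg_end, runs[i, "start"]) <= locomotion_factor * body_len)
      if (mergeable) {
        seg_end <- runs[i, "end"]
        groomed <- groomed + (runs[i, "end"] - runs[i, "start"])
        pauses <- pauses + 1L
      } else {
        flush()
        seg_start <- runs[i, "start"]; seg_end <- runs[i, "end"]
        groomed <- runs[i, "end"] - runs[i, "start"]
        pauses <- 0L
      }
    }
  }
  flush()
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$start <- as.integer(res$start); res$end <- as.integer(res$end)
  attr(res, "fps") <- fps
  class(res) <- c("bout_table", "data.frame")
  res
}

#' Bin bouts into fixed time segments
#'
#' Each bout is credited — its whole groomed duration and a count of one — to
#' the bin containing its start frame, so bins hold whole numbers of bouts and
#' a bin can hold more than its own width of grooming when a long bout starts
#' inside it.
#'
#' @param bouts a `bout_table` from [segment_bouts()].
#' @param bin_s bin width in seconds.
#' @param total_s total assay duration in seconds (sets the number of bins);
#'   defaults to the end of the last bout.
#' @param fps frames per second used for the bout frame indices.
#' @return Data frame with `bin` (0-based), `t_start_s`, `groomed_s`, `n_bouts`.
#' @export
bin_bouts <- function(bouts, bin_s, total_s = NULL, fps = attr(bouts, "fps")) {
  .assert(bin_s > 0, "bin_s must be > 0")
  if (is.null(fps)) fps <- 30
  if (is.null(total_s))
    total_s <- if (nrow(bouts)) max(bouts$end) / fps else bin_s
  n_bins <- max(1L, ceiling(total_s / bin_s))
  groomed <- numeric(n_bins); counts <- integer(n_bins)
  if (nrow(bouts)) {
    b <- pmin(floor((bouts$start / fps) / bin_s), n_bins - 1L) + 1L
    for (i in seq_along(b)) {
      groomed[b[i]] <- groomed[b[i]] + bouts$groomed_s[i]
      counts[b[i]] <- counts[b[i]] + 1L
    }
  }
  data.frame(bin = seq_len(n_bins) - 1L,
             t_start_s = (seq_len(n_bins) - 1L) * bin_s,
             groomed_s = groomed, n_bouts = counts)
}

#' Grooming phenotype panel for one animal
#'
#' Summaries of the bout structure of a single open-field assay:
#' \describe{
#'   \item{GrTime5m/20m/55m}{groomed seconds in bouts starting within the
#'     first 5 / 20 / 55 minutes.}
#'   \item{GrNum5m/20m/55m}{number of bouts starting within each horizon.}
#'   \item{GrAvgLen5m/20m/55m}{average groomed seconds per bout (0 when no
#'     bouts).}
#'   \item{GrTimeSlope55min, GrNumSlope55min}{ordinary least-squares slope of
#'     1-minute-binned groomed seconds (resp. bout counts) against bin index
#'     over the 55 one-minute bins; units s/min and bouts/min.}
#'   \item{GrPeakMidBin}{midpoint minute of the 5-minute bin with the most
#'     grooming (ties go to the earliest bin).}
#'   \item{GrPeakVal}{groomed seconds in that peak 5-minute bin.}
#'   \item{GrPeakSlope}{`GrPeakVal / GrPeakMidBin` — rate of rise to peak.}
#' }
#' Horizons longer than the recording are reported as `NA`.
#'
#' @param bouts a `bout_table` from [segment_bouts()].
#' @param eth the source [ethogram] (sets duration and fps).
#' @return A one-row data frame of class `grooming_metrics`.
#' @export
grooming_metrics <- function(bouts, eth) {
  .assert(inherits(eth, "ethogram"), "eth must be an ethogram")
  fps <- eth$fps
  dur_s <- length(eth$labels) / fps
  start_s <- bouts$start / fps
  horizon <- function(mins) {
    if (dur_s < mins * 60 - 1e-9) return(c(NA_real_, NA_real_, NA_real_))
    sel <- start_s < mins * 60
    tt <- sum(bouts$groomed_s[sel]); nn <- sum(sel)
    c(tt, nn, if (nn > 0) tt / nn else 0)
  }
  h5 <- horizon(5); h20 <- horizon(20); h55 <- horizon(55)

  slope_t <- slope_n <- peak_mid <- peak_val <- peak_slope <- NA_real_
  if (dur_s >= 55 * 60 - 1e-9) {
    b1 <- bin_bouts(bouts, bin_s = 60, total_s = 55 * 60, fps = fps)
    b1 <- b1[b1$bin < 55, ]
    slope_t <- .ols_slope(b1$groomed_s, b1$bin)
    slope_n <- .ols_slope(b1$n_bouts, b1$bin)
    b5 <- bin_bouts(bouts, bin_s = 300, total_s = 55 * 60, fps = fps)
    b5 <- b5[b5$bin < 11, ]
    peak <- which.max(b5$groomed_s)          # earliest max on ties
    peak_mid <- (b5$bin[peak] * 5) + 2.5
    peak_val <- b5$groomed_s[peak]
    peak_slope <- peak_val / peak_mid
  }
  res <- data.frame(
    GrTime5m = h5[1], GrNum5m = h5[2], GrAvgLen5m = h5[3],
    GrTime20m = h20[1], GrNum20m = h20[2], GrAvgLen20m = h20[3],
    GrTime55m = h55[1], GrNum55m = h55[2], GrAvgLen55m = h55[3],
    GrTimeSlope55min = slope_t, GrNumSlope55min = slope_n,
    GrPeakMidBin = peak_mid, GrPeakVal = peak_val, GrPeakSlope = peak_slope)
  class(res) <- c("grooming_metrics", "data.frame")
  res
}
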