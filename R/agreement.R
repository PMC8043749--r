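#' Frame-level agreement between two annotations
#'
#' @param a,b [ethogram] objects of equal length.
#' @return Fraction of frames on which the two annotations carry the same
#'   label, in \[0, 1\].
#' @export
frame_agreement <- function(a, b) {
  .assert(inherits(a, "ethogram") && inherits(b, "ethogram"),
          "a and b must be ethograms")
  .assert(length(a$labels) == length(b$labels), "ethograms must have equal length")
  mean(a$labels == b$labels)
}

#' Classify disagreement intervals between two annotations
#'
#' Each maximal run of frames on which the two annotations differ is placed in
#' a three-way taxonomy, decided by the agreed labels flanking the run:
#' \describe{
#'   \item{missed_bout}{both flanking agreed frames are not-grooming — one
#'     annotator called a bout the other did not.}
#'   \item{skipped_break}{both flanking agreed frames are grooming — one
#'     annotator recorded a break inside a bout the other bridged.}
#'   \item{misalignment}{one flank is agreed grooming and the other agreed
#'     not-grooming — both saw a bout start or end but disagree on the exact
#'     frame.}
#' }
#' Sequence boundaries count as agreed not-grooming flanks.
#'
#' @param a,b [ethogram] objects of equal length.
#' @return A list with `intervals`, a data frame of 0-based half-open frame
#'   intervals (`start`, `end`, `category`), and `summary`, the per-category
#'   count, total frames, and share of all disagreement frames.
#' @export
classify_disagreements <- function(a, b) {
  .assert(inherits(a, "ethogram") && inherits(b, "ethogram"),
          "a and b must be ethograms")
  la <- a$labels; lb <- b$labels
  .assert(length(la) == length(lb), "ethograms must have equal length")
  n <- length(la)
  runs <- .runs_of(la != lb)
  cats <- character(nrow(runs))
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      s <- runs[i, "start"]; e <- runs[i, "end"]
      # flanking agreed frames; out-of-range flank counts as not_grooming (0)
      left <- if (s > 0) la[s] else 0L          # la==lb on flanks
      right <- if (e < n) la[e + 1L] else 0L
      cats[i] <- if (left == 0L && right == 0L) "missed_bout"
                 else if (left == 1L && right == 1L) "skipped_break"
                 else "misalignment"
    }
  }
  intervals <- data.frame(start = as.integer(runs[, "start"]),
                          end = as.integer(runs[, "end"]),
                          category = cats, stringsAsFactors = FALSE)
  all_cats <- c("missed_bout", "skipped_break", "misalignment")
  frames <- intervals$end - intervals$start
  tot <- sum(frames)
  summary <- data.frame(
    category = all_cats,
    count = vapply(all_cats, function(cc) sum(cats == cc), integer(1)),
    frames = vapply(all_cats, function(cc) sum(frames[cats == cc]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  summary$fraction_of_disagreement <-
    if (tot > 0) summary$frames / tot else 0
  list(intervals = intervals, summary = summary)
}
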