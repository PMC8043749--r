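#' Remove per-strain outlier animals by the 1.5 IQR rule
#'
#' Within each strain, animals whose value (typically total grooming time,
#' `GrTime55m`) falls strictly below `Q1 - 1.5 IQR` or strictly above
#' `Q3 + 1.5 IQR` are dropped. Quartiles use the type-7 (linear
#' interpolation) convention. Strains with fewer than `min_group` animals
#' pass through unfiltered, since quartiles are not meaningful there.
#'
#' @param values numeric vector, one value per animal.
#' @param strain grouping factor/vector parallel to `values`.
#' @param min_group smallest group size to filter (default 4).
#' @return Logical vector, `TRUE` for animals kept.
#' @export
remove_outliers <- function(values, strain, min_group = 4) {
  .assert(length(values) == length(strain), "values and strain must match")
  keep <- rep(TRUE, length(values))
  for (g in unique(strain)) {
    idx <- which(strain == g)
    if (length(idx) < min_group) next
    q <- stats::quantile(values[idx], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    keep[idx] <- values[idx] >= q[1] - 1.5 * iqr & values[idx] <= q[2] + 1.5 * iqr
  }
  keep
}

#' Strain-level summary of grooming phenotypes
#'
#' Aggregates per-animal metrics and 5-minute binned grooming curves to
#' strain level, and measures how long each strain stays near its grooming
#' peak: `GrPeakLength` is the number of consecutive 5-minute bins, in the
#' run containing the peak bin, whose mean grooming is at least
#' `peak_frac` of the peak bin's value.
#'
#' @param metrics data frame of per-animal metrics with a `strain` column
#'   (as produced by [grooming_metrics()], row-bound with metadata).
#' @param curves matrix of per-animal 5-minute binned groomed seconds
#'   (animals x bins), rows aligned with `metrics`.
#' @param peak_frac fraction of the peak defining "at peak" (default 0.9).
#' @return A list with `means`, `sds` (per-strain metric summaries),
#'   `curves` (strain x bin mean curves) and `GrPeakLength` per strain.
#' @export
strain_summary <- function(metrics, curves, peak_frac = 0.9) {
  .assert(!is.null(metrics$strain), "metrics must carry a strain column")
  .assert(nrow(curves) == nrow(metrics), "curves rows must align with metrics")
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  strains <- unique(as.character(metrics$strain))
  agg <- function(f) {
    vals <- vapply(strains, function(s)
      vapply(num_cols, function(cc) f(metrics[[cc]][metrics$strain == s]),
             numeric(1)), numeric(length(num_cols)))
    m <- matrix(vals, nrow = length(strains), ncol = length(num_cols),
                byrow = TRUE, dimnames = list(strains, num_cols))
    m
  }
  means <- agg(function(v) mean(v, na.rm = TRUE))
  sds <- agg(function(v) stats::sd(v, na.rm = TRUE))
  cm <- t(vapply(strains, function(s)
    colMeans(curves[metrics$strain == s, , drop = FALSE]),
    numeric(ncol(curves))))
  peak_len <- vapply(strains, function(s) {
    v <- cm[s == strains, ]
    if (all(v <= 0)) return(0L)
    at_peak <- v >= peak_frac * max(v)
    runs <- .runs_of(at_peak)
    pk <- which.max(v) - 1L
    hit <- runs[, "start"] <= pk & runs[, "end"] > pk
    as.integer(runs[hit, "end"] - runs[hit, "start"])
  }, integer(1))
  list(strains = strains, means = means, sds = sds, curves = cm,
       GrPeakLength = peak_len)
}

#' Cluster strains into grooming pattern types
#'
#' k-means on z-scored strain features (typically overall grooming quantity
#' plus the relative 5-minute temporal profile), with many restarts for a
#' reproducible partition, followed by a principal-component projection for
#' display. Cluster labels are relabeled deterministically in order of
#' descending cluster-mean value of `order_by` (the first feature column by
#' default), so label 1 is always the heaviest-grooming type.
#'
#' @param features numeric matrix or data frame, one row per strain.
#' @param k number of clusters (default 3).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of k-means restarts (default 50).
#' @param order_by column of `features` used to order cluster labels.
#' @return A list with `cluster` (relabeled integer vector), `centers`
#'   (z-score space), `pc` (strain x 2 matrix of PC1/PC2 scores), and the
#'   fitted `kmeans` object.
#' @export
cluster_grooming_types <- function(features, k = 3, seed = 1, nstart = 50,
                                   order_by = 1) {
  X <- as.matrix(features)
  .assert(all(is.finite(X)), "features must be finite")
  .assert(k >= 1 && k <= nrow(X), "need 1 <= k <= number of strains")
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0   # constant features carry no signal
  set.seed(seed)
  km <- stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 100)
  ord <- order(tapply(X[, order_by], km$cluster, mean), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  cl <- relabel[km$cluster]
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)$x
  pc <- pc[, seq_len(min(2, ncol(pc))), drop = FALSE]
  list(cluster = cl, centers = km$centers, pc = pc, kmeans = km)
}
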