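# Independent reference implementations used to cross-check the package.
# These are written as direct, unoptimized transcriptions of the rules and
# share no code with the implementations they verify.

# Brute-force bout segmenter: explicit frame scans, iterative left-to-right
# merging, qualification last.
brute_force_bouts <- function(labels, fps, xs = NULL, ys = NULL, Ls = NULL,
                              min_bout_s = 3, max_pause_s = 10,
                              locomotion_factor = 2) {
  n <- length(labels)
  # enumerate grooming runs by scanning frames
  runs <- list()
  i <- 1
  while (i <= n) {
    if (labels[i] == 1) {
      j <- i
      while (j < n && labels[j + 1] == 1) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)   # 1-based inclusive
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(data.frame(start = integer(0), end = integer(0),
                                       groomed_s = numeric(0)))
  body <- if (is.null(Ls)) NA else mean(Ls)
  path_len <- function(a, b) {            # frames a..b (1-based inclusive)
    if (is.null(xs) || b < a) return(0)
    tot <- 0
    for (t in a:b) {
      pm <- max(t - 1, 1)
      tot <- tot + sqrt((xs[t] - xs[pm])^2 + (ys[t] - ys[pm])^2)
    }
    tot
  }
  # merge adjacent runs left to right
  segs <- list(c(runs[[1]], runs[[1]][2] - runs[[1]][1] + 1, 0)) # s,e,groomed_frames,pauses
  if (length(runs) > 1) for (k in 2:length(runs)) {
    cur <- segs[[length(segs)]]
    gap_start <- cur[2] + 1; gap_end <- runs[[k]][1] - 1
    gap_s <- (gap_end - gap_start + 1) / fps
    ok_pause <- gap_s < max_pause_s
    ok_move <- is.null(xs) ||
      path_len(gap_start, gap_end) <= locomotion_factor * body
    if (ok_pause && ok_move) {
      cur[2] <- runs[[k]][2]
      cur[3] <- cur[3] + runs[[k]][2] - runs[[k]][1] + 1
      cur[4] <- cur[4] + 1
      segs[[length(segs)]] <- cur
    } else segs[[length(segs) + 1]] <- c(runs[[k]],
                                         runs[[k]][2] - runs[[k]][1] + 1, 0)
  }
  keep <- Filter(function(s) s[3] / fps > min_bout_s, segs)
  if (!length(keep)) return(data.frame(start = integer(0), end = integer(0),
                                       groomed_s = numeric(0)))
  data.frame(start = sapply(keep, function(s) s[1] - 1L),  # back to 0-based
             end = sapply(keep, function(s) s[2]),
             groomed_s = sapply(keep, function(s) s[3] / fps),
             span_s = sapply(keep, function(s) (s[2] - s[1] + 1) / fps),
             n_pauses = sapply(keep, function(s) s[4]))
}

# random ethogram + track pair for segmentation fuzzing
random_eth_track <- function(n_frames = 600, fps = 30) {
  # blocky labels: alternating runs of geometric length
  labels <- integer(0)
  state <- 0L
  while (length(labels) < n_frames) {
    len <- 1 + stats::rgeom(1, 1 / (if (state == 1) 90 else 150))
    labels <- c(labels, rep(state, len))
    state <- 1L - state
  }
  labels <- labels[1:n_frames]
  if (all(labels == 0)) labels[sample(n_frames, 5)] <- 1L
  step <- stats::runif(n_frames, 0, 0.25)
  th <- stats::runif(n_frames, 0, 2 * pi)
  list(eth = ethogram(labels, fps),
       track = ellipse_track(cumsum(step * cos(th)), cumsum(step * sin(th)),
                             W = rep(3, n_frames), L = rep(6, n_frames),
                             fps = fps))
}

# OLS Wald oracle: direct lm.fit-free normal-equation solve, chi-square p
ols_wald_oracle <- function(y, x, W) {
  X <- cbind(W, x)
  XtX <- t(X) %*% X
  bh <- solve(XtX, t(X) %*% y)
  r <- y - X %*% bh
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  covb <- s2 * solve(XtX)
  b <- bh[ncol(X)]
  se <- sqrt(covb[ncol(X), ncol(X)])
  c(beta = b, se = se,
    p = stats::pchisq((b / se)^2, df = 1, lower.tail = FALSE))
}

# Brute-force greedy QTL clumping from first principles
brute_force_qtl <- function(snp, chrom, bp, p, X, p_threshold,
                            r2_threshold = 0.2, max_span_bp = 1e7) {
  sig <- which(p < p_threshold)
  loci <- list()
  unassigned <- sig
  while (length(unassigned)) {
    ord <- unassigned[order(p[unassigned], chrom[unassigned], bp[unassigned])]
    pk <- ord[1]
    memb <- pk
    for (j in setdiff(unassigned, pk)) {
      if (chrom[j] != chrom[pk]) next
      if (abs(bp[j] - bp[pk]) > max_span_bp) next
      if (stats::sd(X[, j]) == 0 || stats::sd(X[, pk]) == 0) next
      if (stats::cor(X[, j], X[, pk])^2 > r2_threshold) memb <- c(memb, j)
    }
    loci[[length(loci) + 1]] <- list(peak = snp[pk], members = sort(snp[memb]))
    unassigned <- setdiff(unassigned, memb)
  }
  loci
}

# greedy one-to-one matching of found module labels to planted labels,
# returning the fraction of nodes whose matched label agrees
label_agreement <- function(planted, found) {
  tab <- table(planted, found)
  agree <- 0
  while (length(tab) && nrow(tab) && ncol(tab)) {
    best <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    agree <- agree + tab[best[1], best[2]]
    tab <- tab[-best[1], -best[2], drop = FALSE]
  }
  agree / length(planted)
}
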