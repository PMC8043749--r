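#' Linkage-disequilibrium decay curve
#'
#' For every pair of SNPs on the same chromosome at most `max_dist_bp` apart,
#' computes the squared Pearson correlation of dosages, bins the pairs by
#' distance, and returns the per-bin mean r-squared and mean distance, with a
#' loess smooth overlaid. Inbred panels show large LD blocks, so the curve
#' starts near 1 and decays over megabases.
#'
#' @param G filtered, imputed [genotype_matrix] with positions sorted within
#'   chromosome.
#' @param max_dist_bp maximum pair distance (default 2.5 Mb).
#' @param bin_bp distance bin width (default 5000 bp).
#' @param loess_span span for the loess overlay (default 0.3).
#' @return Data frame `bin_start`, `bin_mean_dist`, `mean_r2`, `n_pairs`,
#'   `loess_r2`.
#' @export
ld_decay <- function(G, max_dist_bp = 2.5e6, bin_bp = 5000, loess_span = 0.3) {
  dists <- list(); r2s <- list(); k <- 0
  for (chr in unique(G$map$chrom)) {
    idx <- which(G$map$chrom == chr)
    idx <- idx[order(G$map$bp[idx])]
    bp <- G$map$bp[idx]
    X <- G$X[, idx, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    m <- length(idx)
    for (i in seq_len(m - 1)) {
      j <- which(bp[(i + 1):m] - bp[i] <= max_dist_bp) + i
      if (!length(j)) next
      ok <- sds[i] > 0 & sds[j] > 0
      if (!any(ok)) next
      j <- j[ok]
      r <- suppressWarnings(stats::cor(X[, i], X[, j, drop = FALSE]))
      k <- k + 1
      dists[[k]] <- bp[j] - bp[i]
      r2s[[k]] <- as.numeric(r)^2
    }
  }
  d <- unlist(dists); r2 <- unlist(r2s)
  if (!length(d))
    return(data.frame(bin_start = numeric(0), bin_mean_dist = numeric(0),
                      mean_r2 = numeric(0), n_pairs = integer(0),
                      loess_r2 = numeric(0)))
  bin <- floor(d / bin_bp)
  agg <- data.frame(
    bin_start = sort(unique(bin)) * bin_bp,
    bin_mean_dist = as.numeric(tapply(d, bin, mean)),
    mean_r2 = as.numeric(tapply(r2, bin, mean)),
    n_pairs = as.integer(tapply(r2, bin, length)))
  agg$loess_r2 <- if (nrow(agg) >= 10) {
    stats::predict(stats::loess(mean_r2 ~ bin_mean_dist, data = agg,
                                span = loess_span))
  } else agg$mean_r2
  agg
}

#' Greedy LD clumping of significant SNPs into QTL
#'
#' Starting from the significant SNP with the smallest p-value genome-wide,
#' assigns it a locus, adds every still-unassigned significant SNP on the
#' same chromosome within `max_span_bp` of the peak whose dosage correlation
#' with the peak exceeds `r2_threshold`, then moves to the next smallest
#' unassigned p-value, until every significant SNP belongs to exactly one
#' locus. Ties in p are broken by (chrom, bp) ascending.
#'
#' @param assoc an `assoc_result` from [lmm_gwas()].
#' @param G the matching [genotype_matrix] (same SNP universe).
#' @param p_threshold significance threshold (e.g. from
#'   [permutation_threshold()]); only SNPs with `p < p_threshold` take part.
#' @param r2_threshold locus-membership r-squared (strict `>`; default 0.2).
#' @param max_span_bp maximum distance from the peak SNP, upstream and
#'   downstream (default 10 Mb).
#' @param phenotype optional phenotype label carried into the output.
#' @return A `qtl_table` data frame: one row per locus with peak SNP, peak p,
#'   span, and member count; member SNP ids are in the `members` list column.
#' @export
greedy_qtl <- function(assoc, G, p_threshold, r2_threshold = 0.2,
                       max_span_bp = 1e7, phenotype = NA_character_) {
  sig <- which(assoc$p < p_threshold)
  empty <- data.frame(phenotype = character(0), peak_snp = character(0),
                      chrom = character(0), peak_bp = numeric(0),
                      peak_p = numeric(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0))
  empty$members <- list()
  class(empty) <- c("qtl_table", "data.frame")
  if (!length(sig)) return(empty)
  idx <- match(assoc$snp, G$map$id)
  .assert(!anyNA(idx), "assoc and G must share the SNP universe")
  ord <- sig[order(assoc$p[sig], assoc$chrom[sig], assoc$bp[sig])]
  assigned <- rep(FALSE, length(ord))
  loci <- list()
  for (i in seq_along(ord)) {
    if (assigned[i]) next
    pk <- ord[i]
    cand <- which(!assigned &
                    assoc$chrom[ord] == assoc$chrom[pk] &
                    abs(assoc$bp[ord] - assoc$bp[pk]) <= max_span_bp)
    xpk <- G$X[, idx[pk]]
    memb <- vapply(cand, function(jj) {
      j <- ord[jj]
      if (j == pk) return(TRUE)
      xj <- G$X[, idx[j]]
      if (stats::sd(xj) == 0 || stats::sd(xpk) == 0) return(FALSE)
      stats::cor(xpk, xj)^2 > r2_threshold
    }, logical(1))
    take <- cand[memb]
    assigned[take] <- TRUE
    mem_ids <- assoc$snp[ord[take]]
    loci[[length(loci) + 1L]] <- data.frame(
      phenotype = phenotype,
      peak_snp = assoc$snp[pk], chrom = assoc$chrom[pk],
      peak_bp = assoc$bp[pk], peak_p = assoc$p[pk],
      start_bp = min(assoc$bp[ord[take]]),
      end_bp = max(assoc$bp[ord[take]]),
      n_snps = length(take), stringsAsFactors = FALSE)
    loci[[length(loci)]]$members <- list(mem_ids)
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  class(out) <- c("qtl_table", "data.frame")
  out
}

#' Cluster association peaks across phenotypes
#'
#' Aggregates the peak SNPs of all phenotypes' QTL, forms the peak-SNP by
#' phenotype matrix of -log10 p (0 where a SNP was not tested or has no
#' signal recorded), and k-means-clusters the rows into `k` groups of SNPs
#' with similar cross-phenotype association profiles — a pleiotropy map.
#'
#' @param assoc_list named list of `assoc_result` objects, one per phenotype.
#' @param qtl_list named list of `qtl_table` objects from [greedy_qtl()],
#'   aligned with `assoc_list`.
#' @param k number of clusters (default 7).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 50).
#' @return A `peak_cluster_set`: list with `peaks` (data frame snp, chrom, bp,
#'   cluster, phenotypes that peak at the SNP), `logp` (the matrix), and the
#'   `kmeans` fit.
#' @export
cluster_peaks <- function(assoc_list, qtl_list, k = 7, seed = 1, nstart = 50) {
  .assert(length(assoc_list) == length(qtl_list),
          "assoc_list and qtl_list must align")
  phen <- names(assoc_list)
  peak_ids <- unique(unlist(lapply(qtl_list, function(q) q$peak_snp)))
  .assert(length(peak_ids) >= k, "need at least k peak SNPs")
  logp <- sapply(assoc_list, function(a) {
    v <- -log10(a$p[match(peak_ids, a$snp)])
    v[is.na(v)] <- 0
    v
  })
  rownames(logp) <- peak_ids
  set.seed(seed)
  km <- stats::kmeans(logp, centers = k, nstart = nstart, iter.max = 100)
  ref <- assoc_list[[1]]
  owner <- lapply(peak_ids, function(sid)
    phen[vapply(qtl_list, function(q) sid %in% q$peak_snp, logical(1))])
  peaks <- data.frame(snp = peak_ids,
                      chrom = ref$chrom[match(peak_ids, ref$snp)],
                      bp = ref$bp[match(peak_ids, ref$snp)],
                      cluster = as.integer(km$cluster),
                      stringsAsFactors = FALSE)
  peaks$phenotypes <- owner
  structure(list(peaks = peaks, logp = logp, kmeans = km,
                 phenotypes = phen), class = "peak_cluster_set")
}

#' Minimum-p combined scan for one peak cluster
#'
#' The phenotypes of a cluster are those in which any of the cluster's peak
#' SNPs is a QTL peak; their genome scans are combined by taking, at each
#' SNP, the minimum p-value across those phenotypes.
#'
#' @param pcs a `peak_cluster_set` from [cluster_peaks()].
#' @param assoc_list the same named list of scans used to build `pcs`.
#' @param cluster cluster label to combine.
#' @return Data frame `snp`, `chrom`, `bp`, `p` (the combined scan).
#' @export
combine_cluster_scans <- function(pcs, assoc_list, cluster) {
  sel <- pcs$peaks$cluster == cluster
  .assert(any(sel), "no peaks carry that cluster label")
  phens <- unique(unlist(pcs$peaks$phenotypes[sel]))
  .assert(length(phens) > 0, "cluster has no owning phenotypes")
  ref <- assoc_list[[phens[1]]]
  P <- sapply(phens, function(ph) assoc_list[[ph]]$p[match(ref$snp,
                                                           assoc_list[[ph]]$snp)])
  P <- as.matrix(P)
  data.frame(snp = ref$snp, chrom = ref$chrom, bp = ref$bp,
             p = apply(P, 1, min, na.rm = TRUE), stringsAsFactors = FALSE)
}

#' Count phenotype associations per gene (pleiotropy)
#'
#' A gene is associated with a phenotype when its interval overlaps (by at
#' least one base) any QTL span of that phenotype. Counts distinct
#' phenotypes per gene; [select_pleiotropic()] keeps genes at or above a
#' pleiotropy cutoff.
#'
#' @param qtl_list named list of `qtl_table` objects (names = phenotypes).
#' @param genes data frame with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive; see [read_gene_intervals()]).
#' @return Data frame `gene`, `n_phenotypes`, sorted by descending count.
#' @export
gene_pleiotropy <- function(qtl_list, genes) {
  .assert(all(c("gene", "chrom", "start", "end") %in% names(genes)),
          "genes needs columns gene, chrom, start, end")
  gr_genes <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end))
  hits <- lapply(names(qtl_list), function(ph) {
    q <- qtl_list[[ph]]
    if (!nrow(q)) return(integer(0))
    gr_q <- GenomicRanges::GRanges(
      seqnames = as.character(q$chrom),
      ranges = IRanges::IRanges(start = q$start_bp, end = q$end_bp))
    unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_genes, gr_q)))
  })
  counts <- integer(nrow(genes))
  for (h in hits) counts[h] <- counts[h] + 1L
  out <- data.frame(gene = genes$gene, n_phenotypes = counts,
                    stringsAsFactors = FALSE)
  out[order(-out$n_phenotypes, out$gene), , drop = FALSE]
}

#' @rdname gene_pleiotropy
#' @param counts output of [gene_pleiotropy()].
#' @param min_phenotypes minimum distinct phenotypes (default 6).
#' @export
select_pleiotropic <- function(counts, min_phenotypes = 6) {
  counts$gene[counts$n_phenotypes >= min_phenotypes]
}
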