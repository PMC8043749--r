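geno_from_cols <- function(..., chrom = NULL, bp = NULL) {
  X <- cbind(...)
  m <- ncol(X)
  genotype_matrix(X, data.frame(
    id = sprintf("q%02d", seq_len(m)),
    chrom = if (is.null(chrom)) rep("chr1", m) else chrom,
    bp = if (is.null(bp)) seq_len(m) * 1e6 else bp))
}
assoc_from <- function(G, p) {
  out <- data.frame(snp = G$map$id, chrom = G$map$chrom, bp = G$map$bp, p = p,
                    beta = 0, se = 1, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

test_that("LD decay: perfect proxies, independence level, block decay", {
  set.seed(71)
  n <- 40
  x <- stats::rbinom(n, 2, 0.5)
  G <- geno_from_cols(x, x, bp = c(1000, 1100))
  ld <- ld_decay(G)
  expect_equal(ld$mean_r2[1], 1)
  expect_equal(ld$bin_start[1], 0)

  # independent SNPs: E[r^2] ~ 1/(n-1)
  ni <- 200
  Xi <- matrix(stats::rbinom(ni * 60, 2, 0.5), ni, 60)
  Gi <- genotype_matrix(Xi, data.frame(id = sprintf("i%02d", 1:60),
                                       chrom = "chr1", bp = (1:60) * 5e4))
  ldi <- ld_decay(Gi)
  expect_lt(abs(stats::weighted.mean(ldi$mean_r2, ldi$n_pairs) - 1 / (ni - 1)),
            3 / (ni - 1))

  # block LD: within-block pairs correlated, curve decreasing with distance
  pop <- simulate_population(population_sim_config(
    n_strains = 60, replicates = 1, n_chromosomes = 1, snps_per_chrom = 200,
    block_len = 20, n_founders = 2, miss_rate = 0, seed = 72))
  ldb <- ld_decay(filter_genotypes(pop$G), max_dist_bp = 2.5e6)
  near <- ldb$mean_r2[ldb$bin_mean_dist < 2.5e5]
  far <- ldb$mean_r2[ldb$bin_mean_dist > 1.5e6]
  expect_gt(mean(near), mean(far) + 0.2)
})

test_that("greedy clumping follows p-order, r2 and the 10 Mb span rule", {
  x1 <- c(0, 0, 0, 0, 2, 2, 2, 2)
  x2 <- c(0, 0, 0, 2, 2, 2, 2, 0)   # r2 with x1 = 0.25
  x3 <- c(0, 2, 0, 2, 0, 2, 0, 2)   # r2 with x1 and x2 = 0
  G <- geno_from_cols(x1, x2, x3)
  a <- assoc_from(G, c(1e-8, 1e-7, 1e-6))
  q <- greedy_qtl(a, G, p_threshold = 1e-5)
  expect_equal(nrow(q), 2)
  expect_equal(q$peak_snp, c("q01", "q03"))
  expect_setequal(q$members[[1]], c("q01", "q02"))
  expect_equal(q$members[[2]], "q03")
  expect_true(all(q$peak_p <= sapply(seq_len(nrow(q)), function(i)
    min(a$p[a$snp %in% q$members[[i]]]))))

  # perfect correlation but 12 Mb apart: two separate loci
  G2 <- geno_from_cols(x1, x1, bp = c(1e6, 13e6))
  q2 <- greedy_qtl(assoc_from(G2, c(1e-8, 1e-7)), G2, p_threshold = 1e-5)
  expect_equal(nrow(q2), 2)

  # within 10 Mb they clump
  G3 <- geno_from_cols(x1, x1, bp = c(1e6, 9e6))
  q3 <- greedy_qtl(assoc_from(G3, c(1e-8, 1e-7)), G3, p_threshold = 1e-5)
  expect_equal(nrow(q3), 1)
  expect_equal(q3$n_snps, 2)

  # nothing significant: empty table
  expect_equal(nrow(greedy_qtl(a, G, p_threshold = 1e-10)), 0)
})

test_that("greedy clumping partitions the significant set, any order", {
  set.seed(73)
  for (rep in 1:25) {
    n <- 30; m <- 40
    X <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
    # induce some LD by copying columns with noise
    for (j in seq(2, m, by = 3)) {
      X[, j] <- X[, j - 1]
      flip <- sample(n, 3)
      X[flip, j] <- stats::rbinom(3, 2, 0.4)
    }
    G <- genotype_matrix(X, data.frame(
      id = sprintf("r%02d", 1:m),
      chrom = rep(c("chr1", "chr2"), each = m / 2),
      bp = rep(seq_len(m / 2) * 8e5, 2)))
    p <- stats::runif(m)^4
    a <- assoc_from(G, p)
    q <- greedy_qtl(a, G, p_threshold = 0.05)
    members <- unlist(q$members)
    sig <- a$snp[a$p < 0.05]
    expect_setequal(members, sig)               # covers the significant set
    expect_equal(anyDuplicated(members), 0L)    # exactly once each

    # equivalence with the first-principles reference
    ref <- brute_force_qtl(a$snp, a$chrom, a$bp, a$p, X, p_threshold = 0.05)
    expect_equal(nrow(q), length(ref))
    for (i in seq_along(ref)) {
      expect_equal(q$peak_snp[i], ref[[i]]$peak)
      expect_setequal(q$members[[i]], ref[[i]]$members)
    }

    # shuffling the input row order changes nothing
    ord <- sample(m)
    a_sh <- a[ord, ]; class(a_sh) <- class(a)
    q_sh <- greedy_qtl(a_sh, G, p_threshold = 0.05)
    expect_equal(q_sh$peak_snp, q$peak_snp)
  }
})

test_that("peak clustering groups pleiotropy profiles and min-p combines", {
  set.seed(74)
  n <- 60; m <- 30
  X <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
  G <- genotype_matrix(X, data.frame(id = sprintf("c%02d", 1:m),
                                     chrom = "chr1", bp = (1:m) * 2e6))
  # two phenotype groups hitting disjoint SNP sets
  mk_assoc <- function(hot) {
    p <- stats::runif(m, 0.2, 1)
    p[hot] <- 10^-stats::runif(length(hot), 6, 9)
    assoc_from(G, p)
  }
  assoc_list <- list(ph1 = mk_assoc(1:3), ph2 = mk_assoc(2:4),
                     ph3 = mk_assoc(15:17), ph4 = mk_assoc(16:18))
  qtl_list <- lapply(assoc_list, function(a)
    greedy_qtl(a, G, p_threshold = 1e-5, r2_threshold = 0.95))
  pcs <- cluster_peaks(assoc_list, qtl_list, k = 2, seed = 1)
  grp <- split(pcs$peaks$snp, pcs$peaks$cluster)
  lo <- vapply(grp, function(g) all(g %in% sprintf("c%02d", 1:4)), logical(1))
  expect_true(sum(lo) == 1)   # one cluster holds the early block, one the late

  comb <- combine_cluster_scans(pcs, assoc_list, cluster = pcs$peaks$cluster[
    pcs$peaks$snp == "c01"])
  # min-p combine at a SNP equals the smallest p across that cluster's phenotypes
  expect_equal(comb$p[comb$snp == "c02"],
               min(assoc_list$ph1$p[2], assoc_list$ph2$p[2]))
  expect_true(all(comb$p <= 1))
})

test_that("gene pleiotropy counts distinct phenotypes by interval overlap", {
  genes <- data.frame(gene = c("inQTL", "noQTL", "twoSame"),
                      chrom = c("chr1", "chr2", "chr1"),
                      start = c(5e6, 5e6, 40e6), end = c(6e6, 6e6, 41e6))
  qt <- function(chrom, s, e) {
    q <- data.frame(phenotype = "x", peak_snp = "s", chrom = chrom,
                    peak_bp = s, peak_p = 1e-8, start_bp = s, end_bp = e,
                    n_snps = 1)
    q$members <- list("s"); class(q) <- c("qtl_table", "data.frame"); q
  }
  qtl_list <- list(
    p1 = qt("chr1", 4e6, 5.5e6), p2 = qt("chr1", 5.9e6, 7e6),
    p3 = qt("chr1", 1e6, 8e6), p4 = qt("chr1", 5e6, 5e6),
    p5 = qt("chr1", 5.2e6, 5.3e6), p6 = qt("chr1", 5.5e6, 9e6),
    p7 = rbind(qt("chr1", 39e6, 42e6), qt("chr1", 40.5e6, 43e6)))
  counts <- gene_pleiotropy(qtl_list, genes)
  expect_equal(counts$n_phenotypes[counts$gene == "inQTL"], 6L)
  expect_equal(counts$n_phenotypes[counts$gene == "noQTL"], 0L)
  # two overlapping QTL of one phenotype still count once
  expect_equal(counts$n_phenotypes[counts$gene == "twoSame"], 1L)
  expect_identical(select_pleiotropic(counts, 6), "inQTL")
})
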