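make_geno <- function(X, chrom = NULL, bp = NULL) {
  m <- ncol(X)
  genotype_matrix(X, data.frame(
    id = sprintf("s%03d", seq_len(m)),
    chrom = if (is.null(chrom)) rep("chr1", m) else chrom,
    bp = if (is.null(bp)) seq_len(m) * 1e5 else bp))
}

test_that("SNP filters are inclusive at the stated boundaries", {
  n <- 50
  x_maf08 <- c(rep(2, 46), rep(0, 4))            # MAF 0.08: removed
  x_maf10 <- c(rep(2, 45), rep(0, 5))            # MAF exactly 0.10: kept
  x_miss6 <- c(rep(NA, 3), rep_len(c(0, 2), n - 3))       # 6% missing: removed
  x_miss4 <- c(rep(NA, 2), rep(c(0, 2), 24))     # 4% missing: kept
  G <- make_geno(cbind(x_maf08, x_maf10, x_miss6, x_miss4))
  Gf <- filter_genotypes(G)
  expect_setequal(Gf$map$id, G$map$id[c(2, 4)])
  # remaining missing dosages are mean-imputed
  expect_false(anyNA(Gf$X))
  kept_miss <- unname(Gf$X[1:2, Gf$map$id == G$map$id[4]])
  expect_equal(kept_miss, rep(mean(rep(c(0, 2), 24)), 2))
  expect_warning(filter_genotypes(make_geno(cbind(x_maf08))), "no SNPs")
})

test_that("kinship reflects genetic identity and chromosome exclusion", {
  # identical individuals: constant matrix
  X <- matrix(rep(c(0, 2, 2, 0, 2, 0), each = 4), 4, 6)
  G <- make_geno(X, chrom = rep(c("chr1", "chr2"), each = 3))
  K <- kinship(G)
  expect_equal(max(K) - min(K), 0)
  expect_equal(attr(kinship(G, exclude_chrom = "chr1"), "n_snps"), 3)

  # two clonal groups with opposite genotypes: block structure
  Xb <- rbind(matrix(2, 2, 6), matrix(0, 2, 6))
  Kb <- kinship(make_geno(Xb))
  expect_true(all(Kb[1:2, 1:2] > Kb[1:2, 3:4]))
  expect_equal(Kb, t(Kb))
  ev <- eigen(Kb, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("identity kinship reduces the LMM to the OLS Wald oracle", {
  set.seed(31)
  n <- 80; m <- 20
  X <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
  G <- make_geno(X)
  sex <- rep(0:1, n / 2)
  y <- 0.4 * X[, 3] + 0.5 * sex + stats::rnorm(n)
  got <- lmm_gwas(y, G, covariates = data.frame(sex = sex), K = diag(n))
  W <- cbind(1, sex)
  for (j in seq_len(m)) {
    ref <- ols_wald_oracle(y, X[, j], W)
    expect_equal(got$beta[j], unname(ref["beta"]), tolerance = 1e-6)
    expect_equal(got$se[j], unname(ref["se"]), tolerance = 1e-6)
    expect_equal(got$p[j], unname(ref["p"]), tolerance = 1e-6)
  }
})

test_that("association p-values are invariant to affine rescaling of y", {
  set.seed(32)
  n <- 60
  X <- matrix(stats::rbinom(n * 15, 2, 0.3), n, 15)
  G <- make_geno(X)
  y <- stats::rnorm(n) + 0.5 * X[, 1]
  a1 <- lmm_gwas(y, G)
  a2 <- lmm_gwas(7.3 * y + 11, G)
  expect_equal(a1$p, a2$p, tolerance = 1e-8)
  expect_equal(a2$beta, 7.3 * a1$beta, tolerance = 1e-8)
})

test_that("constant SNPs return p = 1 instead of failing", {
  set.seed(33)
  n <- 40
  X <- cbind(rep(2, n), matrix(stats::rbinom(n * 5, 2, 0.5), n, 5))
  a <- lmm_gwas(stats::rnorm(n), make_geno(X))
  expect_equal(a$p[1], 1)
  expect_true(all(a$p > 0 & a$p <= 1))
  expect_true(all(a$se > 0))
})

test_that("planted SNP effects are recovered with correct coverage", {
  pop <- simulate_population(population_sim_config(
    n_strains = 60, replicates = 2, n_chromosomes = 2, snps_per_chrom = 100,
    n_causal = 1, causal_beta = 1, h2 = 0.3, miss_rate = 0, seed = 41))
  Gf <- filter_genotypes(pop$G)
  # with the generating kinship supplied the model is correctly specified
  a <- lmm_gwas(pop$pheno$y, Gf, covariates = data.frame(sex = pop$pheno$sex),
                K = pop$K)
  hit <- a[a$snp == pop$truth$causal$snp, ]
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$beta - 1), 3 * hit$se)
  expect_lt(hit$p, 1e-4)
})

test_that("PVE recovers null and moderate heritability", {
  pop0 <- simulate_population(population_sim_config(
    n_strains = 100, replicates = 1, n_chromosomes = 2, snps_per_chrom = 150,
    n_causal = 0, h2 = 0, sex_effect = 0, miss_rate = 0, seed = 51))
  vc0 <- estimate_pve(pop0$pheno$y, filter_genotypes(pop0$G))
  expect_lt(abs(vc0$PVE), 2 * vc0$PVESE + 1e-8)

  pop5 <- simulate_population(population_sim_config(
    n_strains = 150, replicates = 1, n_chromosomes = 2, snps_per_chrom = 200,
    n_causal = 0, h2 = 0.5, sex_effect = 0, miss_rate = 0, seed = 52))
  vc5 <- estimate_pve(pop5$pheno$y, filter_genotypes(pop5$G))
  expect_lt(abs(vc5$PVE - 0.5), 2 * vc5$PVESE)
  expect_true(vc5$PVE >= 0 && vc5$PVE <= 1)
  expect_gt(vc5$sigma_g2, 0)

  # variance fully captured by a covariate: residual heritability near zero
  sex <- rep(0:1, length(pop0$pheno$y) / 2)
  y_cov <- 3 * sex + stats::rnorm(length(sex), 0, 0.1)
  vc_cov <- estimate_pve(y_cov, filter_genotypes(pop0$G),
                         covariates = data.frame(sex = sex))
  expect_lt(vc_cov$PVE, 0.15)
})

test_that("permutation threshold behaves at the edges", {
  set.seed(61)
  n <- 100
  # single SNP: threshold is just the alpha quantile of one uniform p
  X1 <- matrix(stats::rbinom(n, 2, 0.5), n, 1)
  thr1 <- permutation_threshold(stats::rnorm(n), make_geno(X1),
                                n_perm = 400, seed = 2, K = diag(n))
  expect_lt(abs(thr1$threshold - 0.05), 0.025)

  # duplicating every SNP adds no tests: identical threshold
  set.seed(62)
  Xm <- matrix(stats::rbinom(n * 30, 2, 0.4), n, 30)
  y <- stats::rnorm(n)
  G1 <- make_geno(Xm)
  G2 <- make_geno(cbind(Xm, Xm),
                  chrom = rep("chr1", 60), bp = c(1:30, 1:30 + 0.5) * 1e5)
  t1 <- permutation_threshold(y, G1, n_perm = 150, seed = 3)
  t2 <- permutation_threshold(y, G2, n_perm = 150, seed = 3)
  # identical up to eigendecomposition round-off
  expect_equal(t1$threshold, t2$threshold, tolerance = 1e-6)
  expect_equal(t1$min_p, t2$min_p, tolerance = 1e-5)
})
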