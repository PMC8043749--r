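#' Centered relatedness (kinship) matrix
#'
#' Computes the centered genomic relationship matrix `K = Xc Xc' / m` where
#' `Xc` is the dosage matrix with each SNP column centered by its mean
#' (twice the allele frequency) and `m` is the number of SNPs used. With
#' `exclude_chrom`, SNPs on that chromosome are left out
#' (leave-one-chromosome-out), so association tests on that chromosome are
#' not shrunk by the very markers being tested (proximal contamination).
#'
#' @param G a filtered, imputed [genotype_matrix] (see [filter_genotypes()]).
#' @param exclude_chrom chromosome to leave out, or `NULL` for all SNPs.
#' @return An n x n symmetric matrix with attribute `excluded_chrom` and
#'   `n_snps` (number of SNPs used).
#' @export
kinship <- function(G, exclude_chrom = NULL) {
  keep <- if (is.null(exclude_chrom)) rep(TRUE, nrow(G$map))
          else G$map$chrom != exclude_chrom
  .assert(any(keep), "no SNPs left after chromosome exclusion")
  X <- G$X[, keep, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  K <- tcrossprod(Xc) / ncol(Xc)
  dimnames(K) <- list(G$ids, G$ids)
  attr(K, "excluded_chrom") <- exclude_chrom
  attr(K, "n_snps") <- ncol(Xc)
  K
}

# eigendecompose K with a PSD check; small negative eigenvalues within
# numerical tolerance are clamped to zero
#' @noRd
.eigen_K <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  tol <- 1e-6 * max(abs(e$values), 1)
  .assert(min(e$values) > -tol, "kinship matrix is not positive semi-definite")
  e$values <- pmax(e$values, 0)
  e
}

# Profiled restricted log-likelihood (up to an additive constant) of the
# model y ~ W fixed effects, V = sigma_e^2 (lambda K + I), evaluated in the
# eigenbasis of K. ystar/Wstar are U'y and U'W; s the eigenvalues.
#' @noRd
.reml_loglik <- function(loglam, s, ystar, Wstar) {
  v <- exp(loglam) * s + 1
  wi <- 1 / v
  WtW <- crossprod(Wstar * wi, Wstar)
  beta <- solve(WtW, crossprod(Wstar * wi, ystar))
  r <- ystar - Wstar %*% beta
  rss <- sum(r^2 * wi)
  n <- length(ystar); p <- ncol(Wstar)
  -0.5 * ((n - p) * log(rss) + sum(log(v)) +
            as.numeric(determinant(WtW, logarithm = TRUE)$modulus))
}

# REML estimate of lambda = sigma_g^2 / sigma_e^2 by bounded scalar search
# over log lambda in [-10, 10]
#' @noRd
.reml_lambda <- function(s, ystar, Wstar, interval = c(-10, 10)) {
  opt <- stats::optimize(.reml_loglik, interval = interval, maximum = TRUE,
                         tol = 1e-6, s = s, ystar = ystar, Wstar = Wstar)
  list(loglam = opt$maximum, lambda = exp(opt$maximum),
       loglik = opt$objective,
       at_boundary = min(abs(opt$maximum - interval)) < 1e-3)
}

# Generalized-least-squares single-SNP scan at fixed lambda.
# Returns beta, se and Wald chi-square p per SNP column of Xstar.
#' @noRd
.gls_scan <- function(lambda, s, ystar, Wstar, Xstar) {
  wi <- 1 / (lambda * s + 1)
  sw <- sqrt(wi)
  yw <- ystar * sw
  Ww <- Wstar * sw
  Xw <- Xstar * sw
  qW <- qr(Ww)
  yr <- qr.resid(qW, yw)
  Xr <- qr.resid(qW, Xw)
  xx <- colSums(Xr^2)
  xy <- as.numeric(crossprod(Xr, yr))
  n <- length(yw); dfree <- n - ncol(Ww) - 1L
  ok <- xx > 1e-10 * n
  beta <- ifelse(ok, xy / xx, 0)
  rss <- pmax(sum(yr^2) - beta^2 * xx, 0)
  se <- ifelse(ok, sqrt(rss / dfree / xx), Inf)
  p <- ifelse(ok, stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE), 1)
  p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
  list(beta = beta, se = se, p = p)
}

#' @noRd
.design_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  d <- as.data.frame(covariates)
  .assert(nrow(d) == n, "covariates must have one row per individual")
  stats::model.matrix(~ ., data = d)
}

#' Linear mixed model genome-wide association scan
#'
#' Fits, per SNP, the model `y = W a + x b + u + e` with random polygenic
#' effect `u ~ N(0, sigma_g^2 K)` and residual `e ~ N(0, sigma_e^2 I)`. The
#' variance ratio `lambda = sigma_g^2 / sigma_e^2` is estimated once per
#' chromosome by restricted maximum likelihood under the null model (no SNP
#' term) using a single eigendecomposition of the leave-one-chromosome-out
#' kinship matrix; each SNP is then tested by generalized least squares and a
#' Wald test, `p = P(chi^2_1 >= (b/se)^2)`. SNPs that are constant after
#' filtering return `p = 1` by convention.
#'
#' @param y numeric phenotype vector.
#' @param G a filtered, imputed [genotype_matrix].
#' @param covariates optional data frame/matrix of fixed covariates (e.g. sex,
#'   or the dosage at a known marker to be conditioned on); an intercept is
#'   always included.
#' @param loco use leave-one-chromosome-out kinship (default `TRUE`); with
#'   `FALSE` a single all-SNP kinship is used for every chromosome.
#' @param K optional kinship matrix to use for every chromosome (e.g.
#'   `diag(n)` for unrelated individuals); overrides `loco`.
#' @return An `assoc_result` data frame: `snp`, `chrom`, `bp`, `beta`, `se`,
#'   `p`, with the per-chromosome `lambda` estimates as an attribute.
#' @export
lmm_gwas <- function(y, G, covariates = NULL, loco = TRUE, K = NULL) {
  n <- nrow(G$X)
  .assert(length(y) == n, "y must have one value per individual")
  W <- .design_matrix(covariates, n)
  .assert(n >= ncol(W) + 3, "need n >= number of covariates + 3")
  chroms <- unique(G$map$chrom)
  res <- vector("list", length(chroms))
  lambdas <- numeric(length(chroms)); names(lambdas) <- as.character(chroms)
  shared <- NULL
  if (!is.null(K)) {
    loco <- FALSE
    e <- .eigen_K(K)
    shared <- list(e = e, ystar = crossprod(e$vectors, y),
                   Wstar = crossprod(e$vectors, W))
  } else if (!loco) {
    K <- kinship(G)
    e <- .eigen_K(K)
    shared <- list(e = e, ystar = crossprod(e$vectors, y),
                   Wstar = crossprod(e$vectors, W))
  }
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    if (loco && length(chroms) > 1) {
      K <- kinship(G, exclude_chrom = chr)
      e <- .eigen_K(K)
      ystar <- crossprod(e$vectors, y)
      Wstar <- crossprod(e$vectors, W)
    } else if (loco) {
      # single chromosome: LOCO impossible, fall back to all-SNP kinship
      K <- kinship(G)
      e <- .eigen_K(K)
      ystar <- crossprod(e$vectors, y)
      Wstar <- crossprod(e$vectors, W)
    } else {
      e <- shared$e; ystar <- shared$ystar; Wstar <- shared$Wstar
    }
    fit <- .reml_lambda(e$values, ystar, Wstar)
    lambdas[ci] <- fit$lambda
    on_chr <- which(G$map$chrom == chr)
    Xstar <- crossprod(e$vectors, G$X[, on_chr, drop = FALSE])
    sc <- .gls_scan(fit$lambda, e$values, ystar, Wstar, Xstar)
    res[[ci]] <- data.frame(snp = G$map$id[on_chr],
                            chrom = G$map$chrom[on_chr],
                            bp = G$map$bp[on_chr],
                            beta = sc$beta, se = sc$se, p = sc$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "lambda") <- lambdas
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %d SNPs, %d chromosome(s); min p = %.3g\n",
              nrow(x), length(unique(x$chrom)), min(x$p)))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more SNPs\n", nrow(x) - 10))
  invisible(x)
}

#' Chip heritability (PVE) under the null mixed model
#'
#' Restricted-maximum-likelihood variance components of
#' `y = W a + u + e`, `u ~ N(0, sigma_g^2 K)`, with no SNP term and (by
#' convention) an all-SNP kinship matrix. The proportion of variance
#' explained is `PVE = sigma_g^2 kappa / (sigma_g^2 kappa + sigma_e^2)` with
#' `kappa = mean(diag(K))`, the average genetic variance per individual. Its
#' standard error `PVESE` comes from the curvature of the restricted
#' likelihood at the optimum via the delta method on log lambda.
#'
#' @param y phenotype vector.
#' @param K kinship matrix (from [kinship()]), or a [genotype_matrix] from
#'   which an all-SNP kinship is computed.
#' @param covariates optional fixed covariates (intercept always included).
#' @return Object of class `varcomp`: list with `sigma_g2`, `sigma_e2`,
#'   `delta` (`sigma_e2/sigma_g2`), `lambda`, `PVE`, `PVESE`, and `converged`
#'   (`FALSE` when the lambda estimate sits on the search boundary).
#' @export
estimate_pve <- function(y, K, covariates = NULL) {
  if (inherits(K, "genotype_matrix")) K <- kinship(K)
  n <- length(y)
  .assert(nrow(K) == n, "K must match length of y")
  W <- .design_matrix(covariates, n)
  e <- .eigen_K(K)
  ystar <- crossprod(e$vectors, y)
  Wstar <- crossprod(e$vectors, W)
  fit <- .reml_lambda(e$values, ystar, Wstar)
  lam <- fit$lambda
  # residual variance at the optimum
  v <- lam * e$values + 1
  wi <- 1 / v
  WtW <- crossprod(Wstar * wi, Wstar)
  beta <- solve(WtW, crossprod(Wstar * wi, ystar))
  rss <- sum((ystar - Wstar %*% beta)^2 * wi)
  sigma_e2 <- rss / (n - ncol(W))
  sigma_g2 <- lam * sigma_e2
  kappa <- mean(diag(K))
  pve <- lam * kappa / (lam * kappa + 1)
  # curvature of the profiled restricted log-likelihood in log lambda
  h <- 1e-3
  ll <- function(x) .reml_loglik(x, e$values, ystar, Wstar)
  d2 <- (ll(fit$loglam + h) - 2 * fit$loglik + ll(fit$loglam - h)) / h^2
  se_loglam <- if (d2 < -1e-10) sqrt(-1 / d2) else {
    # flat likelihood (boundary): use a broad step to bound the curvature
    d2b <- (ll(fit$loglam + 0.5) - 2 * fit$loglik + ll(fit$loglam - 0.5)) / 0.25
    if (d2b < -1e-10) sqrt(-1 / d2b) else Inf
  }
  pvese <- pve * (1 - pve) * se_loglam
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 delta = 1 / lam, lambda = lam, kappa = kappa,
                 PVE = pve, PVESE = pvese,
                 converged = !fit$at_boundary), class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("<varcomp> PVE = %.3f (SE %.3f), sigma_g2 = %.3g, sigma_e2 = %.3g%s\n",
              x$PVE, x$PVESE, x$sigma_g2, x$sigma_e2,
              if (x$converged) "" else " [boundary]"))
  invisible(x)
}

#' Permutation-based genome-wide significance threshold
#'
#' Shuffles the phenotype `n_perm` times, reruns the full mixed-model genome
#' scan for each shuffle, records the minimum p-value per scan, and returns
#' the empirical `alpha`-quantile of that min-p distribution. This corrects
#' for the number of tests while respecting the LD between SNPs (perfectly
#' correlated SNPs add no effective tests).
#'
#' @param y phenotype vector (the study uses one approximately normal
#'   phenotype, e.g. distance traveled, as the calibration trait).
#' @param G filtered, imputed [genotype_matrix].
#' @param covariates optional fixed covariates.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha genome-wide error rate (default 0.05).
#' @param seed RNG seed for the shuffles.
#' @param loco use LOCO kinship inside each scan (default `FALSE`; the
#'   threshold is a genome-level summary and a single all-SNP kinship keeps
#'   the permutation loop affordable).
#' @param K optional kinship matrix to use instead of the all-SNP kinship.
#' @return A list with `threshold` (p-value scale), `alpha`, `n_perm`, and
#'   `min_p` (the permutation min-p sample).
#' @export
permutation_threshold <- function(y, G, covariates = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = 1, loco = FALSE,
                                  K = NULL) {
  .assert(n_perm >= 100, "n_perm must be >= 100")
  n <- nrow(G$X)
  W <- .design_matrix(covariates, n)
  if (is.null(K)) K <- kinship(G) else loco <- FALSE
  e <- .eigen_K(K)
  Wstar <- crossprod(e$vectors, W)
  chroms <- unique(G$map$chrom)
  Xstars <- lapply(chroms, function(chr)
    crossprod(e$vectors, G$X[, G$map$chrom == chr, drop = FALSE]))
  loco_pre <- NULL
  if (loco && length(chroms) > 1) {
    loco_pre <- lapply(chroms, function(chr) {
      el <- .eigen_K(kinship(G, exclude_chrom = chr))
      list(e = el, Wstar = crossprod(el$vectors, W),
           Xstar = crossprod(el$vectors, G$X[, G$map$chrom == chr, drop = FALSE]))
    })
  }
  set.seed(seed)
  min_p <- vapply(seq_len(n_perm), function(b) {
    yp <- y[sample.int(n)]
    if (is.null(loco_pre)) {
      ystar <- crossprod(e$vectors, yp)
      lam <- .reml_lambda(e$values, ystar, Wstar)$lambda
      min(vapply(Xstars, function(Xs)
        min(.gls_scan(lam, e$values, ystar, Wstar, Xs)$p), numeric(1)))
    } else {
      min(vapply(loco_pre, function(pp) {
        ystar <- crossprod(pp$e$vectors, yp)
        lam <- .reml_lambda(pp$e$values, ystar, pp$Wstar)$lambda
        min(.gls_scan(lam, pp$e$values, ystar, pp$Wstar, pp$Xstar)$p)
      }, numeric(1)))
    }
  }, numeric(1))
  # order-statistic quantile: the ceiling(alpha * n_perm)-th smallest min p
  thr <- sort(min_p)[max(1L, ceiling(alpha * n_perm))]
  list(threshold = thr, alpha = alpha, n_perm = n_perm, min_p = min_p)
}
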