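#' Simulate a grooming ethogram with prediction streams and tracking
#'
#' Generates an alternating-renewal (semi-Markov) grooming label sequence for
#' one open-field assay. Bout initiations follow a time-varying rate profile
#' chosen by `archetype` — the three strain-level temporal patterns seen in
#' 55-minute assays: an inverted-U (rise to a mid-assay peak then decline),
#' an early plateau, and a monotone increase. Bout durations are lognormal;
#' bouts may contain brief motion-free pauses. Alongside the ground-truth
#' ethogram the generator emits `n_streams` noisy per-frame probability
#' streams (truth passed through a logistic noise channel with
#' stream-specific bias, emulating an ensemble of classifiers) and an
#' ellipse-fit track whose W/L shape ratio fluctuates at grooming-level
#' variance (sd 2.5e-4) during grooming and resting-level variance (sd 1e-5)
#' otherwise, with near-zero centroid motion during grooming and pauses.
#'
#' @param archetype `"type1_invertedU"`, `"type2_plateau"`, or
#'   `"type3_increasing"`.
#' @param duration_s assay length in seconds (default 3300 = 55 min).
#' @param fps frames per second (default 30).
#' @param seed RNG seed.
#' @param n_streams number of prediction streams (default 32).
#' @param bout_median_s,bout_sigma lognormal bout-duration parameters
#'   (median seconds and log-scale sd).
#' @param base_rate mean bout-initiation rate (bouts per second of
#'   non-grooming time) before the archetype profile is applied.
#' @param p_pause probability a bout contains a pause.
#' @param pause_mean_s mean pause duration (exponential, capped below 10 s).
#' @param stream_slope,stream_bias_sd,stream_noise_sd logistic channel
#'   parameters for the prediction streams.
#' @param wl_sd_groom,wl_sd_rest W/L per-frame noise sd during grooming and
#'   otherwise.
#' @return List with `truth` ([ethogram]), `streams` (list of
#'   [prediction_series]), `track` ([ellipse_track]), and `true_bouts`
#'   (data frame of generated bout intervals in frames).
#' @export
simulate_ethogram <- function(archetype = c("type1_invertedU", "type2_plateau",
                                            "type3_increasing"),
                              duration_s = 3300, fps = 30, seed = 1,
                              n_streams = 32,
                              bout_median_s = 15, bout_sigma = 0.6,
                              base_rate = 1 / 120,
                              p_pause = 0.3, pause_mean_s = 3,
                              stream_slope = 8, stream_bias_sd = 0.5,
                              stream_noise_sd = 1,
                              wl_sd_groom = 2.5e-4, wl_sd_rest = 1e-5) {
  archetype <- match.arg(archetype)
  set.seed(seed)
  n <- round(duration_s * fps)
  rate_profile <- switch(archetype,
    type1_invertedU = function(t) 0.2 + 1.6 * sin(pi * t / duration_s),
    type2_plateau   = function(t) pmin(t / (duration_s / 6), 1) * 1.2 + 0.1,
    type3_increasing = function(t) 0.2 + 1.8 * t / duration_s)
  labels <- integer(n)
  bouts <- list()
  t <- 0
  rate_max <- base_rate * max(rate_profile(seq(0, duration_s, length.out = 512)))
  repeat {
    # thinning: candidate events at the profile's peak rate, accepted with
    # probability rate(t) / rate_max, give an inhomogeneous Poisson process
    if (rate_max <= 0) break
    repeat {
      t <- t + stats::rexp(1, rate_max)
      if (t >= duration_s) break
      if (stats::runif(1) <
          base_rate * rate_profile(t) / rate_max) break
    }
    if (t >= duration_s) break
    dur <- stats::rlnorm(1, meanlog = log(bout_median_s), sdlog = bout_sigma)
    dur <- min(dur, duration_s - t - 1 / fps)
    if (dur < 1 / fps) break
    f0 <- floor(t * fps); f1 <- min(floor((t + dur) * fps), n)
    if (f1 > f0) {
      labels[(f0 + 1):f1] <- 1L
      # possibly split the bout with a motion-free pause
      if (stats::runif(1) < p_pause && (f1 - f0) / fps > 6) {
        pdur <- min(stats::rexp(1, 1 / pause_mean_s), 9.5)
        pf <- max(1L, round(pdur * fps))
        mid <- f0 + floor((f1 - f0) / 2)
        pe <- min(mid + pf, f1 - 1L)
        if (pe > mid) labels[(mid + 1):pe] <- 0L
      }
      bouts[[length(bouts) + 1L]] <- c(start = f0, end = f1)
    }
    t <- t + dur
  }
  true_bouts <- if (length(bouts)) as.data.frame(do.call(rbind, bouts))
                else data.frame(start = integer(0), end = integer(0))

  streams <- lapply(seq_len(n_streams), function(s) {
    bias <- stats::rnorm(1, 0, stream_bias_sd)
    eta <- stream_slope * (labels - 0.5) + bias + stats::rnorm(n, 0, stream_noise_sd)
    prediction_series(stats::plogis(eta), fps = fps)
  })

  ratio <- 0.55 + ifelse(labels == 1L, stats::rnorm(n, 0, wl_sd_groom),
                         stats::rnorm(n, 0, wl_sd_rest))
  L <- rep(6, n)                      # body length, cm
  W <- ratio * L
  # centroid: locomotion only while not grooming
  step <- ifelse(labels == 1L, 0.0005, 0.12)
  theta <- stats::runif(n, 0, 2 * pi)
  x <- cumsum(step * cos(theta))
  y <- cumsum(step * sin(theta))
  track <- ellipse_track(x, y, W, L, fps = fps)

  list(truth = ethogram(labels, fps = fps), streams = streams,
       track = track, true_bouts = true_bouts)
}

# shift run boundaries of a binary label vector by clamped normal jitter,
# preserving segment order
#' @noRd
.jitter_labels <- function(labels, sd_frames) {
  n <- length(labels)
  b <- which(diff(labels) != 0)          # boundary after frame b (1-based)
  if (!length(b) || sd_frames <= 0) return(labels)
  lo <- c(1, b[-length(b)])              # clamp windows between neighbors
  hi <- c(b[-1], n - 1)
  lo <- pmax(lo, floor((c(0, b[-length(b)]) + b) / 2) + 1)
  hi <- pmin(hi, ceiling((b + c(b[-1], n)) / 2) - 1)
  nb <- b + round(stats::rnorm(length(b), 0, sd_frames))
  nb <- pmin(pmax(nb, lo), hi)
  out <- integer(n)
  cur <- labels[1]; pos <- 1L
  for (i in seq_along(nb)) {
    out[pos:nb[i]] <- cur
    pos <- nb[i] + 1L
    cur <- 1L - cur
  }
  out[pos:n] <- cur
  out
}

#' Simulate a pair of noisy annotators
#'
#' Applies, independently per annotator, the three characteristic annotation
#' error modes to a ground-truth ethogram: boundary jitter (normal shift of
#' each bout start/end, clamped so segments keep their order), deletion of
#' short bouts, and fill-in of brief pauses between grooming runs. With a
#' single error mode enabled, every disagreement interval between the two
#' annotators falls in the corresponding taxonomy category of
#' [classify_disagreements()] (misalignment, missed_bout, skipped_break).
#'
#' @param truth ground-truth [ethogram].
#' @param jitter_sd_frames sd of the boundary shift in frames (0 = off).
#' @param p_drop_short_bout probability of deleting each short bout.
#' @param p_fill_pause probability of filling each short interior pause.
#' @param short_bout_max_s bouts shorter than this are deletion candidates.
#' @param fill_pause_max_s pauses shorter than this are fill candidates.
#' @param seed RNG seed.
#' @return List of two [ethogram]s, `a` and `b`.
#' @export
simulate_annotators <- function(truth, jitter_sd_frames = 0,
                                p_drop_short_bout = 0, p_fill_pause = 0,
                                short_bout_max_s = 3, fill_pause_max_s = 10,
                                seed = 1) {
  .assert(inherits(truth, "ethogram"), "truth must be an ethogram")
  set.seed(seed)
  fps <- truth$fps
  one <- function() {
    lab <- .jitter_labels(truth$labels, jitter_sd_frames)
    if (p_drop_short_bout > 0) {
      runs <- .runs_of(lab == 1L)
      for (i in seq_len(nrow(runs))) {
        len_s <- (runs[i, "end"] - runs[i, "start"]) / fps
        if (len_s < short_bout_max_s && stats::runif(1) < p_drop_short_bout)
          lab[(runs[i, "start"] + 1):runs[i, "end"]] <- 0L
      }
    }
    if (p_fill_pause > 0) {
      gaps <- .runs_of(lab == 0L)
      n <- length(lab)
      for (i in seq_len(nrow(gaps))) {
        s <- gaps[i, "start"]; e <- gaps[i, "end"]
        interior <- s > 0 && e < n          # flanked by grooming on both sides
        if (interior && (e - s) / fps < fill_pause_max_s &&
            stats::runif(1) < p_fill_pause)
          lab[(s + 1):e] <- 1L
      }
    }
    ethogram(lab, fps = fps)
  }
  list(a = one(), b = one())
}

#' Configuration for the strain-population simulator
#'
#' @param n_strains number of inbred strains.
#' @param replicates animals per strain x sex combination.
#' @param n_chromosomes,snps_per_chrom genome dimensions.
#' @param block_len SNPs per haplotype block (LD block size).
#' @param n_founders founder haplotypes per block (few founders = strong LD
#'   and kinship, matching an inbred panel).
#' @param bp_spacing base pairs between adjacent SNPs (default 50 kb).
#' @param n_causal number of planted causal SNPs.
#' @param causal_beta effect size per causal SNP (dosage scale).
#' @param h2 target proportion of phenotypic variance from the polygenic
#'   term, in \[0, 1).
#' @param sex_effect additive male-vs-female effect.
#' @param miss_rate per-genotype missing rate (applied at strain level).
#' @param seed RNG seed.
#' @return A `population_sim_config` list.
#' @export
population_sim_config <- function(n_strains = 50, replicates = 2,
                                  n_chromosomes = 4, snps_per_chrom = 250,
                                  block_len = 10, n_founders = 4,
                                  bp_spacing = 5e4,
                                  n_causal = 0, causal_beta = 1,
                                  h2 = 0.3, sex_effect = 0.5,
                                  miss_rate = 0.02, seed = 1) {
  .assert(h2 >= 0 && h2 < 1, "h2 must lie in [0, 1)")
  structure(as.list(environment()), class = "population_sim_config")
}

#' Simulate a replicated inbred-strain population
#'
#' Draws strain genomes block-wise from a small pool of founder haplotypes
#' (inducing realistic block LD and strain kinship), replicates each strain
#' across animals and sexes (all replicates of a strain share its genotype),
#' and generates phenotypes `y = sum_c x_c beta_c + g + sex gamma + e` with
#' polygenic effect `g ~ N(0, sigma_g^2 K)` drawn from the realized kinship
#' of the simulated genomes and scaled so that
#' `Var(polygenic) / Var(polygenic + residual)` equals the target `h2`
#' (planted causal effects sit on top of this background).
#'
#' @param config a [population_sim_config()].
#' @return List with `G` (a [genotype_matrix], including missing calls),
#'   `K` (the kinship used to draw the polygenic term), `pheno` (data frame
#'   `id`, `strain`, `sex`, `y`), and `truth` (planted parameters: causal
#'   SNP ids and effects, variance components, `h2`).
#' @export
simulate_population <- function(config = population_sim_config()) {
  cf <- config
  set.seed(cf$seed)
  m <- cf$n_chromosomes * cf$snps_per_chrom
  # founder haplotypes per block, strains pick one founder per block
  strain_geno <- matrix(0, cf$n_strains, m)
  for (chr in seq_len(cf$n_chromosomes)) {
    off <- (chr - 1) * cf$snps_per_chrom
    nblocks <- ceiling(cf$snps_per_chrom / cf$block_len)
    for (b in seq_len(nblocks)) {
      cols <- off + ((b - 1) * cf$block_len + 1):min(b * cf$block_len,
                                                     cf$snps_per_chrom)
      founders <- matrix(stats::rbinom(cf$n_founders * length(cols), 1, 0.5),
                         cf$n_founders, length(cols))
      pick <- sample.int(cf$n_founders, cf$n_strains, replace = TRUE)
      strain_geno[, cols] <- 2 * founders[pick, , drop = FALSE]
    }
  }
  map <- data.frame(
    id = sprintf("snp%05d", seq_len(m)),
    chrom = rep(sprintf("chr%d", seq_len(cf$n_chromosomes)),
                each = cf$snps_per_chrom),
    bp = rep(seq_len(cf$snps_per_chrom) * cf$bp_spacing, cf$n_chromosomes))

  # expand to individuals: replicates x 2 sexes per strain
  per_strain <- 2 * cf$replicates
  n <- cf$n_strains * per_strain
  strain <- rep(seq_len(cf$n_strains), each = per_strain)
  sex <- rep(rep(c(0L, 1L), each = cf$replicates), cf$n_strains)
  X <- strain_geno[strain, , drop = FALSE]

  # kinship of the complete genomes (before missingness)
  Xc <- sweep(X, 2, colMeans(X))
  K <- tcrossprod(Xc) / m
  kappa <- mean(diag(K))
  sigma_e2 <- 1
  sigma_g2 <- if (cf$h2 > 0 && kappa > 0) cf$h2 / (kappa * (1 - cf$h2)) else 0
  g <- if (sigma_g2 > 0) {
    e <- eigen(K, symmetric = TRUE)
    as.numeric(e$vectors %*% (sqrt(pmax(e$values, 0)) *
                                stats::rnorm(n))) * sqrt(sigma_g2)
  } else numeric(n)

  causal <- data.frame(snp = character(0), beta = numeric(0))
  y_causal <- numeric(n)
  if (cf$n_causal > 0) {
    freqs <- colMeans(X) / 2
    ok <- which(pmin(freqs, 1 - freqs) >= 0.15)
    picks <- sample(ok, min(cf$n_causal, length(ok)))
    for (j in picks) y_causal <- y_causal + cf$causal_beta * X[, j]
    causal <- data.frame(snp = map$id[picks], beta = cf$causal_beta,
                         stringsAsFactors = FALSE)
  }
  y <- y_causal + g + cf$sex_effect * sex + stats::rnorm(n, 0, sqrt(sigma_e2))

  # strain-level missingness, copied to all replicates
  Xna <- X
  if (cf$miss_rate > 0) {
    miss <- matrix(stats::runif(cf$n_strains * m) < cf$miss_rate,
                   cf$n_strains, m)
    Xna[miss[strain, , drop = FALSE]] <- NA
  }
  ids <- sprintf("s%03d_%s%d", strain, ifelse(sex == 1, "m", "f"),
                 rep(seq_len(cf$replicates), 2 * cf$n_strains))
  G <- genotype_matrix(Xna, map, ids = ids)
  pheno <- data.frame(id = ids, strain = sprintf("strain%03d", strain),
                      sex = sex, y = y, stringsAsFactors = FALSE)
  list(G = G, K = K, pheno = pheno,
       truth = list(causal = causal, h2 = cf$h2, sigma_g2 = sigma_g2,
                    sigma_e2 = sigma_e2, kappa = kappa, seed = cf$seed))
}

#' Simulate a module-structured gene-trait p-value table
#'
#' Genes and traits are partitioned into `n_modules` planted modules;
#' within-module pairs draw small p-values from `within_p_dist`, all other
#' pairs from `background_p_dist` (near-uniform). The planted labels are
#' returned for recovery scoring.
#'
#' @param n_genes,n_traits,n_modules table dimensions.
#' @param within_p_dist,background_p_dist functions `n -> p-values`;
#'   defaults `rbeta(n, 0.1, 1)` within modules and `runif(n)` background.
#' @param seed RNG seed.
#' @return List with `table` (data frame `gene`, `trait`, `subchapter`, `p`),
#'   `gene_module`, `trait_module`.
#' @export
simulate_phewas <- function(n_genes = 100, n_traits = 40, n_modules = 4,
                            within_p_dist = function(n) stats::rbeta(n, 0.1, 1),
                            background_p_dist = function(n) stats::runif(n),
                            seed = 1) {
  .assert(n_modules <= min(n_genes, n_traits) || n_modules == 0,
          "n_modules must not exceed min(n_genes, n_traits)")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  traits <- sprintf("T%03d", seq_len(n_traits))
  gmod <- if (n_modules > 0) rep_len(seq_len(n_modules), n_genes) else rep(0L, n_genes)
  tmod <- if (n_modules > 0) rep_len(seq_len(n_modules), n_traits) else rep(0L, n_traits)
  tab <- expand.grid(gene = genes, trait = traits, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  within <- n_modules > 0 &
    gmod[match(tab$gene, genes)] == tmod[match(tab$trait, traits)]
  p <- numeric(nrow(tab))
  p[within] <- pmin(pmax(within_p_dist(sum(within)), 1e-300), 1)
  p[!within] <- pmin(pmax(background_p_dist(sum(!within)), 1e-300), 1)
  tab$subchapter <- sprintf("sub%02d", tmod[match(tab$trait, traits)])
  tab$p <- p
  list(table = tab,
       gene_module = stats::setNames(gmod, genes),
       trait_module = stats::setNames(tmod, traits))
}
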