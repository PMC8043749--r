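#' Default pipeline configuration
#'
#' Returns the full configuration tree for [run_pipeline()] with every
#' parameter at its default. Every stochastic stage draws its seed
#' deterministically from the single top-level `seed`, so a config fully
#' determines a run.
#'
#' @param out_dir output directory for the run.
#' @param seed master RNG seed.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(out_dir = "groomscan_run", seed = 1) {
  structure(list(
    out_dir = out_dir,
    seed = seed,
    stages = c("simulate", "ethogram", "agreement", "metrics", "patterns",
               "covariates", "gwas", "qtl", "phewas"),
    fps = 30,
    behavior = list(
      n_animals = 4,
      duration_s = 3300,
      archetype = "type1_invertedU",
      n_streams = 32,
      smooth_window = 46,
      threshold = 0.5,
      resting_window = 31,
      resting_std = 5e-5,
      min_bout_s = 3,
      max_pause_s = 10,
      locomotion_factor = 2,
      write_streams = FALSE),
    annotator = list(
      jitter_sd_frames = 2,
      p_drop_short_bout = 0.5,
      p_fill_pause = 0.3),
    patterns = list(
      strains_per_type = 4,
      animals_per_strain = 3,
      duration_s = 3300,
      k = 3),
    covariates = list(
      n_animals = 200,
      sex_effect = 1,
      criterion = "aic"),
    population = list(
      n_strains = 40, replicates = 2, n_chromosomes = 4,
      snps_per_chrom = 150, block_len = 10, n_founders = 4,
      bp_spacing = 5e4, n_causal = 2, causal_beta = 1,
      h2 = 0.3, sex_effect = 0.5, miss_rate = 0.02),
    gwas = list(
      maf_min = 0.10, miss_max = 0.05, loco = TRUE,
      n_perm = 200, alpha = 0.05),
    qtl = list(r2_threshold = 0.2, max_span_bp = 1e7),
    phewas = list(
      n_genes = 60, n_traits = 24, n_modules = 3,
      p_max = 1e-3, n_restarts = 10)
  ), class = "run_config")
}

# merge user config into defaults; unknown keys anywhere are an error
#' @noRd
.merge_config <- function(user, defaults, path = "") {
  .assert(is.list(user), sprintf("config%s must be a list", path))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                        collapse = ", ")), call. = FALSE)
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      out[[nm]] <- .merge_config(user[[nm]], defaults[[nm]],
                                 paste0(path, ".", nm))
    else out[[nm]] <- user[[nm]]
  }
  out
}

#' Run the simulate-and-analyze pipeline
#'
#' Executes the selected stages in dependency order — ethogram cleaning,
#' annotator agreement, bout metrics, mixed-model GWAS with permutation
#' threshold, greedy QTL clumping, and bipartite PheWAS module detection —
#' on simulated inputs, writing each stage's outputs plus a machine-readable
#' `manifest.json` recording every parameter actually used (defaults
#' included). Reruns with an identical config produce byte-identical
#' outputs.
#'
#' @param config a [default_config()]-shaped list (partial trees allowed:
#'   anything omitted takes its default), or a path to a YAML file with the
#'   same structure. Unknown keys raise an error before any stage runs.
#' @return Invisibly, a list with the merged `config`, the written file
#'   `outputs`, and the in-memory stage `results`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cf <- .merge_config(unclass(config), unclass(default_config()))
  valid_stages <- c("simulate", "ethogram", "agreement", "metrics", "patterns",
                    "covariates", "gwas", "qtl", "phewas")
  bad <- setdiff(cf$stages, valid_stages)
  .assert(length(bad) == 0,
          paste("unknown stage(s):", paste(bad, collapse = ", ")))
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  results <- list()
  emit <- function(rel, writer) {
    path <- file.path(cf$out_dir, rel)
    writer(path)
    outputs <<- c(outputs, rel)
  }
  need <- function(s) s %in% cf$stages
  bh <- cf$behavior

  # --- behavioral side ------------------------------------------------
  sims <- NULL
  if (need("simulate") || need("ethogram") || need("agreement") || need("metrics")) {
    sims <- lapply(seq_len(bh$n_animals), function(i)
      simulate_ethogram(bh$archetype, duration_s = bh$duration_s,
                        fps = cf$fps, seed = cf$seed * 1000L + i,
                        n_streams = bh$n_streams))
    if (need("simulate")) {
      for (i in seq_along(sims)) {
        emit(sprintf("truth_animal%02d.csv", i),
             function(p) write_ethogram_csv(sims[[i]]$truth, p))
        emit(sprintf("track_animal%02d.csv", i),
             function(p) write_track_csv(sims[[i]]$track, p))
        if (isTRUE(bh$write_streams))
          emit(sprintf("streams_animal%02d.csv", i),
               function(p) write_predictions_csv(sims[[i]]$streams, p))
      }
    }
  }
  eths <- NULL
  if (need("ethogram") || need("metrics")) {
    eths <- lapply(seq_along(sims), function(i) {
      s <- sims[[i]]
      cons <- smooth_predictions(merge_predictions(s$streams, "mean"),
                                 window = bh$smooth_window)
      eth <- binarize(cons, threshold = bh$threshold)
      apply_resting_mask(eth, resting_mask(s$track, window = bh$resting_window,
                                           std_threshold = bh$resting_std))
    })
    if (need("ethogram"))
      for (i in seq_along(eths))
        emit(sprintf("ethogram_animal%02d.csv", i),
             function(p) write_ethogram_csv(eths[[i]], p))
    results$ethograms <- eths
  }
  if (need("agreement")) {
    an <- cf$annotator
    agr <- lapply(seq_along(sims), function(i) {
      pair <- simulate_annotators(sims[[i]]$truth,
                                  jitter_sd_frames = an$jitter_sd_frames,
                                  p_drop_short_bout = an$p_drop_short_bout,
                                  p_fill_pause = an$p_fill_pause,
                                  seed = cf$seed * 2000L + i)
      cd <- classify_disagreements(pair$a, pair$b)
      cbind(animal = i, agreement = frame_agreement(pair$a, pair$b),
            cd$summary)
    })
    agr <- do.call(rbind, agr)
    emit("agreement.tsv", function(p)
      utils::write.table(agr, p, sep = "\t", row.names = FALSE, quote = FALSE))
    results$agreement <- agr
  }
  if (need("metrics")) {
    met <- lapply(seq_along(eths), function(i) {
      bouts <- segment_bouts(eths[[i]], sims[[i]]$track,
                             min_bout_s = bh$min_bout_s,
                             max_pause_s = bh$max_pause_s,
                             locomotion_factor = bh$locomotion_factor)
      cbind(animal = i, grooming_metrics(bouts, eths[[i]]))
    })
    met <- do.call(rbind, met)
    emit("metrics.tsv", function(p)
      utils::write.table(met, p, sep = "\t", row.names = FALSE, quote = FALSE))
    results$metrics <- met
  }

  if (need("patterns")) {
    pt <- cf$patterns
    archetypes <- c("type1_invertedU", "type2_plateau", "type3_increasing")
    rows <- list(); curves <- list()
    for (ai in seq_along(archetypes)) for (si in seq_len(pt$strains_per_type)) {
      strain_id <- sprintf("%s_s%02d", archetypes[ai], si)
      for (rep in seq_len(pt$animals_per_strain)) {
        s <- simulate_ethogram(archetypes[ai], duration_s = pt$duration_s,
                               fps = cf$fps, n_streams = 1,
                               seed = cf$seed * 7000L +
                                 ai * 997L + si * 101L + rep)
        b <- segment_bouts(s$truth, s$track)
        rows[[length(rows) + 1L]] <- data.frame(
          strain = strain_id, archetype = archetypes[ai],
          grooming_metrics(b, s$truth))
        curves[[length(curves) + 1L]] <-
          bin_bouts(b, 300, total_s = pt$duration_s, fps = cf$fps)$groomed_s
      }
    }
    met <- do.call(rbind, rows)
    crv <- do.call(rbind, curves)
    keep <- remove_outliers(met$GrTime55m, met$strain)
    ss <- strain_summary(met[keep, ], crv[keep, , drop = FALSE])
    tot <- ss$means[, "GrTime55m"]
    feats <- cbind(total = tot, ss$curves / pmax(rowSums(ss$curves), 1e-9))
    cl <- cluster_grooming_types(feats, k = pt$k,
                                 seed = cf$seed * 8000L + 1L)
    emit("strain_clusters.tsv", function(p)
      utils::write.table(
        data.frame(strain = ss$strains, cluster = cl$cluster,
                   pc1 = cl$pc[, 1], pc2 = cl$pc[, 2],
                   GrPeakLength = ss$GrPeakLength),
        p, sep = "\t", row.names = FALSE, quote = FALSE))
    results$strain_clusters <- cl
    results$strain_summary <- ss
  }
  if (need("covariates")) {
    cv <- cf$covariates
    set.seed(cf$seed * 9000L + 1L)
    nc <- cv$n_animals
    tab <- data.frame(
      sex = factor(rep(c("f", "m"), length.out = nc)),
      weight = stats::rnorm(nc, 25, 3),
      room = factor(sample(c("r1", "r2"), nc, replace = TRUE)),
      season = factor(sample(c("spring", "summer", "fall", "winter"),
                             nc, replace = TRUE)))
    yc <- cv$sex_effect * (tab$sex == "m") + stats::rnorm(nc)
    sel <- stepwise_select(yc, tab, criterion = cv$criterion)
    emit("covariates.tsv", function(p)
      utils::write.table(sel$coefficients, p, sep = "\t", row.names = FALSE,
                         quote = FALSE))
    results$covariate_model <- sel
  }

  # --- genetics side --------------------------------------------------
  if (need("gwas") || need("qtl")) {
    pcf <- do.call(population_sim_config,
                   c(cf$population, list(seed = cf$seed * 3000L + 1L)))
    pop <- simulate_population(pcf)
    Gf <- filter_genotypes(pop$G, maf_min = cf$gwas$maf_min,
                           miss_max = cf$gwas$miss_max)
    assoc <- lmm_gwas(pop$pheno$y, Gf,
                      covariates = data.frame(sex = pop$pheno$sex),
                      loco = cf$gwas$loco)
    thr <- permutation_threshold(pop$pheno$y, Gf,
                                 covariates = data.frame(sex = pop$pheno$sex),
                                 n_perm = cf$gwas$n_perm,
                                 alpha = cf$gwas$alpha,
                                 seed = cf$seed * 4000L + 1L)
    pve <- estimate_pve(pop$pheno$y, Gf,
                        covariates = data.frame(sex = pop$pheno$sex))
    if (need("gwas")) {
      emit("assoc.tsv", function(p) write_assoc_tsv(assoc, p))
      emit("gwas_summary.json", function(p)
        jsonlite::write_json(list(threshold = thr$threshold,
                                  alpha = cf$gwas$alpha,
                                  n_perm = cf$gwas$n_perm,
                                  PVE = pve$PVE, PVESE = pve$PVESE,
                                  planted_causal = pop$truth$causal$snp),
                             p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    }
    results$assoc <- assoc
    results$threshold <- thr$threshold
    results$pve <- pve
    results$population_truth <- pop$truth
    if (need("qtl")) {
      qtls <- greedy_qtl(assoc, Gf, p_threshold = thr$threshold,
                         r2_threshold = cf$qtl$r2_threshold,
                         max_span_bp = cf$qtl$max_span_bp,
                         phenotype = "y")
      emit("qtl.tsv", function(p) {
        q <- as.data.frame(qtls)
        q$members <- vapply(q$members, paste, "", collapse = ",")
        utils::write.table(q, p, sep = "\t", row.names = FALSE, quote = FALSE)
      })
      if (nrow(qtls))
        emit("qtl.bed", function(p) write_qtl_bed(qtls, p))
      results$qtls <- qtls
    }
  }
  if (need("phewas")) {
    ph <- cf$phewas
    sim <- simulate_phewas(n_genes = ph$n_genes, n_traits = ph$n_traits,
                           n_modules = ph$n_modules,
                           seed = cf$seed * 5000L + 1L)
    net <- build_bipartite(sim$table, p_max = ph$p_max)
    part <- detect_modules(net, n_restarts = ph$n_restarts,
                           seed = cf$seed * 6000L + 1L)
    ranking <- rank_modules(net, part, sim$table)
    emit("modules.tsv", function(p)
      utils::write.table(
        data.frame(node = names(part$membership),
                   type = ifelse(names(part$membership) %in% net$genes,
                                 "gene", "trait"),
                   module = as.integer(part$membership)),
        p, sep = "\t", row.names = FALSE, quote = FALSE))
    emit("module_ranking.tsv", function(p)
      utils::write.table(ranking, p, sep = "\t", row.names = FALSE,
                         quote = FALSE))
    results$modules <- part
    results$module_ranking <- ranking
  }

  # the manifest records analysis parameters, not the run location, so two
  # runs of one config are byte-identical wherever they land
  cf_rec <- cf
  cf_rec$out_dir <- NULL
  emit("manifest.json", function(p)
    jsonlite::write_json(list(config = cf_rec, outputs = sort(outputs)),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  invisible(list(config = cf, outputs = sort(outputs), results = results))
}
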