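#' Build a gene-trait weighted bipartite network
#'
#' One node per gene and per trait; an edge connects a gene-trait pair whose
#' association p-value is at most `p_max`, weighted by `-log10(p)`. Genes or
#' traits left without edges are dropped.
#'
#' @param assoc data frame with columns `gene`, `trait`, `p`, and optionally
#'   `subchapter` (trait category).
#' @param p_max edge inclusion threshold (default 1e-3).
#' @return An object of class `bipartite_net`: list with `edges` (gene,
#'   trait, weight), `genes`, `traits`, `trait_category`.
#' @export
build_bipartite <- function(assoc, p_max = 1e-3) {
  .assert(all(c("gene", "trait", "p") %in% names(assoc)),
          "assoc needs columns gene, trait, p")
  .assert(nrow(assoc) == 0 || (all(assoc$p > 0) && all(assoc$p <= 1)),
          "p values must lie in (0, 1]")
  keep <- assoc$p <= p_max
  edges <- data.frame(gene = as.character(assoc$gene[keep]),
                      trait = as.character(assoc$trait[keep]),
                      weight = -log10(assoc$p[keep]),
                      stringsAsFactors = FALSE)
  cat_map <- NULL
  if ("subchapter" %in% names(assoc))
    cat_map <- unique(data.frame(trait = as.character(assoc$trait),
                                 subchapter = as.character(assoc$subchapter),
                                 stringsAsFactors = FALSE))
  structure(list(edges = edges,
                 genes = sort(unique(edges$gene)),
                 traits = sort(unique(edges$trait)),
                 trait_category = cat_map), class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("<bipartite_net> %d genes, %d traits, %d edges (total weight %.1f)\n",
              length(x$genes), length(x$traits), nrow(x$edges),
              sum(x$edges$weight)))
  invisible(x)
}

#' Simes combination of p-values
#'
#' For sorted p-values `p_(1) <= ... <= p_(m)`, returns
#' `min_i m p_(i) / i`, capped at 1 — valid under positive dependence and
#' used here to combine gene-level p-values into a trait-level association.
#'
#' @param pvals non-empty numeric vector of p-values in (0, 1\].
#' @return Combined p-value.
#' @export
simes_combine <- function(pvals) {
  .assert(length(pvals) >= 1, "pvals must be non-empty")
  .assert(all(pvals > 0 & pvals <= 1), "p values must lie in (0, 1]")
  m <- length(pvals)
  min(1, min(m * sort(pvals) / seq_len(m)))
}

# Barber weighted bipartite modularity of a labeled network.
# Q = (1/F) sum_c [ w(c) - K_c D_c / F ] over labels c, where w(c) is the
# within-label edge weight, K_c/D_c the gene-/trait-side weighted degrees in
# the label, and F the total edge weight.
#' @noRd
.barber_Q <- function(edges, glab, tlab) {
  F_tot <- sum(edges$weight)
  if (F_tot <= 0) return(0)
  kg <- tapply(edges$weight, edges$gene, sum)
  dt <- tapply(edges$weight, edges$trait, sum)
  labs <- union(unique(glab), unique(tlab))
  q <- 0
  for (cc in labs) {
    within <- sum(edges$weight[glab[edges$gene] == cc & tlab[edges$trait] == cc])
    Kc <- sum(kg[names(glab)[glab == cc]], na.rm = TRUE)
    Dc <- sum(dt[names(tlab)[tlab == cc]], na.rm = TRUE)
    q <- q + (within - Kc * Dc / F_tot)
  }
  q / F_tot
}

#' Detect modules by weighted bipartite modularity maximization
#'
#' Maximizes Barber's weighted bipartite modularity
#' `Q = (1/F) sum_ij (A_ij - k_i d_j / F) delta(g_i, g_j)` (the sum runs over
#' gene-trait pairs; `F` is total edge weight, `k`/`d` weighted degrees) by
#' asynchronous label propagation — each node repeatedly adopts the
#' neighboring label with the largest modularity gain, ties to the smallest
#' label — followed by a greedy label-merge phase, restarted `n_restarts`
#' times from random sweep orders; the best-Q partition wins. Deterministic
#' for a fixed seed.
#'
#' @param net a non-empty [build_bipartite()] network.
#' @param n_restarts label-propagation restarts (default 20).
#' @param seed RNG seed.
#' @return Object of class `module_partition`: list with `membership` (named
#'   integer vector over genes then traits), `Q`, `n_modules`, and
#'   `contribution` (per-module additive share of Q).
#' @export
detect_modules <- function(net, n_restarts = 20, seed = 1) {
  .assert(inherits(net, "bipartite_net"), "net must be a bipartite_net")
  .assert(nrow(net$edges) > 0, "network is empty")
  edges <- net$edges
  genes <- net$genes; traits <- net$traits
  F_tot <- sum(edges$weight)
  kg <- tapply(edges$weight, factor(edges$gene, levels = genes), sum)
  dt <- tapply(edges$weight, factor(edges$trait, levels = traits), sum)
  g_adj <- split(seq_len(nrow(edges)), edges$gene)   # edge rows per gene
  t_adj <- split(seq_len(nrow(edges)), edges$trait)

  one_run <- function() {
    glab <- stats::setNames(seq_along(genes), genes)
    tlab <- stats::setNames(length(genes) + seq_along(traits), traits)
    nodes <- data.frame(
      name = c(genes, traits),
      is_gene = rep(c(TRUE, FALSE), c(length(genes), length(traits))),
      stringsAsFactors = FALSE)
    repeat {
      moved <- FALSE
      for (ii in sample.int(nrow(nodes))) {
        nd <- nodes$name[ii]
        if (nodes$is_gene[ii]) {
          rows <- g_adj[[nd]]
          # candidate labels: labels of neighboring traits
          cand_lab <- tlab[edges$trait[rows]]
          S <- tapply(edges$weight[rows], cand_lab, sum)
          labs <- as.integer(names(S))
          Dtot <- vapply(labs, function(cc) sum(dt[tlab == cc]), numeric(1))
          gain <- S - kg[[nd]] * Dtot / F_tot
          best <- labs[order(-gain, labs)][1]
          if (max(gain) > 1e-12 && best != glab[[nd]]) {
            cur <- glab[[nd]]
            cur_gain <- if (as.character(cur) %in% names(S))
              S[[as.character(cur)]] - kg[[nd]] * sum(dt[tlab == cur]) / F_tot
            else 0
            if (max(gain) > cur_gain + 1e-12) { glab[nd] <- best; moved <- TRUE }
          }
        } else {
          rows <- t_adj[[nd]]
          cand_lab <- glab[edges$gene[rows]]
          S <- tapply(edges$weight[rows], cand_lab, sum)
          labs <- as.integer(names(S))
          Ktot <- vapply(labs, function(cc) sum(kg[glab == cc]), numeric(1))
          gain <- S - dt[[nd]] * Ktot / F_tot
          best <- labs[order(-gain, labs)][1]
          if (max(gain) > 1e-12 && best != tlab[[nd]]) {
            cur <- tlab[[nd]]
            cur_gain <- if (as.character(cur) %in% names(S))
              S[[as.character(cur)]] - dt[[nd]] * sum(kg[glab == cur]) / F_tot
            else 0
            if (max(gain) > cur_gain + 1e-12) { tlab[nd] <- best; moved <- TRUE }
          }
        }
      }
      if (!moved) break
    }
    # greedy merge phase on the label graph
    repeat {
      labs <- sort(unique(c(glab, tlab)))
      if (length(labs) < 2) break
      wl_g <- glab[edges$gene]; wl_t <- tlab[edges$trait]
      Kc <- vapply(labs, function(cc) sum(kg[glab == cc]), numeric(1))
      Dc <- vapply(labs, function(cc) sum(dt[tlab == cc]), numeric(1))
      # zero-gain merges are allowed when the labels share edges, so a
      # connected pair ends up in one module; disconnected labels only merge
      # on strictly positive gain (never, for Barber Q)
      best_gain <- -1e-9; best_pair <- NULL
      for (a in seq_along(labs)) for (b in seq_along(labs)) {
        if (a == b) next
        ca <- labs[a]; cb <- labs[b]
        cross <- sum(edges$weight[(wl_g == ca & wl_t == cb) |
                                    (wl_g == cb & wl_t == ca)])
        if (cross <= 0) next
        gain <- (cross - (Kc[a] * Dc[b] + Kc[b] * Dc[a]) / F_tot) / F_tot
        if (gain > best_gain + 1e-12) { best_gain <- gain; best_pair <- c(ca, cb) }
      }
      if (is.null(best_pair)) break
      glab[glab == best_pair[2]] <- best_pair[1]
      tlab[tlab == best_pair[2]] <- best_pair[1]
    }
    list(glab = glab, tlab = tlab, Q = .barber_Q(edges, glab, tlab))
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- one_run()
    if (is.null(best) || run$Q > best$Q + 1e-12) best <- run
  }
  memb <- c(best$glab, best$tlab)
  relabel <- stats::setNames(seq_along(unique(memb)), unique(memb))
  memb <- relabel[as.character(memb)]
  names(memb) <- c(genes, traits)
  glab <- memb[genes]; tlab <- memb[traits]
  labs <- sort(unique(memb))
  contrib <- vapply(labs, function(cc) {
    within <- sum(edges$weight[glab[edges$gene] == cc & tlab[edges$trait] == cc])
    Kc <- sum(kg[genes[glab == cc]], na.rm = TRUE)
    Dc <- sum(dt[traits[tlab == cc]], na.rm = TRUE)
    (within - Kc * Dc / F_tot) / F_tot
  }, numeric(1))
  names(contrib) <- labs
  structure(list(membership = memb, Q = sum(contrib),
                 n_modules = length(labs), contribution = contrib,
                 genes = genes, traits = traits), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules, Q = %.4f\n", x$n_modules, x$Q))
  invisible(x)
}

#' Rank modules by modularity contribution and median Simes association
#'
#' For each module, reports (1) its additive contribution to the network
#' modularity Q and (2) the median over the module's traits of
#' `-log10(Simes p)`, where each trait's Simes p combines the p-values of
#' that trait with the module's genes. Both rankings are returned; strongly
#' associated, well-separated modules lead both lists.
#'
#' @param net the [build_bipartite()] network.
#' @param partition a `module_partition` from [detect_modules()].
#' @param assoc the full gene-trait p-value table (columns `gene`, `trait`,
#'   `p`) used for the Simes combination.
#' @return Data frame, one row per module: `module`, `n_genes`, `n_traits`,
#'   `modularity_contribution`, `median_log10_simes`, `rank_modularity`,
#'   `rank_simes`, ordered by `rank_simes`.
#' @export
rank_modules <- function(net, partition, assoc) {
  memb <- partition$membership
  labs <- sort(unique(memb))
  rows <- lapply(labs, function(cc) {
    gs <- intersect(names(memb)[memb == cc], partition$genes)
    ts <- intersect(names(memb)[memb == cc], partition$traits)
    med <- NA_real_
    if (length(gs) && length(ts)) {
      simes_t <- vapply(ts, function(tr) {
        pv <- assoc$p[assoc$trait == tr & assoc$gene %in% gs]
        if (!length(pv)) return(NA_real_)
        simes_combine(pv)
      }, numeric(1))
      med <- stats::median(-log10(simes_t), na.rm = TRUE)
    }
    data.frame(module = cc, n_genes = length(gs), n_traits = length(ts),
               modularity_contribution = unname(partition$contribution[as.character(cc)]),
               median_log10_simes = med)
  })
  out <- do.call(rbind, rows)
  out$rank_modularity <- rank(-out$modularity_contribution, ties.method = "min")
  out$rank_simes <- rank(-out$median_log10_simes, ties.method = "min")
  out[order(out$rank_simes), , drop = FALSE]
}
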