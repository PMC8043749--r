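two_block_net <- function(w = 1) {
  ed <- rbind(expand.grid(gene = paste0("ga", 1:3), trait = paste0("ta", 1:3)),
              expand.grid(gene = paste0("gb", 1:3), trait = paste0("tb", 1:3)))
  ed$p <- 10^(-w)
  build_bipartite(ed, p_max = 1)
}

test_that("bipartite construction applies the p <= 1e-3 rule", {
  tab <- data.frame(gene = c("g1", "g2", "g3"), trait = c("t1", "t1", "t2"),
                    p = c(2e-3, 1e-4, 1e-3))
  net <- build_bipartite(tab)
  expect_equal(nrow(net$edges), 2)           # 2e-3 excluded, 1e-3 included
  expect_equal(net$edges$weight[net$edges$gene == "g2"], 4.0)
  expect_false("g1" %in% net$genes)          # isolated nodes dropped
  empty <- build_bipartite(tab[0, ])
  expect_equal(nrow(empty$edges), 0)
  expect_error(build_bipartite(data.frame(gene = "g", trait = "t", p = 0)),
               "\\(0, 1\\]")
})

test_that("Simes combination matches its closed form", {
  expect_equal(simes_combine(c(0.01, 0.04)), 0.02)
  expect_equal(simes_combine(c(0.04, 0.01)), 0.02)   # order-free
  expect_equal(simes_combine(0.37), 0.37)
  expect_equal(simes_combine(rep(0.2, 7)), 0.2)
  expect_error(simes_combine(numeric(0)), "non-empty")
  # monotone: decreasing any input never increases the output
  set.seed(81)
  for (i in 1:50) {
    p <- stats::runif(6)
    p2 <- p
    j <- sample(6, 1)
    p2[j] <- p2[j] * stats::runif(1)
    expect_lte(simes_combine(p2), simes_combine(p))
  }
})

test_that("module detection handles closed-form networks", {
  # two disconnected equal-weight complete blocks: Q = 0.5, blocks recovered
  net <- two_block_net()
  part <- detect_modules(net, n_restarts = 5, seed = 1)
  expect_equal(part$Q, 0.5, tolerance = 1e-12)
  expect_equal(part$n_modules, 2)
  memb <- part$membership
  expect_length(unique(memb[c(paste0("ga", 1:3), paste0("ta", 1:3))]), 1)
  expect_length(unique(memb[c(paste0("gb", 1:3), paste0("tb", 1:3))]), 1)
  # per-module contributions sum to Q
  expect_equal(sum(part$contribution), part$Q)

  # a single edge carries zero modularity and one module
  single <- build_bipartite(data.frame(gene = "g", trait = "t", p = 1e-4))
  ps <- detect_modules(single, n_restarts = 2, seed = 1)
  expect_equal(ps$Q, 0)
  expect_equal(ps$n_modules, 1)
})

test_that("module detection recovers planted modules", {
  sim <- simulate_phewas(n_genes = 60, n_traits = 24, n_modules = 3, seed = 82)
  net <- build_bipartite(sim$table)
  part <- detect_modules(net, n_restarts = 10, seed = 3)
  gm <- sim$gene_module[intersect(names(sim$gene_module), net$genes)]
  agree <- label_agreement(gm, part$membership[names(gm)])
  expect_gte(agree, 0.95)
  # partition quality dominates trivial partitions (all-in-one has Q = 0)
  expect_gt(part$Q, 0)
})

test_that("best-Q is stable under node input order for a fixed seed", {
  sim <- simulate_phewas(n_genes = 40, n_traits = 16, n_modules = 2, seed = 83)
  tab <- sim$table
  net1 <- build_bipartite(tab)
  net2 <- build_bipartite(tab[rev(seq_len(nrow(tab))), ])
  q1 <- detect_modules(net1, n_restarts = 8, seed = 5)$Q
  q2 <- detect_modules(net2, n_restarts = 8, seed = 5)$Q
  expect_equal(q1, q2, tolerance = 1e-9)
})

test_that("module ranking orders by median Simes association", {
  # module A at p = 1e-6 everywhere; module B at 1e-3: A ranks first
  ed <- rbind(expand.grid(gene = paste0("ga", 1:3), trait = paste0("ta", 1:3)),
              expand.grid(gene = paste0("gb", 1:3), trait = paste0("tb", 1:3)))
  ed$p <- ifelse(grepl("a", ed$gene), 1e-6, 1e-3)
  net <- build_bipartite(ed, p_max = 1)
  part <- detect_modules(net, n_restarts = 5, seed = 1)
  rk <- rank_modules(net, part, ed)
  top <- rk$module[rk$rank_simes == 1]
  expect_true(all(grepl("a", names(part$membership)[part$membership == top])))
  expect_equal(rk$median_log10_simes[rk$rank_simes == 1], 6)

  # single-module partition: contribution equals Q
  single <- build_bipartite(data.frame(gene = c("g1", "g1", "g2"),
                                       trait = c("t1", "t2", "t1"),
                                       p = c(1e-4, 1e-5, 1e-4)))
  sp <- detect_modules(single, n_restarts = 3, seed = 1)
  rks <- rank_modules(single, sp, data.frame(gene = c("g1", "g1", "g2"),
                                             trait = c("t1", "t2", "t1"),
                                             p = c(1e-4, 1e-5, 1e-4)))
  expect_equal(sum(rks$modularity_contribution), sp$Q)
  # one gene, one trait module: median Simes is that pair's -log10 p
  pair <- build_bipartite(data.frame(gene = "g", trait = "t", p = 1e-4))
  pp <- detect_modules(pair, n_restarts = 2, seed = 1)
  rkp <- rank_modules(pair, pp, data.frame(gene = "g", trait = "t", p = 1e-4))
  expect_equal(rkp$median_log10_simes, 4)
})
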