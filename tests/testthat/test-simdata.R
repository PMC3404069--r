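test_that("genotypes are binary, evenly partitioned, and seed-determined", {
  sp <- sim_params(n_samples = 40, n_genes = 23, n_chromosomes = 5,
                   n_edges = 10, seed = 9)
  g <- simulate_genotypes(sp)
  expect_true(all(g$values %in% c(0L, 1L)))
  expect_equal(nrow(g$marker_map), 23)
  sizes <- table(g$marker_map$chromosome)
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(g$marker_map$mutation_type %in% c("cis", "trans")))
  # positions restart per chromosome
  expect_true(all(tapply(g$marker_map$position_index,
                         g$marker_map$chromosome,
                         function(p) identical(p, seq_along(p)))))
  expect_identical(g, simulate_genotypes(sp))
})

test_that("zero-recombination limit gives constant chromosomes", {
  sp <- sim_params(n_samples = 15, n_genes = 20, n_chromosomes = 4,
                   n_edges = 5, recomb_prob = 1e-12, seed = 2)
  g <- simulate_genotypes(sp)
  for (chr in unique(g$marker_map$chromosome)) {
    cols <- which(g$marker_map$chromosome == chr)
    expect_true(all(apply(g$values[, cols, drop = FALSE], 1L,
                          function(r) length(unique(r)) == 1L)))
  }
})

test_that("adjacent-marker correlation matches 1 - 2r; chromosomes independent", {
  for (r in c(0.5, 0.1)) {
    sp <- sim_params(n_samples = 2000, n_genes = 100, n_chromosomes = 2,
                     n_edges = 5, recomb_prob = r, seed = 31)
    g <- simulate_genotypes(sp)
    adj <- sapply(1:49, function(j) cor(g$values[, j], g$values[, j + 1]))
    expect_lt(abs(mean(adj) - (1 - 2 * r)), 0.05)
  }
  # across the chromosome boundary (marker 50 | 51) no linkage remains
  sp <- sim_params(n_samples = 2000, n_genes = 100, n_chromosomes = 2,
                   n_edges = 5, recomb_prob = 0.1, seed = 31)
  g <- simulate_genotypes(sp)
  expect_lt(abs(cor(g$values[, 50], g$values[, 51])), 0.06)
  # symmetric cross: allele frequency 0.5 within Monte-Carlo error
  freqs <- colMeans(g$values)
  se <- sqrt(0.25 / 2000)
  expect_true(all(abs(freqs - 0.5) < 4 * se))
})

test_that("network has the exact edge count with no self-loops or duplicates", {
  for (seed in 1:8) {
    sp <- sim_params(n_samples = 10, n_genes = 50, n_chromosomes = 5,
                     n_edges = 120, seed = seed)
    net <- simulate_network(sp)
    expect_equal(nrow(net), 120)
    expect_false(any(net$regulator == net$target))
    expect_false(anyDuplicated(paste(net$regulator, net$target)) > 0)
  }
  empty <- simulate_network(sim_params(n_samples = 5, n_genes = 10,
                                       n_chromosomes = 2, n_edges = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_error(sim_params(n_samples = 5, n_genes = 4, n_chromosomes = 2,
                          n_edges = 13, seed = 1), "exceeds")
})

test_that("mean out-degree equals edges per gene at benchmark scale", {
  sp <- sim_params(n_samples = 2, n_genes = 1000, n_chromosomes = 20,
                   n_edges = 2000, seed = 4)
  net <- simulate_network(sp)
  out_deg <- table(factor(net$regulator, levels = attr(net, "gene_ids")))
  expect_equal(mean(out_deg), 2.0)
})

test_that("out-degree is heavier-tailed than in-degree", {
  wins <- 0L
  for (seed in 1:20) {
    sp <- sim_params(n_samples = 2, n_genes = 100, n_chromosomes = 5,
                     n_edges = 300, seed = seed)
    net <- simulate_network(sp)
    gid <- attr(net, "gene_ids")
    vo <- var(table(factor(net$regulator, levels = gid)))
    vi <- var(table(factor(net$target, levels = gid)))
    wins <- wins + (vo > vi)
  }
  expect_gte(wins, 18L)
})

test_that("cis effect with no network shifts exactly the mutated gene", {
  sp <- sim_params(n_samples = 30, n_genes = 8, n_chromosomes = 2,
                   n_edges = 0, noise_sd = 0, effect_size_cis = 1, seed = 6)
  geno <- simulate_genotypes(sp)
  geno$marker_map$mutation_type <- c("cis", rep("trans", 7))
  gids <- geno$marker_map$gene_id
  net <- gold_network(character(0), character(0), numeric(0), gene_ids = gids)
  expr <- simulate_expression(net, geno, sp)
  g1 <- geno$values[, 1] == 1
  expect_equal(unname(mean(expr[g1, 1]) - mean(expr[!g1, 1])), 1)
  expect_true(all(apply(expr[, -1], 2L, sd) == 0))
})

test_that("no effects and no noise give constant expression", {
  sp <- sim_params(n_samples = 20, n_genes = 10, n_chromosomes = 2,
                   n_edges = 15, noise_sd = 0, effect_size_cis = 0,
                   effect_size_trans = 0, seed = 7)
  sim <- simulate_sysgen(sp)
  expect_true(all(apply(sim$expression, 2L, sd) < 1e-12))
})

test_that("noiseless expression is an exact steady-state fixed point", {
  sp <- sim_params(n_samples = 12, n_genes = 15, n_chromosomes = 3,
                   n_edges = 25, noise_sd = 0, seed = 8)
  geno <- simulate_genotypes(sp)
  net <- simulate_network(sp)
  expr <- simulate_expression(net, geno, sp)
  B0 <- attr(expr, "adjacency")
  map <- geno$marker_map
  for (i in seq_len(nrow(expr))) {
    ci <- rep(1, 15)
    on_cis <- map$mutation_type == "cis" & geno$values[i, ] == 1L
    ci[on_cis] <- ci[on_cis] + sp$effect_size_cis
    B <- B0
    on_trans <- which(map$mutation_type == "trans" & geno$values[i, ] == 1L)
    if (length(on_trans))
      B[, on_trans] <- B[, on_trans] * (1 + sp$effect_size_trans)
    # damping bound holds for the realized genotype-specific system
    expect_lte(max(Mod(eigen(B, only.values = TRUE)$values)),
               sp$network_damping + 1e-8)
    expect_equal(unname(expr[i, ]), unname(drop(ci + B %*% expr[i, ])),
                 tolerance = 1e-10)
  }
})

test_that("a single cis-driven edge propagates to the target", {
  st <- planted_study(n_samples = 200, seed = 3)
  m <- st$genotypes$values[, 3]
  expect_gt(cor(m, st$expression[, st$target]), 0.5)
})

test_that("the full simulation is bit-identical under a fixed seed", {
  sp <- sim_params(n_samples = 25, n_genes = 12, n_chromosomes = 3,
                   n_edges = 20, seed = 77)
  expect_identical(simulate_sysgen(sp), simulate_sysgen(sp))
})
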