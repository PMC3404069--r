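# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles enumerate pairs / ranks directly and never call
# the package's metric code paths.

# exhaustive positive-negative pair counting; unranked items are treated as
# a block below the list (ranked-vs-unranked decided outright, unranked
# pairs get half credit)
brute_auroc <- function(labels, P, N) {
  rp <- sum(labels); rn <- length(labels) - rp
  pu <- P - rp; nu <- N - rn
  pos_ranks <- which(labels == 1)
  neg_ranks <- which(labels == 0)
  conc <- 0
  for (i in pos_ranks) {
    for (j in neg_ranks) conc <- conc + (i < j)
    conc <- conc + nu                       # ranked positive beats unranked negs
  }
  conc <- conc + 0.5 * pu * nu              # both unranked: coin flip
  conc / (P * N)
}

# direct average-precision sum over the ranks of retrieved positives
brute_ap <- function(labels, P) {
  tp <- 0; s <- 0
  for (k in seq_along(labels)) {
    if (labels[k] == 1) {
      tp <- tp + 1
      s <- s + tp / k
    }
  }
  s / P
}

# random truncated prediction instance with known class totals
random_instance <- function(max_len = 10L) {
  P <- sample(1:6, 1L)
  N <- sample(1:12, 1L)
  len <- sample(0:min(max_len, P + N), 1L)
  # a random ranking never places more positives/negatives than exist
  pool <- sample(c(rep(1L, P), rep(0L, N)))
  list(labels = pool[seq_len(len)], P = P, N = N)
}

# tiny learner settings keeping forests and CV desk-scale
tiny_learner <- function(seed = 1L, n_trees = 300L, ...) {
  learner_params(n_trees = n_trees, seed = seed, ...)
}

# planted-signal regression design: one strong marker, the rest noise
planted_design <- function(n = 100L, p = 50L, planted = 1L, noise_sd = 0.1,
                           seed = 1L) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1L, 0.5), n, p,
              dimnames = list(NULL, sprintf("M%02d", seq_len(p))))
  y <- X[, planted] + rnorm(n, 0, noise_sd)
  list(X = X, y = y)
}

# single-edge regulatory study: cis marker on the regulator drives the
# target through one positive edge
planted_study <- function(n_samples = 200L, n_genes = 30L, seed = 1L,
                          noise_sd = 0.05) {
  sp <- sim_params(n_samples = n_samples, n_genes = n_genes,
                   n_chromosomes = 5, n_edges = 1, noise_sd = noise_sd,
                   effect_size_cis = 2, seed = seed)
  geno <- simulate_genotypes(sp)
  gids <- geno$marker_map$gene_id
  reg <- gids[3L]; tgt <- gids[17L]
  # the planted cis marker is the only genetic effect in the study
  geno$marker_map$mutation_type <- rep("trans", n_genes)
  geno$marker_map$mutation_type[3L] <- "cis"
  net <- gold_network(reg, tgt, weight = 1, gene_ids = gids)
  expr <- simulate_expression(net, geno, sp)
  list(genotypes = geno, network = net, expression = expr, params = sp,
       regulator = reg, target = tgt)
}
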