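# Synthetic systems-genetics benchmark generator: RIL genotypes with local
# linkage, directed regulatory networks, and steady-state expression with
# cis/trans genetic effects.

gene_ids_for <- function(n) sprintf("G%0*d", nchar(n), seq_len(n))
marker_ids_for <- function(n) sprintf("M%0*d", nchar(n), seq_len(n))
sample_ids_for <- function(n) sprintf("S%0*d", nchar(n), seq_len(n))

#' Simulate recombinant-inbred-line genotypes with local linkage
#'
#' One biallelic marker per gene, evenly partitioned across chromosomes
#' (chromosome sizes differ by at most one). Within a chromosome each
#' sample's genotype vector is a two-state Markov chain: the first marker is
#' 0 or 1 with probability one half (a balanced two-parent cross), and each
#' subsequent marker flips the previous allele with probability
#' \code{recomb_prob}. The stationary correlation between adjacent markers
#' is therefore \eqn{1 - 2r}; markers on different chromosomes segregate
#' independently. Every marker is additionally annotated as cis- or
#' trans-acting (promoter versus coding mutation), drawn i.i.d. with
#' probability \code{cis_prob}.
#'
#' @param params a [sim_params()] object.
#' @return an object of class \code{genotype_matrix}: a list with
#'   \code{values} (samples x markers 0/1 matrix), \code{sample_ids}, and
#'   \code{marker_map} (data frame: marker_id, gene_id, chromosome,
#'   position_index, mutation_type).
#' @export
simulate_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_samples
  p <- params$n_genes
  k <- params$n_chromosomes

  # even partition: first (p mod k) chromosomes get one extra marker
  sizes <- rep(p %/% k, k) + c(rep(1L, p %% k), rep(0L, k - p %% k))
  chrom <- rep(seq_len(k), sizes)
  pos <- unlist(lapply(sizes, seq_len), use.names = FALSE)

  set.seed(derive_seed(params$seed, 1L))
  G <- matrix(0L, n, p)
  start <- 1L
  for (c_i in seq_len(k)) {
    len <- sizes[c_i]
    first <- rbinom(n, 1L, 0.5)
    if (len > 1L) {
      flips <- matrix(rbinom(n * (len - 1L), 1L, params$recomb_prob),
                      n, len - 1L)
      # cumulative flip count modulo 2 realizes the chain
      cum <- t(apply(flips, 1L, cumsum))
      chromG <- (first + cbind(0L, cum)) %% 2L
    } else {
      chromG <- matrix(first, n, 1L)
    }
    G[, start:(start + len - 1L)] <- chromG
    start <- start + len
  }

  set.seed(derive_seed(params$seed, 2L))
  mtype <- ifelse(runif(p) < params$cis_prob, "cis", "trans")

  gid <- gene_ids_for(p)
  mid <- marker_ids_for(p)
  sid <- sample_ids_for(n)
  dimnames(G) <- list(sid, mid)
  structure(list(
    values = G,
    sample_ids = sid,
    marker_map = data.frame(
      marker_id = mid, gene_id = gid, chromosome = chrom,
      position_index = pos, mutation_type = mtype,
      stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("RIL genotype matrix: %d samples x %d markers on %d chromosomes (%d cis, %d trans)\n",
              nrow(x$values), ncol(x$values), max(x$marker_map$chromosome),
              sum(x$marker_map$mutation_type == "cis"),
              sum(x$marker_map$mutation_type == "trans")))
  invisible(x)
}

#' Construct a gold-standard directed network by hand
#'
#' Useful for planted designs and for wrapping edge lists read from disk.
#' Self-loops and duplicate edges are rejected.
#'
#' @param regulator,target character vectors of gene ids, one edge per
#'   element.
#' @param weight signed simulation edge weights (default 1).
#' @param gene_ids the gene universe; defaults to the genes mentioned.
#' @return a \code{gold_network} data frame.
#' @export
gold_network <- function(regulator, target, weight = rep(1, length(regulator)),
                         gene_ids = sort(unique(c(regulator, target)))) {
  if (any(regulator == target)) abort_fmt("self-loops are not allowed")
  if (anyDuplicated(paste(regulator, target)))
    abort_fmt("duplicate edges are not allowed")
  net <- data.frame(regulator = as.character(regulator),
                    target = as.character(target),
                    weight = as.numeric(weight), stringsAsFactors = FALSE)
  attr(net, "gene_ids") <- gene_ids
  class(net) <- c("gold_network", "data.frame")
  net
}

#' Simulate a directed gold-standard regulatory network
#'
#' Draws exactly \code{n_edges} distinct directed non-self edges among the
#' genes. Regulators are sampled with probability proportional to a
#' power-law propensity (Pareto with exponent \code{power_exponent}),
#' yielding a heavy-tailed out-degree distribution with a few hub
#' regulators; targets are sampled with probability proportional to an
#' exponential propensity, yielding a light-tailed in-degree distribution.
#' Each edge carries a signed weight of magnitude scale
#' \code{edge_weight_scale}, used only by the expression simulator — the
#' gold standard itself is the unweighted edge set.
#'
#' @param params a [sim_params()] object.
#' @return an object of class \code{gold_network}: a data frame with columns
#'   \code{regulator}, \code{target}, \code{weight} and attribute
#'   \code{gene_ids}.
#' @export
simulate_network <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params$n_genes
  m <- params$n_edges
  max_edges <- p * (p - 1)
  if (m > max_edges)
    abort_fmt("n_edges (%d) exceeds the %d possible directed edges", m, max_edges)
  gid <- gene_ids_for(p)

  set.seed(derive_seed(params$seed, 3L))
  if (m == 0L) {
    net <- data.frame(regulator = character(0), target = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
    attr(net, "gene_ids") <- gid
    class(net) <- c("gold_network", "data.frame")
    return(net)
  }

  out_prop <- (1 - runif(p))^(-1 / (params$power_exponent - 1))  # Pareto tail
  in_prop <- rexp(p)
  keyset <- integer(0)
  regs <- integer(0); tgts <- integer(0)
  tries <- 0L
  while (length(regs) < m && tries < 200L) {
    tries <- tries + 1L
    need <- m - length(regs)
    r <- sample.int(p, 2L * need + 10L, replace = TRUE, prob = out_prop)
    t <- sample.int(p, 2L * need + 10L, replace = TRUE, prob = in_prop)
    ok <- r != t
    key <- (r[ok] - 1L) * p + t[ok]
    new <- !duplicated(key) & !(key %in% keyset)
    keep <- which(new)[seq_len(min(need, sum(new)))]
    regs <- c(regs, r[ok][keep]); tgts <- c(tgts, t[ok][keep])
    keyset <- c(keyset, key[keep])
  }
  if (length(regs) < m) {
    # dense request: fill the remainder uniformly from the unused pairs
    all_key <- setdiff(seq_len(p * p),
                       c(keyset, (seq_len(p) - 1L) * p + seq_len(p)))
    extra <- sample(all_key, m - length(regs))
    regs <- c(regs, (extra - 1L) %/% p + 1L)
    tgts <- c(tgts, (extra - 1L) %% p + 1L)
  }

  w <- params$edge_weight_scale * runif(m, 0.5, 1.5) *
    sample(c(-1, 1), m, replace = TRUE)
  net <- data.frame(regulator = gid[regs], target = gid[tgts], weight = w,
                    stringsAsFactors = FALSE)
  attr(net, "gene_ids") <- gid
  class(net) <- c("gold_network", "data.frame")
  net
}

#' Simulate steady-state expression with cis and trans genetic effects
#'
#' For each sample the expression vector is the steady state of the linear
#' system \eqn{x = c + B(g) x + e}: \eqn{c} is the basal expression (1 for
#' every gene), raised by \code{effect_size_cis} for genes whose cis marker
#' carries allele 1; \eqn{B(g)} is the weighted adjacency (entry
#' \code{[target, regulator]}), in which every outgoing edge weight of a
#' gene whose trans marker carries allele 1 is multiplied by
#' \code{1 + effect_size_trans}; and \eqn{e} is i.i.d. Gaussian noise with
#' standard deviation \code{noise_sd}. The base adjacency is rescaled once
#' so that even the worst-case genotype (all trans alleles present) has
#' spectral radius at most \code{network_damping}, which guarantees a unique
#' stable steady state for every sample. The system is then solved exactly
#' as \eqn{x = (I - B(g))^{-1} (c + e)}.
#'
#' @param network a [simulate_network()] gold network (with weights).
#' @param genotypes a [simulate_genotypes()] object over the same genes.
#' @param params a [sim_params()] object.
#' @return a samples x genes numeric matrix with sample and gene ids as
#'   dimnames.
#' @export
simulate_expression <- function(network, genotypes, params) {
  stopifnot(inherits(params, "sim_params"),
            inherits(genotypes, "genotype_matrix"),
            inherits(network, "gold_network"))
  gid <- attr(network, "gene_ids") %||% sort(unique(c(network$regulator, network$target)))
  map <- genotypes$marker_map
  if (!setequal(gid, map$gene_id))
    abort_fmt("network gene set does not match the genotype marker map")
  p <- length(gid)
  G <- genotypes$values
  if (ncol(G) != p) abort_fmt("genotype/network dimension mismatch")

  B0 <- matrix(0, p, p, dimnames = list(gid, gid))
  if (nrow(network) > 0L)
    B0[cbind(match(network$target, gid), match(network$regulator, gid))] <-
      network$weight

  # genes are indexed in marker-map order; marker j <-> gene j
  gene_of_marker <- match(map$gene_id, gid)
  is_cis <- map$mutation_type == "cis"
  amp <- 1 + max(params$effect_size_trans, 0)

  # one conservative rescale: |B(g)| is entrywise below the all-trans-on
  # magnitude matrix, whose spectral radius bounds every sample's
  M <- abs(B0)
  M[, gene_of_marker[!is_cis]] <- M[, gene_of_marker[!is_cis]] * amp
  rho <- if (all(M == 0)) 0 else max(Mod(eigen(M, only.values = TRUE)$values))
  if (rho > params$network_damping) B0 <- B0 * (params$network_damping / rho)

  set.seed(derive_seed(params$seed, 4L))
  n <- nrow(G)
  E <- matrix(NA_real_, n, p, dimnames = list(rownames(G), gid))
  noise <- matrix(rnorm(n * p, 0, params$noise_sd), n, p)
  basal <- rep(1, p)
  cis_genes <- gene_of_marker[is_cis]
  cis_markers <- which(is_cis)
  trans_genes <- gene_of_marker[!is_cis]
  trans_markers <- which(!is_cis)
  I_p <- diag(p)
  for (i in seq_len(n)) {
    ci <- basal
    on_cis <- G[i, cis_markers] == 1L
    ci[cis_genes[on_cis]] <- ci[cis_genes[on_cis]] + params$effect_size_cis
    B <- B0
    on_trans <- trans_genes[G[i, trans_markers] == 1L]
    if (length(on_trans))
      B[, on_trans] <- B[, on_trans] * (1 + params$effect_size_trans)
    E[i, ] <- solve(I_p - B, ci + noise[i, ])
  }
  # the damped base adjacency, exposed so the steady-state identity
  # x = c + B(g) x + e can be verified externally
  attr(E, "adjacency") <- B0
  E
}

#' Run the full synthetic-benchmark generator
#'
#' Convenience wrapper chaining [simulate_genotypes()], [simulate_network()]
#' and [simulate_expression()] under one parameter set. The result is a
#' deterministic function of \code{params} (including its seed).
#'
#' @param params a [sim_params()] object.
#' @return a list of class \code{sysgen_sim} with elements
#'   \code{genotypes}, \code{network}, \code{expression}, \code{params}.
#' @export
#' @examples
#' sim <- simulate_sysgen(sim_params(n_samples = 30, n_genes = 20,
#'                                   n_chromosomes = 4, n_edges = 30,
#'                                   seed = 42))
#' dim(sim$expression)
simulate_sysgen <- function(params) {
  geno <- simulate_genotypes(params)
  net <- simulate_network(params)
  expr <- simulate_expression(net, geno, params)
  structure(list(genotypes = geno, network = net, expression = expr,
                 params = params),
            class = "sysgen_sim")
}

#' @export
print.sysgen_sim <- function(x, ...) {
  cat(sprintf("Synthetic systems-genetics study: %d samples, %d genes, %d gold edges (seed %d)\n",
              nrow(x$expression), ncol(x$expression), nrow(x$network),
              x$params$seed))
  invisible(x)
}
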