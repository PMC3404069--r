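#' Simulation parameters for the systems-genetics benchmark generator
#'
#' Bundles every knob of the synthetic recombinant-inbred-line (RIL) study:
#' genotypes on evenly sized chromosomes with local linkage, a directed
#' regulatory network with scale-free out-degree and exponential in-degree,
#' and steady-state expression with cis and trans genetic effects.
#'
#' Defaults mirror the DREAM5 SYSGEN A design where that design states a
#' value: 1,000 genes with one biallelic marker each on 20 chromosomes,
#' about 2,000 directed edges, a 0.25 probability that a marker acts in cis
#' (promoter mutation) versus trans (coding mutation), and 300 samples (the
#' intermediate RIL panel size). The remaining magnitudes (effect sizes,
#' recombination fraction, noise, damping) are not published for that
#' benchmark; the defaults here are fixed, documented choices giving a
#' realistic RIL panel: adjacent-marker linkage r = 0.1 (adjacent genotype
#' correlation 0.8), a cis effect of two noise standard deviations times
#' five, and network feedback damped to spectral radius 0.5.
#'
#' @param n_samples number of RIL samples.
#' @param n_genes number of genes; also the number of markers (one marker
#'   per gene).
#' @param n_chromosomes number of chromosomes the markers are evenly spread
#'   over (sizes differ by at most one).
#' @param n_edges number of directed regulatory edges.
#' @param recomb_prob probability in (0, 0.5] that adjacent markers on a
#'   chromosome recombine (the allele flips along the chromosome).
#' @param cis_prob probability that a marker's mutation is cis-acting; the
#'   complement is the trans probability.
#' @param effect_size_cis additive shift of the gene's basal expression when
#'   the cis allele is 1.
#' @param effect_size_trans relative amplification of a gene's outgoing edge
#'   weights when the trans allele is 1 (weights are multiplied by
#'   \code{1 + effect_size_trans}).
#' @param edge_weight_scale magnitude scale of the signed simulation edge
#'   weights.
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise added to
#'   each gene's basal term before the steady state is solved.
#' @param network_damping upper bound in (0, 1) imposed on the spectral
#'   radius of the (genotype-dependent) weighted adjacency, guaranteeing a
#'   unique stable steady state.
#' @param power_exponent exponent of the power-law out-degree propensity.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the parameter set including the seed.
#' @return an object of class \code{sim_params} (a validated list).
#' @seealso [simulate_genotypes()], [simulate_network()],
#'   [simulate_expression()], [simulate_sysgen()]
#' @export
#' @examples
#' sp <- sim_params(n_samples = 50, n_genes = 40, n_chromosomes = 4,
#'                  n_edges = 60, seed = 1)
#' sp$trans_prob
sim_params <- function(n_samples = 300L,
                       n_genes = 1000L,
                       n_chromosomes = 20L,
                       n_edges = 2000L,
                       recomb_prob = 0.1,
                       cis_prob = 0.25,
                       effect_size_cis = 2,
                       effect_size_trans = 1,
                       edge_weight_scale = 1,
                       noise_sd = 0.2,
                       network_damping = 0.5,
                       power_exponent = 2,
                       seed = 1L) {
  p <- list(
    n_samples = check_count(n_samples, "n_samples"),
    n_genes = check_count(n_genes, "n_genes"),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    n_edges = check_count(n_edges, "n_edges", min = 0L),
    recomb_prob = check_prob(recomb_prob, "recomb_prob", 0, 0.5, open_lo = TRUE),
    cis_prob = check_prob(cis_prob, "cis_prob"),
    effect_size_cis = as.numeric(effect_size_cis),
    effect_size_trans = as.numeric(effect_size_trans),
    edge_weight_scale = as.numeric(edge_weight_scale),
    noise_sd = check_prob(noise_sd, "noise_sd", 0, Inf),
    network_damping = check_prob(network_damping, "network_damping", 0, 1,
                                 open_lo = TRUE, open_hi = TRUE),
    power_exponent = as.numeric(power_exponent),
    seed = check_count(seed, "seed", min = 0L)
  )
  p$trans_prob <- 1 - p$cis_prob
  if (p$n_genes < p$n_chromosomes)
    abort_fmt("n_genes (%d) must be >= n_chromosomes (%d)",
              p$n_genes, p$n_chromosomes)
  if (p$n_edges > p$n_genes * (p$n_genes - 1L))
    abort_fmt("n_edges (%d) exceeds the %d possible directed non-self edges",
              p$n_edges, p$n_genes * (p$n_genes - 1L))
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Systems-genetics simulation parameters\n")
  cat(sprintf("  %d samples, %d genes/markers on %d chromosomes, %d edges\n",
              x$n_samples, x$n_genes, x$n_chromosomes, x$n_edges))
  cat(sprintf("  recomb_prob %.3g, cis_prob %.2f, cis effect %.3g, trans effect %.3g\n",
              x$recomb_prob, x$cis_prob, x$effect_size_cis, x$effect_size_trans))
  cat(sprintf("  noise sd %.3g, damping %.2f, seed %d\n",
              x$noise_sd, x$network_damping, x$seed))
  invisible(x)
}

#' Hyperparameters of the four base marker-importance scorers
#'
#' Defaults follow the published committee protocol: regression forests of
#' 5,000 trees with \code{mtry} one third of the markers and minimum node
#' size 5; LASSO as the elastic-net family member with quadratic penalty
#' \eqn{\lambda_2 = 0.001} and the L1 constraint expressed as a fraction
#' \eqn{s} of the full-model L1 norm, chosen by 10-fold cross-validation
#' with an imposed floor of 0.25; the Elastic Net identically but with
#' \eqn{\lambda_2 = 1} and no floor on \eqn{s}.
#'
#' @param n_trees trees per forest (5,000 in the reference protocol; smaller
#'   values are adequate for desk-scale benchmarks).
#' @param mtry_fraction fraction of markers tried at each split.
#' @param min_node_size minimum terminal node size of the regression trees.
#' @param lasso_lambda2 quadratic (ridge) penalty of the LASSO-side fit;
#'   the small default makes it near-pure LASSO while keeping the fit
#'   defined on perfectly collinear markers.
#' @param elnet_lambda2 quadratic penalty of the Elastic-Net fit.
#' @param s_grid candidate L1-norm fractions in (0, 1] scanned by the
#'   cross-validation.
#' @param s_min floor applied to the cross-validated \eqn{s} of the LASSO.
#' @param elnet_s_min optional floor for the Elastic Net (\code{NULL}, the
#'   default, imposes none).
#' @param cv_folds cross-validation folds.
#' @param standardize standardize markers and response per gene before the
#'   penalized fits.
#' @param zero_tol absolute coefficients below this are reported as exact
#'   zeros, so that the LASSO support used for committee filtering is
#'   solver-independent.
#' @param seed integer seed; per-gene sub-seeds are derived from it.
#' @return an object of class \code{learner_params}.
#' @export
#' @examples
#' learner_params(n_trees = 300, seed = 7)
learner_params <- function(n_trees = 5000L,
                           mtry_fraction = 1 / 3,
                           min_node_size = 5L,
                           lasso_lambda2 = 0.001,
                           elnet_lambda2 = 1,
                           s_grid = seq(0.05, 1, by = 0.05),
                           s_min = 0.25,
                           elnet_s_min = NULL,
                           cv_folds = 10L,
                           standardize = TRUE,
                           zero_tol = 1e-10,
                           seed = 1L) {
  p <- list(
    n_trees = check_count(n_trees, "n_trees"),
    mtry_fraction = check_prob(mtry_fraction, "mtry_fraction", 0, 1, open_lo = TRUE),
    min_node_size = check_count(min_node_size, "min_node_size"),
    lasso_lambda2 = check_prob(lasso_lambda2, "lasso_lambda2", 0, Inf, open_lo = TRUE),
    elnet_lambda2 = check_prob(elnet_lambda2, "elnet_lambda2", 0, Inf, open_lo = TRUE),
    s_grid = sort(unique(as.numeric(s_grid))),
    s_min = check_prob(s_min, "s_min", 0, 1),
    elnet_s_min = if (is.null(elnet_s_min)) NULL else
      check_prob(elnet_s_min, "elnet_s_min", 0, 1),
    cv_folds = check_count(cv_folds, "cv_folds", min = 2L),
    standardize = isTRUE(standardize),
    zero_tol = check_prob(zero_tol, "zero_tol", 0, Inf),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (any(p$s_grid <= 0) || any(p$s_grid > 1))
    abort_fmt("all s_grid values must lie in (0, 1]")
  if (p$s_min > max(p$s_grid))
    abort_fmt("s_min (%.3g) exceeds the largest s_grid value", p$s_min)
  structure(p, class = "learner_params")
}

#' @export
print.learner_params <- function(x, ...) {
  cat("Base-learner hyperparameters\n")
  cat(sprintf("  forests: %d trees, mtry fraction %.3g, min node size %d\n",
              x$n_trees, x$mtry_fraction, x$min_node_size))
  cat(sprintf("  LASSO lambda2 %.3g (s floor %.2f), ElNet lambda2 %.3g, %d-fold CV over %d s values\n",
              x$lasso_lambda2, x$s_min, x$elnet_lambda2, x$cv_folds,
              length(x$s_grid)))
  invisible(x)
}
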