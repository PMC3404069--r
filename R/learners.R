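# The four base marker-importance scorers, one target gene at a time, and
# the per-gene loop assembling a full markers x genes score matrix.

METHOD_LABELS <- c("RF.sf", "RF.pi", "LASSO", "ElNet")

# position-independent per-gene seed: derived from the gene identifier so
# the result does not depend on column order
gene_seed <- function(seed, gene_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(gene_id))) h <- (h * 131 + ch) %% 2147483647
  derive_seed(seed, h)
}

as_genotype_values <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) genotypes$values
  else as.matrix(genotypes)
}

check_xy <- function(X, y) {
  if (nrow(X) != length(y))
    abort_fmt("genotypes have %d samples but the expression vector has %d",
              nrow(X), length(y))
  if (nrow(X) < 2L) abort_fmt("need at least 2 samples")
  if (any(!is.finite(y))) abort_fmt("expression vector contains non-finite values")
}

# one regression forest serving both RF importances; permutation importance
# is computed inside the same fit so both measures come from identical trees
fit_forest <- function(X, y, params, seed) {
  set.seed(seed)
  randomForest::randomForest(
    x = X, y = y,
    ntree = params$n_trees,
    mtry = max(1L, floor(params$mtry_fraction * ncol(X))),
    nodesize = params$min_node_size,
    importance = TRUE)
}

#' Random-forest selection frequency (RF.sf) of each marker
#'
#' Grows a regression forest predicting one gene's expression from all
#' markers and scores each marker by the number of internal nodes, over all
#' trees, at which it was chosen as the splitting variable. Scores are
#' non-negative and sum to the forest's total internal-node count.
#'
#' @param genotypes a \code{genotype_matrix} or samples x markers 0/1 matrix.
#' @param expression_of_gene numeric expression vector for one target gene.
#' @param params a [learner_params()] object.
#' @param seed optional seed overriding \code{params$seed} (used by the
#'   per-gene driver).
#' @return named numeric vector of selection counts per marker.
#' @export
rf_selection_frequency <- function(genotypes, expression_of_gene, params,
                                   seed = NULL) {
  gene_scores_one(genotypes, expression_of_gene, "RF.sf", params, seed)
}

#' Unscaled random-forest permutation importance (RF.pi) of each marker
#'
#' For every tree, the marker's out-of-bag values are permuted once and the
#' increase in out-of-bag mean squared error recorded; the score is the
#' plain mean over trees, deliberately not divided by its standard
#' deviation (the "unscaled" importance). Scores can be negative for
#' uninformative markers; a marker never used by any tree scores exactly 0.
#'
#' @inheritParams rf_selection_frequency
#' @return named numeric vector of mean OOB MSE increases per marker.
#' @export
rf_permutation_importance <- function(genotypes, expression_of_gene, params,
                                      seed = NULL) {
  gene_scores_one(genotypes, expression_of_gene, "RF.pi", params, seed)
}

#' LASSO importance scores of each marker
#'
#' Near-pure LASSO as the elastic-net family member with quadratic penalty
#' \code{lasso_lambda2} (default 0.001). The L1 constraint is expressed as
#' the fraction \eqn{s} of the full model's L1 norm; \eqn{s} is chosen on a
#' grid by \code{cv_folds}-fold cross-validated prediction error and then
#' clamped from below at \code{s_min} (default 0.25). Scores are the
#' absolute coefficients at the selected \eqn{s}; values below
#' \code{zero_tol} are exact zeros, defining the support used by the
#' filtered committee. Among a group of near-collinear markers the LASSO
#' concentrates the coefficient mass on one of them.
#'
#' @inheritParams rf_selection_frequency
#' @return named numeric vector of absolute coefficients (attribute
#'   \code{"s"} carries the selected L1 fraction).
#' @export
lasso_scores <- function(genotypes, expression_of_gene, params, seed = NULL) {
  gene_scores_one(genotypes, expression_of_gene, "LASSO", params, seed)
}

#' Elastic-Net importance scores of each marker
#'
#' Identical procedure to [lasso_scores()] but with quadratic penalty
#' \code{elnet_lambda2} (default 1) and, by default, no floor on the
#' cross-validated L1 fraction. The heavier ridge component spreads
#' coefficient mass across groups of correlated markers (e.g. markers in
#' linkage disequilibrium) instead of picking a single representative.
#'
#' @inheritParams rf_selection_frequency
#' @return named numeric vector of absolute coefficients.
#' @export
elnet_scores <- function(genotypes, expression_of_gene, params, seed = NULL) {
  gene_scores_one(genotypes, expression_of_gene, "ElNet", params, seed)
}

# shared single-method entry; 'methods' driver below reuses forests
gene_scores_one <- function(genotypes, y, method, params, seed = NULL) {
  X <- as_genotype_values(genotypes)
  check_xy(X, y)
  out <- gene_scores(X, y, method, params,
                     seed %||% params$seed)[[method]]
  names(out) <- colnames(X)
  out
}

# compute all requested methods for one gene; a single forest serves both
# RF measures so RF.sf and RF.pi always agree on the trees they summarize
gene_scores <- function(X, y, methods, params, seed) {
  p <- ncol(X)
  res <- list()
  constant <- stats::sd(y) < 1e-12
  if (any(methods %in% c("RF.sf", "RF.pi"))) {
    if (constant) {
      if ("RF.sf" %in% methods) res$RF.sf <- rep(0, p)
      if ("RF.pi" %in% methods) res$RF.pi <- rep(0, p)
    } else {
      fit <- fit_forest(X, y, params, seed)
      if ("RF.sf" %in% methods)
        res$RF.sf <- as.numeric(randomForest::varUsed(fit, count = TRUE))
      if ("RF.pi" %in% methods)
        res$RF.pi <- as.numeric(randomForest::importance(fit, type = 1,
                                                         scale = FALSE))
    }
  }
  if ("LASSO" %in% methods)
    res$LASSO <- if (constant) rep(0, p) else
      enet_importance(X, y, params$lasso_lambda2, params,
                      s_min = params$s_min, seed = derive_seed(seed, 7L))
  if ("ElNet" %in% methods)
    res$ElNet <- if (constant) rep(0, p) else
      enet_importance(X, y, params$elnet_lambda2, params,
                      s_min = params$elnet_s_min %||% 0,
                      seed = derive_seed(seed, 11L))
  res
}

#' Score every gene against every marker with one base method
#'
#' Applies the chosen scorer gene by gene, producing a markers x genes
#' score matrix. Genes are processed independently with per-gene seeds
#' derived from the global seed and the gene identifier, so the result does
#' not depend on the order of the expression columns and each column equals
#' the corresponding single-gene call.
#'
#' @param genotypes a \code{genotype_matrix} or samples x markers matrix.
#' @param expression samples x genes numeric matrix (same sample order).
#' @param method one of \code{"RF.sf"}, \code{"RF.pi"}, \code{"LASSO"},
#'   \code{"ElNet"}.
#' @param params a [learner_params()] object.
#' @param verbose print per-gene progress.
#' @return a \code{score_matrix} object (markers x genes values plus the
#'   method label).
#' @export
#' @examples
#' sim <- simulate_sysgen(sim_params(n_samples = 40, n_genes = 8,
#'                                   n_chromosomes = 2, n_edges = 10, seed = 3))
#' sm <- map_all_genes(sim$genotypes, sim$expression, "LASSO",
#'                     learner_params(seed = 3))
#' dim(sm$values)
map_all_genes <- function(genotypes, expression, method = METHOD_LABELS,
                          params = learner_params(), verbose = FALSE) {
  method <- match.arg(method)
  X <- as_genotype_values(genotypes)
  expression <- as.matrix(expression)
  if (nrow(X) != nrow(expression))
    abort_fmt("genotypes have %d samples but expression has %d",
              nrow(X), nrow(expression))
  gids <- colnames(expression) %||% gene_ids_for(ncol(expression))
  mids <- colnames(X) %||% marker_ids_for(ncol(X))
  vals <- matrix(NA_real_, ncol(X), ncol(expression),
                 dimnames = list(mids, gids))
  for (g in seq_len(ncol(expression))) {
    if (verbose) message(sprintf("[%s] gene %d/%d (%s)", method, g,
                                 ncol(expression), gids[g]))
    vals[, g] <- tryCatch(
      gene_scores(X, expression[, g], method, params,
                  gene_seed(params$seed, gids[g]))[[method]],
      error = function(e) abort_fmt("gene %s: %s", gids[g], conditionMessage(e)))
  }
  score_matrix(vals, method)
}

#' Construct a score matrix
#'
#' @param values markers x genes numeric matrix with dimnames.
#' @param method method or committee label.
#' @return an object of class \code{score_matrix}.
#' @export
score_matrix <- function(values, method) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) abort_fmt("score matrix has non-finite entries")
  if (is.null(rownames(values))) rownames(values) <- marker_ids_for(nrow(values))
  if (is.null(colnames(values))) colnames(values) <- gene_ids_for(ncol(values))
  structure(list(values = values, method = method), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix [%s]: %d markers x %d genes, %d nonzero (%.1f%%)\n",
              x$method, nrow(x$values), ncol(x$values), sum(x$values != 0),
              100 * mean(x$values != 0)))
  invisible(x)
}
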