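# The central model-fitting interface: fit a committee of marker-importance
# scorers to a genotype/expression study and carry everything needed for
# ranking and evaluation in one classed object.

# per-gene driver computing several methods from shared fits (one forest
# serves both RF measures)
map_all_methods <- function(genotypes, expression, methods, params,
                            verbose = FALSE) {
  X <- as_genotype_values(genotypes)
  expression <- as.matrix(expression)
  if (nrow(X) != nrow(expression))
    abort_fmt("genotypes have %d samples but expression has %d",
              nrow(X), nrow(expression))
  gids <- colnames(expression) %||% gene_ids_for(ncol(expression))
  mids <- colnames(X) %||% marker_ids_for(ncol(X))
  vals <- lapply(methods, function(m)
    matrix(NA_real_, ncol(X), ncol(expression), dimnames = list(mids, gids)))
  names(vals) <- methods
  for (g in seq_len(ncol(expression))) {
    if (verbose) message(sprintf("gene %d/%d (%s)", g, ncol(expression), gids[g]))
    sc <- tryCatch(
      gene_scores(X, expression[, g], methods, params,
                  gene_seed(params$seed, gids[g])),
      error = function(e) abort_fmt("gene %s: %s", gids[g], conditionMessage(e)))
    for (m in methods) vals[[m]][, g] <- sc[[m]]
  }
  lapply(methods, function(m) score_matrix(vals[[m]], m)) |>
    stats::setNames(methods)
}

#' Fit a committee eQTL mapping model
#'
#' The main entry point. For every gene, each requested base method scores
#' all markers (random-forest selection frequency \code{RF.sf}, unscaled
#' permutation importance \code{RF.pi}, absolute \code{LASSO} and
#' \code{ElNet} coefficients); the committee combines the member score
#' matrices by averaging their scaled, centered values, and — for a
#' filtered committee such as \code{"{RF.sf+RF.pi+ElNet}|LASSO"} — zeroes
#' every pair outside the LASSO support. The returned object supports
#' \code{print}, \code{summary}, \code{coef} (the committee score matrix),
#' \code{predict} (a ranked directed edge list, optionally truncated or
#' randomly padded to a budget) and \code{plot} (ROC and precision-recall
#' curves against a gold network).
#'
#' @param genotypes a \code{genotype_matrix} (from [simulate_genotypes()] or
#'   [read_genotypes()]) or a plain samples x markers 0/1 matrix.
#' @param expression samples x genes numeric matrix, same sample order.
#' @param committee committee specification string (see
#'   [parse_committee()]); a single method name fits just that scorer.
#' @param params a [learner_params()] object.
#' @param scope z-scoring scope for the committee, \code{"global"} or
#'   \code{"per_gene"}.
#' @param verbose print per-gene progress.
#' @return an object of class \code{eqtl_map}.
#' @export
#' @examples
#' sim <- simulate_sysgen(sim_params(n_samples = 40, n_genes = 10,
#'                                   n_chromosomes = 2, n_edges = 12, seed = 5))
#' fit <- eqtl_map(sim$genotypes, sim$expression, committee = "LASSO",
#'                 params = learner_params(n_trees = 50, seed = 5))
#' fit
#' head(predict(fit))
eqtl_map <- function(genotypes, expression,
                     committee = "{RF.sf+RF.pi+ElNet}|LASSO",
                     params = learner_params(),
                     scope = c("global", "per_gene"),
                     verbose = FALSE) {
  scope <- match.arg(scope)
  spec <- if (inherits(committee, "committee_spec")) committee
          else parse_committee(committee)
  needed <- union(spec$members, if (spec$filter_by_lasso) "LASSO")
  scores <- map_all_methods(genotypes, expression, needed, params, verbose)
  members <- scores[spec$members]
  comm <- if (spec$filter_by_lasso)
    combine_filtered(members, scores[["LASSO"]], scope = scope,
                     zero_tol = params$zero_tol)
  else if (length(members) == 1L)
    zscore_matrix(members[[1L]], scope = scope)
  else combine_unfiltered(members, scope = scope)
  structure(list(
    call = match.call(),
    committee_spec = spec,
    params = params,
    scope = scope,
    scores = scores,
    committee = comm,
    marker_map = if (inherits(genotypes, "genotype_matrix"))
      genotypes$marker_map else NULL,
    gene_ids = colnames(comm$values),
    n_samples = nrow(as_genotype_values(genotypes))
  ), class = "eqtl_map")
}

#' @export
print.eqtl_map <- function(x, ...) {
  cat("Committee eQTL mapping fit\n")
  print(x$committee_spec)
  cat(sprintf("  %d samples, %d markers x %d genes, %s scaling\n",
              x$n_samples, nrow(x$committee$values),
              ncol(x$committee$values), x$scope))
  cat(sprintf("  committee scores: %d nonzero of %d candidate pairs\n",
              sum(x$committee$values != 0), length(x$committee$values)))
  invisible(x)
}

#' @export
summary.eqtl_map <- function(object, ...) {
  nz <- vapply(object$scores, function(s) sum(s$values != 0), 0)
  out <- list(spec = object$committee_spec,
              n_samples = object$n_samples,
              dims = dim(object$committee$values),
              member_nonzero = nz,
              committee_nonzero = sum(object$committee$values != 0),
              top = utils::head(predict(object), 10L))
  class(out) <- "summary.eqtl_map"
  out
}

#' @export
print.summary.eqtl_map <- function(x, ...) {
  print(x$spec)
  cat(sprintf("%d markers x %d genes over %d samples\n",
              x$dims[1L], x$dims[2L], x$n_samples))
  cat("nonzero scores per member:\n")
  print(x$member_nonzero)
  cat(sprintf("committee: %d nonzero pairs\n", x$committee_nonzero))
  cat("top predictions:\n")
  print(x$top)
  invisible(x)
}

#' Extract the committee score matrix (or a member's)
#'
#' @param object an \code{eqtl_map} fit.
#' @param member optional base-method label to extract instead of the
#'   committee.
#' @param ... unused.
#' @return markers x genes numeric matrix.
#' @export
coef.eqtl_map <- function(object, member = NULL, ...) {
  if (is.null(member)) return(object$committee$values)
  if (!member %in% names(object$scores))
    abort_fmt("no scores for member '%s' (have: %s)", member,
              paste(names(object$scores), collapse = ", "))
  object$scores[[member]]$values
}

#' Ranked edge predictions from a fitted committee
#'
#' Converts the committee score matrix into an ordered directed edge list.
#' For a filtered committee zero-score pairs are dropped ("no prediction");
#' with a \code{budget} the list is truncated or randomly padded to that
#' length, mirroring the benchmark's fixed-size submission format.
#'
#' @param object an \code{eqtl_map} fit.
#' @param budget optional fixed list length (e.g. 100000).
#' @param drop_zero drop zero-score pairs; defaults to TRUE for filtered
#'   committees.
#' @param seed seed for the padding draw (defaults to the fit's seed).
#' @param ... unused.
#' @return a \code{ranked_edges} data frame.
#' @export
predict.eqtl_map <- function(object, budget = NULL,
                             drop_zero = object$committee_spec$filter_by_lasso,
                             seed = NULL, ...) {
  edges <- scores_to_edges(object$committee, object$marker_map,
                           drop_zero = drop_zero)
  if (!is.null(budget))
    edges <- pad_predictions(edges, budget, object$gene_ids,
                             seed = seed %||% object$params$seed)
  edges
}

#' Evaluate and plot a fitted committee against a gold network
#'
#' @param x an \code{eqtl_map} fit.
#' @param gold gold-standard edge set; without it the committee score
#'   distribution is shown instead.
#' @param budget optional prediction budget before evaluation.
#' @param ... passed to the underlying plot calls.
#' @return the \code{eqtl_eval} object, invisibly (if gold supplied).
#' @export
plot.eqtl_map <- function(x, gold = NULL, budget = NULL, ...) {
  if (is.null(gold)) {
    graphics::hist(x$committee$values, breaks = 50,
                   main = sprintf("Committee scores: %s", x$committee$method),
                   xlab = "score")
    return(invisible(NULL))
  }
  ev <- evaluate_edges(predict(x, budget = budget), gold,
                       universe = x$gene_ids)
  plot(ev, ...)
  invisible(ev)
}
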