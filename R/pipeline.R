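# End-to-end driver: simulate (or load) -> score -> combine -> rank ->
# evaluate, persisting every intermediate so each stage can be audited or
# re-entered independently.

#' Run the full mapping pipeline
#'
#' Either simulates a synthetic study (when \code{config$sim} is a
#' [sim_params()] object) or loads genotype/expression/gold files from
#' \code{config$paths}, then fits the committee, emits the ranked edge
#' list (optionally padded to \code{budget}) and, when a gold network is
#' available, evaluates it. All intermediates are written under
#' \code{config$out_dir}; rerunning with an identical config reproduces
#' identical outputs.
#'
#' @param config a list with elements: \code{out_dir}; either \code{sim}
#'   (a \code{sim_params}) or \code{paths} (list with \code{genotypes},
#'   \code{expression}, optionally \code{gold}); \code{committee} (spec
#'   string, default \code{"{RF.sf+RF.pi+ElNet}|LASSO"}); \code{learner}
#'   (a \code{learner_params}); \code{budget} (prediction budget, NULL for
#'   none); \code{scope}; \code{verbose}.
#' @return a list with the fit, the ranked edges, the evaluation (or NULL)
#'   and the written file paths.
#' @export
#' @examples
#' cfg <- list(out_dir = tempfile("run"),
#'             sim = sim_params(n_samples = 30, n_genes = 10,
#'                              n_chromosomes = 2, n_edges = 12, seed = 2),
#'             committee = "LASSO",
#'             learner = learner_params(n_trees = 50, seed = 2))
#' res <- run_pipeline(cfg)
#' res$evaluation
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% abort_fmt("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  committee <- config$committee %||% "{RF.sf+RF.pi+ElNet}|LASSO"
  learner <- config$learner %||% learner_params()
  scope <- config$scope %||% "global"
  paths <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_sysgen(config$sim))
    geno <- sim$genotypes
    expr <- sim$expression
    gold <- sim$network
    paths$genotypes <- file.path(out_dir, "genotypes.tsv")
    paths$expression <- file.path(out_dir, "expression.tsv")
    paths$gold <- file.path(out_dir, "gold_network.tsv")
    stage("persist inputs", {
      write_genotypes(geno, paths$genotypes)
      write_matrix_tsv(expr, paths$expression,
                       meta = sprintf("seed: %d", config$sim$seed))
      write_edge_list(gold, paths$gold, scored = FALSE)
    })
  } else {
    p <- config$paths %||% abort_fmt("config needs either $sim or $paths")
    for (f in c(p$genotypes, p$expression, p$gold))
      if (!file.exists(f)) abort_fmt("input file does not exist: %s", f)
    geno <- stage("load genotypes", read_genotypes(p$genotypes))
    expr <- stage("load expression", read_matrix_tsv(p$expression))
    gold <- if (!is.null(p$gold))
      stage("load gold", read_edge_list(p$gold, as_gold = TRUE))
  }

  fit <- stage("map", eqtl_map(geno, expr, committee = committee,
                               params = learner, scope = scope,
                               verbose = isTRUE(config$verbose)))
  for (m in names(fit$scores)) {
    paths[[paste0("scores_", m)]] <- file.path(out_dir,
                                               sprintf("scores_%s.tsv", m))
    write_score_matrix(fit$scores[[m]], paths[[paste0("scores_", m)]])
  }
  paths$committee <- file.path(out_dir, "scores_committee.tsv")
  write_score_matrix(fit$committee, paths$committee)

  edges <- stage("rank", predict(fit, budget = config$budget))
  paths$predictions <- file.path(out_dir, "predictions.tsv")
  write_edge_list(edges, paths$predictions,
                  meta = sprintf("committee: %s", fit$committee$method))

  evaluation <- NULL
  if (!is.null(gold) && nrow(gold) > 0L) {
    evaluation <- stage("evaluate",
                        evaluate_edges(edges, gold, universe = fit$gene_ids))
    paths$roc <- file.path(out_dir, "roc_curve.tsv")
    paths$pr <- file.path(out_dir, "pr_curve.tsv")
    utils::write.table(evaluation$roc, paths$roc, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(evaluation$pr, paths$pr, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    report <- c(sprintf("committee\t%s", fit$committee$method),
                sprintf("n_predictions\t%d", evaluation$n_predictions),
                sprintf("P\t%d", evaluation$P),
                sprintf("N\t%d", evaluation$N),
                sprintf("AUROC\t%.6f", evaluation$auroc),
                sprintf("AUPR\t%.6f", evaluation$aupr))
    paths$report <- file.path(out_dir, "report.tsv")
    writeLines(report, paths$report)
  }

  list(fit = fit, edges = edges, evaluation = evaluation, paths = paths)
}
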