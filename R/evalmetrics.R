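# ROC / precision-recall evaluation of ranked edge predictions against a
# gold-standard network, under the challenge's class-imbalanced setting:
# the negative class is every directed non-self pair absent from the gold.

edge_keys <- function(reg, tgt, universe) {
  ri <- match(reg, universe); ti <- match(tgt, universe)
  if (anyNA(ri) || anyNA(ti))
    abort_fmt("edge gene %s is outside the evaluation universe",
              c(reg, tgt)[which(is.na(c(ri, ti)))[1L]])
  (ri - 1) * length(universe) + ti
}

#' Label ranked predictions against a gold network
#'
#' Converts a ranked edge list into the ordered binary labels the curve and
#' area computations consume, together with the class totals: P is the
#' number of gold edges, N the number of remaining directed non-self pairs
#' over the gene universe. Predictions outside the universe, self-pairs,
#' and duplicated predictions are rejected.
#'
#' @param edges a \code{ranked_edges} data frame (or any data frame with
#'   regulator and target columns, taken in row order).
#' @param gold a \code{gold_network} or two-column data frame of true
#'   directed edges.
#' @param universe character vector of gene ids.
#' @return list with \code{labels} (ordered 0/1), \code{P}, \code{N}.
#' @export
label_predictions <- function(edges, gold, universe) {
  if (nrow(gold) == 0L)
    abort_fmt("empty gold network: metrics are undefined without positives")
  if (any(gold[[1L]] == gold[[2L]]))
    abort_fmt("gold network contains a self-edge")
  gk <- edge_keys(gold[[1L]], gold[[2L]], universe)
  if (anyDuplicated(gk)) abort_fmt("gold network contains duplicate edges")
  g <- length(universe)
  P <- length(gk)
  N <- g * (g - 1) - P
  if (nrow(edges) == 0L)
    return(list(labels = integer(0), P = P, N = N))
  if (any(edges$regulator == edges$target))
    abort_fmt("prediction list contains a self-edge")
  ek <- edge_keys(edges$regulator, edges$target, universe)
  if (anyDuplicated(ek)) abort_fmt("prediction list contains duplicate edges")
  list(labels = as.integer(ek %in% gk), P = P, N = N)
}

check_labels <- function(labels, P, N) {
  if (P < 1) abort_fmt("no positives: metric undefined")
  rp <- sum(labels); rn <- length(labels) - rp
  if (rp > P || rn > N)
    abort_fmt("ranked list contains more positives/negatives than the totals allow")
  c(rp = rp, rn = rn)
}

#' Area under the ROC curve of a ranked binary list
#'
#' Equals the Mann-Whitney statistic: the probability that a true edge is
#' ranked above a non-edge, with half credit for ties. For a truncated list
#' the unranked pairs are treated as ranked uniformly at random below the
#' list: a ranked positive beats every unranked negative, an unranked
#' positive loses to every ranked negative, and unranked-vs-unranked pairs
#' score one half. Explicit padding ([pad_predictions()]) makes the
#' convention concrete instead; both agree in expectation.
#'
#' @param labels ordered binary vector (1 = true edge), best rank first.
#' @param P total number of positives (gold edges).
#' @param N total number of negatives (non-edges).
#' @param tie_groups optional vector (e.g. the scores) marking tied ranks;
#'   tied positive-negative pairs then receive half credit.
#' @return AUROC in [0, 1].
#' @export
#' @examples
#' auroc(c(1, 0, 1, 0), P = 2, N = 2)  # 0.75
auroc <- function(labels, P, N, tie_groups = NULL) {
  if (N < 1) abort_fmt("no negatives: AUROC undefined")
  cnt <- check_labels(labels, P, N)
  if (length(labels) == 0L) {
    warning("empty prediction list: AUROC reported as 0", call. = FALSE)
    return(0)
  }
  P_un <- P - cnt[["rp"]]; N_un <- N - cnt[["rn"]]
  if (is.null(tie_groups)) {
    neg_after <- cnt[["rn"]] - cumsum(1 - labels)      # ranked negs below each rank
    conc <- sum((neg_after + N_un)[labels == 1]) + 0.5 * P_un * N_un
  } else {
    stopifnot(length(tie_groups) == length(labels))
    grp <- cumsum(!duplicated(tie_groups) |
                    c(TRUE, tie_groups[-1L] != tie_groups[-length(tie_groups)]))
    pos_g <- tapply(labels, grp, sum)
    neg_g <- tapply(1 - labels, grp, sum)
    negs_below <- rev(cumsum(rev(neg_g))) - neg_g
    conc <- sum(pos_g * (negs_below + N_un)) + 0.5 * sum(pos_g * neg_g) +
      0.5 * P_un * N_un
  }
  conc / (P * N)
}

#' Area under the precision-recall curve (average precision)
#'
#' The non-interpolated average precision: the mean, over all P gold edges,
#' of the precision at the rank where each is retrieved. Gold edges never
#' retrieved contribute zero (precision at unreached recall is 0), so a
#' truncated list is penalized on recall exactly as the challenge's
#' evaluation intends.
#'
#' @inheritParams auroc
#' @return AUPR in [0, 1].
#' @export
#' @examples
#' aupr(c(1, 0, 1, 0), P = 2, N = 2)  # (1 + 2/3) / 2
aupr <- function(labels, P, N) {
  check_labels(labels, P, N)
  if (length(labels) == 0L) {
    warning("empty prediction list: AUPR reported as 0", call. = FALSE)
    return(0)
  }
  prec_at <- cumsum(labels) / seq_along(labels)
  sum(prec_at[labels == 1]) / P
}

#' ROC curve points of a ranked binary list
#'
#' One (FPR, TPR) point per rank prefix plus the origin. The curve reaches
#' (1, 1) only when the list ranks every pair; the trapezoidal area over a
#' complete list equals [auroc()].
#'
#' @inheritParams auroc
#' @return a \code{curve_points} data frame with columns x (FPR), y (TPR).
#' @export
roc_curve <- function(labels, P, N) {
  check_labels(labels, P, N)
  if (length(labels) == 0L)
    warning("empty prediction list: curve is the origin only", call. = FALSE)
  pts <- data.frame(x = c(0, cumsum(1 - labels) / N),
                    y = c(0, cumsum(labels) / P))
  structure(pts, curve_kind = "roc", class = c("curve_points", "data.frame"))
}

#' Precision-recall curve points of a ranked binary list
#'
#' One (recall, precision) point per rank prefix, starting at recall 0 with
#' the precision of the first prediction (the conventional PR origin).
#'
#' @inheritParams auroc
#' @return a \code{curve_points} data frame with columns x (recall),
#'   y (precision).
#' @export
pr_curve <- function(labels, P, N) {
  check_labels(labels, P, N)
  if (length(labels) == 0L) {
    warning("empty prediction list: curve is the origin only", call. = FALSE)
    pts <- data.frame(x = 0, y = 1)
  } else {
    prec <- cumsum(labels) / seq_along(labels)
    pts <- data.frame(x = c(0, cumsum(labels) / P), y = c(prec[1L], prec))
  }
  structure(pts, curve_kind = "pr", class = c("curve_points", "data.frame"))
}

#' Evaluate a ranked edge list against a gold network
#'
#' Labels the predictions over the universe of directed non-self gene
#' pairs, then computes AUROC, AUPR and both curves.
#'
#' @param edges a \code{ranked_edges} data frame.
#' @param gold gold-standard directed edge set.
#' @param universe character vector of gene ids (defaults to the genes
#'   appearing in the gold network attribute, if present).
#' @return an object of class \code{eqtl_eval} with elements auroc, aupr,
#'   roc, pr, P, N, n_predictions.
#' @export
evaluate_edges <- function(edges, gold, universe = NULL) {
  universe <- universe %||% attr(gold, "gene_ids")
  if (is.null(universe))
    abort_fmt("no gene universe supplied and the gold network carries none")
  lab <- label_predictions(edges, gold, universe)
  structure(list(
    auroc = auroc(lab$labels, lab$P, lab$N),
    aupr = aupr(lab$labels, lab$P, lab$N),
    roc = roc_curve(lab$labels, lab$P, lab$N),
    pr = pr_curve(lab$labels, lab$P, lab$N),
    P = lab$P, N = lab$N, n_predictions = length(lab$labels)
  ), class = "eqtl_eval")
}

#' @export
print.eqtl_eval <- function(x, ...) {
  cat(sprintf("network prediction evaluation: %d predictions, P = %d, N = %d\n",
              x$n_predictions, x$P, x$N))
  cat(sprintf("  AUROC %.4f   AUPR %.4f\n", x$auroc, x$aupr))
  invisible(x)
}

#' @export
plot.eqtl_eval <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$roc$x, x$roc$y, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUROC %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  plot(x$pr$x, x$pr$y, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Recall", ylab = "Precision",
       main = sprintf("Precision-recall (AUPR %.3f)", x$aupr), ...)
  graphics::abline(h = x$P / (x$P + x$N), lty = 3, col = "grey50")
  invisible(x)
}
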