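# From score matrices to ordered directed edge predictions, with the
# benchmark's top-K truncation and random-padding conventions.

#' Turn a score matrix into an ordered directed edge list
#'
#' Each (marker, gene) score becomes a candidate edge from the marker's
#' gene to the target gene (one marker per gene identifies markers with
#' regulators). Self-pairs are removed; with \code{drop_zero} the pairs
#' with score exactly 0 are removed too ("no prediction" — the filtered
#' committee's semantics). The remainder is sorted by decreasing score with
#' a deterministic lexicographic tie-break (regulator id, then target id).
#'
#' @param scores a \code{score_matrix}.
#' @param marker_map data frame mapping \code{marker_id} to \code{gene_id}
#'   (as produced by [simulate_genotypes()]); defaults to the identity
#'   mapping marker i -> gene i by position.
#' @param drop_zero drop zero-score pairs instead of ranking them last.
#' @return a \code{ranked_edges} data frame: rank, regulator, target,
#'   score, is_padded.
#' @export
#' @examples
#' sm <- score_matrix(matrix(c(0, .4, .9, 0), 2, 2,
#'                    dimnames = list(c("M1", "M2"), c("G1", "G2"))), "toy")
#' scores_to_edges(sm, drop_zero = TRUE)
scores_to_edges <- function(scores, marker_map = NULL, drop_zero = FALSE) {
  stopifnot(inherits(scores, "score_matrix"))
  v <- scores$values
  mids <- rownames(v)
  gids <- colnames(v)
  if (is.null(marker_map)) {
    if (nrow(v) != ncol(v))
      abort_fmt("no marker map supplied and the matrix is not square")
    reg_of_marker <- gids
  } else {
    idx <- match(mids, marker_map$marker_id)
    if (anyNA(idx))
      abort_fmt("marker %s is not in the marker map", mids[which(is.na(idx))[1L]])
    reg_of_marker <- marker_map$gene_id[idx]
  }
  reg <- rep(reg_of_marker, times = ncol(v))
  tgt <- rep(gids, each = nrow(v))
  sc <- as.vector(v)
  keep <- reg != tgt
  if (drop_zero) keep <- keep & sc != 0
  reg <- reg[keep]; tgt <- tgt[keep]; sc <- sc[keep]
  o <- order(-sc, reg, tgt, method = "radix")
  ranked_edges(data.frame(
    rank = seq_along(o), regulator = reg[o], target = tgt[o], score = sc[o],
    is_padded = rep(FALSE, length(o)), stringsAsFactors = FALSE))
}

ranked_edges <- function(df) {
  class(df) <- c("ranked_edges", "data.frame")
  df
}

#' @export
print.ranked_edges <- function(x, n = 6L, ...) {
  cat(sprintf("ranked edge list: %d predictions (%d padded)\n",
              nrow(x), sum(x$is_padded)))
  if (nrow(x)) print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("  ... %d more\n", nrow(x) - n))
  invisible(x)
}

#' Truncate or randomly pad a prediction list to a fixed budget
#'
#' The benchmark evaluates a fixed number of top predictions (100,000 at
#' full scale). A longer list is truncated; a shorter one — typical for the
#' sparse filtered committee — is topped up with uniformly sampled directed
#' non-self edges from the gene universe that do not collide with existing
#' predictions, each flagged \code{is_padded} with score 0. Original order
#' is preserved.
#'
#' @param edges a \code{ranked_edges} data frame.
#' @param budget target list length.
#' @param gene_universe character vector of gene ids defining the candidate
#'   edge universe.
#' @param seed integer seed for the padding draw.
#' @return a \code{ranked_edges} data frame of exactly \code{budget} rows.
#' @export
pad_predictions <- function(edges, budget, gene_universe, seed = 1L) {
  budget <- check_count(budget, "budget", min = 0L)
  g <- length(gene_universe)
  if (budget > g * (g - 1L))
    abort_fmt("budget %d exceeds the %d possible directed edges", budget,
              g * (g - 1L))
  if (nrow(edges) >= budget) {
    out <- edges[seq_len(budget), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    return(ranked_edges(out))
  }
  # enumerate free (regulator, target) keys and sample without replacement
  ri <- match(edges$regulator, gene_universe)
  ti <- match(edges$target, gene_universe)
  if (anyNA(ri) || anyNA(ti))
    abort_fmt("prediction list contains genes outside the universe")
  used <- (ri - 1) * g + ti
  diag_keys <- (seq_len(g) - 1) * g + seq_len(g)
  free <- setdiff(seq_len(g * g), c(used, diag_keys))
  set.seed(derive_seed(seed, 13L))
  add <- sample(free, budget - nrow(edges))
  pad <- data.frame(
    rank = NA_integer_,
    regulator = gene_universe[(add - 1) %/% g + 1],
    target = gene_universe[(add - 1) %% g + 1],
    score = 0, is_padded = TRUE, stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(edges), pad)
  out$rank <- seq_len(nrow(out))
  ranked_edges(out)
}
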