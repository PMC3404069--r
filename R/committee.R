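# Committees: equal-weight averages of scaled and centered score matrices,
# optionally gated to zero outside the LASSO support.

#' Parse a committee specification string
#'
#' The grammar mirrors the field's shorthand: members joined by \code{+},
#' an optional surrounding \code{{...}}, and an optional \code{|LASSO}
#' suffix requesting the filtered committee (the members are averaged and
#' the average is set to zero wherever the LASSO coefficient is zero; the
#' LASSO matrix itself is not averaged). Examples: \code{"RF.sf+LASSO"},
#' \code{"{RF.sf+RF.pi+ElNet}|LASSO"}.
#'
#' @param spec committee string.
#' @return a list with \code{members} (character vector) and
#'   \code{filter_by_lasso} (flag), of class \code{committee_spec}.
#' @export
#' @examples
#' parse_committee("{RF.sf+RF.pi+ElNet}|LASSO")
parse_committee <- function(spec) {
  s <- gsub("[[:space:]]", "", spec)
  filt <- grepl("\\|LASSO$", s)
  if (filt) s <- sub("\\|LASSO$", "", s)
  s <- sub("^\\{", "", sub("\\}$", "", s))
  members <- strsplit(s, "+", fixed = TRUE)[[1L]]
  if (length(members) == 0L || any(members == ""))
    abort_fmt("empty committee specification '%s'", spec)
  bad <- setdiff(members, METHOD_LABELS)
  if (length(bad))
    abort_fmt("unknown method '%s' in committee '%s' (known: %s)",
              bad[1L], spec, paste(METHOD_LABELS, collapse = ", "))
  structure(list(members = members, filter_by_lasso = filt, label = spec),
            class = "committee_spec")
}

#' @export
print.committee_spec <- function(x, ...) {
  cat(sprintf("committee: %s%s\n", paste(x$members, collapse = " + "),
              if (x$filter_by_lasso) " | gated by the LASSO support" else ""))
  invisible(x)
}

#' Center and scale a score matrix
#'
#' With \code{scope = "global"} (the default for committees) the mean and
#' standard deviation of all entries are used, preserving between-gene
#' differences in signal strength; with \code{scope = "per_gene"} each gene
#' column is standardized separately. A zero standard deviation leaves the
#' centered values unscaled (hence all zeros) with a warning.
#'
#' @param scores a \code{score_matrix} (or bare matrix).
#' @param scope \code{"global"} or \code{"per_gene"}.
#' @return a \code{score_matrix} of z-scores.
#' @export
zscore_matrix <- function(scores, scope = c("global", "per_gene")) {
  scope <- match.arg(scope)
  m <- if (inherits(scores, "score_matrix")) scores$values else as.matrix(scores)
  if (length(m) == 0L) abort_fmt("empty score matrix")
  if (scope == "global") {
    s <- stats::sd(m)
    if (is.na(s) || s < 1e-300) {
      warning("constant score matrix: centered but not scaled", call. = FALSE)
      z <- m - mean(m)
    } else z <- (m - mean(m)) / s
  } else {
    z <- m
    for (g in seq_len(ncol(m))) {
      s <- stats::sd(m[, g])
      if (is.na(s) || s < 1e-300) {
        warning(sprintf("constant scores for gene %s: centered only",
                        colnames(m)[g]), call. = FALSE)
        z[, g] <- m[, g] - mean(m[, g])
      } else z[, g] <- (m[, g] - mean(m[, g])) / s
    }
  }
  label <- if (inherits(scores, "score_matrix")) scores$method else "scores"
  score_matrix(z, label)
}

check_same_index <- function(mats) {
  ref <- mats[[1L]]$values
  for (m in mats[-1L]) {
    dm <- dimnames(m$values)
    if (!identical(rownames(ref), dm[[1L]])) {
      bad <- c(setdiff(dm[[1L]], rownames(ref)), setdiff(rownames(ref), dm[[1L]]))
      abort_fmt("marker sets differ between members (first mismatch: %s)", bad[1L])
    }
    if (!identical(colnames(ref), dm[[2L]])) {
      bad <- c(setdiff(dm[[2L]], colnames(ref)), setdiff(colnames(ref), dm[[2L]]))
      abort_fmt("gene sets differ between members (first mismatch: %s)", bad[1L])
    }
  }
  invisible(TRUE)
}

#' Unfiltered committee: mean of scaled and centered member scores
#'
#' Each member matrix is z-scored ([zscore_matrix()]) and the committee is
#' the entrywise arithmetic mean. Z-scoring makes the combination invariant
#' to any positive affine rescaling of a member's raw scores, so methods on
#' incommensurable scales (split counts, MSE increases, coefficients)
#' contribute equally.
#'
#' @param matrices list of \code{score_matrix} objects sharing marker and
#'   gene index sets.
#' @param scope scaling scope passed to [zscore_matrix()].
#' @return a \code{score_matrix} labelled with the member list.
#' @export
combine_unfiltered <- function(matrices, scope = c("global", "per_gene")) {
  scope <- match.arg(scope)
  if (length(matrices) == 0L) abort_fmt("no member matrices")
  matrices <- lapply(matrices, function(m)
    if (inherits(m, "score_matrix")) m else score_matrix(m, "scores"))
  check_same_index(matrices)
  zs <- lapply(matrices, zscore_matrix, scope = scope)
  acc <- zs[[1L]]$values
  for (m in zs[-1L]) acc <- acc + m$values
  score_matrix(acc / length(zs),
               paste(vapply(matrices, function(m) m$method, ""), collapse = "+"))
}

#' Filtered committee: member average gated by the LASSO support
#'
#' The members (typically RF.sf, RF.pi and ElNet) are combined exactly as
#' in [combine_unfiltered()]; every (marker, gene) score is then set to
#' zero where the supplied LASSO score is zero (below \code{zero_tol}).
#' Only marker-gene pairs retained by the very sparse LASSO keep a nonzero
#' committee score, so the result's support is a subset of the LASSO
#' support — the committee inherits the LASSO's one-marker-per-linked-region
#' behaviour while ranking within the support by the richer average.
#'
#' @param members list of member \code{score_matrix} objects (the LASSO is
#'   not itself averaged).
#' @param lasso the LASSO \code{score_matrix} used as the gate.
#' @param scope scaling scope for the members.
#' @param zero_tol threshold below which a LASSO score counts as zero.
#' @return a \code{score_matrix} labelled \code{"{members}|LASSO"}.
#' @export
combine_filtered <- function(members, lasso, scope = c("global", "per_gene"),
                             zero_tol = 1e-10) {
  scope <- match.arg(scope)
  if (!inherits(lasso, "score_matrix")) lasso <- score_matrix(lasso, "LASSO")
  if (any(lasso$values < 0))
    abort_fmt("LASSO gate scores must be non-negative absolute coefficients")
  comm <- combine_unfiltered(members, scope = scope)
  check_same_index(list(comm, lasso))
  out <- comm$values
  out[lasso$values < zero_tol] <- 0
  score_matrix(out, sprintf("{%s}|LASSO", comm$method))
}
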