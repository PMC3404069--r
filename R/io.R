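# Plain-text interchange formats: TSV matrices with id headers, 2/3-column
# edge lists (challenge submission style), and the marker map. Every writer
# prepends '#' metadata comment lines; every reader skips them.

meta_header <- function(kind, extra = character()) {
  c(sprintf("# %s written by eqtlcommittee %s", kind,
            as.character(utils::packageVersion("eqtlcommittee"))),
    if (length(extra)) paste("#", extra))
}

#' Write a numeric matrix as TSV with row and column identifiers
#'
#' First column holds row ids under the header cell \code{id}; comment
#' lines starting with \code{#} carry metadata and are skipped on read.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file.
#' @param meta optional character vector of extra metadata lines.
#' @export
write_matrix_tsv <- function(m, path, meta = character()) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort_fmt("matrix must carry row and column identifiers")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header("matrix", meta), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

# split the non-comment lines of a TSV file, keeping original line numbers
tsv_lines <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(raw)
  list(fields = strsplit(raw[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path input file.
#' @return numeric matrix with row/column ids as dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tl <- tsv_lines(path)
  if (length(tl$fields) < 2L) abort_fmt("%s: no data rows", path)
  header <- tl$fields[[1L]]
  cols <- header[-1L]
  if (anyDuplicated(cols))
    abort_fmt("%s: duplicate column id '%s'", path, cols[duplicated(cols)][1L])
  rows <- tl$fields[-1L]
  n <- length(rows)
  ids <- character(n)
  vals <- matrix(NA_real_, n, length(cols))
  for (i in seq_len(n)) {
    f <- rows[[i]]
    if (length(f) != length(header))
      abort_fmt("%s line %d: expected %d fields, found %d", path,
                tl$lineno[i + 1L], length(header), length(f))
    ids[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v))
      abort_fmt("%s line %d: non-numeric cell '%s'", path, tl$lineno[i + 1L],
                f[-1L][which(is.na(v))[1L]])
    vals[i, ] <- v
  }
  if (anyDuplicated(ids))
    abort_fmt("%s: duplicate row id '%s'", path, ids[duplicated(ids)][1L])
  dimnames(vals) <- list(ids, cols)
  vals
}

#' Write a directed edge list (challenge submission style)
#'
#' Two tab-separated columns (regulator, target), plus a third score column
#' for ranked prediction lists.
#'
#' @param edges \code{ranked_edges}, \code{gold_network}, or a data frame
#'   with regulator/target (and optionally score) columns.
#' @param path output file.
#' @param scored include the score column.
#' @param meta extra metadata comment lines.
#' @export
write_edge_list <- function(edges, path, scored = !is.null(edges$score),
                            meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header("edge list", meta), con)
  if (nrow(edges)) {
    lines <- paste(edges$regulator, edges$target, sep = "\t")
    if (scored)
      lines <- paste(lines, format(edges$score, digits = 17, trim = TRUE),
                     sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a directed edge list
#'
#' A 2-column file is an unscored edge set; a 3-column file a scored,
#' ordered prediction list (order preserved; rank taken as given). With
#' \code{as_gold = TRUE} the result is a \code{gold_network}, and
#' self-edges or duplicates are rejected.
#'
#' @param path input file.
#' @param as_gold interpret as a gold-standard network.
#' @return a \code{ranked_edges} data frame or \code{gold_network}.
#' @export
read_edge_list <- function(path, as_gold = FALSE) {
  tl <- tsv_lines(path)
  n <- length(tl$fields)
  reg <- character(n); tgt <- character(n); sc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- tl$fields[[i]]
    if (!length(f) %in% c(2L, 3L))
      abort_fmt("%s line %d: expected 2 or 3 tab-separated fields, found %d",
                path, tl$lineno[i], length(f))
    reg[i] <- f[1L]; tgt[i] <- f[2L]
    if (length(f) == 3L) {
      sc[i] <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(sc[i]))
        abort_fmt("%s line %d: non-numeric score '%s'", path, tl$lineno[i], f[3L])
    }
  }
  if (any(reg == tgt))
    abort_fmt("%s line %d: self-edge %s -> %s", path,
              tl$lineno[which(reg == tgt)[1L]],
              reg[which(reg == tgt)[1L]], reg[which(reg == tgt)[1L]])
  if (anyDuplicated(paste(reg, tgt)))
    abort_fmt("%s: duplicate edge %s", path,
              paste(reg, tgt)[duplicated(paste(reg, tgt))][1L])
  if (as_gold) {
    net <- data.frame(regulator = reg, target = tgt, stringsAsFactors = FALSE)
    class(net) <- c("gold_network", "data.frame")
    return(net)
  }
  ranked_edges(data.frame(rank = seq_len(n), regulator = reg, target = tgt,
                          score = sc, is_padded = FALSE,
                          stringsAsFactors = FALSE))
}

#' Write / read the marker map
#'
#' TSV columns: marker_id, gene_id, chromosome, position_index,
#' mutation_type.
#'
#' @param marker_map data frame as produced by [simulate_genotypes()].
#' @param path file path.
#' @export
write_marker_map <- function(marker_map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header("marker map"), con)
  writeLines(paste(colnames(marker_map), collapse = "\t"), con)
  writeLines(do.call(paste, c(marker_map, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  tl <- tsv_lines(path)
  header <- tl$fields[[1L]]
  need <- c("marker_id", "gene_id", "chromosome", "position_index",
            "mutation_type")
  if (!identical(header, need))
    abort_fmt("%s: marker map header must be: %s", path,
              paste(need, collapse = ", "))
  rows <- tl$fields[-1L]
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- need
  df$chromosome <- as.integer(df$chromosome)
  df$position_index <- as.integer(df$position_index)
  if (anyDuplicated(df$marker_id) || anyDuplicated(df$gene_id))
    abort_fmt("%s: marker/gene ids must be unique", path)
  df
}

#' Write / read a genotype matrix together with its marker map
#'
#' The 0/1 genotype values go to \code{path} in the matrix TSV format and
#' the marker map to \code{paste0(path, ".map")} (or \code{map_path}).
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param path genotype TSV path.
#' @param map_path marker-map TSV path.
#' @export
write_genotypes <- function(genotypes, path, map_path = paste0(path, ".map")) {
  write_matrix_tsv(genotypes$values, path)
  write_marker_map(genotypes$marker_map, map_path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, map_path = paste0(path, ".map")) {
  v <- read_matrix_tsv(path)
  if (!all(v %in% c(0, 1)))
    abort_fmt("%s: genotype entries must be 0 or 1", path)
  storage.mode(v) <- "integer"
  map <- read_marker_map(map_path)
  if (!identical(colnames(v), map$marker_id))
    abort_fmt("marker ids in %s and %s disagree", path, map_path)
  structure(list(values = v, sample_ids = rownames(v), marker_map = map),
            class = "genotype_matrix")
}

#' Write a score matrix with its method label as metadata
#'
#' @param scores a \code{score_matrix}.
#' @param path output file.
#' @export
write_score_matrix <- function(scores, path) {
  write_matrix_tsv(scores$values, path,
                   meta = sprintf("method: %s", scores$method))
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  raw <- readLines(path, n = 20L)
  lab <- sub("^# method: ", "", grep("^# method: ", raw, value = TRUE))
  score_matrix(read_matrix_tsv(path),
               if (length(lab)) lab[1L] else "scores")
}
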