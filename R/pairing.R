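#' Build the binary within-sample rank-pair matrix
#'
#' For each unordered gene couple \{A, B\} (canonical orientation:
#' lexicographically smaller id first) and each sample s, the indicator is
#' `C_s = 1` iff `expr_s(A) > expr_s(B)` strictly, else 0 (ties score 0).
#' Exactly `g*(g-1)/2` pairs are emitted. Because the indicator depends
#' only on the within-sample ranking of the two genes, the matrix is
#' invariant to any strictly increasing per-sample transform of the
#' expression values - the construction needs no normalization.
#'
#' @param expr an [expression_matrix()] restricted to the genes to pair
#'   (>= 2 genes); gene ids must not contain the `"|"` separator
#' @return a `pair_matrix`: binary matrix (pairs x samples) with pair ids
#'   `"A|B"` as rownames and per-pair indicator frequencies as attribute
#'   `frequencies`
#' @export
build_pair_matrix <- function(expr) {
  v <- unclass(expr)
  g <- nrow(v)
  if (g < 2) lp_stop("need >= 2 genes to build pairs", "lncpair_precondition_error")
  if (ncol(v) < 1) lp_stop("need >= 1 sample", "lncpair_precondition_error")
  ids <- rownames(v)
  if (any(grepl("|", ids, fixed = TRUE))) {
    lp_stop("gene ids must not contain the pair separator '|'",
            "lncpair_validation_error")
  }
  ord <- order(ids)
  v <- v[ord, , drop = FALSE]
  ids <- ids[ord]
  cmb <- utils::combn(g, 2L)
  ind <- (v[cmb[1L, ], , drop = FALSE] > v[cmb[2L, ], , drop = FALSE]) * 1L
  rownames(ind) <- paste(ids[cmb[1L, ]], ids[cmb[2L, ]], sep = "|")
  colnames(ind) <- colnames(v)
  pair_matrix(ind)
}

#' Construct a `pair_matrix` from a binary indicator matrix
#'
#' @param ind binary matrix, pair ids `"A|B"` as rownames, samples as
#'   columns
#' @return validated `pair_matrix` with recomputed `frequencies`
#' @export
pair_matrix <- function(ind) {
  if (!is.matrix(ind) || is.null(rownames(ind)) || is.null(colnames(ind))) {
    lp_stop("pair matrix needs pair rownames and sample colnames",
            "lncpair_validation_error")
  }
  if (!all(ind %in% c(0L, 1L))) {
    lp_stop("pair matrix entries must be 0 or 1", "lncpair_validation_error")
  }
  if (anyDuplicated(rownames(ind))) {
    lp_stop("duplicated pair ids", "lncpair_validation_error")
  }
  storage.mode(ind) <- "integer"
  structure(ind, frequencies = rowMeans(ind),
            class = c("pair_matrix", "matrix", "array"))
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d pairs x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Indicator frequencies of a pair matrix
#' @param pm a `pair_matrix`
#' @return named numeric vector, the per-pair mean indicator over samples
#' @export
pair_frequencies <- function(pm) attr(pm, "frequencies")

#' Keep pairs whose indicator frequency can discriminate outcomes
#'
#' A pair whose indicator is almost always 0 or almost always 1 carries no
#' rank information; a pair is a valid match when the fraction of samples
#' with `C = 1` lies strictly inside `(low, high)`.
#'
#' @param pm a `pair_matrix`
#' @param low,high open-interval bounds (defaults 0.2 and 0.8)
#' @return the filtered `pair_matrix` (possibly with zero rows)
#' @export
filter_valid_pairs <- function(pm, low = 0.2, high = 0.8) {
  if (!(low < high) || low <= 0 || high >= 1) {
    lp_stop("need 0 < low < high < 1", "lncpair_config_error")
  }
  f <- pair_frequencies(pm)
  keep <- f > low & f < high
  pair_matrix(unclass(pm)[keep, , drop = FALSE])
}

#' Write a pair matrix (and its frequencies) as TSV
#' @param pm a `pair_matrix`
#' @param path indicator TSV path (pair_id rows x sample columns)
#' @param freq_path optional frequencies TSV path
#' @return invisibly, `path`
#' @export
write_pair_matrix <- function(pm, path, freq_path = NULL) {
  df <- data.frame(pair_id = rownames(pm), unclass(pm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(freq_path)) {
    utils::write.table(
      data.frame(pair_id = rownames(pm), frequency = pair_frequencies(pm)),
      freq_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a pair matrix written by [write_pair_matrix()]
#' @param path indicator TSV path
#' @return a `pair_matrix`
#' @export
read_pair_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  pair_matrix(m)
}
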