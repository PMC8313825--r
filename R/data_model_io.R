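#' lncpair: rank-based lncRNA pair signatures for survival prognosis
#'
#' Core containers: an expression matrix with tumor/normal sample labels, a
#' cleaned clinical table, a gene annotation map, and an immune gene set.
#' All readers consume plain TSV dialects so the pipeline has no binary
#' dependencies.
#'
#' @name lncpair-package
#' @useDynLib lncpair, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

#' Ensembl lncRNA biotypes recognised by default
#'
#' The default vocabulary used by [subset_lncrnas()]. Configurable because
#' annotation releases disagree on how lncRNAs are subdivided.
#'
#' @return character vector of biotype strings
#' @export
lncrna_biotypes <- function() {
  c("lncRNA", "lincRNA", "antisense", "processed_transcript",
    "sense_intronic", "sense_overlapping")
}

#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' @param ids character vector of gene ids such as `"ENSG000001.5"`
#' @return ids with a trailing `".NN"` removed
#' @export
strip_gene_version <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

#' Construct a validated expression matrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); non-negative
#' @param sample_group character/factor of length `ncol(values)` with values
#'   `"tumor"` or `"normal"`
#' @return an `expr_matrix` object (the matrix with a `sample_group`
#'   attribute)
#' @export
expression_matrix <- function(values, sample_group) {
  if (!is.matrix(values) || !is.numeric(values)) {
    lp_stop("expression values must be a numeric matrix", "lncpair_validation_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    lp_stop("expression matrix needs gene rownames and sample colnames",
            "lncpair_validation_error")
  }
  if (anyNA(values) || any(values < 0)) {
    lp_stop("expression values must be non-negative and non-missing",
            "lncpair_validation_error")
  }
  if (anyDuplicated(rownames(values))) {
    lp_stop("duplicated gene ids after loading", "lncpair_validation_error")
  }
  if (anyDuplicated(colnames(values))) {
    lp_stop("duplicated sample ids", "lncpair_validation_error")
  }
  sample_group <- as.character(sample_group)
  if (length(sample_group) != ncol(values) ||
      !all(sample_group %in% c("tumor", "normal"))) {
    lp_stop("sample_group must be 'tumor'/'normal', one per sample",
            "lncpair_validation_error")
  }
  structure(values, sample_group = sample_group,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  g <- table(attr(x, "sample_group"))
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s=%d", names(g), g), collapse = ", ")))
  invisible(x)
}

#' Sample group labels of an expression matrix
#' @param x an `expr_matrix`
#' @return character vector of `"tumor"`/`"normal"` labels
#' @export
sample_group <- function(x) attr(x, "sample_group")

#' Subset an expression matrix by genes and/or samples
#'
#' Keeps the `sample_group` attribute consistent with the selected columns.
#'
#' @param x an `expr_matrix`
#' @param genes gene ids (or row indices) to keep; `NULL` keeps all
#' @param samples sample ids (or column indices) to keep; `NULL` keeps all
#' @return the validated submatrix
#' @export
expr_subset <- function(x, genes = NULL, samples = NULL) {
  grp <- sample_group(x)
  v <- unclass(x)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, colnames(v)) else samples
    v <- v[, idx, drop = FALSE]
    grp <- grp[idx]
  }
  expression_matrix(v, grp)
}

#' Read a genes-in-rows expression TSV
#'
#' First column holds gene ids, remaining columns one sample each. Sample
#' groups come from a two-column sidecar TSV (`sample_id`, `group`).
#' Ensembl version suffixes are stripped from gene ids, and duplicated gene
#' ids are collapsed by keeping the row with the highest mean expression.
#'
#' @param path expression TSV path
#' @param groups_path sidecar TSV path assigning `"tumor"`/`"normal"` per
#'   sample; if `NULL` all samples are labelled `"tumor"`
#' @return an [expression_matrix()]
#' @export
read_expression <- function(path, groups_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) lp_stop("expression TSV needs >= 2 columns", "lncpair_parse_error")
  ids <- strip_gene_version(as.character(df[[1L]]))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        lp_stop(sprintf("non-numeric cell at row '%s', column '%s'",
                        ids[bad[1L]], names(vals)[j]), "lncpair_parse_error")
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    lp_stop("duplicated sample column in expression TSV", "lncpair_validation_error")
  }
  if (anyNA(m)) lp_stop("missing expression values", "lncpair_validation_error")
  if (any(m < 0)) lp_stop("negative expression value", "lncpair_validation_error")
  if (anyDuplicated(ids)) {
    means <- rowMeans(m)
    ord <- order(-means)              # highest-mean duplicate wins
    keep <- ord[!duplicated(ids[ord])]
    m <- m[sort(keep), , drop = FALSE]
  }
  grp <- rep("tumor", ncol(m))
  if (!is.null(groups_path)) {
    g <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    idx <- match(colnames(m), g[[1L]])
    if (anyNA(idx)) {
      lp_stop(sprintf("samples missing from group sidecar: %s",
                      paste(colnames(m)[is.na(idx)], collapse = ", ")),
              "lncpair_validation_error")
    }
    grp <- as.character(g[[2L]])[idx]
  }
  expression_matrix(m, grp)
}

#' Write an expression matrix and its group sidecar as TSV
#'
#' @param x an `expr_matrix`
#' @param path expression TSV path
#' @param groups_path optional sidecar TSV path
#' @return invisibly, `path`
#' @export
write_expression <- function(x, path, groups_path = NULL) {
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(
      data.frame(sample_id = colnames(x), group = sample_group(x)),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read and clean a clinical table
#'
#' Mandatory columns (after `col_map` renaming): `sample_id`, `os_time`
#' (days), `os_event` (0 = censored, 1 = death). Any further columns are
#' carried as covariates. Cleaning removes records with zero or negative
#' follow-up time and duplicated sample ids (first occurrence kept); the
#' counts removed per rule are attached as attribute `cleaning_report`.
#'
#' @param path TSV path
#' @param col_map named character vector mapping file column names to the
#'   canonical names, e.g. `c(id = "sample_id", time = "os_time")`
#' @return a `clinical_table` data.frame with attribute `cleaning_report`
#' @export
read_clinical <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    hit <- match(names(col_map), names(df))
    names(df)[hit[!is.na(hit)]] <- unname(col_map[!is.na(hit)])
  }
  clinical_table(df)
}

#' Validate and clean an in-memory clinical data.frame
#'
#' @param df data.frame with columns `sample_id`, `os_time`, `os_event` and
#'   optional covariates
#' @return a cleaned `clinical_table` with attribute `cleaning_report`
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    lp_stop(sprintf("clinical table missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "lncpair_schema_error")
  }
  df$os_time <- as.numeric(df$os_time)
  ev <- df$os_event
  if (!all(ev %in% c(0, 1))) {
    lp_stop("os_event values outside {0,1}", "lncpair_validation_error")
  }
  df$os_event <- as.integer(ev)
  n0 <- nrow(df)
  keep_time <- is.finite(df$os_time) & df$os_time > 0
  df <- df[keep_time, , drop = FALSE]
  n_zero <- n0 - nrow(df)
  dup <- duplicated(df$sample_id)
  df <- df[!dup, , drop = FALSE]
  report <- c(removed_zero_followup = n_zero, removed_duplicate = sum(dup))
  rownames(df) <- NULL
  structure(df, cleaning_report = report,
            class = c("clinical_table", "data.frame"))
}

#' Cleaning report of a clinical table
#' @param x a `clinical_table`
#' @return named integer vector of removal counts per cleaning rule
#' @export
cleaning_report <- function(x) attr(x, "cleaning_report")

#' Write a clinical table as TSV
#' @param x a `clinical_table`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_clinical <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation (two-column TSV or GTF)
#'
#' A TSV must have columns `gene_id` and `biotype` (optional `symbol`).
#' A GTF is parsed from its `gene` feature lines, taking `gene_id` and
#' `gene_biotype`/`gene_type` attributes. Version suffixes are stripped and
#' one record per gene id is kept.
#'
#' @param path file path; format auto-detected from the `.gtf` extension
#' @return data.frame with columns `gene_id`, `biotype`, `symbol`
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    fields <- strsplit(ln, "\t", fixed = TRUE)
    is_gene <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene",
                      logical(1))
    attrs <- vapply(fields[is_gene], `[[`, character(1), 9L)
    pull <- function(key) {
      m <- regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs))
      out <- rep(NA_character_, length(attrs))
      hit <- grepl(sprintf('%s "', key), attrs)
      out[hit] <- sub(sprintf('%s "([^"]*)"', key), "\\1", m)
      out
    }
    gene_id <- pull("gene_id")
    biotype <- pull("gene_biotype")
    if (all(is.na(biotype))) biotype <- pull("gene_type")
    symbol <- pull("gene_name")
    ann <- data.frame(gene_id = gene_id, biotype = biotype, symbol = symbol,
                      stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("gene_id", "biotype") %in% names(ann))) {
      lp_stop("annotation TSV needs 'gene_id' and 'biotype' columns",
              "lncpair_schema_error")
    }
    if (is.null(ann$symbol)) ann$symbol <- NA_character_
  }
  ann$gene_id <- strip_gene_version(ann$gene_id)
  ann <- ann[!duplicated(ann$gene_id),
             c("gene_id", "biotype", "symbol"), drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write a gene annotation as two-column TSV
#' @param ann annotation data.frame from [read_annotation()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set (one identifier per line, `#` comments allowed)
#' @param path file path
#' @return character vector of gene ids (version suffixes stripped)
#' @export
read_gene_set <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  ids <- unique(strip_gene_version(ln))
  if (!length(ids)) lp_stop("empty gene set", "lncpair_validation_error")
  ids
}

#' Write a gene set, one identifier per line
#' @param ids character vector
#' @param path output path
#' @return invisibly, `path`
#' @export
write_gene_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Subset an expression matrix to lncRNA genes
#'
#' @param x an `expr_matrix`
#' @param annotation data.frame from [read_annotation()]
#' @param biotypes biotype vocabulary counting as lncRNA
#' @return the lncRNA submatrix, sample order preserved
#' @export
subset_lncrnas <- function(x, annotation, biotypes = lncrna_biotypes()) {
  keep_ids <- annotation$gene_id[annotation$biotype %in% biotypes]
  hit <- intersect(rownames(x), keep_ids)
  if (!length(hit)) lp_stop("no lncRNAs found in expression matrix",
                            "lncpair_empty_result_error")
  expr_subset(x, genes = hit)
}
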