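#' Default ICI-related marker genes
#'
#' Immune-checkpoint molecules conventionally compared between risk
#' groups; configurable because identifier schemes differ across datasets.
#'
#' @return character vector of gene symbols
#' @export
ici_genes <- function() c("CTLA4", "PDCD1", "LAG3", "TIGIT", "HAVCR2")

#' Default ordinal encoding for stage-like clinical covariates
#'
#' Maps the shipped category labels to ordered integers for the
#' independence Cox analysis; override to match other dictionaries.
#'
#' @return named list: covariate name -> named numeric vector
#' @export
default_ordinal_map <- function() {
  list(stage = c(I = 1, II = 2, III = 3, IV = 4),
       t_stage = c(T1 = 1, T2 = 2, T3 = 3, T4 = 4),
       n_stage = c(N0 = 0, N1 = 1, N2 = 2, N3 = 3),
       m_stage = c(M0 = 0, M1 = 1),
       grade = c(G1 = 1, G2 = 2, G3 = 3, G4 = 4),
       gender = c(female = 0, male = 1))
}

assoc_row <- function(feature, test, statistic, p, direction = NA_character_,
                      detail = NA_character_) {
  data.frame(feature = feature, test = test, statistic = statistic, p = p,
             direction = direction, significant = is.finite(p) & p < 0.05,
             detail = detail, stringsAsFactors = FALSE)
}

# independent-samples rank-sum comparison; direction by median difference
wilcox_compare <- function(high, low) {
  suppressWarnings(wt <- stats::wilcox.test(high, low))
  dir <- if (stats::median(high) < stats::median(low)) "lower in high"
         else if (stats::median(high) > stats::median(low)) "higher in high"
         else "equal medians"
  list(statistic = unname(wt$statistic), p = wt$p.value, direction = dir)
}

#' Association between risk groups and clinical characteristics
#'
#' Per categorical clinical feature: a chi-squared test (no continuity
#' correction) of the risk-group x category contingency table, dropping
#' empty categories with a warning; plus a comparison of the risk score
#' across the feature's categories by Wilcoxon rank-sum (two categories)
#' or Kruskal-Wallis (more).
#'
#' @param profile a `risk_profile` (scores named by sample id)
#' @param clinical a `clinical_table`
#' @param features covariate columns to test (default: all non-core
#'   columns of `clinical`)
#' @return data.frame of association results (feature, test, statistic, p,
#'   direction, significant)
#' @export
clinical_association <- function(profile, clinical, features = NULL) {
  idx <- match(names(profile$scores), clinical$sample_id)
  if (anyNA(idx)) lp_stop("profile samples missing from clinical table",
                          "lncpair_alignment_error")
  cl <- clinical[idx, , drop = FALSE]
  if (is.null(features)) {
    features <- setdiff(names(cl), c("sample_id", "os_time", "os_event"))
  }
  grp <- profile$group
  out <- list()
  for (f in features) {
    v <- as.character(cl[[f]])
    ok <- !is.na(v)
    tab <- table(grp[ok], v[ok])
    empty <- colSums(tab) == 0
    if (any(empty)) {
      warning(sprintf("dropping empty categories of '%s'", f))
      tab <- tab[, !empty, drop = FALSE]
    }
    if (ncol(tab) >= 2 && nrow(tab) == 2) {
      suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
      out[[length(out) + 1L]] <- assoc_row(f, "chi_squared",
                                           unname(ct$statistic), ct$p.value)
    }
    # risk-score differences across categories
    cats <- unique(v[ok])
    if (length(cats) == 2) {
      s1 <- profile$scores[ok][v[ok] == cats[1]]
      s2 <- profile$scores[ok][v[ok] == cats[2]]
      if (length(s1) >= 2 && length(s2) >= 2) {
        suppressWarnings(wt <- stats::wilcox.test(s1, s2))
        out[[length(out) + 1L]] <- assoc_row(
          f, "wilcoxon_rank_sum", unname(wt$statistic), wt$p.value,
          detail = paste(cats, collapse = " vs "))
      }
    } else if (length(cats) > 2) {
      kw <- stats::kruskal.test(profile$scores[ok], factor(v[ok]))
      out[[length(out) + 1L]] <- assoc_row(f, "kruskal_wallis",
                                           unname(kw$statistic), kw$p.value)
    }
  }
  do.call(rbind, out)
}

#' Univariate and multivariate Cox on the risk score and clinical factors
#'
#' Tests whether the risk score is prognostic independently of the clinical
#' covariates. Stage-like covariates are encoded as ordered integers via
#' `ordinal_map`; unmapped non-numeric covariates are skipped. Rows with
#' missing values are dropped casewise (counted in the report), and
#' collinear covariates are dropped (later column loses) with a warning.
#'
#' @param scores named per-sample risk scores
#' @param clinical a `clinical_table`
#' @param ordinal_map encoding dictionary, see [default_ordinal_map()]
#' @param covariates clinical columns to include (default: every column
#'   that is numeric or mapped)
#' @return list with `univariate` (named list of `cox_fit`, one per
#'   covariate including `risk_score`), `multivariate` (joint `cox_fit`)
#'   and `report`
#' @export
independence_cox <- function(scores, clinical,
                             ordinal_map = default_ordinal_map(),
                             covariates = NULL) {
  idx <- match(names(scores), clinical$sample_id)
  if (anyNA(idx)) lp_stop("score samples missing from clinical table",
                          "lncpair_alignment_error")
  cl <- clinical[idx, , drop = FALSE]
  pool <- setdiff(names(cl), c("sample_id", "os_time", "os_event"))
  if (!is.null(covariates)) pool <- intersect(pool, covariates)
  X <- data.frame(risk_score = as.numeric(scores))
  for (f in pool) {
    v <- cl[[f]]
    if (is.numeric(v)) {
      X[[f]] <- v
    } else if (f %in% names(ordinal_map)) {
      X[[f]] <- unname(ordinal_map[[f]][as.character(v)])
    }
  }
  ok <- stats::complete.cases(X)
  n_dropped <- sum(!ok)
  X <- as.matrix(X[ok, , drop = FALSE])
  tm <- cl$os_time[ok]
  ev <- cl$os_event[ok]
  # drop exactly collinear covariates, later column loses
  qr_x <- qr(cbind(1, scale(X, scale = FALSE)))
  if (qr_x$rank < ncol(X) + 1L) {
    keep <- sort(qr_x$pivot[seq_len(qr_x$rank)]) - 1L
    keep <- keep[keep >= 1L]
    dropped_cols <- setdiff(colnames(X), colnames(X)[keep])
    warning(sprintf("dropping collinear covariate(s): %s",
                    paste(dropped_cols, collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  prep <- cox_prepare(tm, ev)
  uni <- lapply(colnames(X), function(cn) {
    cox_fit(tm, ev, matrix(X[, cn], ncol = 1, dimnames = list(NULL, cn)),
            prep = prep)
  })
  names(uni) <- colnames(X)
  multi <- cox_fit(tm, ev, X, prep = prep)
  list(univariate = uni, multivariate = multi,
       report = c(n_used = sum(ok), n_dropped_missing = n_dropped))
}

#' Spearman correlation and group comparison of immune infiltration
#'
#' Per (cell type, method): Spearman correlation of the risk score with the
#' infiltration score (two-sided p), and a Wilcoxon rank-sum comparison of
#' infiltration between high- and low-risk groups. Constant infiltration
#' columns are skipped and counted.
#'
#' @param profile a `risk_profile`
#' @param infiltration long data.frame: sample_id, cell_type, method, score
#' @return data.frame of association results; attribute `report` holds the
#'   skipped-column count
#' @export
immune_correlation <- function(profile, infiltration) {
  shared <- intersect(names(profile$scores), infiltration$sample_id)
  if (length(shared) < 3) lp_stop("need >= 3 shared samples",
                                  "lncpair_precondition_error")
  inf <- infiltration[infiltration$sample_id %in% shared, , drop = FALSE]
  keys <- unique(inf[, c("cell_type", "method")])
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(keys))) {
    sub <- inf[inf$cell_type == keys$cell_type[i] &
               inf$method == keys$method[i], , drop = FALSE]
    sc <- profile$scores[sub$sample_id]
    grp <- profile$group[match(sub$sample_id, names(profile$scores))]
    label <- paste(keys$cell_type[i], keys$method[i], sep = "/")
    if (stats::sd(sub$score) == 0) {
      skipped <- skipped + 1L
      next
    }
    suppressWarnings(
      sp <- stats::cor.test(sc, sub$score, method = "spearman",
                            exact = FALSE))
    out[[length(out) + 1L]] <- assoc_row(
      label, "spearman", unname(sp$estimate), sp$p.value,
      direction = ifelse(sp$estimate < 0, "negative", "positive"))
    if (sum(grp == "high") >= 2 && sum(grp == "low") >= 2) {
      wc <- wilcox_compare(sub$score[grp == "high"], sub$score[grp == "low"])
      out[[length(out) + 1L]] <- assoc_row(
        label, "wilcoxon_rank_sum", wc$statistic, wc$p, wc$direction)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "report") <- c(skipped_constant = skipped)
  res
}

#' Compare gene expression between risk groups
#'
#' Per listed gene: Wilcoxon rank-sum of `log2(x+1)` expression between
#' high- and low-risk samples, with the direction of the median
#' difference. Genes absent from the matrix are reported, not fatal.
#'
#' @param expr an [expression_matrix()]
#' @param profile a `risk_profile` over samples of `expr`
#' @param genes gene ids/symbols to test (default [ici_genes()])
#' @return data.frame of association results; attribute `missing_genes`
#'   lists genes not found
#' @export
group_expression_compare <- function(expr, profile, genes = ici_genes()) {
  present <- intersect(genes, rownames(expr))
  missing <- setdiff(genes, present)
  ids <- intersect(names(profile$scores), colnames(expr))
  grp <- profile$group[match(ids, names(profile$scores))]
  out <- list()
  for (g in present) {
    v <- log2(unclass(expr)[g, ids] + 1)
    wc <- wilcox_compare(v[grp == "high"], v[grp == "low"])
    out[[length(out) + 1L]] <- assoc_row(g, "wilcoxon_rank_sum",
                                         wc$statistic, wc$p, wc$direction)
  }
  res <- if (length(out)) do.call(rbind, out) else
    assoc_row(character(0), character(0), numeric(0), numeric(0),
              character(0), character(0))
  attr(res, "missing_genes") <- missing
  res
}

#' Compare drug IC50 between risk groups
#'
#' Per drug: Wilcoxon rank-sum on IC50 between high- and low-risk groups
#' with the direction of the median difference ("lower in high" means
#' higher inferred sensitivity of the high-risk group). Drugs with fewer
#' than two samples in either group are skipped and counted.
#'
#' @param profile a `risk_profile`
#' @param drugs long data.frame: sample_id, drug, ic50
#' @return data.frame of association results; attribute `report` counts
#'   skipped drugs
#' @export
drug_sensitivity_compare <- function(profile, drugs) {
  out <- list()
  skipped <- 0L
  for (d in unique(drugs$drug)) {
    sub <- drugs[drugs$drug == d & drugs$sample_id %in%
                   names(profile$scores), , drop = FALSE]
    grp <- profile$group[match(sub$sample_id, names(profile$scores))]
    if (sum(grp == "high") < 2 || sum(grp == "low") < 2) {
      skipped <- skipped + 1L
      next
    }
    wc <- wilcox_compare(sub$ic50[grp == "high"], sub$ic50[grp == "low"])
    out[[length(out) + 1L]] <- assoc_row(d, "wilcoxon_rank_sum",
                                         wc$statistic, wc$p, wc$direction)
  }
  res <- do.call(rbind, out)
  attr(res, "report") <- c(skipped_drugs = skipped)
  res
}

#' Read a long-format infiltration table TSV
#' @param path TSV with columns sample_id, cell_type, method, score
#' @return data.frame
#' @export
read_infiltration <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_type", "method", "score")
  if (!all(need %in% names(df))) {
    lp_stop("infiltration TSV needs sample_id, cell_type, method, score",
            "lncpair_schema_error")
  }
  df
}

#' Read a long-format drug-response table TSV
#' @param path TSV with columns sample_id, drug, ic50
#' @return data.frame
#' @export
read_drug_response <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "drug", "ic50") %in% names(df))) {
    lp_stop("drug TSV needs sample_id, drug, ic50", "lncpair_schema_error")
  }
  df
}
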