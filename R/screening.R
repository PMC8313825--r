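#' Screen immune-related lncRNAs by co-expression
#'
#' Pearson correlation of every (lncRNA, immune gene) couple on the
#' `log2(x+1)` scale across all samples; the p-value comes from the usual
#' t transform `t = r * sqrt((n-2)/(1-r^2))` against a t distribution with
#' n-2 degrees of freedom. An lncRNA is retained when ANY immune gene
#' has correlation above `r_min` with `p < p_max`. The printed rule is one-sided on
#' positive correlation; set `abs_cor = TRUE` to screen on `|r|`. No
#' multiplicity correction is applied to the raw p threshold.
#'
#' Zero-variance genes yield undefined correlations; affected couples are
#' skipped and counted in the report rather than raising an error.
#'
#' @param expr an [expression_matrix()]
#' @param lnc_ids,immune_ids gene id vectors present in `expr`
#' @param r_min correlation threshold (default 0.4)
#' @param p_max p-value threshold (default 0.001)
#' @param abs_cor screen on `|r|` instead of `r`
#' @return list with `ids` (retained lncRNAs), `correlations` (data.frame:
#'   lnc_id, immune_gene_id, r, p) and `report` (skipped-couple count)
#' @export
screen_irlncrnas <- function(expr, lnc_ids, immune_ids,
                             r_min = 0.4, p_max = 0.001, abs_cor = FALSE) {
  lnc_ids <- intersect(lnc_ids, rownames(expr))
  immune_ids <- intersect(immune_ids, rownames(expr))
  if (!length(lnc_ids) || !length(immune_ids)) {
    lp_stop("lncRNA and immune id sets must both be present in the matrix",
            "lncpair_precondition_error")
  }
  n <- ncol(expr)
  if (n < 3) lp_stop("need >= 3 samples for the correlation screen",
                     "lncpair_precondition_error")
  lx <- t(log2(unclass(expr)[lnc_ids, , drop = FALSE] + 1))
  ix <- t(log2(unclass(expr)[immune_ids, , drop = FALSE] + 1))
  sd_l <- apply(lx, 2, stats::sd)
  sd_i <- apply(ix, 2, stats::sd)
  suppressWarnings(r <- stats::cor(lx, ix))
  r[sd_l == 0, ] <- NA_real_
  r[, sd_i == 0] <- NA_real_
  rr <- pmin(pmax(r, -1), 1)
  tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rr) >= 1 - 1e-12] <- 0
  res <- data.frame(
    lnc_id = rep(lnc_ids, times = length(immune_ids)),
    immune_gene_id = rep(immune_ids, each = length(lnc_ids)),
    r = as.numeric(r), p = as.numeric(p), stringsAsFactors = FALSE)
  skipped <- sum(is.na(res$r))
  ok <- !is.na(res$r)
  crit <- if (abs_cor) abs(res$r) > r_min else res$r > r_min
  pass <- ok & crit & res$p < p_max
  ids <- sort(unique(res$lnc_id[pass]))
  list(ids = ids, correlations = res,
       report = c(couples_tested = nrow(res), couples_skipped = skipped,
                  retained = length(ids)))
}

#' Tumor-vs-normal differential expression of lncRNAs
#'
#' `log2fc` is the difference of group means of `log2(x+1)`. The default
#' test engine is the two-sided Wilcoxon rank-sum test, in keeping with the
#' rank-based philosophy of the pair transform (an empirical-Bayes moderated
#' t is deliberately not reproduced; a Welch t on `log2(x+1)` is available
#' via `engine = "welch"`). P-values are Benjamini-Hochberg adjusted over
#' all tested genes, and a gene is flagged DE iff `|log2fc| > lfc_min` and
#' `fdr < fdr_max`.
#'
#' @param expr an [expression_matrix()] restricted to candidate genes, with
#'   both tumor and normal groups present (>= 2 samples each)
#' @param lfc_min absolute log2 fold-change threshold (default 1.0)
#' @param fdr_max FDR threshold (default 0.05)
#' @param engine `"wilcoxon"` (default) or `"welch"`
#' @return data.frame: gene_id, log2fc, p, fdr, direction, de (logical)
#' @export
differential_expression <- function(expr, lfc_min = 1.0, fdr_max = 0.05,
                                    engine = c("wilcoxon", "welch")) {
  engine <- match.arg(engine)
  grp <- sample_group(expr)
  if (sum(grp == "tumor") < 2 || sum(grp == "normal") < 2) {
    lp_stop("differential expression needs >= 2 samples per group",
            "lncpair_precondition_error")
  }
  v <- unclass(expr)
  lv <- log2(v + 1)
  tum <- grp == "tumor"
  log2fc <- rowMeans(lv[, tum, drop = FALSE]) -
            rowMeans(lv[, !tum, drop = FALSE])
  p <- vapply(seq_len(nrow(v)), function(i) {
    a <- lv[i, tum]
    b <- lv[i, !tum]
    if (stats::sd(c(a, b)) == 0) return(1)
    if (engine == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    } else {
      stats::t.test(a, b)$p.value
    }
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(v), log2fc = log2fc, p = p, fdr = fdr,
             direction = ifelse(log2fc > 0, "up", "down"),
             de = abs(log2fc) > lfc_min & fdr < fdr_max,
             stringsAsFactors = FALSE, row.names = NULL)
}
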