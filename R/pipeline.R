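#' Pipeline run configuration
#'
#' Collects every input path and tuning threshold of the cascade. The
#' defaults are the thresholds of the published procedure: correlation
#' screen Pearson correlation above 0.4 at `p < 0.001`, DE gates `|log2FC| > 1` at
#' `FDR < 0.05`, pair validity strictly inside (0.2, 0.8), univariate Cox
#' screen at `p < 0.05`, LASSO-Cox selection at the CV-deviance minimizer,
#' and ROC evaluation at 1/3/5 years (in days).
#'
#' @param expression,groups,clinical,annotation,immune_genes input paths
#'   (may be `NULL` when calling [run_cascade()] on in-memory objects)
#' @param infiltration,ic50 optional downstream table paths
#' @param r_min,cor_p co-expression screen thresholds
#' @param abs_cor screen on absolute correlation
#' @param lfc_min,fdr_max differential-expression gates
#' @param pair_low,pair_high pair validity bounds (open interval)
#' @param uni_p univariate Cox retention threshold
#' @param lambda_rule `"lambda_min"` or `"lambda_1se"`
#' @param n_folds LASSO cross-validation folds
#' @param min_group_frac cutpoint guard fraction
#' @param eval_times ROC horizons in days
#' @param seed master integer seed
#' @param out_dir output directory for [run_pipeline()]
#' @return a `run_config` list
#' @export
run_config <- function(expression = NULL, groups = NULL, clinical = NULL,
                       annotation = NULL, immune_genes = NULL,
                       infiltration = NULL, ic50 = NULL,
                       r_min = 0.4, cor_p = 0.001, abs_cor = FALSE,
                       lfc_min = 1.0, fdr_max = 0.05,
                       pair_low = 0.2, pair_high = 0.8,
                       uni_p = 0.05,
                       lambda_rule = c("lambda_min", "lambda_1se"),
                       n_folds = 10L, min_group_frac = 0.1,
                       eval_times = c(365, 1095, 1825),
                       seed = 1L, out_dir = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(r_min >= -1, r_min <= 1, cor_p > 0, cor_p <= 1,
            lfc_min >= 0, fdr_max > 0, fdr_max <= 1,
            pair_low > 0, pair_high < 1, pair_low < pair_high,
            uni_p >= 0, uni_p <= 1, min_group_frac >= 0,
            min_group_frac < 0.5, all(eval_times > 0))
  cfg <- list(expression = expression, groups = groups, clinical = clinical,
              annotation = annotation, immune_genes = immune_genes,
              infiltration = infiltration, ic50 = ic50,
              r_min = r_min, cor_p = cor_p, abs_cor = abs_cor,
              lfc_min = lfc_min, fdr_max = fdr_max,
              pair_low = pair_low, pair_high = pair_high, uni_p = uni_p,
              lambda_rule = lambda_rule, n_folds = as.integer(n_folds),
              min_group_frac = min_group_frac, eval_times = eval_times,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

stage_fail <- function(stage, manifest, msg) {
  stop(structure(class = c("lncpair_stage_error", "lncpair_error",
                           "error", "condition"),
                 list(message = sprintf("stage '%s': %s", stage, msg),
                      call = NULL, stage = stage, manifest = manifest)))
}

#' Run the full modelling cascade on in-memory inputs
#'
#' Executes screen -> differential expression -> pairing -> validity filter
#' -> univariate Cox -> LASSO-Cox -> stepwise Cox -> risk scoring -> tdROC
#' -> AIC cutpoint -> stratification, plus the downstream comparisons when
#' infiltration / IC50 tables are given. An empty survivor set at any stage
#' aborts with a stage-named error carrying the manifest so far.
#'
#' @param expr an [expression_matrix()] (tumor and normal samples)
#' @param clinical a `clinical_table` covering the tumor samples
#' @param annotation annotation data.frame ([read_annotation()] format)
#' @param immune_set character vector of immune gene ids
#' @param config a [run_config()]
#' @param infiltration,drug_response optional long-format tables
#' @return a `pipeline_result` list with every stage's output and a
#'   `manifest` of cascade counts
#' @export
run_cascade <- function(expr, clinical, annotation, immune_set, config,
                        infiltration = NULL, drug_response = NULL) {
  man <- list(config = config[!vapply(config, is.null, logical(1))],
              counts = list(), seed = config$seed)
  note <- function(k, v) man$counts[[k]] <<- v

  note("genes_in", nrow(expr))
  lnc <- tryCatch(subset_lncrnas(expr, annotation),
                  error = function(e) NULL)
  if (is.null(lnc)) stage_fail("subset_lncrnas", man, "no lncRNAs found")
  note("lncRNAs", nrow(lnc))

  scr <- screen_irlncrnas(expr, rownames(lnc), immune_set,
                          r_min = config$r_min, p_max = config$cor_p,
                          abs_cor = config$abs_cor)
  if (!length(scr$ids)) stage_fail("screen_irlncrnas", man, "no irlncRNAs retained")
  note("irlncRNAs", length(scr$ids))

  de <- differential_expression(expr_subset(expr, genes = scr$ids),
                                lfc_min = config$lfc_min,
                                fdr_max = config$fdr_max)
  de_ids <- de$gene_id[de$de]
  if (length(de_ids) < 2) stage_fail("differential_expression", man,
                                     "fewer than 2 DE irlncRNAs")
  note("DEirlncRNAs", length(de_ids))
  note("DE_up", sum(de$de & de$direction == "up"))
  note("DE_down", sum(de$de & de$direction == "down"))

  tumor_ids <- intersect(colnames(expr)[sample_group(expr) == "tumor"],
                         clinical$sample_id)
  if (length(tumor_ids) < 10) stage_fail("alignment", man,
                                         "fewer than 10 tumor samples with clinical data")
  clin <- clinical[match(tumor_ids, clinical$sample_id), , drop = FALSE]
  texpr <- expr_subset(expr, genes = de_ids, samples = tumor_ids)

  pm <- build_pair_matrix(texpr)
  note("pairs_built", nrow(pm))
  pm <- filter_valid_pairs(pm, config$pair_low, config$pair_high)
  if (!nrow(pm)) stage_fail("filter_valid_pairs", man, "no valid pairs")
  note("valid_pairs", nrow(pm))

  uni <- univariate_pair_screen(pm, clin, p_max = config$uni_p)
  if (!length(uni$retained)) stage_fail("univariate_pair_screen", man,
                                        "no univariate survivors")
  note("univariate_survivors", length(uni$retained))

  ind <- t(unclass(pm)[uni$retained, clin$sample_id, drop = FALSE])
  las <- lasso_cox(clin$os_time, clin$os_event, ind,
                   n_folds = config$n_folds,
                   seed = derive_seed(config$seed, "lasso_folds"),
                   lambda_rule = config$lambda_rule)
  if (!length(las$selected)) stage_fail("lasso_cox", man,
                                        "no covariates survive the LASSO")
  note("lasso_candidates", length(las$selected))

  sw <- stepwise_cox(clin$os_time, clin$os_event,
                     ind[, las$selected, drop = FALSE])
  if (!length(sw$covariates)) stage_fail("stepwise_cox", man,
                                         "stepwise selected the empty model")
  note("signature_size", length(sw$covariates))

  sig <- signature_from_fit(sw)
  scores <- risk_score(pm, sig)[clin$sample_id]

  rocs <- lapply(config$eval_times, function(tt) {
    tryCatch(td_roc(clin$os_time, clin$os_event, scores, tt),
             error = function(e) NULL)
  })
  names(rocs) <- paste0("t", config$eval_times)
  t_ref <- config$eval_times[length(config$eval_times)]
  scan <- aic_cutpoint(clin$os_time, clin$os_event, scores, t_ref = t_ref,
                       min_group_frac = config$min_group_frac)
  profile <- stratify(scores, scan$cutoff)
  note("n_high", profile$n_high)
  note("n_low", profile$n_low)

  lr <- logrank_test(clin$os_time, clin$os_event, profile$group)
  km_high <- km_estimate(clin$os_time[profile$group == "high"],
                         clin$os_event[profile$group == "high"])
  km_low <- km_estimate(clin$os_time[profile$group == "low"],
                        clin$os_event[profile$group == "low"])

  assoc <- clinical_association(profile, clin)
  indep <- independence_cox(scores, clin)
  imm <- if (!is.null(infiltration)) immune_correlation(profile, infiltration)
  drg <- if (!is.null(drug_response)) drug_sensitivity_compare(profile,
                                                               drug_response)
  ici <- group_expression_compare(expr_subset(expr, samples = tumor_ids),
                                  profile)

  structure(list(manifest = man, screen = scr, de = de, pair_matrix = pm,
                 univariate = uni, lasso = las, stepwise = sw,
                 signature = sig, scores = scores, rocs = rocs,
                 cutpoint = scan, profile = profile, logrank = lr,
                 km = list(high = km_high, low = km_low),
                 clinical_assoc = assoc, independence = indep,
                 immune = imm, drugs = drg, ici = ici,
                 clinical = clin),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result; cascade counts:\n")
  cnt <- x$manifest$counts
  cat(paste(sprintf("  %s: %s", names(cnt), unlist(cnt)), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Run the pipeline end-to-end from files on disk
#'
#' Loads every input named in the configuration, runs [run_cascade()], and
#' writes each stage's TSV plus a `manifest.json` into `config$out_dir`.
#'
#' @param config a [run_config()] with input paths set
#' @return the `pipeline_result`, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  expr <- read_expression(config$expression, config$groups)
  clinical <- read_clinical(config$clinical)
  annotation <- read_annotation(config$annotation)
  immune_set <- read_gene_set(config$immune_genes)
  infil <- if (!is.null(config$infiltration)) read_infiltration(config$infiltration)
  drugs <- if (!is.null(config$ic50)) read_drug_response(config$ic50)
  res <- run_cascade(expr, clinical, annotation, immune_set, config,
                     infiltration = infil, drug_response = drugs)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  invisible(res)
}

#' Write all stage outputs of a pipeline result as TSV/JSON
#'
#' @param res a `pipeline_result`
#' @param out_dir output directory (created if absent)
#' @return invisibly, `out_dir`
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(res$screen$correlations, "correlations.tsv")
  wt(res$de, "differential_expression.tsv")
  write_pair_matrix(res$pair_matrix, p("pair_matrix.tsv"),
                    p("pair_frequencies.tsv"))
  wt(res$univariate$results, "univariate_cox.tsv")
  fit <- res$stepwise
  wt(data.frame(covariate = fit$covariates, beta = fit$beta, hr = fit$hr,
                ci_low = fit$ci95[, 1], ci_high = fit$ci95[, 2], p = fit$p),
     "signature_cox.tsv")
  wt(data.frame(sample_id = names(res$scores), score = res$scores,
                group = res$profile$group), "risk_table.tsv")
  for (nm in names(res$rocs)) {
    r <- res$rocs[[nm]]
    if (is.null(r)) next
    wt(data.frame(threshold = r$thresholds, sensitivity = r$sensitivity,
                  specificity = r$specificity), sprintf("roc_%s.tsv", nm))
  }
  wt(data.frame(cutoff = res$cutpoint$candidates, aic = res$cutpoint$aic),
     "cutpoint_scan.tsv")
  if (!is.null(res$clinical_assoc)) wt(res$clinical_assoc,
                                       "clinical_association.tsv")
  if (!is.null(res$independence)) {
    uni <- do.call(rbind, lapply(names(res$independence$univariate), function(cn) {
      f <- res$independence$univariate[[cn]]
      data.frame(covariate = cn, analysis = "univariate", beta = f$beta,
                 hr = f$hr, ci_low = f$ci95[, 1], ci_high = f$ci95[, 2],
                 p = f$p)
    }))
    mf <- res$independence$multivariate
    mul <- data.frame(covariate = mf$covariates, analysis = "multivariate",
                      beta = mf$beta, hr = mf$hr, ci_low = mf$ci95[, 1],
                      ci_high = mf$ci95[, 2], p = mf$p)
    wt(rbind(uni, mul), "independence_cox.tsv")
  }
  if (!is.null(res$immune)) wt(res$immune, "immune_correlation.tsv")
  if (!is.null(res$drugs)) wt(res$drugs, "drug_sensitivity.tsv")
  if (!is.null(res$ici) && nrow(res$ici)) wt(res$ici, "ici_expression.tsv")
  jsonlite::write_json(
    list(counts = res$manifest$counts, seed = res$manifest$seed,
         signature = list(pair_ids = res$signature$pair_ids,
                          betas = res$signature$betas),
         cutoff = res$cutpoint$cutoff,
         auc = lapply(res$rocs, function(r) if (is.null(r)) NA else r$auc),
         logrank_p = res$logrank$p,
         version = as.character(utils::packageVersion("lncpair"))),
    p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
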