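#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' tumor/normal groups, a latent-factor co-expression structure tying some
#' lncRNAs to immune genes, differential expression in tumors, survival
#' times whose hazard depends on planted within-sample rank-pair indicators
#' with known log-hazard-ratio coefficients, independent exponential
#' censoring with an administrative cutoff, and group-shifted
#' infiltration/IC50 tables.
#'
#' Gene ids are generated in lexicographic order (`LNC001 < LNC002 < ...`)
#' and planted pairs are stated in canonical orientation (lexicographically
#' smaller gene first), so the planted linear predictor is exactly
#' reproducible from the emitted matrix via the pairing rule.
#'
#' @param n_tumor,n_normal sample counts
#' @param n_lnc,n_immune gene counts (lncRNAs; immune protein-coding genes)
#' @param n_coexpressed lncRNAs sharing a latent factor with an immune gene
#' @param n_de differentially expressed lncRNAs (a prefix of the lncRNAs,
#'   so planted pair members are differentially expressed by construction)
#' @param de_log2fc mean tumor-vs-normal shift (log2 units) for DE lncRNAs
#' @param target_r target Pearson correlation, on the log scale, between a
#'   co-expressed lncRNA and its immune partner; the latent loading is
#'   `a = sqrt(target_r / (1 - target_r))` so that `a^2 / (a^2 + 1) = r`
#'   under unit noise
#' @param noise_sd residual standard deviation on the log2 scale
#' @param planted_pairs list of `list(a =, b =, beta =)` pair effects; `a`
#'   must sort before `b`. Default: two pairs with log hazard ratios +1/-1.
#' @param baseline_hazard exponential baseline event rate per day
#' @param censor_rate exponential censoring rate per day (0 disables)
#' @param admin_censor_time administrative follow-up cutoff in days
#'   (`Inf` disables)
#' @param stage_eta_cor correlation between the ordinal stage covariate and
#'   the true linear predictor
#' @param infil_rho attenuation (positive = infiltration decreases with
#'   risk) used for every simulated cell type by default
#' @param drug_gammas named numeric vector of per-drug signed slopes of
#'   log-IC50 on the standardized linear predictor
#' @param seed master integer seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_tumor = 100L, n_normal = 20L,
                       n_lnc = 60L, n_immune = 30L,
                       n_coexpressed = 30L, n_de = 40L,
                       de_log2fc = 2, target_r = 0.8, noise_sd = 1,
                       planted_pairs = list(
                         list(a = "LNC001", b = "LNC002", beta = 1),
                         list(a = "LNC003", b = "LNC004", beta = -1)),
                       baseline_hazard = 1e-3, censor_rate = 5e-4,
                       admin_censor_time = 3650,
                       stage_eta_cor = 0.2,
                       infil_rho = 0.4,
                       drug_gammas = c(methotrexate = -0.5, docetaxel = 0.5,
                                       cisplatin = 0, paclitaxel = 0),
                       seed = 1L) {
  for (nm in c("n_tumor", "n_normal", "n_lnc", "n_immune")) {
    check_scalar(get(nm), nm)
  }
  check_scalar(baseline_hazard, "baseline_hazard")
  check_scalar(noise_sd, "noise_sd")
  if (censor_rate < 0) lp_stop("censor_rate must be >= 0", "lncpair_config_error")
  if (target_r <= 0 || target_r >= 1) {
    lp_stop("target_r must be in (0,1)", "lncpair_config_error")
  }
  if (n_coexpressed > n_lnc || n_de > n_lnc) {
    lp_stop("n_coexpressed and n_de cannot exceed n_lnc", "lncpair_config_error")
  }
  if (n_coexpressed > n_immune) {
    lp_stop("n_coexpressed cannot exceed n_immune (one partner each)",
            "lncpair_config_error")
  }
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_lnc = as.integer(n_lnc), n_immune = as.integer(n_immune),
              n_coexpressed = as.integer(n_coexpressed),
              n_de = as.integer(n_de),
              de_log2fc = de_log2fc, target_r = target_r,
              noise_sd = noise_sd, planted_pairs = planted_pairs,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              admin_censor_time = admin_censor_time,
              stage_eta_cor = stage_eta_cor, infil_rho = infil_rho,
              drug_gammas = drug_gammas, seed = as.integer(seed))
  lnc_ids <- sim_gene_ids("LNC", cfg$n_lnc)
  de_ids <- lnc_ids[seq_len(cfg$n_de)]
  for (pp in planted_pairs) {
    if (!all(c(pp$a, pp$b) %in% de_ids)) {
      lp_stop(sprintf("planted pair (%s,%s) members must be among the DE lncRNAs",
                      pp$a, pp$b), "lncpair_config_error")
    }
    if (pp$a >= pp$b) {
      lp_stop("planted pairs must be in canonical orientation (a < b)",
              "lncpair_config_error")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(prefix, n) {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  if (prefix == "IMM") {
    # name the leading immune genes after the checkpoint genes so the
    # checkpoint-expression comparison is exercised on simulated data
    ici <- ici_genes()
    k <- min(n, length(ici))
    ids[seq_len(k)] <- ici[seq_len(k)]
  }
  ids
}

#' Simulate an expression matrix with planted co-expression and DE structure
#'
#' Log2-scale model: gene value = baseline mean + latent-factor term (for
#' co-expressed lncRNA/immune couples) + tumor DE shift (DE lncRNAs only)
#' + Gaussian noise; values are exponentiated to a non-negative FPKM-like
#' scale. Each co-expressed lncRNA `j` shares an independent standard-normal
#' latent factor with immune gene `j`, both with loading
#' `a = sqrt(r/(1-r))`, giving expected log-scale Pearson correlation
#' `a^2/(a^2+1) = r`.
#'
#' @param cfg a [sim_config()]
#' @return list with `expr` ([expression_matrix()]), `annotation`,
#'   `immune_set`, and `truth` (partial: planted co-expression/DE ids, seed)
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "expression"))
  n <- cfg$n_tumor + cfg$n_normal
  sample_ids <- sprintf("S%04d", seq_len(n))
  group <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
  lnc_ids <- sim_gene_ids("LNC", cfg$n_lnc)
  imm_ids <- sim_gene_ids("IMM", cfg$n_immune)
  a <- sqrt(cfg$target_r / (1 - cfg$target_r))

  # planted pair members share a baseline mean so their rank comparison is
  # informative (indicator frequency near 0.5); other means are spread out.
  # Baselines sit high enough that the log2(x+1) pseudocount used by the
  # screening stages is negligible against the planted effects.
  mu_lnc <- stats::runif(cfg$n_lnc, 3, 8)
  for (pp in cfg$planted_pairs) {
    shared <- stats::runif(1, 4, 7)
    mu_lnc[match(c(pp$a, pp$b), lnc_ids)] <- shared
  }
  mu_imm <- stats::runif(cfg$n_immune, 3, 8)

  z <- matrix(stats::rnorm(cfg$n_coexpressed * n), cfg$n_coexpressed, n)
  log_lnc <- matrix(stats::rnorm(cfg$n_lnc * n, sd = cfg$noise_sd),
                    cfg$n_lnc, n) + mu_lnc
  log_imm <- matrix(stats::rnorm(cfg$n_immune * n, sd = cfg$noise_sd),
                    cfg$n_immune, n) + mu_imm
  if (cfg$n_coexpressed > 0) {
    idx <- seq_len(cfg$n_coexpressed)
    log_lnc[idx, ] <- log_lnc[idx, ] + a * z
    log_imm[idx, ] <- log_imm[idx, ] + a * z
  }
  if (cfg$n_de > 0) {
    de_idx <- seq_len(cfg$n_de)
    log_lnc[de_idx, group == "tumor"] <-
      log_lnc[de_idx, group == "tumor"] + cfg$de_log2fc
  }
  vals <- 2 ^ rbind(log_lnc, log_imm)
  rownames(vals) <- c(lnc_ids, imm_ids)
  colnames(vals) <- sample_ids
  expr <- expression_matrix(vals, group)

  annotation <- data.frame(
    gene_id = c(lnc_ids, imm_ids),
    biotype = rep(c("lncRNA", "protein_coding"),
                  c(cfg$n_lnc, cfg$n_immune)),
    symbol = c(lnc_ids, imm_ids),
    stringsAsFactors = FALSE)
  truth <- list(coexpressed = lnc_ids[seq_len(cfg$n_coexpressed)],
                de = lnc_ids[seq_len(cfg$n_de)],
                immune_partner = stats::setNames(
                  imm_ids[seq_len(cfg$n_coexpressed)],
                  lnc_ids[seq_len(cfg$n_coexpressed)]),
                seed = cfg$seed)
  list(expr = expr, annotation = annotation, immune_set = imm_ids,
       truth = truth)
}

# internal: pair indicators for a named pair list, by the strict pairing rule
planted_indicators <- function(expr, pairs) {
  vapply(pairs, function(pp) {
    as.numeric(unclass(expr)[pp$a, ] > unclass(expr)[pp$b, ])
  }, numeric(ncol(expr)))
}

#' Simulate censored survival outcomes driven by planted pair indicators
#'
#' For each tumor sample the true pair indicators `C_j` are computed from
#' the emitted expression by the strict within-sample rank rule, giving the
#' linear predictor `eta = sum(beta_j * C_j)`. Event times are exponential
#' with rate `baseline_hazard * exp(eta)`; censoring is the minimum of an
#' independent exponential and the administrative cutoff. Times under one
#' day are rounded up to one day. Clinical stage is drawn mildly correlated
#' with `eta`.
#'
#' @param expr the [expression_matrix()] emitted by [simulate_expression()]
#' @param cfg the same [sim_config()]
#' @return list with `clinical` (a `clinical_table` for tumor samples) and
#'   `truth` (planted pairs/betas, per-sample eta and indicators, seed)
#' @export
simulate_survival <- function(expr, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (pp in cfg$planted_pairs) {
    if (!all(c(pp$a, pp$b) %in% rownames(expr))) {
      lp_stop("planted pair genes missing from expression matrix",
              "lncpair_config_error")
    }
  }
  set.seed(derive_seed(cfg$seed, "survival"))
  tumor <- which(sample_group(expr) == "tumor")
  te <- expr_subset(expr, samples = tumor)
  C <- planted_indicators(te, cfg$planted_pairs)      # samples x pairs
  betas <- vapply(cfg$planted_pairs, `[[`, numeric(1), "beta")
  eta <- as.numeric(C %*% betas)
  nt <- length(tumor)

  t_event <- stats::rexp(nt, rate = cfg$baseline_hazard * exp(eta))
  t_cens <- if (cfg$censor_rate > 0) stats::rexp(nt, rate = cfg$censor_rate)
            else rep(Inf, nt)
  t_cens <- pmin(t_cens, cfg$admin_censor_time)
  os_time <- pmax(pmin(t_event, t_cens), 1)
  os_event <- as.integer(t_event <= t_cens)
  if (all(os_event == 0L)) {
    warning("degenerate configuration: all samples censored")
  }

  es <- as.numeric(scale(eta))
  if (all(!is.finite(es))) es <- rep(0, nt)
  rho <- cfg$stage_eta_cor
  stage_lat <- rho * es + sqrt(max(0, 1 - rho^2)) * stats::rnorm(nt)
  stage <- cut(stage_lat, breaks = stats::quantile(stage_lat, 0:4 / 4),
               labels = c("I", "II", "III", "IV"), include.lowest = TRUE)
  t_lat <- rho * es + sqrt(max(0, 1 - rho^2)) * stats::rnorm(nt)
  t_stage <- cut(t_lat, breaks = stats::quantile(t_lat, 0:4 / 4),
                 labels = c("T1", "T2", "T3", "T4"), include.lowest = TRUE)
  n_stage <- sample(c("N0", "N1", "N2", "N3"), nt, replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.1))
  clinical <- clinical_table(data.frame(
    sample_id = colnames(te),
    os_time = os_time,
    os_event = os_event,
    age = round(stats::rnorm(nt, 60, 10)),
    gender = sample(c("male", "female"), nt, replace = TRUE),
    grade = sample(c("G1", "G2", "G3"), nt, replace = TRUE),
    stage = as.character(stage),
    t_stage = as.character(t_stage),
    n_stage = n_stage,
    m_stage = sample(c("M0", "M1"), nt, replace = TRUE, prob = c(0.95, 0.05)),
    stringsAsFactors = FALSE))
  truth <- list(
    planted_pairs = lapply(cfg$planted_pairs, function(pp) {
      list(pair_id = paste(pp$a, pp$b, sep = "|"), beta = pp$beta)
    }),
    eta = stats::setNames(eta, colnames(te)),
    indicators = stats::setNames(
      as.data.frame(C), vapply(cfg$planted_pairs, function(pp)
        paste(pp$a, pp$b, sep = "|"), character(1))),
    seed = cfg$seed)
  list(clinical = clinical, truth = truth)
}

#' Simulate immune-infiltration and drug-IC50 tables tied to risk
#'
#' Each simulated cell-type score is `-rho * scale(eta) + noise`, emulating
#' the negative association between risk and immune infiltration; each
#' drug's log-IC50 is `gamma * scale(eta) + noise` with a per-drug signed
#' slope so that both directions of drug sensitivity are representable.
#'
#' @param truth the `truth` list from [simulate_survival()] (needs `eta`)
#' @param cfg the same [sim_config()]
#' @return list with `infiltration` (long data.frame: sample_id, cell_type,
#'   method, score) and `drug_response` (sample_id, drug, ic50)
#' @export
simulate_downstream_tables <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "downstream"))
  eta <- truth$eta
  ids <- names(eta)
  n <- length(eta)
  es <- as.numeric(scale(eta))
  if (anyNA(es)) es <- rep(0, n)
  cell_types <- c("B_cell", "mast_cell", "myeloid_dendritic", "NK_cell",
                  "T_reg", "CD4_T_cell", "CD8_T_cell")
  rho <- cfg$infil_rho
  infil <- do.call(rbind, lapply(cell_types, function(ct) {
    score <- -rho * es + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    data.frame(sample_id = ids, cell_type = ct, method = "simulated",
               score = score, stringsAsFactors = FALSE)
  }))
  drugs <- names(cfg$drug_gammas)
  drug <- do.call(rbind, lapply(drugs, function(d) {
    g <- cfg$drug_gammas[[d]]
    lic50 <- g * es + sqrt(max(0, 1 - g^2)) * stats::rnorm(n)
    data.frame(sample_id = ids, drug = d, ic50 = exp(lic50),
               stringsAsFactors = FALSE)
  }))
  list(infiltration = infil, drug_response = drug)
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Convenience wrapper running [simulate_expression()],
#' [simulate_survival()] and [simulate_downstream_tables()]. When `out_dir`
#' is given, the exact TSV dialects read by the loaders are written plus a
#' `truth.json` with the planted pairs, betas and per-sample linear
#' predictor.
#'
#' @param cfg a [sim_config()]
#' @param out_dir optional output directory (created if absent)
#' @return list with `expr`, `annotation`, `immune_set`, `clinical`,
#'   `infiltration`, `drug_response`, `truth`
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  ex <- simulate_expression(cfg)
  sv <- simulate_survival(ex$expr, cfg)
  truth <- c(ex$truth, sv$truth)
  dt <- simulate_downstream_tables(sv$truth, cfg)
  out <- list(expr = ex$expr, annotation = ex$annotation,
              immune_set = ex$immune_set, clinical = sv$clinical,
              infiltration = dt$infiltration,
              drug_response = dt$drug_response, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_expression(out$expr, p("expression.tsv"), p("sample_groups.tsv"))
    write_clinical(out$clinical, p("clinical.tsv"))
    write_annotation(out$annotation, p("annotation.tsv"))
    write_gene_set(out$immune_set, p("immune_genes.txt"))
    utils::write.table(out$infiltration, p("infiltration.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(out$drug_response, p("drug_ic50.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(planted_pairs = truth$planted_pairs,
           eta = as.list(truth$eta), seed = cfg$seed),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
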