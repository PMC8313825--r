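#' Construct a pair signature
#'
#' @param pair_ids character pair ids (`"A|B"`), distinct
#' @param betas finite nonzero log-hazard-ratio coefficients, one per pair
#' @return a `pair_signature` object
#' @export
pair_signature <- function(pair_ids, betas) {
  if (anyDuplicated(pair_ids)) lp_stop("duplicated pair ids in signature",
                                       "lncpair_validation_error")
  if (length(pair_ids) != length(betas) || !all(is.finite(betas)) ||
      any(betas == 0)) {
    lp_stop("signature betas must be finite, nonzero, one per pair",
            "lncpair_validation_error")
  }
  structure(list(pair_ids = as.character(pair_ids),
                 betas = as.numeric(betas)),
            class = "pair_signature")
}

#' Extract a pair signature from a multivariate Cox fit
#' @param fit a `cox_fit` whose covariates are pair ids
#' @return a [pair_signature()]
#' @export
signature_from_fit <- function(fit) {
  pair_signature(fit$covariates, fit$beta)
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("pair_signature: %d pairs\n", length(x$pair_ids)))
  print(data.frame(pair_id = x$pair_ids, beta = x$betas))
  invisible(x)
}

#' Per-sample risk score of a pair signature
#'
#' `score_s = sum_i beta_i * C_{i,s}` over the signature's pairs. Every
#' signature pair must be present in the pair matrix; a missing pair is an
#' error, never a silent zero.
#'
#' @param pm a `pair_matrix`
#' @param sig a [pair_signature()]
#' @return named numeric vector of scores (one per sample)
#' @export
risk_score <- function(pm, sig) {
  miss <- setdiff(sig$pair_ids, rownames(pm))
  if (length(miss)) {
    lp_stop(sprintf("signature pairs absent from pair matrix: %s",
                    paste(miss, collapse = ", ")),
            "lncpair_missing_pair_error")
  }
  ind <- unclass(pm)[sig$pair_ids, , drop = FALSE]
  stats::setNames(as.numeric(crossprod(ind, sig$betas)), colnames(pm))
}

#' Time-dependent ROC curve under censoring (cumulative/dynamic, IPCW)
#'
#' Cases are subjects with an event by `t_eval`; controls are subjects
#' still under observation beyond `t_eval`. Subjects censored before
#' `t_eval` contribute through inverse-probability-of-censoring weights
#' from the product-limit estimate of the censoring distribution: a case
#' dying at `t` is weighted `1/G(t-)` and every control `1/G(t_eval)`.
#' The AUC is the trapezoidal integral of the curve swept over the observed
#' score values, which with zero censoring reduces exactly to the
#' Mann-Whitney U statistic with ties counted one half.
#'
#' @param time positive follow-up times
#' @param event 0/1 event indicator
#' @param scores per-sample risk scores (higher = riskier)
#' @param t_eval evaluation horizon in the time unit of `time`
#' @return a `timed_roc`: list with `t_eval`, `thresholds`, `sensitivity`,
#'   `specificity`, `auc`
#' @export
td_roc <- function(time, event, scores, t_eval) {
  stopifnot(length(time) == length(scores))
  is_case <- time <= t_eval & event == 1
  is_ctrl <- time > t_eval
  if (!any(is_case)) lp_stop("no events by t_eval", "lncpair_precondition_error")
  if (!any(is_ctrl)) lp_stop("no controls beyond t_eval",
                             "lncpair_precondition_error")
  km_cens <- km_estimate(time, 1 - event)
  w_case <- 1 / pmax(km_surv_at(km_cens, time[is_case], left = TRUE), 1e-12)
  g_eval <- max(km_surv_at(km_cens, t_eval), 1e-12)
  w_ctrl <- rep(1 / g_eval, sum(is_ctrl))
  sc_case <- scores[is_case]
  sc_ctrl <- scores[is_ctrl]
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(c) sum(w_case[sc_case > c]) / sum(w_case),
                 numeric(1))
  spec <- vapply(thr, function(c) sum(w_ctrl[sc_ctrl <= c]) / sum(w_ctrl),
                 numeric(1))
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
             (tpr[-length(tpr)] + tpr[-1]) / 2)
  structure(list(t_eval = t_eval, thresholds = thr, sensitivity = sens,
                 specificity = spec, auc = auc,
                 n_case = sum(is_case), n_control = sum(is_ctrl)),
            class = "timed_roc")
}

#' @export
print.timed_roc <- function(x, ...) {
  cat(sprintf("timed_roc at t=%g: AUC=%.4f (%d cases, %d controls)\n",
              x$t_eval, x$auc, x$n_case, x$n_control))
  invisible(x)
}

#' AIC-optimal risk-score cutpoint
#'
#' Candidate cutoffs are midpoints between consecutive distinct sorted
#' scores, restricted so each side keeps at least `min_group_frac` of the
#' samples (guarding against separation-prone extreme dichotomizations).
#' Each candidate's AIC is that of the single-covariate Cox fit on the
#' indicator `score > c`; the chosen cutoff minimizes AIC, with ties broken
#' toward the candidate nearest the median score.
#'
#' @param time positive follow-up times
#' @param event 0/1 event indicator
#' @param scores per-sample risk scores
#' @param t_ref reporting horizon in days carried into the result (the ROC
#'   time the scan accompanies); not used in the optimization
#' @param min_group_frac minimum fraction of samples per side (default 0.1)
#' @return a `cutpoint_scan`: `candidates`, `aic` per candidate, `cutoff`
#'   (argmin), `t_ref`
#' @export
aic_cutpoint <- function(time, event, scores, t_ref = NULL,
                         min_group_frac = 0.1) {
  us <- sort(unique(scores))
  if (length(us) < 2) lp_stop("need >= 2 distinct scores",
                              "lncpair_precondition_error")
  cand <- (us[-1] + us[-length(us)]) / 2
  n <- length(scores)
  n_high <- vapply(cand, function(c) sum(scores > c), numeric(1))
  ok <- pmin(n_high, n - n_high) >= min_group_frac * n
  cand <- cand[ok]
  if (!length(cand)) {
    lp_stop("all candidate cutoffs excluded; lower min_group_frac",
            "lncpair_precondition_error")
  }
  prep <- cox_prepare(time, event)
  aic <- vapply(cand, function(c) {
    fit <- tryCatch(cox_fit(time, event, as.numeric(scores > c), prep = prep),
                    error = function(e) NULL)
    if (is.null(fit) || !length(fit$beta)) Inf else fit$aic
  }, numeric(1))
  best <- which(aic <= min(aic) + 1e-12)
  if (length(best) > 1L) {
    med <- stats::median(scores)
    best <- best[which.min(abs(cand[best] - med))]
  }
  structure(list(candidates = cand, aic = aic, cutoff = cand[best],
                 aic_min = aic[best], t_ref = t_ref,
                 min_group_frac = min_group_frac),
            class = "cutpoint_scan")
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  cat(sprintf("cutpoint_scan: %d candidates, cutoff=%.4f (AIC=%.3f)\n",
              length(x$candidates), x$cutoff, x$aic_min))
  invisible(x)
}

#' Stratify samples into high/low risk groups
#'
#' Membership in the high-risk group requires `score > cutoff` strictly
#' (a score equal to the cutoff is low risk), consistent with the strict
#' pair-indicator rule.
#'
#' @param scores named per-sample risk scores
#' @param cutoff finite threshold
#' @return a `risk_profile`: `scores`, `cutoff`, `group` (character
#'   "high"/"low" per sample), `n_high`, `n_low`
#' @export
stratify <- function(scores, cutoff) {
  if (!is.finite(cutoff)) lp_stop("cutoff must be finite",
                                  "lncpair_precondition_error")
  grp <- ifelse(scores > cutoff, "high", "low")
  structure(list(scores = scores, cutoff = cutoff, group = grp,
                 n_high = sum(grp == "high"), n_low = sum(grp == "low")),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("risk_profile: cutoff=%.4f, %d high / %d low\n",
              x$cutoff, x$n_high, x$n_low))
  invisible(x)
}
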