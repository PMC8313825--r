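# Censored-survival numerics: product-limit estimator, log-rank test,
# Newton-Raphson Cox partial likelihood (Efron/Breslow ties), coordinate
# descent L1-penalized Cox with cross-validation, and AIC stepwise
# selection. All fitting is vectorized over event-time tie groups.

# ---- shared sorted structure ------------------------------------------------

# Sort once, reuse across many fits (univariate screens, cutpoint scans).
# Order is DECREASING in time so risk-set sums are cumulative sums.
cox_prepare <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  ord <- order(-time, event)           # deterministic within ties
  ts <- time[ord]
  ev <- as.integer(event[ord])
  n <- length(ts)
  grp <- cumsum(c(1L, diff(ts) != 0))  # tie-group id, 1 = largest time
  gend <- which(c(grp[-1L] != grp[-n], TRUE))   # last index of each group
  ngrp <- length(gend)
  d <- as.integer(rowsum(ev, grp))     # deaths per group
  egroups <- which(d > 0)
  # expansion rows (k, l), l = 0..d_k-1, used by the Efron correction
  kk <- rep(egroups, d[egroups])
  ll <- unlist(lapply(d[egroups], function(dk) seq_len(dk) - 1), use.names = FALSE)
  frac <- ll / d[kk]
  death_idx <- which(ev == 1L)
  prep <- list(ord = ord, time = ts, event = ev, n = n, grp = grp,
               gend = gend, ngrp = ngrp, d = d, egroups = egroups, kk = kk,
               frac = frac, death_idx = death_idx,
               death_grp = grp[death_idx], n_events = length(death_idx))
  prep$ll_null <- cox_deriv(prep, matrix(0, n, 0), numeric(0))$loglik
  prep
}

# log partial likelihood, score and observed information at beta, via the
# compiled tie-group routine. X must already be in prep's sorted order;
# all-zero expansion fractions give Breslow.
cox_deriv <- function(prep, X, beta, ties = "efron", want_info = TRUE) {
  frac <- if (ties == "efron") prep$frac else rep(0, length(prep$kk))
  res <- cox_deriv_cpp(X, as.numeric(beta), as.integer(prep$gend),
                       as.integer(prep$kk), as.numeric(frac),
                       as.integer(prep$death_idx),
                       as.integer(prep$death_grp), as.integer(prep$ngrp),
                       isTRUE(want_info))
  if (!is.null(res$score)) res$score <- as.numeric(res$score)
  res
}

# Newton-Raphson driver on prepared data; X in sorted order.
cox_newton <- function(prep, X, ties = "efron", max_iter = 50,
                       score_tol = 1e-9, loglik_tol = 1e-12) {
  p <- ncol(X)
  beta <- rep(0, p)
  d0 <- cox_deriv(prep, X, beta, ties)
  loglik <- d0$loglik
  converged <- FALSE
  monotone <- FALSE
  info <- d0$info
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(d0$info, d0$score), error = function(e) NULL)
    if (is.null(step)) {
      lp_stop("singular information matrix (unidentifiable covariates)",
              "lncpair_unidentifiable_error")
    }
    halve <- 0L
    repeat {
      cand <- beta + step
      dc <- cox_deriv(prep, X, cand, ties)
      if (is.finite(dc$loglik) && dc$loglik >= loglik - 1e-12) break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 30L) break
    }
    if (halve > 30L) break
    improved <- dc$loglik - loglik
    beta <- cand
    d0 <- dc
    info <- dc$info
    ll_prev <- loglik
    loglik <- dc$loglik
    if (max(abs(beta)) > 20 && improved > loglik_tol * abs(loglik)) {
      monotone <- TRUE
      break
    }
    if (max(abs(d0$score)) < score_tol ||
        abs(improved) < loglik_tol * (abs(ll_prev) + 1)) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, loglik = loglik, info = info, converged = converged,
       monotone = monotone, iter = iter)
}

# ---- Kaplan-Meier -----------------------------------------------------------

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' @param time positive follow-up times
#' @param event 0 = censored, 1 = event
#' @return a `km_curve`: data.frame-backed object with columns `time`
#'   (distinct observed times), `n_risk`, `n_event`, `n_censor`, `surv`
#'   (product-limit estimate just after `time`)
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) lp_stop("empty input", "lncpair_precondition_error")
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  ut <- unique(t_s)
  n_event <- as.numeric(rowsum(e_s, t_s)[, 1L])
  n_total <- as.numeric(rowsum(rep(1, length(t_s)), t_s)[, 1L])
  n_risk <- length(time) - c(0, cumsum(n_total)[-length(n_total)])
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_total - n_event, surv = surv),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step interpolation; `left = TRUE` gives the left limit
#' S(t-), as needed for censoring-distribution weights.
#'
#' @param km a `km_curve`
#' @param t times at which to evaluate
#' @param left evaluate the left-continuous limit
#' @return survival probabilities at `t`
#' @export
km_surv_at <- function(km, t, left = FALSE) {
  idx <- if (left) {
    vapply(t, function(ti) sum(km$time < ti), integer(1))
  } else {
    findInterval(t, km$time)
  }
  c(1, km$surv)[idx + 1L]
}

# ---- log-rank ---------------------------------------------------------------

#' Two-group log-rank test
#'
#' Observed-minus-expected deaths in group 1 summed over event times, with
#' hypergeometric variance; the statistic is chi-square with 1 df. With no
#' events at all the statistic is 0 and p = 1.
#'
#' @param time positive follow-up times
#' @param event 0/1 event indicator
#' @param group binary group label (two levels)
#' @return list with `chi2`, `p`, `observed` and `expected` (group-1 deaths)
#' @export
logrank_test <- function(time, event, group) {
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2L) {
    lp_stop("log-rank needs exactly two non-empty groups",
            "lncpair_precondition_error")
  }
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) return(list(chi2 = 0, p = 1, observed = 0, expected = 0))
  O <- E <- V <- 0
  for (t0 in dt) {
    at <- time >= t0
    nj <- sum(at)
    n1 <- sum(at & g == 1L)
    dj <- sum(event == 1 & time == t0)
    d1 <- sum(event == 1 & time == t0 & g == 1L)
    O <- O + d1
    E <- E + dj * n1 / nj
    if (nj > 1) V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  list(chi2 = chi2, p = p, observed = O, expected = E)
}

# ---- Cox fit ----------------------------------------------------------------

#' Cox proportional hazards fit by Newton-Raphson
#'
#' Maximizes the log partial likelihood with the Efron tie correction
#' (Breslow available), stopping when the largest score component falls
#' below `1e-9` or the relative log-likelihood change below `1e-12`, with
#' at most 50 iterations and step halving. Standard errors come from the
#' inverse observed information; p-values and 95% confidence intervals are
#' Wald. Monotone likelihood (perfect separation) is flagged when a
#' coefficient passes |beta| > 20 while the likelihood still improves.
#' Constant covariates are unidentifiable: they are excluded from the fit
#' and listed in `$excluded`.
#'
#' @param time positive follow-up times
#' @param event 0/1 event indicator
#' @param x covariate matrix (or vector for a single covariate)
#' @param ties `"efron"` (default) or `"breslow"`
#' @param prep optional precomputed `cox_prepare()` structure for repeated
#'   fits on the same outcomes (internal use)
#' @return a `cox_fit` object: `covariates`, `beta`, `se`, `hr`, `ci95`
#'   (matrix, columns lower/upper), `p`, `loglik`, `loglik_null`, `aic`,
#'   `ties`, `converged`, `monotone_likelihood`, `excluded`, `n`,
#'   `n_events`
#' @export
cox_fit <- function(time, event, x, ties = c("efron", "breslow"),
                    prep = NULL) {
  ties <- match.arg(ties)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                   dimnames = list(NULL, "x"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyNA(x)) lp_stop("missing covariate values", "lncpair_precondition_error")
  if (is.null(prep)) prep <- cox_prepare(time, event)
  if (prep$n <= ncol(x)) lp_stop("need n > number of covariates",
                                 "lncpair_precondition_error")
  xs <- x[prep$ord, , drop = FALSE]
  const <- apply(xs, 2, function(v) max(v) == min(v))
  excluded <- colnames(xs)[const]
  xs <- xs[, !const, drop = FALSE]
  k <- ncol(xs)
  ll_null <- if (ties == "efron") prep$ll_null else
    cox_deriv(prep, xs[, 0, drop = FALSE], numeric(0), ties)$loglik
  if (k == 0L) {
    fit <- list(beta = numeric(0), loglik = ll_null,
                info = matrix(0, 0, 0), converged = TRUE, monotone = FALSE,
                iter = 0L)
  } else {
    fit <- cox_newton(prep, xs, ties)
  }
  se <- if (k && !fit$monotone) {
    inv <- tryCatch(solve(fit$info), error = function(e) NULL)
    if (is.null(inv)) rep(NA_real_, k) else sqrt(pmax(diag(inv), 0))
  } else rep(NA_real_, k)
  zq <- stats::qnorm(0.975)
  beta <- fit$beta
  names(beta) <- colnames(xs)
  ci <- cbind(lower = exp(beta - zq * se), upper = exp(beta + zq * se))
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(covariates = colnames(xs), beta = beta, se = se,
                 hr = exp(beta), ci95 = ci, p = p,
                 loglik = fit$loglik, loglik_null = ll_null,
                 aic = 2 * k - 2 * fit$loglik, ties = ties,
                 converged = fit$converged && !fit$monotone,
                 monotone_likelihood = fit$monotone,
                 excluded = excluded, n = prep$n,
                 n_events = prep$n_events, iter = fit$iter),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties): n=%d, events=%d, loglik=%.4f, AIC=%.4f\n",
              x$ties, x$n, x$n_events, x$loglik, x$aic))
  if (length(x$beta)) {
    print(data.frame(beta = x$beta, HR = x$hr, lower = x$ci95[, 1],
                     upper = x$ci95[, 2], p = x$p))
  } else cat("  (null model)\n")
  invisible(x)
}

#' Univariate Cox screen over all pairs of a pair matrix
#'
#' One single-covariate [cox_fit()] per pair on its 0/1 indicator; pairs
#' with a Wald p below `p_max` are retained. Unidentifiable (constant
#' indicator) or non-converged fits are dropped and counted.
#'
#' @param pm a `pair_matrix`
#' @param clinical a `clinical_table`; sample ids must match `pm` columns
#' @param p_max Wald p threshold (default 0.05)
#' @return list with `results` (data.frame: pair_id, beta, hr, p over all
#'   testable pairs), `retained` (pair ids with p < p_max) and `report`
#' @export
univariate_pair_screen <- function(pm, clinical, p_max = 0.05) {
  miss <- setdiff(clinical$sample_id, colnames(pm))
  miss2 <- setdiff(colnames(pm), clinical$sample_id)
  if (length(miss) || length(miss2)) {
    lp_stop(sprintf("sample mismatch between pair matrix and clinical: %s",
                    paste(union(miss, miss2), collapse = ", ")),
            "lncpair_alignment_error")
  }
  idx <- match(clinical$sample_id, colnames(pm))
  ind <- unclass(pm)[, idx, drop = FALSE]
  prep <- cox_prepare(clinical$os_time, clinical$os_event)
  n_pairs <- nrow(ind)
  beta <- hr <- pv <- rep(NA_real_, n_pairs)
  dropped <- 0L
  for (i in seq_len(n_pairs)) {
    fit <- tryCatch(
      cox_fit(clinical$os_time, clinical$os_event, ind[i, ], prep = prep),
      error = function(e) NULL)
    if (is.null(fit) || !length(fit$beta) || !fit$converged ||
        !is.finite(fit$p[1])) {
      dropped <- dropped + 1L
      next
    }
    beta[i] <- fit$beta[1]
    hr[i] <- fit$hr[1]
    pv[i] <- fit$p[1]
  }
  res <- data.frame(pair_id = rownames(ind), beta = beta, hr = hr, p = pv,
                    stringsAsFactors = FALSE)
  retained <- res$pair_id[!is.na(res$p) & res$p < p_max]
  list(results = res, retained = retained,
       report = c(tested = n_pairs, dropped = dropped,
                  retained = length(retained)))
}

# ---- L1-penalized Cox -------------------------------------------------------

# Breslow per-sample gradient / diagonal Hessian of the log partial
# likelihood with respect to the linear predictor, on prepared data.
cox_eta_deriv <- function(prep, eta) {
  cc <- max(eta)
  w <- exp(eta - cc)
  S0 <- cumsum(w)[prep$gend]
  a <- b <- rep(0, prep$ngrp)
  a[prep$egroups] <- prep$d[prep$egroups] / S0[prep$egroups]
  b[prep$egroups] <- prep$d[prep$egroups] / S0[prep$egroups]^2
  A <- rev(cumsum(rev(a)))[prep$grp]
  B <- rev(cumsum(rev(b)))[prep$grp]
  g <- prep$event - w * A
  h <- pmax(w * A - w^2 * B, 1e-10)
  loglik <- sum(eta[prep$death_idx]) -
    sum(prep$d[prep$egroups] * (log(S0[prep$egroups]) + cc))
  list(g = g, h = h, loglik = loglik)
}

# Penalized fit at one lambda by outer quadratic approximation + inner
# coordinate descent (compiled weighted-least-squares kernel, active-set
# with KKT screening), warm-started at beta0. X standardized, in prep's
# sorted order. Objective: -(1/n) l + lambda * |beta|_1. After the outer
# loop converges, extra rounds run until the exact KKT conditions of the
# partial likelihood are satisfied.
lasso_cox_single <- function(prep, X, lambda, beta0,
                             outer_tol = 1e-4, max_outer = 20L) {
  n <- prep$n
  beta <- beta0
  eta <- as.numeric(X %*% beta)
  obj_prev <- Inf
  for (it in seq_len(max_outer)) {
    dv <- cox_eta_deriv(prep, eta)
    obj <- -dv$loglik / n + lambda * sum(abs(beta))
    if (it > 1L) {
      # stationarity of the exact partial likelihood: the subgradient
      # condition must hold tightly on zero coordinates; the nonzero
      # coordinates are controlled through the coefficient-change and
      # objective-change criteria at the accuracy the path is reported at
      score <- as.numeric(crossprod(X, dv$g))
      viol0 <- if (any(beta == 0)) {
        max(0, max(abs(score[beta == 0])) - lambda * n)
      } else 0
      if ((viol0 <= 1e-9 * n && delta < outer_tol) ||
          abs(obj_prev - obj) < 1e-9 * (abs(obj) + 1)) break
    }
    obj_prev <- obj
    wt <- dv$h
    z <- eta + dv$g / wt
    newbeta <- cd_wls(X, wt, z, beta, lambda, 1e-10, 20L)
    delta <- max(abs(newbeta - beta))
    beta <- newbeta
    eta <- as.numeric(X %*% beta)
  }
  beta
}

# full path on prepared data via the compiled solver; returns std-scale
# coefficients
lasso_cox_path <- function(prep, Xs, lambdas) {
  lasso_path_cox(Xs, as.integer(prep$event), as.integer(prep$grp),
                 as.integer(prep$gend), as.integer(prep$d),
                 as.integer(prep$egroups), as.integer(prep$death_idx),
                 as.numeric(lambdas), 1e-4, 20L, 1e-9, 20L)
}

#' LASSO-penalized Cox regression with cross-validation
#'
#' Coordinate-descent optimization of the L1-penalized Cox partial
#' likelihood (Breslow ties) over a log-spaced 100-point lambda grid from
#' `lambda_max` (the smallest lambda with an all-zero solution, computed
#' from the null-model score) down to `lambda_min_ratio * lambda_max`.
#' Covariates are standardized internally; coefficients are reported on the
#' original scale. K-fold cross-validation (folds stratified by event
#' status) scores each lambda by partial-likelihood deviance
#' `-2 * (l_all(beta_fold) - l_train(beta_fold))`; both the deviance
#' minimizer `lambda_min` and the one-standard-error rule `lambda_1se` are
#' recorded, and covariate selection uses `lambda_min` by default.
#'
#' @param time positive follow-up times
#' @param event 0/1 event indicator
#' @param x covariate matrix (samples x covariates)
#' @param n_folds number of CV folds (default 10)
#' @param seed integer seed for the fold assignment (mandatory)
#' @param nlambda grid size (default 100)
#' @param lambda_min_ratio smallest grid lambda as a fraction of
#'   `lambda_max` (default 0.01)
#' @param lambda optional explicit lambda sequence overriding the grid
#' @param lambda_rule `"lambda_min"` (default) or `"lambda_1se"`
#' @return a `lasso_cox_fit`: `lambda` (grid), `beta` (covariates x
#'   lambdas, original scale), `cvm`, `cvse`, `lambda_min`, `lambda_1se`,
#'   `selected` (covariate names nonzero at the chosen lambda), `seed`
#' @export
lasso_cox <- function(time, event, x, n_folds = 10L, seed,
                      nlambda = 100L, lambda_min_ratio = 0.01,
                      lambda = NULL, lambda_rule = c("lambda_min", "lambda_1se")) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(time)
  if (n < n_folds) lp_stop("need n >= n_folds", "lncpair_precondition_error")
  if (sum(event) < n_folds) {
    lp_stop("fewer events than folds; lower n_folds", "lncpair_precondition_error")
  }
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  keep <- scl > 0
  if (!any(keep)) lp_stop("all covariates constant", "lncpair_precondition_error")
  Xs_all <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2,
                  scl[keep], "/")
  prep <- cox_prepare(time, event)
  Xs <- Xs_all[prep$ord, , drop = FALSE]
  g0 <- cox_eta_deriv(prep, numeric(n))$g
  lambda_max <- max(abs(crossprod(Xs, g0))) / n
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_min_ratio * lambda_max),
                      length.out = nlambda))
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
  }
  betas_std <- lasso_cox_path(prep, Xs, lambda)

  # stratified CV folds
  set.seed(seed)
  fold <- integer(n)
  for (e in c(0, 1)) {
    idx <- which(event == e)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  dev <- matrix(NA_real_, n_folds, length(lambda))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    prep_tr <- cox_prepare(time[tr], event[tr])
    Xtr <- Xs_all[tr, , drop = FALSE][prep_tr$ord, , drop = FALSE]
    bpath <- lasso_cox_path(prep_tr, Xtr, lambda)
    for (i in seq_along(lambda)) {
      eta_all <- as.numeric(Xs_all %*% bpath[, i])
      ll_all <- cox_eta_deriv(prep, eta_all[prep$ord])$loglik
      ll_tr <- cox_eta_deriv(prep_tr,
                             eta_all[tr][prep_tr$ord])$loglik
      dev[f, i] <- -2 * (ll_all - ll_tr)
    }
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, stats::sd) / sqrt(n_folds)
  imin <- which.min(cvm)
  i1se <- which(cvm <= cvm[imin] + cvse[imin])[1L]  # largest lambda within 1 SE
  beta_orig <- matrix(0, ncol(x), length(lambda),
                      dimnames = list(colnames(x), NULL))
  beta_orig[keep, ] <- betas_std / scl[keep]
  chosen <- if (lambda_rule == "lambda_min") imin else i1se
  selected <- colnames(x)[beta_orig[, chosen] != 0]
  structure(list(lambda = lambda, beta = beta_orig, cvm = cvm, cvse = cvse,
                 lambda_min = lambda[imin], lambda_1se = lambda[i1se],
                 lambda_rule = lambda_rule, selected = selected,
                 seed = seed, n_folds = n_folds,
                 scale = scl, center = ctr),
            class = "lasso_cox_fit")
}

#' @export
print.lasso_cox_fit <- function(x, ...) {
  cat(sprintf(
    "lasso_cox_fit: %d covariates, %d lambdas; lambda_min=%.4g, lambda_1se=%.4g, %d selected (%s)\n",
    nrow(x$beta), length(x$lambda), x$lambda_min, x$lambda_1se,
    length(x$selected), x$lambda_rule))
  invisible(x)
}

# ---- stepwise ---------------------------------------------------------------

#' Forward stepwise Cox selection by AIC with backward refinement
#'
#' Starts from the empty model; at each step adds the candidate whose
#' inclusion most decreases AIC, then attempts single-covariate removals
#' that decrease AIC, stopping when no move improves. Candidates whose fit
#' is unidentifiable or fails to converge are skipped at that step.
#'
#' @param time positive follow-up times
#' @param event 0/1 event indicator
#' @param x_candidates covariate matrix of candidates
#' @param ties tie handling for the underlying [cox_fit()]
#' @return the multivariate `cox_fit` on the selected set; when no
#'   candidate lowers AIC below the null model, the null fit is returned
#'   with an empty covariate set and `$null_model = TRUE`
#' @export
stepwise_cox <- function(time, event, x_candidates, ties = "efron") {
  x_candidates <- as.matrix(x_candidates)
  if (is.null(colnames(x_candidates))) {
    colnames(x_candidates) <- paste0("x", seq_len(ncol(x_candidates)))
  }
  if (!ncol(x_candidates)) lp_stop("need >= 1 candidate",
                                   "lncpair_precondition_error")
  prep <- cox_prepare(time, event)
  fit_aic <- function(cols) {
    if (!length(cols)) {
      return(list(aic = -2 * prep$ll_null, fit = NULL))
    }
    fit <- tryCatch(cox_fit(time, event, x_candidates[, cols, drop = FALSE],
                            ties = ties, prep = prep),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        length(fit$beta) < length(cols)) {
      return(list(aic = Inf, fit = NULL))
    }
    list(aic = fit$aic, fit = fit)
  }
  current <- character(0)
  cur <- fit_aic(current)
  all_cols <- colnames(x_candidates)
  repeat {
    moved <- FALSE
    # forward step
    pool <- setdiff(all_cols, current)
    if (length(pool)) {
      trials <- lapply(pool, function(cn) fit_aic(c(current, cn)))
      aics <- vapply(trials, `[[`, numeric(1), "aic")
      if (min(aics) < cur$aic - 1e-8) {
        best <- which.min(aics)
        current <- c(current, pool[best])
        cur <- trials[[best]]
        moved <- TRUE
      }
    }
    # backward refinement
    if (length(current) > 1L) {
      repeat {
        drops <- lapply(current, function(cn) fit_aic(setdiff(current, cn)))
        aics <- vapply(drops, `[[`, numeric(1), "aic")
        if (min(aics) < cur$aic - 1e-8) {
          worst <- which.min(aics)
          current <- setdiff(current, current[worst])
          cur <- drops[[worst]]
          moved <- TRUE
        } else break
      }
    }
    if (!moved) break
  }
  if (!length(current)) {
    ll0 <- prep$ll_null
    out <- structure(list(covariates = character(0), beta = numeric(0),
                          se = numeric(0), hr = numeric(0),
                          ci95 = matrix(numeric(0), 0, 2), p = numeric(0),
                          loglik = ll0, loglik_null = ll0, aic = -2 * ll0,
                          ties = ties, converged = TRUE,
                          monotone_likelihood = FALSE,
                          excluded = character(0), n = prep$n,
                          n_events = prep$n_events, null_model = TRUE),
                     class = "cox_fit")
    return(out)
  }
  fit <- cur$fit
  fit$null_model <- FALSE
  fit
}
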