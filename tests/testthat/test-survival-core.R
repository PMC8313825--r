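test_that("Kaplan-Meier matches a hand-computed toy", {
  # times 1,1,2,2+,3 with events 1,1,1,0,1:
  # S(1) = 1 - 2/5 = 3/5; S(2) = 3/5 * (1 - 1/3) = 2/5; S(3) = 2/5 * 0 = 0
  km <- km_estimate(c(1, 1, 2, 2, 3), c(1, 1, 1, 0, 1))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$n_risk, c(5, 3, 1))
  expect_equal(km$n_event, c(2, 1, 1))
  expect_equal(km$surv, c(3 / 5, 2 / 5, 0))
  expect_equal(km_surv_at(km, c(0.5, 1, 2.5, 10)), c(1, 3 / 5, 2 / 5, 0))
  # left limit at an event time takes the value just before it
  expect_equal(km_surv_at(km, 2, left = TRUE), 3 / 5)
  expect_equal(km_surv_at(km, 2, left = FALSE), 2 / 5)
})

test_that("log-rank matches hand computation and survdiff", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  group <- c("a", "b", "a", "b", "a", "b")
  lr <- logrank_test(time, event, group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-10)
  expect_equal(lr$p, 1 - pchisq(sd$chisq, 1), tolerance = 1e-12)
  expect_equal(lr$observed, unname(sd$obs[1]))
  expect_equal(lr$expected, unname(sd$exp[1]), tolerance = 1e-10)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50
    s <- rand_surv(n, seed = seed)
    g <- sample(c("x", "y"), n, replace = TRUE)
    lr <- logrank_test(s$time, s$event, g)
    sd <- survival::survdiff(survival::Surv(s$time, s$event) ~ g)
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-8)
  }
  # degenerate: no events at all
  expect_equal(logrank_test(c(1, 2), c(0, 0), c("a", "b"))$p, 1)
})

test_that("cox_fit agrees with coxph for both tie methods", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 40
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
    time <- round(rexp(n, exp(0.02 * (x[, 1] + x[, 2]))) * 20) + 1  # ties
    event <- rbinom(n, 1, 0.7)
    for (ties in c("efron", "breslow")) {
      fit <- cox_fit(time, event, x, ties = ties)
      ref <- survival::coxph(survival::Surv(time, event) ~ x,
                             ties = ties)
      expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                   tolerance = 1e-6)
      expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
      expect_equal(fit$aic, stats::AIC(ref), tolerance = 1e-6)
    }
  }
})

test_that("cox_fit handles constant covariates and separation", {
  s <- rand_surv(30, seed = 3)
  x <- cbind(flat = rep(1, 30), ok = rnorm(30))
  fit <- cox_fit(s$time, s$event, x)
  expect_identical(fit$excluded, "flat")
  expect_identical(names(fit$beta), "ok")
  # perfectly separating covariate triggers the monotone-likelihood flag
  time <- c(1:10, 11:20)
  event <- rep(1, 20)
  sep <- c(rep(1, 10), rep(0, 10))
  fit2 <- cox_fit(time, event, sep)
  expect_true(fit2$monotone_likelihood)
})

test_that("univariate pair screen keeps only significant pairs", {
  set.seed(10)
  n <- 120
  good <- rbinom(n, 1, 0.5)
  noise <- replicate(5, rbinom(n, 1, 0.5))
  time <- rexp(n, 1e-3 * exp(1.5 * good)) + 1
  event <- rbinom(n, 1, 0.8)
  raw <- rbind("A|B" = good,
               matrix(t(noise), 5, n,
                      dimnames = list(sprintf("N%d|M%d", 1:5, 1:5), NULL)))
  colnames(raw) <- sprintf("S%03d", seq_len(n))
  pm <- pair_matrix(raw)
  cl <- clinical_table(data.frame(sample_id = colnames(pm),
                                  os_time = time, os_event = event))
  res <- univariate_pair_screen(pm, cl, p_max = 0.05)
  expect_true("A|B" %in% res$retained)
  ref <- survival::coxph(survival::Surv(time, event) ~ good)
  row <- res$results[res$results$pair_id == "A|B", ]
  expect_equal(row$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(res$report["tested"]), 6)
  cl_bad <- clinical_table(data.frame(sample_id = c(colnames(pm)[-1], "zz"),
                                      os_time = time, os_event = event))
  expect_error(univariate_pair_screen(pm, cl_bad),
               class = "lncpair_alignment_error")
})

test_that("lasso path honours its contracts and matches glmnet", {
  set.seed(77)
  n <- 80
  p <- 10
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  eta <- x[, 1] - 0.8 * x[, 2]
  time <- rexp(n, 1e-3 * exp(eta)) + 1
  event <- rbinom(n, 1, 0.75)
  fit <- lasso_cox(time, event, x, seed = 1L)
  # all-zero solution at lambda_max
  expect_true(all(fit$beta[, 1] == 0))
  expect_true(any(fit$beta[, ncol(fit$beta)] != 0))
  expect_equal(fit$lambda[1] / fit$lambda[length(fit$lambda)], 100,
               tolerance = 1e-8)
  gl <- glmnet::glmnet(x, survival::Surv(time, event), family = "cox",
                       lambda = fit$lambda, standardize = TRUE,
                       thresh = 1e-12)
  expect_lt(max(abs(fit$beta - as.matrix(gl$beta))), 1e-3)
  # the true covariates are selected at lambda_min with the right signs
  expect_true(all(c("v1", "v2") %in% fit$selected))
  b_min <- fit$beta[, which(fit$lambda == fit$lambda_min)]
  expect_gt(b_min["v1"], 0)
  expect_lt(b_min["v2"], 0)
})

test_that("lasso cross-validation folds are seed-deterministic", {
  set.seed(5)
  n <- 60
  x <- matrix(rnorm(n * 4), n, 4)
  time <- rexp(n, 1e-3) + 1
  event <- rbinom(n, 1, 0.6)
  f1 <- lasso_cox(time, event, x, seed = 9L)
  f2 <- lasso_cox(time, event, x, seed = 9L)
  expect_identical(f1$cvm, f2$cvm)
  expect_identical(f1$lambda_min, f2$lambda_min)
  expect_error(lasso_cox(time[1:5], event[1:5], x[1:5, ], seed = 1L),
               class = "lncpair_precondition_error")
  expect_error(lasso_cox(time, rep(c(1, 0), c(3, n - 3)), x, seed = 1L),
               class = "lncpair_precondition_error")
})

test_that("stepwise selection recovers true covariates by AIC", {
  set.seed(42)
  n <- 200
  x <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
              dimnames = list(NULL, paste0("c", 1:6)))
  eta <- 1.2 * x[, 1] - 1.2 * x[, 2]
  time <- rexp(n, 1e-3 * exp(eta)) + 1
  event <- rbinom(n, 1, 0.85)
  fit <- stepwise_cox(time, event, x)
  expect_true(all(c("c1", "c2") %in% fit$covariates))
  # the final model's AIC beats dropping either true covariate
  for (drop in c("c1", "c2")) {
    alt <- cox_fit(time, event, x[, setdiff(fit$covariates, drop),
                                  drop = FALSE])
    expect_lt(fit$aic, alt$aic)
  }
  # pure-noise candidates yield the null model
  xn <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
  time_n <- rexp(n, 1e-3) + 1
  fitn <- stepwise_cox(time_n, event, xn)
  if (isTRUE(fitn$null_model)) {
    expect_length(fitn$covariates, 0)
  } else {
    expect_lte(length(fitn$covariates), 1)
  }
})
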