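toy_profile <- function(n = 40, seed = 1) {
  set.seed(seed)
  scores <- setNames(rnorm(n), sprintf("P%03d", seq_len(n)))
  stratify(scores, cutoff = median(scores))
}

toy_clin <- function(profile, seed = 2) {
  set.seed(seed)
  n <- length(profile$scores)
  clinical_table(data.frame(
    sample_id = names(profile$scores),
    os_time = rexp(n, 1e-3) + 1,
    os_event = rbinom(n, 1, 0.7),
    age = round(rnorm(n, 60, 8)),
    gender = sample(c("male", "female"), n, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

test_that("clinical association reproduces the base-R tests exactly", {
  prof <- toy_profile()
  cl <- toy_clin(prof)
  res <- clinical_association(prof, cl)
  # chi-squared without continuity correction on the 2 x k table
  tab <- table(prof$group, cl$gender[match(names(prof$scores),
                                           cl$sample_id)])
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  row <- res[res$feature == "gender" & res$test == "chi_squared", ]
  expect_equal(row$statistic, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(row$p, ct$p.value, tolerance = 1e-12)
  # closed form for a 2x2: n (ad - bc)^2 / (row/col margins product)
  a <- tab[1, 1]; b <- tab[1, 2]; c0 <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  chi_closed <- n * (a * d - b * c0)^2 /
    ((a + b) * (c0 + d) * (a + c0) * (b + d))
  expect_equal(row$statistic, unname(chi_closed), tolerance = 1e-10)
  # Kruskal-Wallis of score across the 4 stages
  kw <- kruskal.test(prof$scores, factor(cl$stage))
  rk <- res[res$feature == "stage" & res$test == "kruskal_wallis", ]
  expect_equal(rk$statistic, unname(kw$statistic), tolerance = 1e-12)
  expect_equal(rk$p, kw$p.value, tolerance = 1e-12)
  expect_identical(res$significant, res$p < 0.05)
})

test_that("association results are invariant to clinical row order", {
  prof <- toy_profile()
  cl <- toy_clin(prof)
  res1 <- clinical_association(prof, cl)
  cl2 <- clinical_table(as.data.frame(cl)[sample(nrow(cl)), ])
  res2 <- clinical_association(prof, cl2)
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-12)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
})

test_that("rank-based downstream tests ignore monotone score transforms", {
  prof <- toy_profile(seed = 4)
  cl <- toy_clin(prof, seed = 5)
  set.seed(6)
  inf <- data.frame(sample_id = rep(names(prof$scores), 2),
                    cell_type = rep(c("CD8_T_cell", "NK_cell"),
                                    each = length(prof$scores)),
                    method = "sim",
                    score = rnorm(2 * length(prof$scores)))
  r1 <- immune_correlation(prof, inf)
  prof2 <- prof
  prof2$scores <- exp(prof$scores / 2)   # strictly increasing transform
  prof2$cutoff <- exp(prof$cutoff / 2)
  r2 <- immune_correlation(prof2, inf)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("immune correlation recovers a planted negative association", {
  prof <- toy_profile(n = 60, seed = 7)
  # perfectly anti-monotone infiltration: Spearman rho must be exactly -1
  inf <- data.frame(sample_id = names(prof$scores),
                    cell_type = "CD8_T_cell", method = "sim",
                    score = -rank(prof$scores))
  res <- immune_correlation(prof, inf)
  sp <- res[res$test == "spearman", ]
  expect_equal(sp$statistic, -1, tolerance = 1e-12)
  expect_identical(sp$direction, "negative")
  expect_true(sp$significant)
  # constant columns are skipped and counted
  inf2 <- rbind(inf, data.frame(sample_id = names(prof$scores),
                                cell_type = "flat", method = "sim",
                                score = 1))
  res2 <- immune_correlation(prof, inf2)
  expect_equal(unname(attr(res2, "report")["skipped_constant"]), 1L)
  expect_false("flat/sim" %in% res2$feature)
  expect_error(immune_correlation(prof, inf[1:2, ]),
               class = "lncpair_precondition_error")
})

test_that("group expression compare matches wilcox.test and flags missing", {
  prof <- toy_profile(n = 30, seed = 9)
  set.seed(10)
  vals <- matrix(rexp(3 * 30) * 10, 3, 30,
                 dimnames = list(c("CTLA4", "PDCD1", "OTHER"),
                                 names(prof$scores)))
  x <- expression_matrix(vals, rep("tumor", 30))
  res <- group_expression_compare(x, prof, genes = c("CTLA4", "PDCD1",
                                                     "LAG3"))
  expect_setequal(res$feature, c("CTLA4", "PDCD1"))
  expect_identical(attr(res, "missing_genes"), "LAG3")
  v <- log2(vals["CTLA4", ] + 1)
  wt <- suppressWarnings(wilcox.test(v[prof$group == "high"],
                                     v[prof$group == "low"]))
  expect_equal(res$p[res$feature == "CTLA4"], wt$p.value, tolerance = 1e-12)
  # empty gene list is not fatal
  res0 <- group_expression_compare(x, prof, genes = character(0))
  expect_equal(nrow(res0), 0L)
})

test_that("drug sensitivity picks up opposite planted directions", {
  set.seed(12)
  n <- 80
  scores <- setNames(rnorm(n), sprintf("P%03d", seq_len(n)))
  prof <- stratify(scores, median(scores))
  es <- as.numeric(scale(scores))
  drugs <- rbind(
    data.frame(sample_id = names(scores), drug = "sens",
               ic50 = exp(-1.2 * es + rnorm(n, sd = 0.2))),
    data.frame(sample_id = names(scores), drug = "res",
               ic50 = exp(1.2 * es + rnorm(n, sd = 0.2))),
    data.frame(sample_id = names(scores)[1], drug = "sparse", ic50 = 1))
  res <- drug_sensitivity_compare(prof, drugs)
  expect_identical(res$direction[res$feature == "sens"], "lower in high")
  expect_identical(res$direction[res$feature == "res"], "higher in high")
  expect_true(all(res$significant[res$feature %in% c("sens", "res")]))
  expect_equal(unname(attr(res, "report")["skipped_drugs"]), 1L)
})

test_that("independence Cox agrees with coxph and drops collinear columns", {
  set.seed(13)
  n <- 150
  scores <- setNames(rnorm(n), sprintf("P%03d", seq_len(n)))
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE)
  stage_num <- c(I = 1, II = 2, III = 3, IV = 4)[stage]
  age <- round(rnorm(n, 60, 9))
  eta <- 0.8 * scores + 0.4 * stage_num
  time <- rexp(n, 1e-3 * exp(eta)) + 1
  event <- rbinom(n, 1, 0.8)
  cl <- clinical_table(data.frame(
    sample_id = names(scores), os_time = time, os_event = event,
    age = age, stage = stage, stringsAsFactors = FALSE))
  res <- independence_cox(scores, cl)
  expect_setequal(names(res$univariate), c("risk_score", "age", "stage"))
  ref_uni <- survival::coxph(survival::Surv(time, event) ~ scores)
  expect_equal(unname(res$univariate$risk_score$beta),
               unname(coef(ref_uni)), tolerance = 1e-6)
  ref_multi <- survival::coxph(
    survival::Surv(time, event) ~ scores + age + stage_num)
  expect_equal(unname(res$multivariate$beta[c("risk_score", "age", "stage")]),
               unname(coef(ref_multi)), tolerance = 1e-6)
  # the score stays significant after adjustment
  expect_lt(res$multivariate$p["risk_score"], 0.05)
  # a duplicated covariate is dropped with a warning
  cl2 <- clinical_table(data.frame(
    sample_id = names(scores), os_time = time, os_event = event,
    age = age, age_copy = age, stringsAsFactors = FALSE))
  expect_warning(res2 <- independence_cox(scores, cl2), "collinear")
  expect_false("age_copy" %in% res2$multivariate$covariates)
})

test_that("missing clinical values are dropped casewise and reported", {
  prof <- toy_profile(n = 50, seed = 14)
  cl <- toy_clin(prof, seed = 15)
  cl$age[1:5] <- NA
  res <- independence_cox(prof$scores, cl)
  expect_equal(unname(res$report["n_dropped_missing"]), 5)
  expect_equal(res$multivariate$n, 45)
})
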