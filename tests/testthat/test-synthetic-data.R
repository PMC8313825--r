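test_that("sim_config validates its arguments", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_tumor = 0), class = "lncpair_config_error")
  expect_error(sim_config(target_r = 1), class = "lncpair_config_error")
  expect_error(sim_config(n_coexpressed = 40, n_immune = 30),
               class = "lncpair_config_error")
  expect_error(sim_config(n_de = 100, n_lnc = 60),
               class = "lncpair_config_error")
})

test_that("simulation is deterministic in the seed", {
  d1 <- simulate_dataset(sim_config(seed = 11L))
  d2 <- simulate_dataset(sim_config(seed = 11L))
  d3 <- simulate_dataset(sim_config(seed = 12L))
  expect_identical(unclass(d1$expr), unclass(d2$expr))
  expect_identical(d1$clinical$os_time, d2$clinical$os_time)
  expect_identical(d1$infiltration$score, d2$infiltration$score)
  expect_false(identical(unclass(d1$expr), unclass(d3$expr)))
  expect_false(identical(d1$clinical$os_time, d3$clinical$os_time))
})

test_that("planted truth is consistent with the package pairing rule", {
  d <- simulate_dataset(sim_config(seed = 3L))
  tumor <- expr_subset(d$expr, samples = sample_group(d$expr) == "tumor")
  pm <- build_pair_matrix(tumor)
  betas <- vapply(d$truth$planted_pairs, `[[`, numeric(1), "beta")
  ids <- vapply(d$truth$planted_pairs, `[[`, character(1), "pair_id")
  sig <- pair_signature(ids, betas)
  sc <- risk_score(pm, sig)
  expect_equal(unname(sc[names(d$truth$eta)]), unname(d$truth$eta))
  # indicators recorded in the truth match the pair matrix rows
  for (id in ids) {
    expect_equal(unname(unclass(pm)[id, names(d$truth$eta)]),
                 d$truth$indicators[[id]])
  }
})

test_that("censoring controls behave as configured", {
  cfg <- sim_config(seed = 8L, censor_rate = 0, admin_censor_time = Inf)
  d <- simulate_dataset(cfg)
  expect_true(all(d$clinical$os_event == 1L))
  cfg2 <- sim_config(seed = 8L, baseline_hazard = 1e-9, censor_rate = 0,
                     admin_censor_time = 100)
  expect_warning(d2 <- simulate_dataset(cfg2), "censored")
  expect_true(all(d2$clinical$os_event == 0L))
  expect_true(all(d2$clinical$os_time <= 100))
})

test_that("written dataset files round-trip through the loaders", {
  dir <- tempfile("simds")
  cfg <- sim_config(seed = 21L, n_tumor = 40L, n_normal = 10L)
  d <- simulate_dataset(cfg, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "expression.tsv", "sample_groups.tsv", "clinical.tsv", "annotation.tsv",
    "immune_genes.txt", "infiltration.tsv", "drug_ic50.tsv", "truth.json")))))
  ex <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "sample_groups.tsv"))
  want <- unclass(d$expr)
  attr(want, "sample_group") <- NULL
  expect_equal(unclass(ex)[rownames(d$expr), ], want, tolerance = 1e-8)
  expect_identical(sample_group(ex), sample_group(d$expr))
  cl <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(cl$os_time, d$clinical$os_time, tolerance = 1e-8)
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_setequal(ann$gene_id[ann$biotype == "lncRNA"],
                  rownames(d$expr)[seq_len(cfg$n_lnc)])
  imm <- read_gene_set(file.path(dir, "immune_genes.txt"))
  expect_identical(imm, d$immune_set)
  inf <- read_infiltration(file.path(dir, "infiltration.tsv"))
  expect_equal(nrow(inf), nrow(d$infiltration))
  dr <- read_drug_response(file.path(dir, "drug_ic50.tsv"))
  expect_equal(nrow(dr), nrow(d$drug_response))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$planted_pairs), 2L)
  expect_equal(truth$planted_pairs[[1]]$beta, 1)
})

test_that("default configuration plants recoverable structure", {
  d <- simulate_dataset(sim_config(seed = 2L))
  expect_equal(dim(d$expr), c(90L, 120L))
  expect_equal(sum(sample_group(d$expr) == "tumor"), 100L)
  # checkpoint genes are present among the immune genes
  expect_true(all(ici_genes() %in% rownames(d$expr)))
  # a planted co-expressed couple really is strongly correlated
  lx <- log2(unclass(d$expr)["LNC001", ] + 1)
  ix <- log2(unclass(d$expr)[d$truth$immune_partner[["LNC001"]], ] + 1)
  expect_gt(cor(lx, ix), 0.5)
  # planted DE lncRNAs are shifted up in tumor
  tum <- sample_group(d$expr) == "tumor"
  de1 <- log2(unclass(d$expr)[d$truth$de[1], ] + 1)
  expect_gt(mean(de1[tum]) - mean(de1[!tum]), 1)
  # both event and censored outcomes occur
  expect_true(any(d$clinical$os_event == 1) && any(d$clinical$os_event == 0))
})
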