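make_expr <- function() {
  set.seed(5)
  v <- matrix(round(runif(24, 0, 50), 3), 6, 4,
              dimnames = list(sprintf("G%02d", 1:6), sprintf("S%d", 1:4)))
  expression_matrix(v, c("tumor", "tumor", "tumor", "normal"))
}

test_that("expression_matrix validates its inputs", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  storage.mode(v) <- "double"
  expect_s3_class(expression_matrix(v, c("tumor", "normal")), "expr_matrix")
  expect_error(expression_matrix(v, c("tumor", "bad")),
               class = "lncpair_validation_error")
  expect_error(expression_matrix(v, "tumor"),
               class = "lncpair_validation_error")
  v2 <- v; v2[1, 1] <- -1
  expect_error(expression_matrix(v2, c("tumor", "normal")),
               class = "lncpair_validation_error")
  v3 <- v; rownames(v3) <- c("a", "a")
  expect_error(expression_matrix(v3, c("tumor", "normal")),
               class = "lncpair_validation_error")
})

test_that("expression round-trips through TSV with groups", {
  x <- make_expr()
  path <- tempfile(fileext = ".tsv")
  gpath <- tempfile(fileext = ".tsv")
  write_expression(x, path, gpath)
  y <- read_expression(path, gpath)
  expect_equal(unclass(y), unclass(x), tolerance = 0)
  expect_identical(sample_group(y), sample_group(x))
})

test_that("read_expression strips versions and collapses duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2",
               "ENSG1.4\t1\t2",
               "ENSG1.7\t10\t20",
               "ENSG2\t5\t6"), path)
  x <- read_expression(path)
  expect_identical(sort(rownames(x)), c("ENSG1", "ENSG2"))
  # the higher-mean duplicate wins
  expect_equal(as.numeric(unclass(x)["ENSG1", ]), c(10, 20))
})

test_that("read_expression names the offending cell on parse errors", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "G1\t1\toops", "G2\t3\t4"), path)
  err <- tryCatch(read_expression(path), error = identity)
  expect_s3_class(err, "lncpair_parse_error")
  expect_match(conditionMessage(err), "G1")
  expect_match(conditionMessage(err), "S2")
})

test_that("clinical cleaning removes non-positive follow-up and duplicates", {
  df <- data.frame(sample_id = c("a", "b", "b", "c", "d"),
                   os_time = c(100, 50, 60, 0, -3),
                   os_event = c(1, 0, 1, 1, 0),
                   stage = c("I", "II", "II", "III", "IV"))
  cl <- clinical_table(df)
  expect_identical(cl$sample_id, c("a", "b"))
  rep <- cleaning_report(cl)
  expect_equal(unname(rep["removed_zero_followup"]), 2)
  expect_equal(unname(rep["removed_duplicate"]), 1)
  # cleaning is idempotent
  cl2 <- clinical_table(as.data.frame(cl))
  for (col in names(cl)) expect_equal(cl2[[col]], cl[[col]])
  expect_equal(sum(cleaning_report(cl2)), 0)
})

test_that("clinical validation rejects bad events and missing columns", {
  expect_error(clinical_table(data.frame(sample_id = "a", os_time = 1,
                                         os_event = 2)),
               class = "lncpair_validation_error")
  expect_error(clinical_table(data.frame(sample_id = "a", os_time = 1)),
               class = "lncpair_schema_error")
})

test_that("annotation reads TSV and GTF identically", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tsymbol",
               "ENSG1.2\tlncRNA\tAL1",
               "ENSG2\tprotein_coding\tTP53"), tsv)
  a1 <- read_annotation(tsv)
  expect_identical(a1$gene_id, c("ENSG1", "ENSG2"))

  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "#!genome-build test",
    paste("1", "src", "gene", "1", "100", ".", "+", ".",
          'gene_id "ENSG1.2"; gene_biotype "lncRNA"; gene_name "AL1";',
          sep = "\t"),
    paste("1", "src", "transcript", "1", "100", ".", "+", ".",
          'gene_id "ENSG1.2"; gene_biotype "lncRNA";', sep = "\t"),
    paste("1", "src", "gene", "200", "300", ".", "-", ".",
          'gene_id "ENSG2"; gene_biotype "protein_coding"; gene_name "TP53";',
          sep = "\t")), gtf)
  a2 <- read_annotation(gtf)
  expect_equal(a2, a1)
})

test_that("gene sets skip comments and strip versions", {
  path <- tempfile()
  writeLines(c("# immune panel", "CTLA4", "ENSG5.9", "", "CTLA4"), path)
  expect_identical(read_gene_set(path), c("CTLA4", "ENSG5"))
  empty <- tempfile()
  writeLines("# only a comment", empty)
  expect_error(read_gene_set(empty), class = "lncpair_validation_error")
})

test_that("subset_lncrnas keeps only annotated lncRNA biotypes", {
  x <- make_expr()
  ann <- data.frame(gene_id = rownames(x),
                    biotype = c("lncRNA", "protein_coding", "lincRNA",
                                "antisense", "miRNA", "protein_coding"),
                    symbol = rownames(x))
  sub <- subset_lncrnas(x, ann)
  expect_setequal(rownames(sub), c("G01", "G03", "G04"))
  ann2 <- ann
  ann2$biotype <- "protein_coding"
  expect_error(subset_lncrnas(x, ann2),
               class = "lncpair_empty_result_error")
})
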