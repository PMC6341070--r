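test_that("expression matrix ingest preserves values, shape and order", {
  m <- toy_matrix(3, 4)
  co <- read_expression_matrix(write_expr_tsv(m))
  expect_identical(dim(co$values), c(3L, 4L))
  expect_identical(co$features, rownames(m))
  expect_identical(co$samples, colnames(m))
  expect_equal(co$values, m)
})

test_that("log2_offset transform applies log2(x + 0.001) and rejects negatives", {
  m <- matrix(c(0, 1, 7, 3), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  co <- read_expression_matrix(write_expr_tsv(m), transform = "log2_offset")
  expect_equal(co$values["a", "s1"], log2(0.001))
  expect_equal(co$values["a", "s1"], -9.966, tolerance = 1e-4)
  expect_equal(co$values, log2(m + 0.001))
  m[1, 1] <- -2
  expect_error(read_expression_matrix(write_expr_tsv(m), transform = "log2_offset"),
               class = "coex_domain_error")
})

test_that("malformed expression files are rejected with informative errors", {
  m <- toy_matrix()
  dup <- write_expr_tsv(m)
  txt <- readLines(dup)
  txt[1] <- "feature_id\ts1\ts2\ts2\ts4"   # repeated sample id
  writeLines(txt, dup)
  expect_error(read_expression_matrix(dup), class = "coex_format_error")

  rownames(m)[2] <- "g1"                    # repeated feature id
  expect_error(read_expression_matrix(write_expr_tsv(m)),
               class = "coex_format_error")

  m <- toy_matrix()
  bad <- write_expr_tsv(m)
  txt <- readLines(bad)
  txt[2] <- sub("\t[0-9.]+$", "\tnot_a_number", txt[2])
  writeLines(txt, bad)
  err <- expect_error(read_expression_matrix(bad), class = "coex_format_error")
  expect_match(conditionMessage(err), "g1")
  expect_match(conditionMessage(err), "s4")
})

test_that("features exceeding the missingness ceiling are dropped, others kept", {
  m <- toy_matrix(4, 10)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  df[1, 2:4] <- NA      # g1: 30% missing -> dropped
  df[2, 2] <- NA        # g2: 10% missing -> kept with NA
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(co <- read_expression_matrix(path), "dropping 1 feature")
  expect_false("g1" %in% co$features)
  expect_true("g2" %in% co$features)
  expect_identical(sum(is.na(co$values["g2", ])), 1L)
})

test_that("gzip-compressed inputs read identically to plain TSV", {
  m <- toy_matrix()
  plain <- write_expr_tsv(m)
  gz <- paste0(tempfile(), ".tsv.gz")
  con <- gzfile(gz, "w"); writeLines(readLines(plain), con); close(con)
  expect_equal(read_expression_matrix(gz)$values,
               read_expression_matrix(plain)$values)
})

test_that("sample metadata is keyed by sample_id and row-order invariant", {
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   tissue = c("tumor", "normal", ""),
                   pair_id = c("p1", "p1", NA),
                   extra = c("x", "y", "z"))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  md <- read_sample_metadata(path)
  expect_true(is.na(md$tissue[md$sample_id == "s3"]))   # empty -> NA
  expect_identical(md$extra, c("x", "y", "z"))          # unknown col kept

  write.table(df[c(3, 1, 2), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  md2 <- read_sample_metadata(path)
  expect_identical(md[order(md$sample_id), ],
                   `rownames<-`(md2[order(md2$sample_id), ], NULL),
                   ignore_attr = TRUE)

  write.table(rbind(df, df[1, ]), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  expect_error(read_sample_metadata(path), class = "coex_format_error")
})

test_that("survival reader validates time and event coding", {
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = c("s1", "s2", "s3"),
                         time = c(100, 250, 0), event = c("1", "0", "true")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- read_survival(path)
  expect_identical(recs$event, c(TRUE, FALSE, TRUE))
  expect_identical(recs$time[3], 0)            # time 0 is a valid boundary

  write.table(data.frame(sample_id = "s1", time = -5, event = 1),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_survival(path), class = "coex_domain_error")

  write.table(data.frame(sample_id = "s1", time = 5, event = "maybe"),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_survival(path), class = "coex_format_error")
})

test_that("association tables round-trip through TSV to 1e-9 relative", {
  co <- corr_cohort(n = 60, n_corr = 2, n_null = 2)
  tb <- associate_all(co, "SEED")
  path <- tempfile(fileext = ".tsv")
  write_association_table(tb, path)
  back <- read_association_table(path)
  expect_identical(back$seed_id, "SEED")
  for (col in c("coefficient", "se", "p_value", "r2", "adjusted_r2"))
    expect_equal(back$results[[col]], tb$results[[col]], tolerance = 1e-9)
  expect_identical(back$results$n, tb$results$n)
  expect_identical(back$results$direction, tb$results$direction)

  empty <- tb; empty$results <- tb$results[0, ]
  expect_error(write_association_table(empty, tempfile()),
               class = "coex_domain_error")
})

test_that("expression write/ingest round trip preserves values", {
  co <- corr_cohort(n = 25, n_corr = 2, n_null = 2)
  path <- write_expr_tsv(signif(co$values, 12))
  back <- read_expression_matrix(path, cohort_id = co$cohort_id)
  expect_equal(back$values, co$values, tolerance = 1e-9)
})

test_that("probe maps allow many probes per gene but not the reverse", {
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(feature_id = c("p1", "p2", "p3"),
                         gene = c("NCOA1", "NCOA1", "RBL2"),
                         tf = c("TRUE", "TRUE", "FALSE")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- read_probe_map(path)
  expect_identical(map_genes(c("p1", "p2", "unmapped"), pm),
                   c("NCOA1", "NCOA1", "unmapped"))
  expect_identical(pm$tf, c(TRUE, TRUE, FALSE))

  write.table(data.frame(feature_id = c("p1", "p1"), gene = c("A", "B")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_probe_map(path), class = "coex_format_error")
})
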