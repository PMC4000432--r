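test_that("long CSV reading drops missing values listwise per variable", {
  path <- write_temp_csv(data.frame(
    center = c("A", "A", "A", "B", "B", "B"),
    preterm = c(1, 0, 1, 0, 0, 1),
    weight = c(2500, 3100, NA, 2800, 2950, 3300)))
  ds <- read_long_csv(path, cluster_col = "center")
  expect_named(ds, c("preterm", "weight"))
  expect_equal(ds$preterm$N, 6)
  expect_equal(ds$weight$N, 5)
  expect_equal(ds$preterm$var_type, "binary")   # auto: values within {0,1}
  expect_equal(ds$weight$var_type, "continuous")
  # type_map overrides auto-classification
  ds2 <- read_long_csv(path, cluster_col = "center", outcome_cols = "preterm",
                       type_map = c(preterm = "continuous"))
  expect_equal(ds2$preterm$var_type, "continuous")
})

test_that("reading validates columns and degenerate cluster structure", {
  path <- write_temp_csv(data.frame(center = c("A", "A"), y = c(1, 2)))
  expect_error(read_long_csv(path, cluster_col = "nope"),
               class = "clustericc_input_error")
  expect_error(read_long_csv(path, cluster_col = "center", outcome_cols = "z"),
               class = "clustericc_input_error")
  # only one cluster left -> degenerate, and the message names the column
  expect_error(read_long_csv(path, cluster_col = "center"),
               regexp = "'y'", class = "clustericc_degenerate_error")
  # one cluster loses all its values for one outcome only
  path2 <- write_temp_csv(data.frame(center = c("A", "A", "B", "B"),
                                     y = c(1, 2, NA, NA),
                                     z = c(1, 2, 3, 4)))
  expect_error(read_long_csv(path2, cluster_col = "center", outcome_cols = "y"),
               class = "clustericc_degenerate_error")
  expect_equal(read_long_csv(path2, cluster_col = "center", outcome_cols = "z")$z$N, 4)
  path3 <- write_temp_csv(data.frame(center = c("A", "B"), y = c("x", "1")))
  expect_error(read_long_csv(path3, cluster_col = "center"),
               class = "clustericc_input_error")
})

test_that("cluster_dataset enforces its invariants", {
  expect_error(cluster_dataset(c(1, NA), c("A", "B")),
               class = "clustericc_input_error")
  expect_error(cluster_dataset(c(1, 2), c("A", "")),
               class = "clustericc_input_error")
  expect_error(cluster_dataset(c(0, 2), c("A", "B"), type = "binary"),
               class = "clustericc_input_error")
  expect_error(cluster_dataset(1:3, rep("A", 3)),
               class = "clustericc_degenerate_error")
  d <- cluster_dataset(c(0, 1, 1, 0), c("A", "A", "B", "B"))
  expect_equal(d$a, 2)
  expect_equal(sum(d$n_i), d$N)
})

test_that("the bundled EMIP transcription has the printed structure", {
  emip <- load_emip_fixture()
  expect_s3_class(emip, "icc_table")
  expect_identical(attr(emip, "provenance"), "fixture")
  expect_equal(nrow(emip), 261)
  counts <- table(emip$table_id)
  expect_equal(counts[["T3"]], 12)
  expect_equal(counts[["T9"]], 18)
  skin <- subset(emip, variable == "Skin color (white)")
  expect_equal(skin$icc, 0.145)
  expect_equal(skin$deff, 42.2)
  expect_equal(skin$n_a, 265)
  cens <- subset(emip, variable == "Previous preterm birth of multiples")
  expect_true(cens$censored)
  expect_equal(cens$icc, 0)
  # variable names unique within each table
  expect_equal(anyDuplicated(paste(emip$table_id, emip$variable)), 0)
})

test_that("results CSV round-trips at the rendered precision", {
  emip <- load_emip_fixture()
  path <- tempfile(fileext = ".csv")
  write_results_csv(emip, path)
  back <- read_results_csv(path)
  expect_equal(nrow(back), nrow(emip))
  expect_equal(back$variable, emip$variable)
  expect_equal(back$icc, emip$icc)
  expect_equal(back$ci_low, emip$ci_low)
  expect_equal(back$ci_high, emip$ci_high)
  expect_equal(back$deff, emip$deff)
  expect_equal(back$estimate, emip$estimate)
  expect_equal(back$n_a, emip$n_a)
  expect_equal(back$censored, emip$censored)
})

test_that("ICC values below 0.001 render as '<0.001'", {
  tab <- icc_table(data.frame(
    table_id = "T1", variable = c("tiny", "small"), var_type = "binary",
    estimate = c(1, 2), icc = c(0.0004, 0.002), ci_low = c(0.0004, 0.001),
    ci_high = c(0.01, 0.02), deff = c(1.1, 1.2), n_a = c(100, 100),
    censored = FALSE))
  path <- tempfile(fileext = ".csv")
  write_results_csv(tab, path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(raw$icc, c("<0.001", "0.002"))
  expect_identical(raw$ci_low, c("<0.001", "0.001"))
  back <- read_results_csv(path)
  expect_equal(back$icc, c(0, 0.002))
  expect_true(back$censored[1])
})

test_that("writing rejects empty tables and unwritable paths", {
  emip <- load_emip_fixture()
  expect_error(write_results_csv(emip[0, ], path = tempfile()),
               class = "clustericc_input_error")
  expect_error(write_results_csv(emip, file.path(tempfile(), "x", "y.csv")),
               class = "clustericc_io_error")
})

test_that("icc_table rejects duplicated variables within a table id", {
  df <- as.data.frame(load_emip_fixture())[c(1, 1), ]
  expect_error(icc_table(df), class = "clustericc_input_error")
  # same variable name in different tables is allowed
  df2 <- as.data.frame(load_emip_fixture())[c(1, 30), ]  # a T1 and a T2 row
  df2$variable <- "same"
  expect_s3_class(icc_table(df2), "icc_table")
})
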