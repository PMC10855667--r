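write_pairs_csv <- function(rows, path) {
  writeLines(c("id,suggestion,ground_truth,human_1,human_2,human_3", rows), path)
  path
}

test_that("well-formed CSV loads with one record per row", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairs_csv(c("p1,fever noted,fever observed,0.8,0.9,0.7",
                    "p2,calm night,quiet night,0.6,0.5,0.6",
                    "p3,ate lunch,meal refused,0.1,0.2,0.2"), path)
  ds <- load_dataset(path)
  expect_equal(ds$n, 3L)
  expect_equal(ds$records[[1]]$id, "p1")
  expect_equal(ds$records[[2]]$human_scores, c(0.6, 0.5, 0.6))
})

test_that("malformed rows are dropped with their line numbers reported", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairs_csv(c("p1,fever noted,fever observed,0.8,0.9,0.7",
                    "p2,calm night,,0.6,0.5,0.6",
                    "p3,ate lunch,meal refused,bad,0.2,0.2"), path)
  expect_warning(ds <- load_dataset(path), "line\\(s\\): 3, 4")
  expect_equal(ds$n, 1L)
})

test_that("schema violations raise classed errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("suggestion,human", "a,0.5"), path)
  expect_error(load_dataset(path), class = "embedhdp_schema_error")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("suggestion,ground_truth,human_1"), path2)
  expect_error(load_dataset(path2), class = "embedhdp_empty_dataset")
})

test_that("tsv extension switches the separator", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("suggestion\tground_truth\thuman", "a b\tc d\t0.4"), path)
  ds <- load_dataset(path)
  expect_equal(ds$records[[1]]$suggestion, "a b")
})

test_that("human aggregation supports mean and median", {
  expect_equal(aggregate_human(c(2, 4, 6)), 4)
  expect_equal(aggregate_human(5), 5)
  expect_equal(aggregate_human(c(1, 2, 4), method = "median"), 2)
  expect_error(aggregate_human(numeric(0)), class = "embedhdp_invalid_input")
})

test_that("pearson_r matches hand values and the direct formula", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8, tolerance = 1e-12)
  # brute-force covariance formula as independent oracle
  direct_r <- function(x, y) {
    n <- length(x)
    sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
    sxy / sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
  }
  set.seed(44)
  for (i in 1:30) {
    x <- rnorm(sample(3:40, 1)); y <- rnorm(length(x))
    expect_equal(pearson_r(x, y), direct_r(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_r(c(1, 2), c(1, 2)), class = "embedhdp_invalid_input")
  expect_error(pearson_r(1:3, 1:4), class = "embedhdp_invalid_input")
  expect_error(pearson_r(c(1, 1, 1), 1:3),
               class = "embedhdp_undefined_correlation")
})

test_that("a metric reproducing the human score correlates perfectly", {
  sd <- generate_dataset(synth_params(n_pairs = 30, frac_over_limit = 0.2, seed = 5))
  oracle <- function(pair, cfg, backend) aggregate_human(pair$human_scores)
  attr(oracle, "metric_name") <- "oracle"
  rep <- run_benchmark(sd$dataset, list(oracle), fast_cfg(), stub300())
  expect_equal(rep$per_metric$oracle$r, 1, tolerance = 1e-12)
  expect_equal(rep$n_kept + rep$n_removed, rep$n_input)
  expect_equal(rep$per_metric$oracle$n_used, rep$n_kept)
})

test_that("a constant metric degrades gracefully without aborting the panel", {
  sd <- generate_dataset(synth_params(n_pairs = 20, frac_over_limit = 0, seed = 6))
  const <- function(pair, cfg, backend) 0.5
  attr(const, "metric_name") <- "const"
  oracle <- function(pair, cfg, backend) aggregate_human(pair$human_scores)
  attr(oracle, "metric_name") <- "oracle"
  rep <- run_benchmark(sd$dataset, list(const, oracle), fast_cfg(), stub300())
  expect_true(is.na(rep$per_metric$const$r))
  expect_match(rep$per_metric$const$errors, "zero variance")
  expect_equal(rep$per_metric$oracle$r, 1, tolerance = 1e-12)
})

test_that("benchmark reports are byte-stable across runs", {
  sd <- generate_dataset(synth_params(n_pairs = 12, frac_over_limit = 0, seed = 8))
  r1 <- run_benchmark(sd$dataset, c("cosine", "rouge1"), fast_cfg(), stub300())
  r2 <- run_benchmark(sd$dataset, c("cosine", "rouge1"), fast_cfg(), stub300())
  expect_identical(r1, r2)
  md <- report_markdown(r1)
  expect_match(md[1], "Correlation coefficient")
  expect_length(md, 2 + 2)
})

test_that("unknown metric names are rejected", {
  sd <- generate_dataset(synth_params(n_pairs = 5, frac_over_limit = 0, seed = 9))
  expect_error(run_benchmark(sd$dataset, "nope", fast_cfg(), stub300()),
               class = "embedhdp_config_error")
})
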