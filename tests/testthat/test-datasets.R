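test_that("loader round-trips a toy cohort and honours orientation", {
  expr <- matrix(seq_len(20) / 2, nrow = 5,
                 dimnames = list(NULL, sprintf("g%d", 1:4)))
  paths <- write_toy_cohort(expr, sample_ids = sprintf("s%d", 1:5),
                            gene_ids = sprintf("g%d", 1:4),
                            time = c(1, 2, 3, 4, 5), event = c(1, 0, 1, 0, 1))
  ds <- load_expression_dataset(paths$expr, paths$clinical, name = "toy")
  expect_equal(n_samples(ds), 5)
  expect_equal(n_genes(ds), 4)
  expect_equal(unname(ds$expression), unname(expr))
  expect_equal(ds$gene_ids, sprintf("g%d", 1:4))
  expect_equal(ds$time, 1:5 + 0)
  # round-trip through the writer in both orientations
  d <- withr::local_tempdir()
  write_expression_dataset(ds, file.path(d, "e.tsv"), file.path(d, "c.tsv"))
  ds2 <- load_expression_dataset(file.path(d, "e.tsv"), file.path(d, "c.tsv"))
  expect_equal(unname(ds2$expression), unname(ds$expression))
  write_expression_dataset(ds, file.path(d, "e2.tsv"), file.path(d, "c2.tsv"),
                           genes_in_rows = FALSE)
  ds3 <- load_expression_dataset(file.path(d, "e2.tsv"),
                                 file.path(d, "c2.tsv"),
                                 genes_in_rows = FALSE)
  expect_equal(unname(ds3$expression), unname(ds$expression))
})

test_that("loader keeps only samples present in both files", {
  expr <- matrix(rnorm(20), nrow = 5)
  paths <- write_toy_cohort(expr, sample_ids = sprintf("s%d", 1:5),
                            gene_ids = sprintf("g%d", 1:4),
                            time = 1:5, event = rep(1, 5))
  clin <- read.delim(paths$clinical)
  write.table(clin[clin$sample_id %in% c("s1", "s3", "s5"), ],
              paths$clinical, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- load_expression_dataset(paths$expr, paths$clinical)
  expect_equal(n_samples(ds), 3)
})

test_that("genes above the missing-rate threshold are dropped, the rest imputed", {
  expr <- matrix(rnorm(20), nrow = 5)
  expr[1:3, 2] <- NA       # gene 2: 60% missing -> dropped at threshold 50%
  expr[1, 3] <- NA         # gene 3: 20% missing -> median-imputed
  paths <- write_toy_cohort(expr, sample_ids = sprintf("s%d", 1:5),
                            gene_ids = sprintf("g%d", 1:4),
                            time = 1:5, event = rep(1, 5))
  expect_message(
    ds <- load_expression_dataset(paths$expr, paths$clinical,
                                  missing_drop_threshold = 0.5),
    "dropping 1 gene")
  expect_equal(n_genes(ds), 3)
  expect_false("g2" %in% ds$gene_ids)
  expect_equal(ds$expression[1, "g3"], median(expr[2:5, 3]))
})

test_that("loader errors are specific: format, empty join, bad times", {
  expr <- matrix(rnorm(20), nrow = 5)
  paths <- write_toy_cohort(expr, sample_ids = sprintf("s%d", 1:5),
                            gene_ids = sprintf("g%d", 1:4),
                            time = 1:5, event = rep(1, 5))
  clin <- read.delim(paths$clinical)
  d <- withr::local_tempdir()

  no_time <- file.path(d, "no_time.tsv")
  write.table(clin[, c("sample_id", "event")], no_time, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_expression_dataset(paths$expr, no_time),
               class = "sigceiling_format_error")

  renamed <- file.path(d, "renamed.tsv")
  clin2 <- clin
  clin2$sample_id <- paste0("x", clin2$sample_id)
  write.table(clin2, renamed, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression_dataset(paths$expr, renamed),
               class = "sigceiling_empty_join_error")

  bad_time <- file.path(d, "bad_time.tsv")
  clin3 <- clin
  clin3$time[2] <- -1
  write.table(clin3, bad_time, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression_dataset(paths$expr, bad_time), "s2",
               class = "sigceiling_validation_error")
})

test_that("cohort filter keeps ER-positive, under-70, chemotherapy-free samples", {
  expr <- matrix(rnorm(24), nrow = 6)
  ds <- expression_dataset(
    expr, time = rep(5, 6), event = rep(1, 6), name = "six",
    gene_ids = sprintf("g%d", 1:4),
    clinical = data.frame(
      er_status = c("positive", "positive", "positive", "negative",
                    "positive", "positive"),
      age = c(50, 71, 69, 50, 50, 50),
      chemotherapy = c("no", "no", "no", "no", "yes", NA)))
  rownames(ds$expression) <- sprintf("s%d", 1:6)
  expect_message(f <- filter_cohort(ds), "retained")
  expect_equal(n_samples(f), 2)
  expect_equal(rownames(f$expression), c("s1", "s3"))
})

test_that("cohort filter is a no-op when all samples qualify and warns when none do", {
  expr <- matrix(rnorm(12), nrow = 3)
  ok <- data.frame(er_status = rep("positive", 3), age = c(40, 50, 60),
                   chemotherapy = rep("no", 3))
  ds <- expression_dataset(expr, time = 1:3, event = c(1, 1, 0),
                           clinical = ok)
  expect_message(f <- filter_cohort(ds))
  expect_equal(f$expression, ds$expression)

  old <- ds
  old$clinical$age <- c(70, 80, 90)
  expect_warning(expect_message(f2 <- filter_cohort(old)),
                 "removed every sample")
  expect_equal(n_samples(f2), 0)

  bare <- expression_dataset(expr, time = 1:3, event = c(1, 1, 0))
  expect_error(filter_cohort(bare),
               class = "sigceiling_configuration_error")
})

test_that("synthetic generator is bit-reproducible given seed", {
  cfg <- synthetic_config(n_samples = 50, n_genes = 30, seed = 9)
  a <- generate_synthetic_dataset(cfg)
  b <- generate_synthetic_dataset(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$time, b$time)
  expect_identical(a$event, b$event)
  c <- generate_synthetic_dataset(synthetic_config(n_samples = 50,
                                                   n_genes = 30, seed = 10))
  expect_false(identical(a$expression, c$expression))
})

test_that("realized event rate tracks the censoring target", {
  for (target in c(0.3, 0.7)) {
    ds <- generate_synthetic_dataset(
      synthetic_config(n_samples = 400, n_genes = 5,
                       censor_rate_target = target, seed = 21))
    expect_lt(abs(event_rate(ds) - (1 - target)), 0.1)
  }
  ds0 <- generate_synthetic_dataset(
    synthetic_config(n_samples = 100, n_genes = 5, censor_rate_target = 0,
                     seed = 21))
  expect_equal(event_rate(ds0), 1)
})

test_that("oracle C of the latent factor is non-decreasing in the hazard coefficient", {
  cs <- vapply(c(0.5, 1, 2, 4), function(b) {
    ds <- generate_synthetic_dataset(
      synthetic_config(n_samples = 400, n_genes = 5, hazard_coef = b,
                       seed = 31))
    oracle_c(attr(ds, "latent_factor"), ds$time, ds$event)
  }, numeric(1))
  expect_false(is.unsorted(cs))
})

test_that("a no-signal generator yields chance-level prognosis", {
  ds <- generate_synthetic_dataset(
    synthetic_config(n_samples = 400, n_genes = 40, hazard_coef = 0,
                     seed = 41))
  sets <- sample_random_gene_sets(ds, set_size = 20, n_sets = 5, seed = 1)
  meds <- vapply(seq_along(sets), function(i) {
    evaluate_signature(ds, sets[[i]], survival_model_spec("coxph", seed = i),
                       seed = i)$median_c
  }, numeric(1))
  expect_lt(abs(mean(meds) - 0.5), 0.05)
})

test_that("weibull shape changes the time distribution but keeps the median anchor", {
  cfg <- synthetic_config(n_samples = 2000, n_genes = 2, hazard_coef = 0,
                          censor_rate_target = 0, weibull_shape = 2,
                          baseline_median_time = 10, seed = 5)
  ds <- generate_synthetic_dataset(cfg)
  expect_lt(abs(median(ds$time) - 10), 0.7)
})
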