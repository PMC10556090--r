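test_that("fivefold evaluation is seeded, stratified, and honours the gene-set contract", {
  ds <- generate_synthetic_dataset(
    synthetic_config(n_samples = 150, n_genes = 40, seed = 12))
  gs <- sample_random_gene_sets(ds, n_sets = 1, seed = 2)[[1]]
  spec <- survival_model_spec("coxph", seed = 4)
  r1 <- evaluate_signature(ds, gs, spec, seed = 9)
  r2 <- evaluate_signature(ds, gs, spec, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$median_c,
               median(unlist(r1[paste0("fold", 1:5)])))
  r3 <- evaluate_signature(ds, gs, spec, seed = 10)
  expect_false(identical(unlist(r1[paste0("fold", 1:5)]),
                         unlist(r3[paste0("fold", 1:5)])))

  alien <- gene_set("alien", c("NOPE1", "NOPE2"), origin = "reported")
  expect_error(evaluate_signature(ds, alien, spec), "NOPE1",
               class = "sigceiling_contract_error")

  # event-stratified folds spread events evenly
  folds <- sigceiling:::stratified_folds(ds$event, 5, seed = 1)
  per_fold_events <- tapply(ds$event, folds, sum)
  expect_lte(diff(range(per_fold_events)), 1)
})

test_that("the oracle latent-factor signature scores high; a random-score stub sits at chance", {
  ds <- generate_synthetic_dataset(
    synthetic_config(n_samples = 400, n_genes = 30, factor_fraction = 0.3,
                     hazard_coef = 2, censor_rate_target = 0.5, seed = 33))
  # inject the true latent factor as a pseudo-gene
  z <- attr(ds, "latent_factor")
  ds_oracle <- expression_dataset(cbind(ds$expression, ORACLE_Z = z),
                                  time = ds$time, event = ds$event,
                                  name = ds$name)
  oracle_set <- gene_set("oracle", "ORACLE_Z", origin = "ml",
                         method = "oracle")
  res <- evaluate_signature(ds_oracle, oracle_set,
                            survival_model_spec("coxph", seed = 1), seed = 1)
  expect_gt(res$median_c, 0.8)

  stub <- evaluate_signature(ds, sample_random_gene_sets(ds, n_sets = 1,
                                                         seed = 3)[[1]],
                             survival_model_spec("stub_random", seed = 1),
                             seed = 1)
  expect_lt(abs(stub$median_c - 0.5), 0.05)
})

test_that("small grids enumerate the exact cartesian product", {
  datasets <- lapply(1:1, function(i) generate_synthetic_dataset(
    synthetic_config(n_samples = 100, n_genes = 30, seed = i)))
  plan <- grid_plan(n_random = 2, random_size = 5,
                    ml_methods = character(0))
  res <- run_grid(datasets, plan, model_ids = c("coxph", "ridge", "stree"),
                  seed = 1, progress = FALSE)
  expect_equal(nrow(res), 1 * 2 * 3)
  expect_true(all(res$median_c >= 0 & res$median_c <= 1, na.rm = TRUE))
  # rerun is bit-identical
  res2 <- run_grid(datasets, plan, model_ids = c("coxph", "ridge", "stree"),
                   seed = 1, progress = FALSE)
  expect_identical(res, res2)
})

test_that("summary statistics match hand-computed MOM/MAD/MAX", {
  res <- data.frame(dataset = "d1", model_id = "coxph",
                    median_c = c(0.6, 0.6, 0.6))
  s <- summarize_grid(res)
  expect_equal(s[, c("mom", "mad", "max_c")],
               data.frame(mom = 0.6, mad = 0, max_c = 0.6))

  res2 <- data.frame(dataset = "d1", model_id = "rsf",
                     median_c = c(0.5, 0.6, 0.8))
  s2 <- summarize_grid(res2)
  expect_equal(s2$mom, 0.6)
  expect_equal(s2$mad, 0.1)
  expect_equal(s2$max_c, 0.8)
  expect_equal(s2$n_signatures, 3)
  expect_true(all(s2$mom <= s2$max_c))

  expect_error(summarize_grid(res[0, ]),
               class = "sigceiling_validation_error")
})

test_that("cohort correlations: perfect line, null shuffles, degenerate input", {
  info <- data.frame(dataset = sprintf("d%d", 1:6),
                     n_patients = c(100, 200, 300, 400, 500, 600),
                     event_rate = rep(0.3, 6))
  stats <- data.frame(dataset = info$dataset, model_id = "coxph",
                      mom = 0.5 + 0.0002 * info$n_patients,
                      mad = rep(0.02, 6))
  out <- correlate_with_cohort(stats, info)
  line <- out[out$statistic == "mom" & out$covariate == "n_patients" &
                out$method == "pearson", ]
  expect_equal(line$estimate, 1.0)

  # shuffled MOM across >= 20 synthetic cohorts: mostly non-significant
  withr::with_seed(99, {
    info2 <- data.frame(dataset = sprintf("d%02d", 1:20),
                        n_patients = sample(100:2000, 20),
                        event_rate = runif(20, 0.1, 0.5))
    pvals <- replicate(50, {
      st <- data.frame(dataset = info2$dataset, model_id = "coxph",
                       mom = sample(runif(20, 0.55, 0.7)),
                       mad = runif(20, 0.01, 0.05))
      o <- correlate_with_cohort(st, info2)
      o$p_value[o$statistic == "mom" & o$covariate == "n_patients" &
                  o$method == "pearson"]
    })
  })
  expect_gte(mean(pvals > 0.05), 0.9)

  expect_error(correlate_with_cohort(stats[1:2, ], info[1:2, ]),
               class = "sigceiling_undefined_result")
})

test_that("random-signature-superiority prevalence uses strict inequality", {
  mk <- function(med, origin = "random", gs = "r") {
    data.frame(dataset = "d1", gene_set = gs, origin = origin,
               method = origin, model_id = "coxph", median_c = med)
  }
  ref <- mk(0.7, origin = "reported", gs = "ref26")

  all_below <- do.call(rbind, lapply(seq(0.4, 0.6, length.out = 10), mk))
  expect_equal(rss_prevalence(all_below, ref)$overall, 0)

  meds <- c(rep(0.75, 44), rep(0.65, 56))
  mixed <- do.call(rbind, Map(mk, meds, gs = sprintf("r%03d", 1:100)))
  out <- rss_prevalence(mixed, ref)
  expect_equal(out$per_group$frac_above, 0.44)
  expect_equal(out$per_group$n_random, 100)

  ties <- do.call(rbind, lapply(rep(0.7, 10), mk))
  expect_equal(rss_prevalence(ties, ref)$overall, 0)
})

test_that("ceiling curve: hand counts, step behaviour, monotone fraction", {
  cc <- ceiling_curve(c(0.5, 0.6, 0.7), thresholds = c(0.55, 0.65, 0.75))
  expect_equal(cc$curve$fraction_above, c(2 / 3, 1 / 3, 0))
  expect_equal(cc$zero_threshold, 0.75)

  flat <- ceiling_curve(rep(0.62, 50), thresholds = seq(0.5, 0.9, 0.01))
  expect_true(all(flat$curve$fraction_above[flat$curve$threshold < 0.62] == 1))
  expect_true(all(flat$curve$fraction_above[flat$curve$threshold >= 0.62] == 0))

  withr::with_seed(4, meds <- runif(500, 0.45, 0.85))
  cc2 <- ceiling_curve(meds)
  expect_false(is.unsorted(-cc2$curve$fraction_above))
  # shifting all medians up cannot lower the ceiling estimate
  cc3 <- ceiling_curve(meds + 0.03)
  expect_gte(cc3$ceiling_estimate, cc2$ceiling_estimate)

  expect_error(ceiling_curve(numeric(0)),
               class = "sigceiling_validation_error")
  expect_error(ceiling_curve(meds, thresholds = c(0.7, 0.6)),
               class = "sigceiling_validation_error")
})

test_that("rank-sum utility and writers round-trip", {
  withr::with_seed(5, {
    a <- runif(30, 0.5, 0.7)
    b <- runif(30, 0.6, 0.8)
  })
  out <- rank_sum_compare(a, b)
  expect_lt(out$p_value, 0.05)

  d <- withr::local_tempdir()
  res <- data.frame(dataset = "d1", gene_set = "g", origin = "random",
                    method = "random", model_id = "coxph",
                    fold1 = 0.6, fold2 = 0.61, fold3 = 0.59, fold4 = 0.6,
                    fold5 = 0.62, median_c = 0.6)
  p1 <- write_results_tsv(res, file.path(d, "res.tsv"))
  back <- read.delim(p1)
  expect_equal(back$median_c, 0.6)
  p2 <- write_summary_json(summarize_grid(res), file.path(d, "s.json"),
                           ceiling = ceiling_curve(res))
  doc <- jsonlite::read_json(p2)
  expect_equal(doc$summary[[1]]$mom, 0.6)
})
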