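#' Evaluate one signature under fivefold cross-validation
#'
#' One random event-stratified permutation splits the cohort into five
#' folds. For each fold the remaining four form the training set:
#' expression is standardized per gene on the training fold only (the same
#' centering/scaling is applied to the test fold), the model is fitted on
#' the training fold, and Harrell's C is computed on the held-out fold.
#' The signature's prognostic power is the median of the five fold
#' C-indices; folds with a failed fit or no comparable pair are recorded
#' as missing and excluded from the median.
#'
#' @param ds an [expression_dataset()].
#' @param gs a [gene_set()] whose genes are all present in `ds`.
#' @param model_spec a [survival_model_spec()].
#' @param seed integer seed controlling the fold permutation (the model's
#'   own seed lives in `model_spec`).
#' @param n_folds number of folds (default 5).
#' @return A one-row data.frame (class `signature_result`): dataset,
#'   gene_set, origin, method, model_id, fold1..fold5, median_c.
#' @export
evaluate_signature <- function(ds, gs, model_spec, seed = 1, n_folds = 5) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(gs, "gene_set"),
            inherits(model_spec, "survival_model_spec"))
  missing_genes <- setdiff(gs$genes, ds$gene_ids)
  if (length(missing_genes)) {
    stop_sigceiling("sigceiling_contract_error",
                    paste0("gene set '", gs$name, "' has genes absent from ",
                           ds$name, ": ",
                           paste(missing_genes, collapse = ", ")))
  }
  X <- ds$expression[, gs$genes, drop = FALSE]
  folds <- stratified_folds(ds$event, n_folds, seed)
  fold_c <- vapply(seq_len(n_folds), function(f) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, sd)
    sdv[sdv == 0] <- 1
    Xtr <- scale(Xtr, center = mu, scale = sdv)
    Xte <- scale(X[test, , drop = FALSE], center = mu, scale = sdv)
    m <- fit_survival_model(model_spec, Xtr, ds$time[!test],
                            ds$event[!test])
    if (model_failed(m)) return(NA_real_)
    harrell_c_or_na(predict_risk(m, Xte), ds$time[test], ds$event[test])
  }, numeric(1))
  res <- data.frame(dataset = ds$name, gene_set = gs$name,
                    origin = gs$origin, method = gs$method,
                    model_id = model_spec$model_id,
                    t(setNames(fold_c, paste0("fold", seq_len(n_folds)))),
                    median_c = median(fold_c, na.rm = !all(is.na(fold_c))),
                    stringsAsFactors = FALSE)
  class(res) <- c("signature_result", class(res))
  res
}

# Event-stratified fold assignment: events and censored observations are
# shuffled separately and dealt round-robin, so every fold holds comparable
# pairs even in small cohorts.
stratified_folds <- function(event, n_folds, seed) {
  folds <- integer(length(event))
  withr::with_seed(seed, {
    for (grp in unique(event)) {
      rows <- which(event == grp)
      folds[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
    }
  })
  folds
}

#' Define a grid plan
#'
#' Describes how gene sets are constructed per dataset for [run_grid()]:
#' `n_random` random draws of `random_size` genes, curated signatures from
#' `reported_paths` (or `n_reported` placeholder slots when only the grid
#' cardinality matters, e.g. in a dry run), and the listed ML selection
#' methods. The benchmark's standard plan is 100 random + 33 reported + 5
#' ML sets per dataset, evaluated by 9 models over 8 cohorts, i.e.
#' 8 x (100 + 33 + 5) x 9 = 9936 signatures.
#'
#' @param n_random random sets per dataset (default 100).
#' @param random_size genes per random set (default 20).
#' @param reported_paths character vector of gene-list files.
#' @param n_reported placeholder count used when `reported_paths` is empty
#'   (default 0).
#' @param ml_methods ML selection methods to run (default all five).
#' @param ml_args named list of extra arguments passed to [select_ml()].
#' @return A list of class `grid_plan`.
#' @export
grid_plan <- function(n_random = 100, random_size = 20,
                      reported_paths = character(), n_reported = 0,
                      ml_methods = c("UM", "SRC", "SRC-VH", "MRMR", "CF"),
                      ml_args = list()) {
  structure(list(n_random = n_random, random_size = random_size,
                 reported_paths = reported_paths, n_reported = n_reported,
                 ml_methods = ml_methods, ml_args = ml_args),
            class = "grid_plan")
}

#' Run the full signature-evaluation grid
#'
#' Enumerates the Cartesian product dataset x gene set x model. Gene sets
#' are constructed per dataset according to the plan. With `dry_run = TRUE`
#' the grid is enumerated without constructing ML sets or fitting models —
#' every row is emitted with missing fold values — which is the cheap way
#' to audit grid cardinality.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param plan a [grid_plan()].
#' @param model_ids character vector of model ids (default all nine).
#' @param seed integer master seed; every signature's fold permutation and
#'   model seed are derived deterministically from it and the grid indices.
#' @param dry_run enumerate only (default `FALSE`).
#' @param progress emit a progress message per dataset (default `TRUE`).
#' @return A data.frame of signature results (one row per grid cell) with
#'   attribute `failures` listing cells whose five folds all failed.
#' @export
run_grid <- function(datasets, plan = grid_plan(),
                     model_ids = model_registry(), seed = 1,
                     dry_run = FALSE, progress = TRUE) {
  stopifnot(inherits(plan, "grid_plan"))
  rows <- list()
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    sets <- build_plan_sets(ds, plan, derive_seed(seed, d), dry_run)
    if (progress) {
      message(sprintf("grid: dataset %s (%d/%d), %d gene sets x %d models",
                      ds$name, d, length(datasets), length(sets),
                      length(model_ids)))
    }
    for (g in seq_along(sets)) {
      gs <- sets[[g]]
      for (m in seq_along(model_ids)) {
        if (dry_run) {
          row <- data.frame(dataset = ds$name, gene_set = gs$name,
                            origin = gs$origin, method = gs$method,
                            model_id = model_ids[m],
                            fold1 = NA_real_, fold2 = NA_real_,
                            fold3 = NA_real_, fold4 = NA_real_,
                            fold5 = NA_real_, median_c = NA_real_,
                            stringsAsFactors = FALSE)
        } else {
          spec <- survival_model_spec(model_ids[m],
                                      seed = derive_seed(seed, d, g, m))
          row <- evaluate_signature(ds, gs, spec,
                                    seed = derive_seed(seed, d, g))
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  failed <- is.na(out$median_c) & !dry_run
  attr(out, "failures") <- out[failed, c("dataset", "gene_set", "model_id")]
  out
}

build_plan_sets <- function(ds, plan, seed, dry_run) {
  sets <- sample_random_gene_sets(ds, set_size = plan$random_size,
                                  n_sets = plan$n_random, seed = seed)
  if (length(plan$reported_paths)) {
    sets <- c(sets, suppressWarnings(
      load_reported_gene_sets(plan$reported_paths, ds)))
  } else if (plan$n_reported > 0) {
    # placeholder curated slots: only meaningful for cardinality audits
    sets <- c(sets, lapply(seq_len(plan$n_reported), function(i) {
      gene_set(sprintf("reported_%02d", i), ds$gene_ids[1],
               origin = "reported", method = "placeholder")
    }))
  }
  if (dry_run) {
    ml <- lapply(plan$ml_methods, function(mm) {
      gene_set(mm, ds$gene_ids[1], origin = "ml", method = mm)
    })
  } else {
    ml <- lapply(plan$ml_methods, function(mm) {
      do.call(select_ml, c(list(ds = ds, method = mm,
                                seed = derive_seed(seed, match(mm, plan$ml_methods))),
                           plan$ml_args))
    })
  }
  c(sets, ml)
}

#' Aggregate signature results per dataset and model
#'
#' For each (dataset, model) group: MOM, the median of the per-signature
#' median C-indices (the center of the distribution); MAD, the median
#' absolute deviation around the MOM; and MAX, the best median C observed.
#'
#' @param results data.frame from [run_grid()] or rows from
#'   [evaluate_signature()].
#' @return data.frame with columns dataset, model_id, mom, mad, max_c,
#'   n_signatures.
#' @export
summarize_grid <- function(results) {
  results <- results[!is.na(results$median_c), , drop = FALSE]
  if (nrow(results) == 0) {
    stop_sigceiling("sigceiling_validation_error",
                    "no defined signature results to summarize")
  }
  groups <- unique(results[, c("dataset", "model_id")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- results$dataset == groups$dataset[i] &
      results$model_id == groups$model_id[i]
    med <- results$median_c[sel]
    mom <- median(med)
    data.frame(dataset = groups$dataset[i], model_id = groups$model_id[i],
               mom = mom, mad = median(abs(med - mom)), max_c = max(med),
               n_signatures = sum(sel), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlate summary statistics with cohort characteristics
#'
#' Tests, per prognostic model, whether the center (MOM) and spread (MAD)
#' of the signature C-index distribution track cohort size or event rate
#' across datasets. Both Pearson and Spearman coefficients are reported
#' with two-sided p-values.
#'
#' @param stats output of [summarize_grid()].
#' @param cohort_info data.frame with columns `dataset`, `n_patients`,
#'   `event_rate` (see [cohort_info()]).
#' @return data.frame with columns model_id, statistic, covariate, method,
#'   estimate, p_value.
#' @export
correlate_with_cohort <- function(stats, cohort_info) {
  merged <- merge(stats, cohort_info, by = "dataset")
  if (length(unique(merged$dataset)) < 3) {
    stop_sigceiling("sigceiling_undefined_result",
                    "cohort correlations need at least 3 datasets")
  }
  grid <- expand.grid(model_id = unique(merged$model_id),
                      statistic = c("mom", "mad"),
                      covariate = c("n_patients", "event_rate"),
                      method = c("pearson", "spearman"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- merged[merged$model_id == g$model_id, ]
    ct <- suppressWarnings(
      cor.test(sub[[g$statistic]], sub[[g$covariate]], method = g$method,
               alternative = "two.sided"))
    data.frame(g, estimate = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize per-dataset cohort characteristics
#'
#' @param datasets list of [expression_dataset()] objects.
#' @return data.frame with dataset, n_patients, event_rate.
#' @export
cohort_info <- function(datasets) {
  do.call(rbind, lapply(datasets, function(ds) {
    data.frame(dataset = ds$name, n_patients = n_samples(ds),
               event_rate = event_rate(ds), stringsAsFactors = FALSE)
  }))
}

#' Prevalence of random-signature superiority
#'
#' For each (dataset, model) group, the fraction of random signatures whose
#' median C-index lies strictly above that of a reference (curated)
#' signature evaluated on the same dataset with the same model, plus the
#' across-dataset average per model and overall.
#'
#' @param random_results rows from [run_grid()] with origin `"random"`.
#' @param reference_results rows for the reference signature (one per
#'   dataset x model).
#' @return A list with `per_group` (dataset, model_id, n_random,
#'   frac_above), `by_model` and `overall` (grand mean fraction).
#' @export
rss_prevalence <- function(random_results, reference_results) {
  random_results <- random_results[random_results$origin == "random", ]
  per <- merge(random_results,
               reference_results[, c("dataset", "model_id", "median_c")],
               by = c("dataset", "model_id"), suffixes = c("", "_ref"))
  if (nrow(per) == 0) {
    stop_sigceiling("sigceiling_validation_error",
                    "no (dataset, model) overlap between random and reference results")
  }
  groups <- unique(per[, c("dataset", "model_id")])
  per_group <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- per$dataset == groups$dataset[i] &
      per$model_id == groups$model_id[i]
    data.frame(dataset = groups$dataset[i], model_id = groups$model_id[i],
               n_random = sum(sel),
               frac_above = mean(per$median_c[sel] > per$median_c_ref[sel],
                                 na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  by_model <- do.call(rbind, lapply(split(per_group, per_group$model_id),
                                    function(g) {
    data.frame(model_id = g$model_id[1], frac_above = mean(g$frac_above),
               stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- rownames(by_model) <- NULL
  list(per_group = per_group, by_model = by_model,
       overall = mean(per_group$frac_above))
}

#' Fraction of signatures above a C-index threshold, and the ceiling
#'
#' Computes, for an ascending grid of thresholds, the fraction of
#' signatures whose median C-index lies strictly above the threshold. The
#' ceiling estimate is the smallest threshold at which this fraction drops
#' below `cut` (default 1%); the smallest threshold with no exceedances at
#' all is also reported.
#'
#' @param results data.frame with a `median_c` column, or a numeric vector
#'   of median C-indices.
#' @param thresholds ascending numeric grid (default `seq(0.5, 0.9, 0.005)`).
#' @param cut fraction defining the ceiling (default 0.01).
#' @return A list of class `ceiling_curve`: `curve` (threshold,
#'   fraction_above), `ceiling_estimate`, `zero_threshold` (NA when never
#'   reached), `cut`, `n_signatures`.
#' @export
ceiling_curve <- function(results, thresholds = seq(0.5, 0.9, by = 0.005),
                          cut = 0.01) {
  med <- if (is.numeric(results)) results else results$median_c
  med <- med[!is.na(med)]
  if (length(med) == 0) {
    stop_sigceiling("sigceiling_validation_error",
                    "no signature results supplied")
  }
  if (is.unsorted(thresholds)) {
    stop_sigceiling("sigceiling_validation_error",
                    "thresholds must be ascending")
  }
  frac <- vapply(thresholds, function(th) mean(med > th), numeric(1))
  below <- which(frac < cut)
  zero <- which(frac == 0)
  structure(list(
    curve = data.frame(threshold = thresholds, fraction_above = frac),
    ceiling_estimate = if (length(below)) thresholds[below[1]] else NA_real_,
    zero_threshold = if (length(zero)) thresholds[zero[1]] else NA_real_,
    cut = cut, n_signatures = length(med)),
    class = "ceiling_curve")
}

#' @export
print.ceiling_curve <- function(x, ...) {
  cat(sprintf("<ceiling_curve> %d signatures; fraction above drops below %.1f%% at C = %s (reaches 0 at C = %s)\n",
              x$n_signatures, 100 * x$cut,
              format(x$ceiling_estimate), format(x$zero_threshold)))
  invisible(x)
}

#' Two-sided rank-sum comparison of two median-C distributions
#'
#' Utility wrapper around the Wilcoxon rank-sum test for comparing, e.g.,
#' random versus reported signature medians within a dataset/model group.
#'
#' @param x,y numeric vectors of median C-indices.
#' @return list with `statistic` and `p_value`.
#' @export
rank_sum_compare <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Write grid results and summaries to disk
#'
#' `write_results_tsv()` writes the per-signature results table;
#' `write_summary_json()` writes a JSON document holding the per-group
#' summary statistics and, optionally, a ceiling curve.
#'
#' @param results data.frame from [run_grid()].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_results_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @param stats output of [summarize_grid()].
#' @param ceiling optional [ceiling_curve()].
#' @export
write_summary_json <- function(stats, path, ceiling = NULL) {
  doc <- list(summary = stats)
  if (!is.null(ceiling)) {
    doc$ceiling <- list(curve = ceiling$curve,
                        ceiling_estimate = ceiling$ceiling_estimate,
                        zero_threshold = ceiling$zero_threshold,
                        cut = ceiling$cut)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
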