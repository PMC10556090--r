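#' Construct a gene set
#'
#' A named list of gene identifiers with an origin tag recording how it was
#' built: `random` (uniform sampling), `reported` (curated list from the
#' literature) or `ml` (machine-learning selection).
#'
#' @param name text label.
#' @param genes non-empty character vector of unique gene identifiers.
#' @param origin one of `"random"`, `"reported"`, `"ml"`.
#' @param method selection method label (e.g. `"UM"`, `"SRC"`, `"SRC-VH"`,
#'   `"MRMR"`, `"CF"`, or a reported signature's name).
#' @return A list of class `gene_set`.
#' @export
gene_set <- function(name, genes, origin, method = origin) {
  genes <- as.character(genes)
  if (length(genes) == 0) {
    stop_sigceiling("sigceiling_validation_error",
                    paste0("gene set '", name, "' is empty"))
  }
  if (anyDuplicated(genes)) {
    stop_sigceiling("sigceiling_validation_error",
                    paste0("gene set '", name, "' has duplicate genes"))
  }
  origin <- match.arg(origin, c("random", "reported", "ml"))
  structure(list(name = name, genes = genes, origin = origin,
                 method = method),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s/%s): %d genes\n", x$name, x$origin,
              x$method, length(x$genes)))
  invisible(x)
}

#' Sample random gene sets
#'
#' Draws `n_sets` gene sets of `set_size` distinct genes each, uniformly
#' without replacement within a set (sets may overlap across draws). The
#' default size of 20 genes reflects the observation that around 20
#' randomly selected genes is optimal for a random prognostic signature.
#'
#' @param ds an [expression_dataset()].
#' @param set_size genes per set (default 20).
#' @param n_sets number of sets (default 100).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return List of [gene_set()] objects with origin `"random"`.
#' @export
sample_random_gene_sets <- function(ds, set_size = 20, n_sets = 100,
                                    seed = 1) {
  if (set_size > n_genes(ds)) {
    stop_sigceiling("sigceiling_validation_error",
                    "set_size exceeds the number of genes in the dataset")
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      gene_set(sprintf("random_%03d", i),
               sample(ds$gene_ids, set_size), origin = "random",
               method = "random")
    })
  })
}

#' Load reported gene signatures from gene-list files
#'
#' Each file holds one gene symbol per line (`#` comments and blank lines
#' ignored). Symbols are matched case-insensitively against the dataset's
#' gene identifiers; a signature matching fewer than `min_match` of its
#' listed genes is dropped with a warning. A match report (listed, matched,
#' retained) is emitted per file.
#'
#' @param list_paths character vector of file paths; the file base name
#'   (without extension) becomes the signature name.
#' @param ds an [expression_dataset()].
#' @param min_match minimum matched fraction for retention (default 0.5).
#' @return List of [gene_set()] objects with origin `"reported"`.
#' @export
load_reported_gene_sets <- function(list_paths, ds, min_match = 0.5) {
  lookup <- setNames(ds$gene_ids, toupper(ds$gene_ids))
  out <- list()
  for (path in list_paths) {
    nm <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    symbols <- unique(lines[nzchar(lines)])
    if (length(symbols) == 0) {
      warning(sprintf("gene list '%s' is empty; skipped", nm), call. = FALSE)
      next
    }
    matched <- lookup[toupper(symbols)]
    matched <- unname(matched[!is.na(matched)])
    frac <- length(matched) / length(symbols)
    message(sprintf("signature '%s': %d listed, %d matched (%.0f%%)%s",
                    nm, length(symbols), length(matched), 100 * frac,
                    if (frac < min_match) " -> dropped" else ""))
    if (frac < min_match) {
      warning(sprintf("signature '%s' matched %.0f%% of its genes (< %.0f%%); dropped",
                      nm, 100 * frac, 100 * min_match), call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- gene_set(nm, matched, origin = "reported",
                                        method = nm)
  }
  out
}

# ---- shared helpers for the ML selectors ------------------------------

check_selectable <- function(ds) {
  if (sum(ds$event) < 2) {
    stop_sigceiling("sigceiling_selection_error",
                    "at least 2 observed events are required for selection")
  }
  v <- apply(ds$expression, 2, var)
  if (all(v == 0)) {
    stop_sigceiling("sigceiling_selection_error",
                    "all genes are constant; nothing to select")
  }
}

# Per-gene univariable Cox Wald z statistics (NA where the fit fails).
univariable_z <- function(ds) {
  y <- surv_response(ds$time, ds$event)
  vapply(seq_len(n_genes(ds)), function(j) {
    x <- ds$expression[, j]
    if (var(x) == 0) return(NA_real_)
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ x)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    s <- summary(fit)$coefficients
    z <- s[1, "z"]
    if (is.finite(z)) z else NA_real_
  }, numeric(1))
}

# Keep the top-variance genes (selection prefilter for forest-based
# selectors); returns column indices into ds$expression.
prefilter_indices <- function(ds, top_var) {
  if (is.null(top_var) || n_genes(ds) <= top_var) return(seq_len(n_genes(ds)))
  v <- apply(ds$expression, 2, var)
  sort(order(v, decreasing = TRUE)[seq_len(top_var)])
}

#' Select the single best univariable gene (UM)
#'
#' Fits a one-gene Cox model per gene and returns the gene with the largest
#' absolute Wald z statistic; ties are broken by lexicographic gene id.
#'
#' @param ds an [expression_dataset()].
#' @return A [gene_set()] of exactly one gene (method `"UM"`).
#' @export
select_univariable <- function(ds) {
  check_selectable(ds)
  z <- univariable_z(ds)
  if (all(is.na(z))) {
    stop_sigceiling("sigceiling_selection_error",
                    "every univariable Cox fit failed")
  }
  az <- abs(z)
  best <- which(az == max(az, na.rm = TRUE))
  best <- best[order(ds$gene_ids[best])][1]
  gene_set("UM", ds$gene_ids[best], origin = "ml", method = "UM")
}

#' Select genes by random-survival-forest permutation importance (SRC)
#'
#' Fits a random survival forest on all genes (optionally prefiltered to
#' the top-variance genes) and ranks genes by permutation importance — the
#' out-of-bag concordance drop after permuting the gene's values.
#'
#' @param ds an [expression_dataset()].
#' @param n_genes number of genes to return (default 20).
#' @param seed integer seed.
#' @param num_trees forest size (default 500).
#' @param prefilter_top_var prefilter to this many top-variance genes
#'   before fitting (default 500; `NULL` disables).
#' @return A [gene_set()] (method `"SRC"`).
#' @export
select_src_importance <- function(ds, n_genes = 20, seed = 1,
                                  num_trees = 500,
                                  prefilter_top_var = 500) {
  check_selectable(ds)
  idx <- prefilter_indices(ds, prefilter_top_var)
  X <- ds$expression[, idx, drop = FALSE]
  rf <- ranger::ranger(x = X, y = surv_response(ds$time, ds$event),
                       num.trees = num_trees, importance = "permutation",
                       seed = seed, num.threads = 1)
  imp <- rf$variable.importance
  top <- names(sort(imp, decreasing = TRUE))[seq_len(min(n_genes, length(imp)))]
  gene_set("SRC", top, origin = "ml", method = "SRC")
}

# Mean minimal depth of every variable over the trees of a ranger forest;
# variables absent from a tree are charged that tree's maximal depth + 1.
mean_minimal_depth <- function(rf, var_names) {
  n_trees <- rf$num.trees
  acc <- setNames(numeric(length(var_names)), var_names)
  for (t in seq_len(n_trees)) {
    ti <- ranger::treeInfo(rf, t)
    depth <- rep(NA_integer_, nrow(ti))
    depth[1] <- 0L
    for (r in seq_len(nrow(ti))) {
      kids <- c(ti$leftChild[r], ti$rightChild[r])
      kids <- kids[!is.na(kids)]
      if (length(kids)) depth[kids + 1L] <- depth[r] + 1L
    }
    maxd <- max(depth, na.rm = TRUE)
    md <- tapply(depth[!is.na(ti$splitvarName)],
                 ti$splitvarName[!is.na(ti$splitvarName)], min)
    this <- setNames(rep(maxd + 1, length(var_names)), var_names)
    this[names(md)] <- md
    acc <- acc + this
  }
  acc / n_trees
}

#' Select genes by variable hunting (SRC-VH)
#'
#' Iterates a three-step loop: (1) compute forest permutation importance;
#' (2) sample a gene subset with probability proportional to importance and
#' fit a forest on it; (3) order the subset's genes by mean minimal depth
#' (the shortest distance from a tree's root to the gene's first split) and
#' add them successively to a joint model for as long as its out-of-bag
#' concordance improves. Genes are ranked by how often the loop selected
#' them; the final set keeps genes whose selection frequency reaches the
#' mean frequency of the genes ever selected.
#'
#' @inheritParams select_src_importance
#' @param n_iter number of hunting iterations (default 50).
#' @param subset_size genes sampled per iteration (default `min(p, 50)`).
#' @param max_model_size cap on the forward-selection path length
#'   (default 20).
#' @param num_trees forest size within each iteration (default 100).
#' @return A [gene_set()] (method `"SRC-VH"`).
#' @export
select_src_vh <- function(ds, n_iter = 50, seed = 1, subset_size = NULL,
                          max_model_size = 20, num_trees = 100,
                          prefilter_top_var = 500) {
  check_selectable(ds)
  idx <- prefilter_indices(ds, prefilter_top_var)
  X <- ds$expression[, idx, drop = FALSE]
  y <- surv_response(ds$time, ds$event)
  p <- ncol(X)
  if (is.null(subset_size)) subset_size <- min(p, 50)

  base_rf <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                            importance = "permutation",
                            seed = derive_seed(seed, 0), num.threads = 1)
  imp <- pmax(base_rf$variable.importance, 0)
  prob <- imp + 1e-8

  freq <- setNames(integer(p), colnames(X))
  for (it in seq_len(n_iter)) {
    sub <- withr::with_seed(derive_seed(seed, it),
                            sample(colnames(X), subset_size, prob = prob))
    rf <- ranger::ranger(x = X[, sub, drop = FALSE], y = y,
                         num.trees = num_trees,
                         seed = derive_seed(seed, it, 1), num.threads = 1)
    ord <- names(sort(mean_minimal_depth(rf, sub)))
    chosen <- ord[1]
    best_c <- oob_concordance(X[, chosen, drop = FALSE], y,
                              derive_seed(seed, it, 2), num_trees)
    for (k in 2:min(length(ord), max_model_size)) {
      cand <- ord[seq_len(k)]
      cc <- oob_concordance(X[, cand, drop = FALSE], y,
                            derive_seed(seed, it, 2), num_trees)
      if (is.na(cc) || cc <= best_c) break
      best_c <- cc
      chosen <- cand
    }
    freq[chosen] <- freq[chosen] + 1L
  }
  picked <- freq[freq > 0]
  if (length(picked) == 0) {
    stop_sigceiling("sigceiling_selection_error",
                    "variable hunting selected no genes")
  }
  keep <- names(picked)[picked >= mean(picked)]
  keep <- keep[order(-picked[keep], keep)]
  gene_set("SRC-VH", keep, origin = "ml", method = "SRC-VH")
}

# OOB concordance of a forest on the given columns; ranger's survival
# prediction error is 1 - Harrell's C on out-of-bag predictions.
oob_concordance <- function(X, y, seed, num_trees) {
  rf <- tryCatch(
    ranger::ranger(x = X, y = y, num.trees = num_trees, seed = seed,
                   num.threads = 1),
    error = function(e) NULL)
  if (is.null(rf)) return(NA_real_)
  1 - rf$prediction.error
}

#' Select genes by minimum redundancy, maximum relevance (MRMR)
#'
#' Relevance of a gene is its absolute univariable Cox Wald z, rescaled to
#' \[0, 1\] so it is commensurable with redundancy (the two terms of the
#' mRMR difference criterion must share a scale, as they do in the
#' mutual-information original); redundancy with an already-selected set is
#' the mean absolute Pearson correlation. Selection is greedy: start from
#' the most relevant gene, then repeatedly add the gene maximizing
#' relevance minus redundancy.
#'
#' @inheritParams select_src_importance
#' @return A [gene_set()] (method `"MRMR"`).
#' @export
select_mrmr <- function(ds, n_genes = 20) {
  check_selectable(ds)
  z <- abs(univariable_z(ds))
  if (all(is.na(z))) {
    stop_sigceiling("sigceiling_selection_error",
                    "every univariable Cox fit failed")
  }
  z[is.na(z)] <- 0
  if (max(z) > 0) z <- z / max(z)
  ids <- ds$gene_ids
  n_pick <- min(n_genes, length(ids))
  first <- which(z == max(z))
  selected <- ids[first[order(ids[first])][1]]
  candidates <- setdiff(ids, selected)
  while (length(selected) < n_pick && length(candidates)) {
    red <- vapply(candidates, function(g) {
      mean(abs(cor(ds$expression[, g], ds$expression[, selected])))
    }, numeric(1))
    scorev <- z[match(candidates, ids)] - red
    best <- candidates[which(scorev == max(scorev))]
    best <- best[order(best)][1]
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  gene_set("MRMR", selected, origin = "ml", method = "MRMR")
}

#' Select genes by conditional forest importance (CF)
#'
#' Permutation importance in which each gene is permuted within strata
#' defined by quartile bins of its most-correlated covariate (absolute
#' Pearson correlation above `cond_threshold`), so that importance is not
#' inflated by correlated neighbours. To keep the importance estimate
#' honest, the importance is cross-fitted: the cohort is split into two
#' event-stratified halves, a forest fitted on each half is scored on the
#' other (in-sample drops would credit genes the trees merely overfitted
#' on), and the concordance drop is averaged over the two directions and
#' over `n_perm` independent permutations each.
#'
#' @inheritParams select_src_importance
#' @param cond_threshold correlation threshold for conditioning covariates
#'   (default 0.2); the most-correlated qualifying gene defines the
#'   permutation strata.
#' @param num_trees forest size (default 100).
#' @param n_perm permutations averaged per gene (default 3).
#' @return A [gene_set()] (method `"CF"`).
#' @export
select_cf <- function(ds, n_genes = 20, cond_threshold = 0.2, seed = 1,
                      num_trees = 100, prefilter_top_var = 500,
                      n_perm = 3) {
  check_selectable(ds)
  idx <- prefilter_indices(ds, prefilter_top_var)
  X <- ds$expression[, idx, drop = FALSE]
  cm <- abs(cor(X))
  diag(cm) <- 0
  half <- stratified_folds(ds$event, 2, derive_seed(seed, 0)) == 1

  direction_importance <- function(fit_rows, eval_rows, dir_seed) {
    rf <- ranger::ranger(x = X[fit_rows, , drop = FALSE],
                         y = surv_response(ds$time[fit_rows],
                                           ds$event[fit_rows]),
                         num.trees = num_trees, seed = dir_seed,
                         num.threads = 1)
    Xh <- X[eval_rows, , drop = FALSE]
    th <- ds$time[eval_rows]; eh <- ds$event[eval_rows]
    risk <- function(Xq) {
      rowSums(predict(rf, data = Xq, num.threads = 1)$chf)
    }
    base_c <- harrell_c_or_na(risk(Xh), th, eh)
    vapply(seq_len(ncol(X)), function(j) {
      partner <- order(cm[, j], decreasing = TRUE)[1]
      strata <- if (cm[partner, j] > cond_threshold) {
        quartile_bin(Xh[, partner])
      } else {
        factor(rep(1, nrow(Xh)))
      }
      drops <- vapply(seq_len(n_perm), function(r) {
        Xp <- Xh
        Xp[, j] <- withr::with_seed(derive_seed(dir_seed, j, r), {
          xj <- Xh[, j]
          for (s in levels(strata)) {
            rows <- which(strata == s)
            if (length(rows) > 1) xj[rows] <- xj[sample(rows)]
          }
          xj
        })
        base_c - harrell_c_or_na(risk(Xp), th, eh)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  }

  imp <- (direction_importance(which(half), which(!half),
                               derive_seed(seed, 1)) +
            direction_importance(which(!half), which(half),
                                 derive_seed(seed, 2))) / 2
  names(imp) <- colnames(X)
  top <- names(sort(imp, decreasing = TRUE))[seq_len(min(n_genes, length(imp)))]
  gene_set("CF", top, origin = "ml", method = "CF")
}

quartile_bin <- function(x) {
  br <- unique(quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1)))
  if (length(br) < 2) return(factor(rep(1, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Run one of the named ML selectors
#'
#' Dispatch helper mapping the method labels `"UM"`, `"SRC"`, `"SRC-VH"`,
#' `"MRMR"`, `"CF"` onto the corresponding selector with its defaults.
#'
#' @param ds an [expression_dataset()].
#' @param method one of the five method labels.
#' @param seed integer seed passed to stochastic selectors.
#' @param ... forwarded to the selector.
#' @return A [gene_set()].
#' @export
select_ml <- function(ds, method, seed = 1, ...) {
  switch(method,
    "UM" = select_univariable(ds),
    "SRC" = select_src_importance(ds, seed = seed, ...),
    "SRC-VH" = select_src_vh(ds, seed = seed, ...),
    "MRMR" = select_mrmr(ds, ...),
    "CF" = select_cf(ds, seed = seed, ...),
    stop_sigceiling("sigceiling_validation_error",
                    paste0("unknown selection method: ", method))
  )
}
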