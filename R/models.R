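#' The nine-model registry
#'
#' Identifiers of the nine censoring-aware prognostic models the benchmark
#' evaluates: the Cox proportional hazards model (`coxph`), its L1-, L2- and
#' mixed-penalty extensions (`lasso`, `ridge`, `elastic_net`), gradient
#' boosting of the Cox partial likelihood with componentwise-linear
#' (`gb_linear`) or depth-limited tree (`gb_tree`) base learners, random
#' survival forests with log-rank splitting (`rsf`), forests whose split
#' points are chosen by maximally selected rank statistics (`rank_rf`), and
#' a single survival tree (`stree`).
#'
#' @return Character vector of the nine model identifiers.
#' @export
model_registry <- function() {
  c("coxph", "lasso", "ridge", "elastic_net", "gb_linear", "gb_tree",
    "rsf", "rank_rf", "stree")
}

# Canonical hyperparameter defaults per model family. All exposed through
# survival_model_spec(hyperparams = ...).
default_hyperparams <- function(model_id) {
  switch(model_id,
    coxph = list(ridge_jitter_lambda = 0.01),
    lasso = list(alpha = 1, nfolds = 3),
    ridge = list(alpha = 0, nfolds = 3),
    elastic_net = list(alpha = 0.5, nfolds = 3),
    gb_linear = list(nrounds = 100, eta = 0.1),
    gb_tree = list(nrounds = 100, eta = 0.1, max_depth = 3),
    rsf = list(num_trees = 500, min_node_size = 15),
    rank_rf = list(num_trees = 500, min_node_size = 15, alpha = 0.5,
                   minprop = 0.1),
    stree = list(min_node_size = 15),
    stub_random = list(),
    stop_sigceiling("sigceiling_validation_error",
                    paste0("unknown model id: ", model_id))
  )
}

#' Specify a prognostic survival model
#'
#' @param model_id one of [model_registry()] (the testing-only
#'   `"stub_random"` model, which emits seeded random scores, is also
#'   accepted).
#' @param hyperparams named list overriding the documented defaults.
#' @param seed integer seed controlling every stochastic element of the fit.
#' @return A list of class `survival_model_spec`.
#' @export
survival_model_spec <- function(model_id, hyperparams = list(), seed = 1) {
  if (!model_id %in% c(model_registry(), "stub_random")) {
    stop_sigceiling("sigceiling_validation_error",
                    paste0("model_id must be one of: ",
                           paste(model_registry(), collapse = ", ")))
  }
  hp <- default_hyperparams(model_id)
  hp[names(hyperparams)] <- hyperparams
  structure(list(model_id = model_id, hyperparams = hp,
                 seed = as.integer(seed)),
            class = "survival_model_spec")
}

surv_response <- function(time, event) survival::Surv(time, event)

# xgboost's Cox objective encodes censoring as a negative label.
xgb_cox_label <- function(time, event) ifelse(event == 1, time, -time)

#' Fit a prognostic model
#'
#' Fits one of the registered models to a standardized training matrix.
#' Non-convergent or failed fits are returned as flagged objects carrying a
#' diagnostic rather than raised as errors, so that a large evaluation grid
#' records them as missing cells and continues.
#'
#' @param spec a [survival_model_spec()].
#' @param X numeric matrix, samples x genes, column names = gene ids.
#' @param time,event survival outcome of the training samples.
#' @return A `fitted_survival_model` with fields `spec`, `state`,
#'   `train_gene_ids` and `diagnostic` (`NULL` when clean).
#' @export
fit_survival_model <- function(spec, X, time, event) {
  stopifnot(inherits(spec, "survival_model_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  if (anyNA(X)) {
    stop_sigceiling("sigceiling_validation_error",
                    "training matrix must have no missing values")
  }
  if (nrow(X) < 20) {
    stop_sigceiling("sigceiling_validation_error",
                    "at least 20 training samples are required")
  }
  if (sum(event == 1) < 2) {
    stop_sigceiling("sigceiling_validation_error",
                    "at least 2 observed events are required")
  }
  out <- structure(list(spec = spec, state = NULL,
                        train_gene_ids = colnames(X), diagnostic = NULL),
                   class = "fitted_survival_model")
  fit <- tryCatch(
    fit_backend(spec, X, time, event),
    error = function(e) {
      list(state = NULL, diagnostic = conditionMessage(e))
    }
  )
  out$state <- fit$state
  out$diagnostic <- fit$diagnostic
  out
}

#' @rdname fit_survival_model
#' @param m a `fitted_survival_model`.
#' @export
model_failed <- function(m) is.null(m$state)

fit_backend <- function(spec, X, time, event) {
  hp <- spec$hyperparams
  seed <- spec$seed
  n <- nrow(X)
  p <- ncol(X)
  switch(spec$model_id,
    coxph = {
      y <- surv_response(time, event)
      fit <- NULL
      diag <- NULL
      if (p < n) {
        fit <- withCallingHandlers(
          tryCatch(survival::coxph(y ~ X, ties = "efron"),
                   error = function(e) NULL),
          warning = function(w) {
            diag <<- conditionMessage(w)
            invokeRestart("muffleWarning")
          })
      }
      beta <- if (!is.null(fit)) unname(coef(fit)) else rep(NA_real_, p)
      if (is.null(fit) || anyNA(beta) || any(!is.finite(beta))) {
        # singular/overdetermined partial likelihood: small ridge jitter
        rj <- suppressWarnings(
          glmnet::glmnet(X, y, family = "cox", alpha = 0,
                         lambda = hp$ridge_jitter_lambda,
                         standardize = FALSE))
        beta <- as.numeric(coef(rj))
        diag <- paste(c(diag, "ridge jitter applied"), collapse = "; ")
      }
      list(state = list(type = "linear", beta = beta), diagnostic = diag)
    },
    lasso = fit_penalized(X, time, event, hp, seed),
    ridge = fit_penalized(X, time, event, hp, seed),
    elastic_net = fit_penalized(X, time, event, hp, seed),
    gb_linear = {
      set.seed(seed)
      bst <- xgboost::xgb.train(
        params = list(objective = "survival:cox", booster = "gblinear",
                      eta = hp$eta, updater = "coord_descent",
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(X, label = xgb_cox_label(time, event)),
        nrounds = hp$nrounds, verbose = 0)
      list(state = list(type = "xgb", booster = bst), diagnostic = NULL)
    },
    gb_tree = {
      set.seed(seed)
      bst <- xgboost::xgb.train(
        params = list(objective = "survival:cox", booster = "gbtree",
                      eta = hp$eta, max_depth = hp$max_depth,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(X, label = xgb_cox_label(time, event)),
        nrounds = hp$nrounds, verbose = 0)
      list(state = list(type = "xgb", booster = bst), diagnostic = NULL)
    },
    rsf = {
      rf <- ranger::ranger(x = X, y = surv_response(time, event),
                           num.trees = hp$num_trees,
                           mtry = ceiling(sqrt(p)),
                           min.node.size = hp$min_node_size,
                           splitrule = "logrank", seed = seed,
                           num.threads = 1)
      list(state = list(type = "ranger", forest = rf), diagnostic = NULL)
    },
    rank_rf = {
      rf <- ranger::ranger(x = X, y = surv_response(time, event),
                           num.trees = hp$num_trees,
                           mtry = ceiling(sqrt(p)),
                           min.node.size = hp$min_node_size,
                           splitrule = "maxstat", alpha = hp$alpha,
                           minprop = hp$minprop, seed = seed,
                           num.threads = 1)
      list(state = list(type = "ranger", forest = rf), diagnostic = NULL)
    },
    stree = {
      # a single fully-grown tree on the full sample = survival tree with
      # log-rank splitting
      tr <- ranger::ranger(x = X, y = surv_response(time, event),
                           num.trees = 1, mtry = p, replace = FALSE,
                           sample.fraction = 1,
                           min.node.size = hp$min_node_size,
                           splitrule = "logrank", seed = seed,
                           num.threads = 1)
      list(state = list(type = "ranger", forest = tr), diagnostic = NULL)
    },
    stub_random = {
      list(state = list(type = "stub"), diagnostic = NULL)
    }
  )
}

fit_penalized <- function(X, time, event, hp, seed) {
  y <- surv_response(time, event)
  foldid <- withr::with_seed(seed, sample(rep_len(seq_len(hp$nfolds),
                                                  nrow(X))))
  cv <- suppressWarnings(
    glmnet::cv.glmnet(X, y, family = "cox", alpha = hp$alpha,
                      foldid = foldid, standardize = FALSE))
  beta <- as.numeric(coef(cv, s = "lambda.min"))
  list(state = list(type = "linear", beta = beta), diagnostic = NULL)
}

#' Predict per-sample risk scores
#'
#' Scores are oriented package-wide as higher = higher risk (worse
#' prognosis): linear models return the linear predictor, boosted models the
#' boosted margin, and tree/forest models the expected cumulative hazard
#' summed over event times (mortality).
#'
#' @param m a `fitted_survival_model`.
#' @param X matrix whose columns are exactly the model's `train_gene_ids`.
#' @return Numeric vector of risk scores, or all-`NA` for a flagged fit.
#' @export
predict_risk <- function(m, X) {
  stopifnot(inherits(m, "fitted_survival_model"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(m$train_gene_ids)) {
      stop_sigceiling("sigceiling_contract_error",
                      "prediction matrix has the wrong number of genes")
    }
    colnames(X) <- m$train_gene_ids
  }
  missing_genes <- setdiff(m$train_gene_ids, colnames(X))
  if (length(missing_genes)) {
    stop_sigceiling("sigceiling_contract_error",
                    paste0("prediction matrix is missing gene(s): ",
                           paste(missing_genes, collapse = ", ")))
  }
  X <- X[, m$train_gene_ids, drop = FALSE]
  if (model_failed(m)) return(rep(NA_real_, nrow(X)))
  st <- m$state
  score <- switch(st$type,
    linear = as.numeric(X %*% st$beta),
    xgb = as.numeric(predict(st$booster, xgboost::xgb.DMatrix(X),
                             outputmargin = TRUE)),
    ranger = {
      pr <- predict(st$forest, data = X, num.threads = 1)
      as.numeric(rowSums(pr$chf))
    },
    stub = withr::with_seed(m$spec$seed + nrow(X),
                            runif(nrow(X)))
  )
  score
}
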