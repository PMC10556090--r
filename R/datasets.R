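#' Construct an expression dataset with survival outcome
#'
#' The unit every selection and evaluation step operates on: a samples ×
#' genes matrix of continuous expression values together with per-sample
#' follow-up time (years), event indicator, and optional clinical covariates.
#'
#' @param expression numeric matrix, samples in rows, genes in columns.
#' @param time numeric vector of positive follow-up times (years).
#' @param event 0/1 vector, 1 = event observed.
#' @param name text label for the dataset.
#' @param endpoint text label for the survival endpoint, e.g. "overall
#'   survival" or "distant-metastasis-free survival".
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `colnames(expression)`.
#' @param clinical optional data.frame of per-sample covariates. Recognised
#'   columns: `age` (years), `er_status` ("positive"/"negative"/"unknown"),
#'   `chemotherapy` ("yes"/"no"/"unknown").
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(expression, time, event, name = "dataset",
                               endpoint = "overall survival",
                               gene_ids = colnames(expression),
                               clinical = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("G%04d", seq_len(ncol(expression)))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(expression)) {
    stop_sigceiling("sigceiling_validation_error",
                    "gene_ids length must equal the number of genes")
  }
  if (anyDuplicated(gene_ids)) {
    stop_sigceiling("sigceiling_validation_error", "gene_ids must be unique")
  }
  if (anyNA(expression)) {
    stop_sigceiling("sigceiling_validation_error",
                    "expression must have no missing values after loading")
  }
  if (length(time) != n || length(event) != n) {
    stop_sigceiling("sigceiling_length_error",
                    "time and event must have one value per sample")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    bad <- which(!is.finite(time) | time <= 0)
    stop_sigceiling("sigceiling_validation_error",
                    paste0("all follow-up times must be positive; offending samples: ",
                           paste(head(bad, 10), collapse = ", ")))
  }
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) {
    stop_sigceiling("sigceiling_validation_error", "event must be 0/1")
  }
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical)
    if (nrow(clinical) != n) {
      stop_sigceiling("sigceiling_length_error",
                      "clinical must have one row per sample")
    }
  }
  colnames(expression) <- gene_ids
  structure(
    list(name = name, expression = expression, gene_ids = gene_ids,
         time = as.numeric(time), event = event, endpoint = endpoint,
         clinical = clinical),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s\n", x$name))
  cat(sprintf("  %d samples x %d genes; endpoint: %s\n",
              n_samples(x), n_genes(x), x$endpoint))
  cat(sprintf("  events: %d (event rate %.3f)\n",
              sum(x$event), event_rate(x)))
  if (!is.null(x$clinical)) {
    cat(sprintf("  clinical covariates: %s\n",
                paste(names(x$clinical), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname expression_dataset
#' @param ds an `expression_dataset`.
#' @export
n_samples <- function(ds) nrow(ds$expression)

#' @rdname expression_dataset
#' @export
n_genes <- function(ds) ncol(ds$expression)

#' @rdname expression_dataset
#' @export
event_rate <- function(ds) sum(ds$event) / n_samples(ds)

# Row subset preserving all per-sample fields and truth attributes.
subset_samples <- function(ds, keep) {
  out <- ds
  out$expression <- ds$expression[keep, , drop = FALSE]
  out$time <- ds$time[keep]
  out$event <- ds$event[keep]
  if (!is.null(ds$clinical)) out$clinical <- ds$clinical[keep, , drop = FALSE]
  lf <- attr(ds, "latent_factor")
  if (!is.null(lf)) attr(out, "latent_factor") <- lf[keep]
  out
}

read_table_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
}

#' Load an expression dataset from expression + clinical tables
#'
#' Reads a delimited expression table (TSV or CSV by extension; by default
#' genes in rows with the first column holding gene identifiers and the
#' header row holding sample identifiers, the layout of GEO series matrices)
#' and a clinical table keyed on `sample_id` with `time` and `event` columns
#' plus optional `age`, `er_status` and `chemotherapy`. The dataset is
#' restricted to samples present in both files. Genes whose missing rate
#' exceeds `missing_drop_threshold` are dropped; remaining missing values
#' are median-imputed per gene.
#'
#' @param expr_path path to the expression table.
#' @param clinical_path path to the clinical table.
#' @param name dataset label; defaults to the expression file name.
#' @param endpoint survival endpoint label.
#' @param genes_in_rows orientation flag; set `FALSE` for samples-in-rows
#'   files with the first column holding sample identifiers.
#' @param missing_drop_threshold genes with a larger fraction of missing
#'   values are dropped (default 0.2).
#' @return An [expression_dataset()].
#' @export
load_expression_dataset <- function(expr_path, clinical_path,
                                    name = basename(expr_path),
                                    endpoint = "overall survival",
                                    genes_in_rows = TRUE,
                                    missing_drop_threshold = 0.2) {
  expr_tab <- read_table_auto(expr_path)
  clin <- read_table_auto(clinical_path)
  need <- c("sample_id", "time", "event")
  missing_cols <- setdiff(need, names(clin))
  if (length(missing_cols)) {
    stop_sigceiling("sigceiling_format_error",
                    paste0("clinical table is missing required column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  ids <- as.character(expr_tab[[1]])
  m <- as.matrix(expr_tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (genes_in_rows) {
    gene_ids <- ids
    sample_ids <- colnames(expr_tab)[-1]
    m <- t(m)
  } else {
    sample_ids <- ids
    gene_ids <- colnames(expr_tab)[-1]
  }
  rownames(m) <- sample_ids
  colnames(m) <- gene_ids

  common <- intersect(sample_ids, as.character(clin$sample_id))
  if (length(common) == 0) {
    stop_sigceiling("sigceiling_empty_join_error",
                    "no samples shared between expression and clinical tables")
  }
  m <- m[common, , drop = FALSE]
  clin <- clin[match(common, as.character(clin$sample_id)), , drop = FALSE]

  bad_time <- !is.finite(clin$time) | clin$time <= 0
  if (any(bad_time)) {
    stop_sigceiling("sigceiling_validation_error",
                    paste0("non-positive or missing follow-up times for sample(s): ",
                           paste(common[bad_time], collapse = ", ")))
  }

  miss_rate <- colMeans(is.na(m))
  keep <- miss_rate <= missing_drop_threshold
  if (any(!keep)) {
    message(sprintf("dropping %d gene(s) with missing rate > %.0f%%",
                    sum(!keep), 100 * missing_drop_threshold))
    m <- m[, keep, drop = FALSE]
  }
  if (anyNA(m)) {
    for (j in which(colSums(is.na(m)) > 0)) {
      mj <- m[, j]
      mj[is.na(mj)] <- median(mj, na.rm = TRUE)
      m[, j] <- mj
    }
  }

  clin_extra <- clin[, setdiff(names(clin), c("time", "event")), drop = FALSE]
  expression_dataset(m, time = clin$time, event = clin$event, name = name,
                     endpoint = endpoint, clinical = clin_extra)
}

#' Write an expression dataset back to the two-file text format
#'
#' Inverse of [load_expression_dataset()]; useful for round-tripping
#' synthetic cohorts.
#'
#' @param ds an [expression_dataset()].
#' @param expr_path,clinical_path output paths (TSV).
#' @param genes_in_rows write genes in rows (default) or samples in rows.
#' @return Invisibly, `ds`.
#' @export
write_expression_dataset <- function(ds, expr_path, clinical_path,
                                     genes_in_rows = TRUE) {
  sample_ids <- rownames(ds$expression)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples(ds)))
  if (genes_in_rows) {
    out <- data.frame(gene_id = ds$gene_ids,
                      t(ds$expression), check.names = FALSE)
    colnames(out) <- c("gene_id", sample_ids)
  } else {
    out <- data.frame(sample_id = sample_ids, ds$expression,
                      check.names = FALSE)
  }
  write.table(out, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- data.frame(sample_id = sample_ids, time = ds$time, event = ds$event)
  if (!is.null(ds$clinical)) clin <- cbind(clin, ds$clinical)
  write.table(clin, clinical_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ds)
}

#' Apply the hormone-receptor-positive cohort filter
#'
#' Restricts a cohort to estrogen-receptor-positive patients under the age
#' of 70 who did not receive chemotherapy — the standard filter for
#' benchmarking signatures developed for hormone-receptor-positive breast
#' cancer without therapy or comorbidity effects. Samples with unknown or
#' missing values for any of the three criteria are excluded
#' (conservative cohort definition).
#'
#' @param ds an [expression_dataset()] whose `clinical` table has `age`,
#'   `er_status` and `chemotherapy` columns.
#' @return The filtered dataset; a message reports the count removed per
#'   criterion, and an empty result raises a warning.
#' @export
filter_cohort <- function(ds) {
  cl <- ds$clinical
  need <- c("er_status", "age", "chemotherapy")
  if (is.null(cl) || !all(need %in% names(cl))) {
    stop_sigceiling("sigceiling_configuration_error",
                    paste0("clinical covariates (", paste(need, collapse = ", "),
                           ") are required; to analyse an unfiltered cohort, ",
                           "skip filter_cohort() explicitly"))
  }
  er_ok <- !is.na(cl$er_status) & cl$er_status == "positive"
  age_ok <- !is.na(cl$age) & cl$age < 70
  chemo_ok <- !is.na(cl$chemotherapy) & cl$chemotherapy == "no"
  message(sprintf(
    "cohort filter [%s]: removed %d non-ER-positive, %d aged >= 70, %d with/unknown chemotherapy; %d of %d retained",
    ds$name, sum(!er_ok), sum(!age_ok), sum(!chemo_ok),
    sum(er_ok & age_ok & chemo_ok), n_samples(ds)))
  keep <- which(er_ok & age_ok & chemo_ok)
  if (length(keep) == 0) {
    warning("cohort filter removed every sample", call. = FALSE)
  }
  subset_samples(ds, keep)
}
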