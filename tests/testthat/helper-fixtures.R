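# Independent O(n^2) pair-enumeration oracle for Harrell's C, written as a
# plain double loop so it shares no code with the package's kernel.
oracle_c <- function(score, time, event) {
  conc <- tied <- comp <- 0
  n <- length(score)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (event[i] == 1 && time[i] < time[j]) {
        comp <- comp + 1
        if (score[i] > score[j]) {
          conc <- conc + 1
        } else if (score[i] == score[j]) {
          tied <- tied + 1
        }
      }
    }
  }
  if (comp == 0) return(NA_real_)
  (conc + 0.5 * tied) / comp
}

# Small random censored-survival instance, with optional score ties.
random_instance <- function(n, tie_scores = TRUE) {
  score <- rnorm(n)
  if (tie_scores) score <- round(score, 1)
  list(score = score,
       time = rexp(n) + 0.01,
       event = rbinom(n, 1, 0.6))
}

# Toy expression/clinical files written to a temp dir; returns the paths.
write_toy_cohort <- function(expr, sample_ids, gene_ids, time, event,
                             extra_clinical = NULL, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  expr_path <- file.path(dir, "expr.tsv")
  clin_path <- file.path(dir, "clinical.tsv")
  tab <- data.frame(gene_id = gene_ids, t(expr), check.names = FALSE)
  colnames(tab) <- c("gene_id", sample_ids)
  write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- data.frame(sample_id = sample_ids, time = time, event = event)
  if (!is.null(extra_clinical)) clin <- cbind(clin, extra_clinical)
  write.table(clin, clin_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = expr_path, clinical = clin_path)
}

# Dataset with a hand-built signal gene: gene "SIG" carries the latent
# factor at the given loading, all other genes at unit loading or pure
# noise, and the hazard follows the factor.
make_signal_dataset <- function(n = 200, p = 30, loading = 3,
                                n_loaded_rest = 0, seed = 42) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    x <- matrix(rnorm(n * p), n, p)
    if (n_loaded_rest > 0) {
      x[, seq_len(n_loaded_rest)] <- x[, seq_len(n_loaded_rest)] + z
    }
    sig <- loading * z + rnorm(n)
    x <- cbind(x, SIG = sig)
    gene_ids <- c(sprintf("G%04d", seq_len(p)), "SIG")
    t_event <- rexp(n, rate = log(2) / 10 * exp(z))
    t_cens <- rexp(n, rate = 0.05)
    expression_dataset(x, time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens),
                       name = "signal", gene_ids = gene_ids)
  })
}
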