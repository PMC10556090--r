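#' Replace a fraction of pixels with uniform noise
#'
#' Each pixel is independently replaced, with probability `p`, by a uniform
#' random integer in \[0, 255\]. `p = 0` returns the images unchanged;
#' `p = 1` replaces every pixel, making the output independent of the input
#' — the property that makes the noise fraction interpretable as the
#' fraction of missing information.
#'
#' @param sample an `image_sample`.
#' @param p noise fraction in \[0, 1\].
#' @param seed integer seed.
#' @return A noised `image_sample` with the same dimensions and source.
#' @export
add_noise <- function(sample, p, seed = 1) {
  stopifnot(inherits(sample, "image_sample"))
  if (!is.finite(p) || p < 0 || p > 1) {
    stop_sigceiling("sigceiling_validation_error",
                    "noise fraction p must lie in [0, 1]")
  }
  if (p == 0) return(sample)
  images <- sample$images
  withr::with_seed(seed, {
    flat <- as.integer(images)
    replace_mask <- runif(length(flat)) < p
    flat[replace_mask] <- sample.int(256, sum(replace_mask),
                                     replace = TRUE) - 1L
    images[] <- flat
  })
  image_sample(images, source = sample$source)
}

#' Reduce an image stack to its first two principal components
#'
#' Flattens each 28x28 image to a 784-vector, mean-centers pixel-wise, and
#' projects onto the first two principal components (eigenvectors of the
#' pixel covariance). Scores are standardized to unit variance by default
#' so the survival-skew coefficient acts on a fixed scale regardless of the
#' image source; signs are fixed so each loading's largest-magnitude entry
#' is positive (PCA is sign-ambiguous).
#'
#' @param sample an `image_sample`.
#' @param scale_scores standardize each component to unit variance
#'   (default `TRUE`).
#' @return An n x 2 matrix with columns `PC1`, `PC2`, carrying attributes
#'   `loadings` (784 x 2 orthonormal matrix) and `var_share` (fraction of
#'   total variance captured by the two components).
#' @export
reduce_pca2 <- function(sample, scale_scores = TRUE) {
  stopifnot(inherits(sample, "image_sample"))
  n <- dim(sample$images)[1]
  X <- matrix(as.numeric(sample$images), nrow = n)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  V <- ev$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  if (scale_scores) {
    sds <- apply(scores, 2, sd)
    sds[sds == 0] <- 1
    scores <- sweep(scores, 2, sds, "/")
  }
  colnames(scores) <- c("PC1", "PC2")
  attr(scores, "loadings") <- V
  attr(scores, "var_share") <-
    sum(pmax(ev$values[1:2], 0)) / sum(pmax(ev$values, 0))
  scores
}

#' Simulate survival times from two principal components
#'
#' Assigns each image the deterministic survival time
#' `T = MST * exp(S * (PC1 + PC2))`: MST is the median survival time
#' (years) reached at `PC1 + PC2 = 0`, and the skew coefficient S controls
#' how right-skewed the resulting time distribution is. No censoring is
#' applied.
#'
#' @param pcs n x 2 matrix of principal-component scores.
#' @param mst median survival time in years (default 10).
#' @param skew skew coefficient S (default 0.6, matching typical
#'   right-skewed survival-time distributions).
#' @return Numeric vector of positive survival times.
#' @export
simulate_survival <- function(pcs, mst = 10, skew = 0.6) {
  pcs <- as.matrix(pcs)
  stopifnot(ncol(pcs) == 2)
  as.numeric(mst * exp(skew * (pcs[, 1] + pcs[, 2])))
}

#' Normalized Shannon entropy of an image
#'
#' Histogram entropy of the pixel intensities over the 256 grey levels,
#' `H = -sum(p_k * log(p_k)) / log(256)` with `p_k` the fraction of pixels
#' at level k (empty levels contribute 0). A constant image has entropy 0;
#' an image using all levels as evenly as possible approaches 1.
#'
#' @param image integer matrix/vector of intensities in \[0, 255\].
#' @return A number in \[0, 1\].
#' @export
normalized_entropy <- function(image) {
  v <- as.integer(image)
  if (min(v) < 0 || max(v) > 255) {
    stop_sigceiling("sigceiling_validation_error",
                    "intensities must lie in [0, 255]")
  }
  p <- tabulate(v + 1L, nbins = 256L) / length(v)
  p <- p[p > 0]
  -sum(p * log(p)) / log(256)
}

mean_stack_entropy <- function(images) {
  n <- dim(images)[1]
  mean(vapply(seq_len(n), function(i) normalized_entropy(images[i, , ]),
              numeric(1)))
}

#' Configuration for the image-noise survival simulation
#'
#' @param n_images images drawn per repetition (default 2000, comparable
#'   to a large expression cohort).
#' @param mst median survival time in years (default 10).
#' @param skew survival skew coefficient S (default 0.6).
#' @param noise_levels ascending noise fractions in \[0, 1\].
#' @param reps repetitions per noise level (default 100).
#' @param seed integer seed.
#' @param ridge_theta ridge penalty stabilizing the two-covariate Cox fit;
#'   needed because at zero noise the survival times are a deterministic
#'   monotone function of the covariates and the unpenalized partial
#'   likelihood has no finite maximum.
#' @param scale_scores standardize PC scores before simulating times.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_images = 2000, mst = 10, skew = 0.6,
                              noise_levels = seq(0, 1, by = 0.1),
                              reps = 100, seed = 1, ridge_theta = 1,
                              scale_scores = TRUE) {
  if (is.unsorted(noise_levels) || min(noise_levels) < 0 ||
      max(noise_levels) > 1) {
    stop_sigceiling("sigceiling_validation_error",
                    "noise_levels must be ascending within [0, 1]")
  }
  structure(list(n_images = as.integer(n_images), mst = mst, skew = skew,
                 noise_levels = noise_levels, reps = as.integer(reps),
                 seed = as.integer(seed), ridge_theta = ridge_theta,
                 scale_scores = scale_scores),
            class = "simulation_config")
}

# Ridge-stabilized two-covariate Cox fit; returns the in-sample C-index of
# its risk score against the supplied (uncensored) times.
cox_pc_cindex <- function(pcs, times, ridge_theta) {
  pc1 <- pcs[, 1]; pc2 <- pcs[, 2]
  ev <- rep(1L, length(times))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(times, ev) ~ survival::ridge(pc1, pc2,
                                                  theta = ridge_theta))),
    error = function(e) NULL)
  score <- if (is.null(fit) || anyNA(coef(fit))) {
    rep(0, length(times))
  } else {
    as.numeric(cbind(pc1, pc2) %*% coef(fit))
  }
  harrell_c_or_na(score, times, ev)
}

#' Simulated C-index as a function of image noise
#'
#' The core of the missing-information analysis. Per repetition: draw
#' `n_images` images from the stack, define each image's true survival time
#' from its noise-free principal components via
#' `T = MST * exp(S * (PC1 + PC2))`; then, for every noise level, replace
#' that fraction of pixels with uniform noise, recompute the two principal
#' components on the noised stack, fit a ridge-stabilized two-covariate Cox
#' model of the true times on the noisy components, and record Harrell's C
#' (in-sample; with two covariates and thousands of samples the optimism is
#' negligible). Per noise level the curve reports the median C over
#' repetitions, the standard error of the median, and the mean normalized
#' pixel entropy of the noised images. The noise percentage equals the
#' missing-information percentage; initial information is 100% minus it.
#'
#' @param sample an `image_sample` (synthetic digits or an IDX file).
#' @param cfg a [simulation_config()].
#' @return A data.frame of class `noise_curve` with columns `noise`,
#'   `median_c`, `se_median`, `mean_entropy`, `missing_info_pct`,
#'   `initial_information_pct`, and attribute `c_reps` (reps x levels
#'   matrix of raw C-indices).
#' @export
cindex_vs_noise <- function(sample, cfg = simulation_config()) {
  stopifnot(inherits(sample, "image_sample"),
            inherits(cfg, "simulation_config"))
  n_stack <- dim(sample$images)[1]
  n_lv <- length(cfg$noise_levels)
  c_mat <- matrix(NA_real_, nrow = cfg$reps, ncol = n_lv)
  entropy <- rep(NA_real_, n_lv)
  for (r in seq_len(cfg$reps)) {
    idx <- withr::with_seed(
      derive_seed(cfg$seed, r),
      sample.int(n_stack, cfg$n_images, replace = n_stack < cfg$n_images))
    imgs <- image_sample(sample$images[idx, , , drop = FALSE],
                         source = sample$source)
    pcs0 <- reduce_pca2(imgs, scale_scores = cfg$scale_scores)
    times <- simulate_survival(pcs0, mst = cfg$mst, skew = cfg$skew)
    for (l in seq_len(n_lv)) {
      noised <- add_noise(imgs, cfg$noise_levels[l],
                          seed = derive_seed(cfg$seed, r, l))
      pcs <- reduce_pca2(noised, scale_scores = cfg$scale_scores)
      c_mat[r, l] <- cox_pc_cindex(pcs, times, cfg$ridge_theta)
      if (r == 1) entropy[l] <- mean_stack_entropy(noised$images)
    }
  }
  curve <- data.frame(
    noise = cfg$noise_levels,
    median_c = apply(c_mat, 2, median, na.rm = TRUE),
    # asymptotic standard error of the median
    se_median = apply(c_mat, 2, function(x) {
      1.2533 * sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
    }),
    mean_entropy = entropy,
    missing_info_pct = 100 * cfg$noise_levels,
    initial_information_pct = 100 - 100 * cfg$noise_levels)
  attr(curve, "c_reps") <- c_mat
  attr(curve, "config") <- cfg
  class(curve) <- c("noise_curve", class(curve))
  curve
}

#' Pair median C-index with mean image entropy per noise level
#'
#' @param curve a `noise_curve` from [cindex_vs_noise()].
#' @return data.frame with columns `mean_entropy`, `median_c`.
#' @export
cindex_vs_entropy <- function(curve) {
  stopifnot(inherits(curve, "noise_curve"))
  data.frame(mean_entropy = curve$mean_entropy, median_c = curve$median_c)
}

#' Missing and initial information of a noise fraction
#'
#' The injected noise percentage is, by construction of the noise model,
#' the percentage of missing information; initial information is its
#' complement, so the two always sum to 100%.
#'
#' @param noise_fraction noise fraction(s) in \[0, 1\].
#' @return Percentage value(s).
#' @export
missing_information <- function(noise_fraction) 100 * noise_fraction

#' @rdname missing_information
#' @export
initial_information <- function(noise_fraction) 100 - 100 * noise_fraction

#' Interpolate the noise level at which the curve reaches a target C
#'
#' Linear interpolation of noise against median C along the (monotonically
#' degrading) curve; used to read off, e.g., how much information is
#' missing where the median C equals 0.75.
#'
#' @param curve a `noise_curve`.
#' @param c_target target C-index value.
#' @return Interpolated noise fraction (NA when the target is outside the
#'   curve's range).
#' @export
noise_at_cindex <- function(curve, c_target) {
  stopifnot(inherits(curve, "noise_curve"))
  ord <- order(curve$median_c)
  stats::approx(x = curve$median_c[ord], y = curve$noise[ord],
                xout = c_target, ties = "ordered")$y
}
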