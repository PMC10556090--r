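# Seven-segment stroke layout on a 28x28 canvas. Each digit lights a
# subset of seven line segments; rendering draws each segment with a soft
# Gaussian pen, so images have digit-like low-dimensional structure
# (class identity plus a few affine nuisance parameters).
segment_endpoints <- function() {
  list(
    A = c(9, 5, 20, 5), B = c(20, 5, 20, 14), C = c(20, 14, 20, 23),
    D = c(9, 23, 20, 23), E = c(9, 14, 9, 23), F = c(9, 5, 9, 14),
    G = c(9, 14, 20, 14)
  )
}

digit_segments <- function() {
  list(`0` = c("A", "B", "C", "D", "E", "F"),
       `1` = c("B", "C"),
       `2` = c("A", "B", "G", "E", "D"),
       `3` = c("A", "B", "G", "C", "D"),
       `4` = c("F", "G", "B", "C"),
       `5` = c("A", "F", "G", "C", "D"),
       `6` = c("A", "F", "G", "E", "C", "D"),
       `7` = c("A", "B", "C"),
       `8` = c("A", "B", "C", "D", "E", "F", "G"),
       `9` = c("A", "B", "C", "D", "F", "G"))
}

#' Generate synthetic digit-like images
#'
#' Renders `n` 28x28 grey-scale images of seven-segment digits (0-9, drawn
#' uniformly) with random affine jitter — translation, scaling, rotation —
#' plus random pen width and stroke brightness. The resulting stack has the
#' two properties the missing-information simulation needs from real
#' handwritten digits: intensities in \[0, 255\] and genuine low-dimensional
#' structure, so the leading principal components are non-degenerate.
#' Deterministic given the seed.
#'
#' @param n number of images (at least 2).
#' @param seed integer seed.
#' @return An `image_sample` with source `"synthetic"`.
#' @export
generate_synthetic_digits <- function(n, seed = 1) {
  segs <- segment_endpoints()
  dmap <- digit_segments()
  px <- expand.grid(x = seq_len(28), y = seq_len(28))
  withr::with_seed(seed, {
    images <- array(0L, dim = c(n, 28, 28))
    digits <- sample(0:9, n, replace = TRUE)
    for (i in seq_len(n)) {
      shift <- rnorm(2, sd = 1.2)
      sc <- runif(1, 0.85, 1.15)
      th <- runif(1, -0.2, 0.2)
      pen <- runif(1, 1.0, 1.6)
      amp <- runif(1, 180, 255)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      d2min <- rep(Inf, nrow(px))
      for (s in dmap[[as.character(digits[i])]]) {
        e <- segs[[s]]
        p1 <- rot %*% (sc * (e[1:2] - c(14.5, 14))) + c(14.5, 14) + shift
        p2 <- rot %*% (sc * (e[3:4] - c(14.5, 14))) + c(14.5, 14) + shift
        v <- p2 - p1
        len2 <- sum(v^2)
        tt <- ((px$x - p1[1]) * v[1] + (px$y - p1[2]) * v[2]) / len2
        tt <- pmin(pmax(tt, 0), 1)
        d2 <- (px$x - (p1[1] + tt * v[1]))^2 + (px$y - (p1[2] + tt * v[2]))^2
        d2min <- pmin(d2min, d2)
      }
      img <- amp * exp(-d2min / (2 * pen^2))
      # px enumerates x (columns) fastest; store as [row, col]
      images[i, , ] <- matrix(as.integer(round(pmin(pmax(img, 0), 255))),
                              28, 28, byrow = TRUE)
    }
    out <- image_sample(images, source = "synthetic")
    attr(out, "digit") <- digits
    out
  })
}
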