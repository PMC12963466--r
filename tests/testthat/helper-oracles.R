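# Independent oracles used across test files. These deliberately use the
# dumbest correct algorithm (enumeration, brute force, textbook Newton
# iterations) and never call the package internals they check.

# all-pairs Feret diameter over every pixel center of a mask
feret_all_pairs <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(0)
  pts <- cbind((idx[, 1] - 1) * spacing[1], (idx[, 2] - 1) * spacing[2])
  best <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    d <- sqrt((pts[i, 1] - pts[-(1:i), 1])^2 + (pts[i, 2] - pts[-(1:i), 2])^2)
    best <- max(best, d)
  }
  best
}

# brute-force circle statistics by scanning every pixel
circle_stats_brute <- function(slice, spacing, center, radius) {
  vals <- c()
  for (i in seq_len(nrow(slice))) {
    for (j in seq_len(ncol(slice))) {
      d <- sqrt(((i - 1) * spacing[1] - center[1])^2 +
                ((j - 1) * spacing[2] - center[2])^2)
      if (d < radius) vals <- c(vals, slice[i, j])
    }
  }
  list(mean = mean(vals), max = max(vals), n_pixels = length(vals))
}

# Newton-Raphson maximum likelihood for logit P(y=1) = b0 + b1 * x
newton_logistic <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (it in seq_len(maxit)) {
    p <- plogis(drop(X %*% b))
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) < tol) break
    H <- crossprod(X, X * (p * (1 - p)))
    b <- b + solve(H, score)
  }
  unname(b)
}

# numeric convolution of a 1D top-hat with a Gaussian on a fine grid
tophat_blur_numeric <- function(x, a, sigma, h = 0.002) {
  g <- seq(-6 * sigma, 6 * sigma, by = h)
  k <- dnorm(g, sd = sigma); k <- k / sum(k)
  vapply(x, function(xi) sum(k * (abs(xi - g) <= a)), numeric(1))
}
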