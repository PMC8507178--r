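# Exact t-distributed stochastic neighbour embedding (O(n^2)).
#
# Written for desk-scale chemical-space maps (hundreds to a few thousand
# molecules described by 1024-bucket count fingerprints). The layout is a
# qualitative visualization; no quantitative claim is derived from it, so
# the implementation favours clarity: exact pairwise affinities with
# per-point perplexity calibration, early exaggeration, and momentum
# gradient descent from a seeded Gaussian initialization.

#' t-SNE embedding of a numeric matrix
#'
#' @param x numeric matrix (rows = objects).
#' @param perplexity target perplexity (effective neighbour count).
#' @param n_iter gradient-descent iterations.
#' @param seed RNG seed for the initial layout.
#' @return an n x 2 matrix of coordinates.
#' @export
tsne_embed <- function(x, perplexity = 30, n_iter = 500, seed = 42) {
  n <- nrow(x)
  if (n < 4) stop("t-SNE needs at least 4 points")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  d2 <- as.matrix(stats::dist(x))^2
  p <- .tsne_affinities(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)

  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  eta <- 200
  for (iter in seq_len(n_iter)) {
    pe <- if (iter <= 100) p * 4 else p   # early exaggeration
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    mult <- (pe - q) * num
    grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - eta * gain * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
    if (iter == 250) momentum <- 0.8
  }
  y
}

# per-point precision calibration by bisection on perplexity
.tsne_affinities <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    di <- d2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      h <- log(sw) + beta * sum(di * w) / sw
      if (abs(h - target) < 1e-5) break
      if (h > target) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- w / sum(w)
  }
  p
}
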