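# Independent oracles used across the suite.

# Brute-force point-to-hull distance by grid search over barycentric
# coordinates. The objective is convex on the simplex, so a coarse
# composition grid contracted repeatedly around the incumbent converges
# to the global minimum; the final resolution is far below the 1e-2
# comparison tolerance.
brute_hull_distance <- function(x_star, points, rounds = 7, res = 12) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 1) return(sqrt(sum((x_star - points[1, ])^2)))
  Zt <- t(points)
  # all compositions of `res` into n parts, as columns summing to 1
  grid <- as.matrix(expand.grid(rep(list(0:res), n - 1)))
  grid <- grid[rowSums(grid) <= res, , drop = FALSE]
  lam_grid <- t(cbind(grid, res - rowSums(grid)) / res)    # n x m
  center <- rep(1 / n, n)
  alpha <- 1
  best <- Inf
  for (r in seq_len(rounds)) {
    lam <- (1 - alpha) * center + alpha * lam_grid          # shrunken simplex
    W <- Zt %*% lam                                         # dim x m
    d2 <- colSums((W - x_star)^2)
    j <- which.min(d2)
    if (d2[j] < best) {
      best <- d2[j]
      center <- lam[, j]
    }
    alpha <- alpha / 2.5
  }
  sqrt(best)
}

# Plain 1-nearest-neighbour by exhaustive distance comparison
# (first index wins ties).
one_nn_predict <- function(train_x, train_y, test_x) {
  apply(test_x, 1, function(q) {
    train_y[which.min(colSums((t(train_x) - q)^2))]
  })
}

# Binary entropy in bits.
h_bits <- function(p) {
  p <- c(p, 1 - p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Random exact joint table (Dirichlet-flat over all cells).
random_joint <- function(nx, ny) {
  g <- matrix(rgamma(nx * ny, 1), nx, ny)
  discrete_joint(g / sum(g))
}

# Small noiseless fixtures shared by inversion tests.
toy_grid <- function() default_grid(3, 3, 3)
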