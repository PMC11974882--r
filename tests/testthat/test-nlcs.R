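test_that("class neighbourhoods pick the nearest same-class points deterministically", {
  x <- rbind(c(0, 0), c(1, 0), c(5, 5), c(10, 10))
  m <- nlcs_fit(x, c("a", "a", "a", "b"), k = 2)
  nb <- class_neighborhood(m, c(0.4, 0), "a")
  expect_equal(nb$index, c(1, 2))
  expect_equal(nb$points, x[1:2, ])
  # k >= class size returns the whole class
  m5 <- nlcs_fit(x, c("a", "a", "a", "b"), k = 5)
  expect_equal(class_neighborhood(m5, c(0, 0), "a")$index, c(1, 2, 3))
  expect_equal(class_neighborhood(m5, c(9, 9), "b")$index, 4)
  # distance ties break toward the lower training index
  xt <- rbind(c(1, 0), c(-1, 0), c(0, 1))
  mt <- nlcs_fit(xt, rep("a", 3), k = 1)
  expect_equal(class_neighborhood(mt, c(0, 0), "a")$index, 1)
  expect_error(class_neighborhood(m, c(0, 0), "zz"), "unknown class")
  expect_error(class_neighborhood(m, c(0, 0, 0), "a"), "dimension")
})

test_that("hull distance solves hand-constructed geometries to 1e-7", {
  # interior point
  hd <- hull_distance(c(0, 0), rbind(c(1, 0), c(-1, 1), c(-1, -1)))
  expect_lt(hd$distance, 1e-7)
  # degenerate single-point hull
  hd1 <- hull_distance(c(3, 4), rbind(c(0, 0)))
  expect_equal(hd1$distance, 5)
  expect_equal(hd1$weights, 1)
  # projection onto the nearest edge of a triangle
  hd2 <- hull_distance(c(2, 0), rbind(c(0, 1), c(0, -1), c(-1, 0)))
  expect_equal(hd2$distance, 2, tolerance = 1e-7)
  expect_equal(hd2$witness, c(0, 0), tolerance = 1e-7)
  # projection onto a vertex
  hd3 <- hull_distance(c(2, 2), rbind(c(0, 1), c(0, -1), c(-1, 0)))
  expect_equal(hd3$distance, sqrt(4 + 1), tolerance = 1e-7)
  expect_equal(hd3$weights[1], 1, tolerance = 1e-7)
  # duplicated vertices do not break the KKT polish
  hd4 <- hull_distance(c(2, 0), rbind(c(0, 1), c(0, 1), c(0, -1)))
  expect_equal(hd4$distance, 2, tolerance = 1e-7)
  expect_error(hull_distance(c(1, 2, 3), rbind(c(0, 1))), "dimension")
  expect_error(hull_distance(c(1, 0), rbind(c(0, 1)), p = 1), "p = 2")
})

test_that("hull distance weights are barycentric and reproduce the witness", {
  set.seed(31)
  for (i in 1:60) {
    dim <- sample(2:5, 1)
    n <- sample(1:6, 1)
    pts <- matrix(rnorm(n * dim), n, dim)
    x <- rnorm(dim) * 2
    hd <- hull_distance(x, pts)
    expect_true(all(hd$weights >= -1e-9))
    expect_lt(abs(sum(hd$weights) - 1), 1e-9)
    expect_lt(max(abs(hd$witness - as.numeric(t(pts) %*% hd$weights))), 1e-7)
    expect_lt(abs(sqrt(sum((x - hd$witness)^2)) - hd$distance), 1e-7)
  }
})

test_that("hull distance agrees with the simplex-grid brute-force oracle", {
  set.seed(32)
  for (i in 1:60) {
    dim <- sample(2:5, 1)
    n <- sample(2:6, 1)
    pts <- matrix(rnorm(n * dim), n, dim)
    x <- rnorm(dim) * 1.5
    expect_lt(abs(hull_distance(x, pts)$distance -
                    brute_hull_distance(x, pts)), 1e-2)
  }
})

test_that("fitting stores class partitions and round-trips labels", {
  set.seed(33)
  x <- matrix(rnorm(20), 10, 2)
  y <- c("b", "a", "b", "a", "b", "a", "b", "a", "b", "b")
  m <- nlcs_fit(x, y, k = 3)
  expect_equal(m$levels, c("a", "b"))                # canonical sorted order
  expect_equal(sum(lengths(m$class_index)), 10)
  expect_equal(m$class_index$a, which(y == "a"))
  # duplicate rows are preserved, not collapsed
  xd <- rbind(x, x[1, ])
  md <- nlcs_fit(xd, c(y, "b"), k = 3)
  expect_equal(nrow(md$x), 11)
  expect_error(nlcs_fit(x, y, k = 0), "k must be")
  expect_error(nlcs_fit(x[0, , drop = FALSE], character(0)), "empty")
  expect_error(nlcs_fit(x, y, p = 3), "p = 2")
})

test_that("prediction assigns the class with the nearest local hull", {
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5), c(5, 6))
  y <- rep(c("a", "b"), each = 3)
  m <- nlcs_fit(x, y, k = 3)
  # a training point of class a, k = 1: distance 0 to its own class
  m1 <- nlcs_fit(x, y, k = 1)
  p1 <- predict(m1, x[1, ])
  expect_equal(as.character(p1), "a")
  expect_equal(unname(attr(p1, "distances")[1, "a"]), 0)
  # interior of class b's local hull, far from class a
  pb <- predict(m, c(5.3, 5.3))
  expect_equal(as.character(pb), "b")
  expect_lt(attr(pb, "distances")[1, "b"], 1e-7)
  expect_gt(attr(pb, "distances")[1, "a"], 1)
})

test_that("NLCS with k = 1 is exactly 1-nearest-neighbour", {
  set.seed(34)
  for (i in 1:20) {
    n <- 30; dim <- sample(2:4, 1)
    x <- matrix(rnorm(n * dim), n, dim)
    y <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    xt <- matrix(rnorm(10 * dim), 10, dim)
    m <- nlcs_fit(x, y, k = 1)
    expect_equal(as.character(predict(m, xt)), one_nn_predict(x, y, xt))
  }
})

test_that("predictions are scale-equivariant and order-invariant", {
  set.seed(35)
  x <- matrix(rnorm(60), 30, 2)
  y <- rep(c("a", "b"), 15)
  xt <- matrix(rnorm(20), 10, 2)
  m <- nlcs_fit(x, y, k = 4)
  p0 <- predict(m, xt)
  # scaling all coordinates by c > 0 scales distances by c, labels unchanged
  for (c_scale in c(0.01, 7)) {
    pc <- predict(nlcs_fit(c_scale * x, y, k = 4), c_scale * xt)
    expect_equal(as.character(pc), as.character(p0))
    expect_equal(attr(pc, "distances"), c_scale * attr(p0, "distances"),
                 tolerance = 1e-6)
  }
  # shuffling the training order changes no prediction (no exact ties here)
  perm <- sample(30)
  pp <- predict(nlcs_fit(x[perm, ], y[perm], k = 4), xt)
  expect_equal(as.character(pp), as.character(p0))
})

test_that("NLCS separates concentric rings where a linear classifier fails", {
  set.seed(36)
  ring <- function(n, r) {
    th <- runif(n, 0, 2 * pi)
    rr <- r + rnorm(n, 0, 0.05)
    cbind(rr * cos(th), rr * sin(th))
  }
  xtr <- rbind(ring(100, 1), ring(100, 3))
  ytr <- rep(c("inner", "outer"), each = 100)
  xte <- rbind(ring(50, 1), ring(50, 3))
  yte <- rep(c("inner", "outer"), each = 50)
  m <- nlcs_fit(xtr, ytr, k = 5)
  acc_nlcs <- mean(as.character(predict(m, xte)) == yte)
  expect_gte(acc_nlcs, 0.98)
  lda <- MASS::lda(xtr, grouping = factor(ytr))
  acc_lda <- mean(as.character(predict(lda, xte)$class) == yte)
  expect_lte(acc_lda, 0.60)
})
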