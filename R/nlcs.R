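#' Fit a K-nearest local convex set (NLCS) classifier
#'
#' NLCS is a lazy, geometry-driven classifier. To label a query point
#' \eqn{x^*} it takes, for every class \eqn{C_i}, the k training points of
#' that class nearest to \eqn{x^*}, forms their convex hull, and assigns
#' the class whose local hull is closest:
#' \deqn{h(x^*) = \arg\min_i \ \min \| x^* - \mathrm{conv}(Z_k^i(x^*)) \|_p.}
#' No decision boundary is learned: fitting only stores the training data
#' partitioned by class, so the method handles highly non-linear class
#' geometries (rings, moons, manifolds) that defeat linear classifiers,
#' at the cost of keeping the data around.
#'
#' With \code{k = 1} each local hull is a single point and NLCS reduces
#' exactly to the 1-nearest-neighbour rule.
#'
#' @param x numeric feature matrix (one row per training point) or data
#'   frame of numeric columns.
#' @param y class labels (factor, character or integer), one per row of
#'   \code{x}. Internally levels are stored in sorted canonical order;
#'   predictions are returned as a factor on the original levels.
#' @param k neighbourhood size (>= 1). Classes with fewer than \code{k}
#'   points use all their points.
#' @param p norm order for the point-to-hull distance. Only the Euclidean
#'   norm \code{p = 2} is implemented (the point-to-hull projection is
#'   then a convex quadratic program); any other value errors.
#' @return An object of class \code{nlcs}.
#' @seealso [predict.nlcs()], [hull_distance()], [class_neighborhood()]
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' m <- nlcs_fit(x, rep(c("a", "b"), each = 20), k = 3)
#' predict(m, rbind(c(0, 0), c(3, 3)))
nlcs_fit <- function(x, y, k = 5, p = 2) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0) stop("empty training set")
  if (nrow(x) != length(y)) stop("x and y must have the same length")
  if (!is.numeric(k) || length(k) != 1 || k < 1) stop("k must be >= 1")
  if (p != 2) stop("only the Euclidean norm (p = 2) is implemented")
  y <- factor(y)                       # canonical sorted level order
  if (any(table(y) == 0)) y <- droplevels(y)
  structure(list(x = x, y = y, levels = levels(y),
                 class_index = split(seq_len(nrow(x)), y),
                 k = as.integer(k), p = p),
            class = "nlcs")
}

#' K-nearest same-class neighbourhood of a query point
#'
#' Returns the \code{min(k, |C_i|)} training points of one class nearest
#' to \code{x_star} in the Euclidean norm. Distance ties are broken by
#' training-set insertion order (lower row index first), so the result is
#' deterministic.
#'
#' @param model an [nlcs_fit()] model.
#' @param x_star numeric query vector.
#' @param class_index integer position of the class in the model's sorted
#'   level order, or a class label.
#' @return A list with \code{points} (rows of the training matrix, nearest
#'   first), \code{index} (their row indices) and \code{dist}.
#' @export
class_neighborhood <- function(model, x_star, class_index) {
  stopifnot(inherits(model, "nlcs"))
  if (is.character(class_index) || is.factor(class_index))
    class_index <- match(as.character(class_index), model$levels)
  if (is.na(class_index) || class_index < 1 || class_index > length(model$levels))
    stop("unknown class")
  idx <- model$class_index[[class_index]]
  if (length(idx) == 0) stop("class has no training points")
  x_star <- as.numeric(x_star)
  if (length(x_star) != ncol(model$x))
    stop("query dimension does not match training features")
  d2 <- colSums((t(model$x[idx, , drop = FALSE]) - x_star)^2)
  ord <- order(d2)                     # stable: ties keep insertion order
  take <- ord[seq_len(min(model$k, length(idx)))]
  list(points = model$x[idx[take], , drop = FALSE],
       index = idx[take], dist = sqrt(d2[take]))
}

#' Euclidean distance from a point to the convex hull of a point set
#'
#' Solves the simplex-constrained least-squares problem
#' \deqn{\min_{\lambda \ge 0,\ \sum_j \lambda_j = 1}
#'       \big\| x^* - \textstyle\sum_j \lambda_j z_j \big\|_2,}
#' a convex quadratic program. The sum-to-one constraint is folded into a
#' non-negative least-squares problem via a heavily weighted extra row
#' (Lawson-Hanson trick) to identify the active support, after which the
#' solution is polished to machine precision by solving the
#' equality-constrained KKT system on the support, with active-set
#' corrections if the support was misidentified.
#'
#' @param x_star numeric query vector.
#' @param points matrix of hull vertices, one per row (at least one), with
#'   \code{ncol == length(x_star)}.
#' @param p norm order; only 2 is implemented.
#' @param tol optimality tolerance for the KKT conditions.
#' @return A list of class \code{hull_distance} with \code{distance},
#'   \code{weights} (barycentric coordinates, non-negative, summing to 1)
#'   and \code{witness} (the projection \eqn{\sum_j \lambda_j z_j}).
#' @export
#' @examples
#' hull_distance(c(2, 0), rbind(c(0, 1), c(0, -1), c(-1, 0)))$distance  # 2
hull_distance <- function(x_star, points, p = 2, tol = 1e-8) {
  if (p != 2) stop("only the Euclidean norm (p = 2) is implemented")
  x_star <- as.numeric(x_star)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 1) stop("need at least one hull point")
  if (ncol(points) != length(x_star))
    stop("query and hull points have different dimensions")
  n <- nrow(points)
  if (n == 1) {
    w <- as.numeric(points[1, ])
    return(structure(list(distance = sqrt(sum((x_star - w)^2)),
                          weights = 1, witness = w),
                     class = "hull_distance"))
  }
  Zt <- t(points)                                    # dim x n
  # distance to a vertex of zero is an exact, cheap answer
  v2 <- colSums((Zt - x_star)^2)
  if (min(v2) == 0) {
    j <- which.min(v2)
    lam <- numeric(n); lam[j] <- 1
    return(structure(list(distance = 0, weights = lam,
                          witness = as.numeric(points[j, ])),
                     class = "hull_distance"))
  }
  # the problem is translation and scale invariant: centre at the query
  # and normalise by the point-cloud radius so all tolerances are relative
  s0 <- sqrt(max(v2))
  Zc <- (Zt - x_star) / s0                           # dim x n, O(1) entries
  # warm start from the weighted-equality NNLS trick
  fit <- tryCatch(pracma::lsqnonneg(rbind(Zc, 1e4),
                                    c(numeric(length(x_star)), 1e4)),
                  error = function(e) NULL)
  support <- if (!is.null(fit) && any(fit$x > 0)) {
    which(fit$x > 1e-10 * max(fit$x))
  } else {
    which.min(v2)                        # cold start: nearest vertex
  }

  G <- crossprod(Zc)                                 # Gram matrix, n x n
  kkt_solve <- function(S) {
    m <- length(S)
    A <- rbind(cbind(G[S, S, drop = FALSE], 1), c(rep(1, m), 0))
    rhs <- c(numeric(m), 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) MASS::ginv(A) %*% rhs)
    list(lambda = as.numeric(sol[seq_len(m)]), mu = as.numeric(sol[m + 1]))
  }
  for (iter in seq_len(4 * n + 8)) {
    ks <- kkt_solve(support)
    # drop negative components until primal feasible on the support
    while (any(ks$lambda < -tol) && length(support) > 1) {
      support <- support[-which.min(ks$lambda)]
      ks <- kkt_solve(support)
    }
    lam <- numeric(n); lam[support] <- pmax(ks$lambda, 0)
    lam <- lam / sum(lam)
    wc <- as.numeric(Zc %*% lam)                     # centred witness
    # dual feasibility: g_j + mu >= 0 for all vertices, g_j = z_j' w_c
    g <- as.numeric(crossprod(Zc, wc))
    mu <- -mean(g[support])
    viol <- g + mu
    worst <- which.min(viol)
    if (viol[worst] >= -tol || worst %in% support) break
    support <- sort(c(support, worst))
  }
  dn <- sqrt(sum(wc^2))
  if (dn < 1e-9) dn <- 0               # interior point, scale-stable zero
  structure(list(distance = s0 * dn,
                 weights = lam, witness = x_star + s0 * wc),
            class = "hull_distance")
}

#' @export
print.hull_distance <- function(x, ...) {
  cat(sprintf("point-to-hull distance %.6g (%d active vertices)\n",
              x$distance, sum(x$weights > 1e-10)))
  invisible(x)
}

#' Predict class labels with an NLCS model
#'
#' For each query row the distance to every class's local convex hull is
#' computed and the nearest class wins; exact distance ties are broken
#' toward the smaller class index in the model's sorted level order.
#'
#' @param object an [nlcs_fit()] model.
#' @param newdata numeric matrix (or single vector) of query points.
#' @param ... unused.
#' @return A factor of predicted labels with attribute
#'   \code{"distances"}: the n x M matrix of per-class hull distances for
#'   audit.
#' @export
predict.nlcs <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop("newdata dimension does not match training features")
  M <- length(object$levels)
  D <- matrix(NA_real_, nrow(newdata), M,
              dimnames = list(NULL, object$levels))
  for (r in seq_len(nrow(newdata))) {
    xq <- newdata[r, ]
    for (i in seq_len(M)) {
      nb <- class_neighborhood(object, xq, i)
      D[r, i] <- hull_distance(xq, nb$points, p = object$p)$distance
    }
  }
  pred <- factor(object$levels[max.col(-D, ties.method = "first")],
                 levels = object$levels)
  attr(pred, "distances") <- D
  pred
}

#' @export
print.nlcs <- function(x, ...) {
  cat(sprintf("NLCS classifier: %d training points, %d features, %d classes, k = %d, p = %g\n",
              nrow(x$x), ncol(x$x), length(x$levels), x$k, x$p))
  cat("  class sizes:", paste(sprintf("%s=%d", x$levels,
                                      lengths(x$class_index)), collapse = ", "), "\n")
  invisible(x)
}
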