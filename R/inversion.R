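#' Invert a signal to a T1-T2-D spectrum
#'
#' Solves the regularized non-negative least-squares problem
#' \deqn{\tilde f = \arg\min_{f \ge 0} \|s - K_0 f\|_2^2 + \lambda \|f\|_2^2}
#' by running the Lawson-Hanson active-set solver on the Tikhonov-augmented
#' system \code{rbind(K0, sqrt(lambda) * I)}. The inversion of the Fredholm
#' system is ill-posed: solutions are non-unique and noise-sensitive, and
#' the ridge penalty trades residual for conditioning. \code{lambda = 0}
#' gives plain NNLS.
#'
#' Residual norms are measured in the Euclidean (p = 2) norm, the only
#' choice with a standard non-negative solver; other residual norms are
#' not supported.
#'
#' @param signal a [simulate_signal()] result or plain numeric vector of
#'   length \code{nrow(kernel)}.
#' @param kernel a [build_kernel()] result.
#' @param lambda non-negative Tikhonov weight.
#' @return An [md_spectrum()] with an attribute \code{inversion}: a list
#'   with the data residual \code{residual} (\eqn{\|s - K_0 \tilde f\|_2}),
#'   \code{lambda}, and the solution norm. Deterministic for fixed inputs.
#' @seealso [choose_lambda()] for data-driven selection of \code{lambda},
#'   [marginalize()] for the 2D correlation maps.
#' @export
invert_signal <- function(signal, kernel, lambda = 0) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  s <- as.numeric(signal)
  K <- unclass(kernel)
  if (length(s) != nrow(K))
    stop(sprintf("signal length %d does not match kernel rows %d",
                 length(s), nrow(K)))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || !is.finite(lambda))
    stop("lambda must be a single non-negative number")
  n <- ncol(K)
  if (all(s == 0)) {
    f <- numeric(n)                      # zero is the unique minimizer
  } else if (lambda == 0) {
    f <- nnls_solve(K, s)
  } else {
    A <- matrix(0, nrow(K) + n, n)
    A[seq_len(nrow(K)), ] <- K
    A[cbind(nrow(K) + seq_len(n), seq_len(n))] <- sqrt(lambda)
    f <- nnls_solve(A, c(s, numeric(n)))
  }
  res <- sqrt(sum((s - K %*% f)^2))
  out <- md_spectrum(attr(kernel, "grid"), f)
  attr(out, "inversion") <- list(residual = res, lambda = lambda,
                                 solution_norm = sqrt(sum(f^2)))
  out
}

# Lawson-Hanson NNLS with loud failure (the benchmark never imputes).
nnls_solve <- function(A, b) {
  r <- tryCatch(pracma::lsqnonneg(A, b),
                error = function(e) stop("NNLS solver failed: ",
                                         conditionMessage(e), call. = FALSE))
  x <- r$x
  x[x < 0] <- 0                          # guard against solver round-off
  x
}

#' L-curve selection of the regularization weight
#'
#' Solves the inversion over a grid of candidate \code{lambda} values and
#' picks the corner of the L-curve: the point of maximum Menger curvature
#' of the (log residual norm, log solution norm) curve. Curvature ties are
#' broken toward the larger \code{lambda}. If the system is consistent at
#' the smallest candidate (relative residual below \code{consistent_tol})
#' regularization buys nothing and the smallest candidate is returned; if
#' all residuals are equal the L-curve is degenerate and the smallest
#' candidate is returned with \code{degenerate = TRUE}.
#'
#' @inheritParams invert_signal
#' @param lambda_grid positive candidate values (any order; sorted
#'   internally).
#' @param consistent_tol relative-residual threshold below which the
#'   unregularized fit is accepted outright.
#' @return A list with \code{lambda} (the choice), \code{curve} (a data
#'   frame of all candidates with residual and solution norms and
#'   curvature, for audit) and \code{degenerate}.
#' @export
choose_lambda <- function(signal, kernel, lambda_grid,
                          consistent_tol = 1e-8) {
  lambda_grid <- sort(as.numeric(lambda_grid))
  if (length(lambda_grid) < 1 || any(lambda_grid <= 0) || anyNA(lambda_grid))
    stop("lambda_grid must be a non-empty vector of positive values")
  s <- as.numeric(signal)
  fits <- lapply(lambda_grid, function(l) attr(invert_signal(s, kernel, l),
                                               "inversion"))
  resid <- vapply(fits, `[[`, numeric(1), "residual")
  snorm <- vapply(fits, `[[`, numeric(1), "solution_norm")
  curve <- data.frame(lambda = lambda_grid, residual = resid,
                      solution_norm = snorm, curvature = NA_real_)
  scale <- max(sqrt(sum(s^2)), .Machine$double.eps)
  if (length(lambda_grid) == 1)
    return(list(lambda = lambda_grid, curve = curve, degenerate = FALSE))
  # consistent system: the unregularized fit already explains the data, so
  # the L-curve has no interior corner and the smallest candidate wins
  resid0 <- attr(invert_signal(s, kernel, 0), "inversion")$residual
  if (resid0 / scale < consistent_tol)
    return(list(lambda = lambda_grid[1], curve = curve, degenerate = FALSE))
  if (diff(range(resid)) / scale < 1e-12) {
    warning("degenerate L-curve: all candidate residuals equal")
    return(list(lambda = lambda_grid[1], curve = curve, degenerate = TRUE))
  }
  eps <- 1e-300
  x <- log(pmax(resid, eps)); y <- log(pmax(snorm, eps))
  n <- length(x)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      a <- c(x[i - 1], y[i - 1]); b <- c(x[i], y[i]); cc <- c(x[i + 1], y[i + 1])
      la <- sqrt(sum((a - b)^2)); lb <- sqrt(sum((b - cc)^2))
      lc <- sqrt(sum((cc - a)^2))
      area2 <- abs((b[1] - a[1]) * (cc[2] - a[2]) -
                     (cc[1] - a[1]) * (b[2] - a[2]))
      curve$curvature[i] <- if (la * lb * lc > 0) 2 * area2 / (la * lb * lc) else 0
    }
    k <- curve$curvature[2:(n - 1)]
    best <- which(k >= max(k) - 1e-15)
    chosen <- lambda_grid[1 + best[length(best)]]   # ties -> larger lambda
  } else {
    chosen <- lambda_grid[1]
  }
  list(lambda = chosen, curve = curve, degenerate = FALSE)
}

#' Marginalize a 3D spectrum to a 2D correlation map
#'
#' Sums spectrum weights over the dropped axis, conserving total mass.
#' The three retained-axis pairs are the conventional 2D correlation
#' distributions T1-T2, T1-D and T2-D.
#'
#' @param spectrum an [md_spectrum()].
#' @param pair \code{"T1-T2"}, \code{"T1-D"} or \code{"T2-D"}.
#' @return An [md_spectrum2d()] whose total weight equals the 3D total.
#' @export
marginalize <- function(spectrum, pair = c("T1-T2", "T1-D", "T2-D")) {
  stopifnot(inherits(spectrum, "md_spectrum"))
  pair <- match.arg(pair)
  g <- spectrum$grid
  # flat order is T1 slowest / D fastest, i.e. column-major dims (D, T2, T1)
  arr <- array(spectrum$weights,
               dim = c(length(g$d), length(g$t2), length(g$t1)))
  w <- switch(pair,
              "T1-T2" = t(colSums(arr)),             # sum over D -> (T2,T1) -> t()
              "T1-D"  = t(apply(arr, c(1, 3), sum)), # sum over T2 -> (D,T1) -> t()
              "T2-D"  = t(apply(arr, c(1, 2), sum))) # sum over T1 -> (D,T2) -> t()
  ax <- switch(pair,
               "T1-T2" = list(g$t1, g$t2),
               "T1-D"  = list(g$t1, g$d),
               "T2-D"  = list(g$t2, g$d))
  md_spectrum2d(pair, ax[[1]], ax[[2]], w)
}

#' Flatten signals and spectra into classifier feature vectors
#'
#' Deterministic flattening used to feed both data representations to the
#' classifiers: a signal vector maps to itself; a 3D spectrum to its flat
#' weight vector (grid order, T1 slowest / D fastest); a 2D spectrum to
#' its weight matrix read row-major over (axis1, axis2). The spectrum
#' mappings are invertible via [devectorize_spectrum()] and
#' [devectorize_spectrum2d()].
#'
#' @param x a \code{signal_vector}, [md_spectrum()] or [md_spectrum2d()].
#' @return A plain numeric vector.
#' @export
vectorize_features <- function(x) UseMethod("vectorize_features")

#' @export
vectorize_features.signal_vector <- function(x) as.numeric(x)

#' @export
vectorize_features.numeric <- function(x) as.numeric(x)

#' @export
vectorize_features.md_spectrum <- function(x) x$weights

#' @export
vectorize_features.md_spectrum2d <- function(x) as.numeric(t(x$weights))

#' @rdname vectorize_features
#' @param v numeric vector produced by \code{vectorize_features}.
#' @param grid the original [parameter_grid()].
#' @export
devectorize_spectrum <- function(v, grid) md_spectrum(grid, v)

#' @rdname vectorize_features
#' @param pair,axis1,axis2 the original 2D spectrum's pair tag and axes.
#' @export
devectorize_spectrum2d <- function(v, pair, axis1, axis2) {
  md_spectrum2d(pair, axis1, axis2,
                matrix(v, nrow = length(axis1), ncol = length(axis2),
                       byrow = TRUE))
}
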