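#' Discrete joint distribution of a label and an observation
#'
#' Container for the joint law P(X, Y) of a discrete label X (rows) and a
#' discrete observation Y (columns), either as an exact probability table
#' or as empirical co-occurrence counts (which are normalized internally
#' and flagged as empirical).
#'
#' @param table non-negative numeric matrix; rows index the states of X,
#'   columns the states of Y.
#' @param type \code{"exact"} (entries sum to 1 within 1e-12) or
#'   \code{"counts"} (non-negative integers).
#' @return An object of class \code{discrete_joint} with elements
#'   \code{p} (the normalized table) and \code{empirical}.
#' @export
discrete_joint <- function(table, type = c("exact", "counts")) {
  type <- match.arg(type)
  p <- as.matrix(table)
  if (anyNA(p) || any(p < 0)) stop("joint table must be non-negative and finite")
  if (sum(p) == 0) stop("joint table is all zero")
  if (type == "exact") {
    if (abs(sum(p) - 1) > 1e-12)
      stop("exact joint probabilities must sum to 1 within 1e-12")
  } else {
    if (any(abs(p - round(p)) > 0)) stop("counts must be integers")
    p <- p / sum(p)
  }
  structure(list(p = p, empirical = (type == "counts")),
            class = "discrete_joint")
}

#' Build a discrete joint from paired label samples
#' @param x,y equal-length vectors of discrete values.
#' @return A \code{discrete_joint} in empirical (counts) mode.
#' @export
joint_from_samples <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  discrete_joint(unclass(table(x, y)), type = "counts")
}

.h <- function(p, base) {          # Shannon entropy with 0 log 0 := 0
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Plug-in entropy and mutual information of a discrete joint
#'
#' Computes the plug-in (maximum-likelihood) Shannon quantities
#' H(X), H(X|Y) and I(X; Y) = H(X) - H(X|Y), with the convention
#' \eqn{0 \log 0 = 0}. All three share one logarithm base (bits by
#' default), which must match the base used in the error bounds.
#'
#' @param joint a [discrete_joint()].
#' @param base logarithm base (> 1); 2 gives bits.
#' @return A list with \code{H_X}, \code{H_X_given_Y}, \code{I_XY} and
#'   \code{base}.
#' @export
entropy_terms <- function(joint, base = 2) {
  stopifnot(inherits(joint, "discrete_joint"))
  if (!is.numeric(base) || base <= 1) stop("base must be > 1")
  p <- joint$p
  H_X <- .h(rowSums(p), base)
  H_Y <- .h(colSums(p), base)
  H_XY <- .h(as.numeric(p), base)
  H_X_given_Y <- max(H_XY - H_Y, 0)
  list(H_X = H_X, H_X_given_Y = H_X_given_Y,
       I_XY = max(H_X - H_X_given_Y, 0), base = base)
}

#' Fano lower bound on prediction error
#'
#' For any predictor of X from Y, the error probability satisfies
#' \deqn{P_e \ \ge\ \frac{H(X|Y) - 1}{\log |\chi|},}
#' where \eqn{|\chi|} is the size of the label support and the logarithm
#' matches the entropy's base. This weakened form can be negative (then it
#' is vacuous); the raw value is returned and \code{clamp = TRUE} floors
#' it at 0 for display.
#'
#' @param H_X_given_Y conditional entropy of the label given the
#'   observation, in the units of \code{base}.
#' @param support_size number of label states (>= 2).
#' @param base logarithm base matching the entropy.
#' @param clamp floor the bound at 0?
#' @return The bound (a single number).
#' @export
fano_lower <- function(H_X_given_Y, support_size, base = 2, clamp = FALSE) {
  if (support_size < 2) stop("support_size must be >= 2")
  v <- (H_X_given_Y - 1) / log(support_size, base = base)
  if (clamp) max(v, 0) else v
}

#' Hellman-Raviv upper bound on maximum-likelihood prediction error
#'
#' The error of the maximum-likelihood (MAP) predictor of X from Y is at
#' most half the conditional entropy: \eqn{P_e \le \frac{1}{2} H(X|Y)}.
#'
#' @inheritParams fano_lower
#' @return The bound \code{H_X_given_Y / 2}.
#' @export
hellman_raviv_upper <- function(H_X_given_Y) {
  if (H_X_given_Y < 0) stop("conditional entropy must be non-negative")
  H_X_given_Y / 2
}

#' Exact Bayes (MAP) error of a discrete joint
#'
#' The error of the optimal predictor: \eqn{P_e = 1 - \sum_y \max_x P(x, y)}.
#' Only defined for exact joint tables; empirical counts should be scored
#' with hold-out error instead.
#'
#' @param joint a [discrete_joint()] in exact mode.
#' @return The Bayes error probability.
#' @export
bayes_error <- function(joint) {
  stopifnot(inherits(joint, "discrete_joint"))
  if (joint$empirical)
    stop("Bayes error requires an exact joint table; use hold-out error for counts")
  1 - sum(apply(joint$p, 2, max))
}

#' Entropy, information and error-bound report for a joint
#'
#' Convenience wrapper combining [entropy_terms()], [fano_lower()],
#' [hellman_raviv_upper()] and (in exact mode) [bayes_error()]. In exact
#' mode with at least two label states the three quantities always
#' sandwich: \code{fano_lower <= bayes_error <= hr_upper}.
#'
#' @inheritParams entropy_terms
#' @return A list of class \code{bounds_report}.
#' @export
bounds_report <- function(joint, base = 2) {
  et <- entropy_terms(joint, base)
  nx <- nrow(joint$p)
  out <- c(et, list(
    fano_lower = if (nx >= 2) fano_lower(et$H_X_given_Y, nx, base) else NA_real_,
    fano_lower_clamped = if (nx >= 2)
      fano_lower(et$H_X_given_Y, nx, base, clamp = TRUE) else NA_real_,
    hr_upper = hellman_raviv_upper(et$H_X_given_Y),
    bayes_error = if (!joint$empirical) bayes_error(joint) else NA_real_))
  class(out) <- "bounds_report"
  out
}

#' @export
print.bounds_report <- function(x, ...) {
  cat(sprintf("H(X) = %.4f, H(X|Y) = %.4f, I(X;Y) = %.4f (base %g)\n",
              x$H_X, x$H_X_given_Y, x$I_XY, x$base))
  cat(sprintf("Fano lower %.4f (clamped %.4f) <= Bayes error %s <= Hellman-Raviv upper %.4f\n",
              x$fano_lower, x$fano_lower_clamped,
              if (is.na(x$bayes_error)) "(empirical mode)" else
                sprintf("%.4f", x$bayes_error), x$hr_upper))
  invisible(x)
}

#' Audit the data processing inequality on a Markov chain
#'
#' For a chain X -> Y -> Y' specified by a prior P(X) and two stochastic
#' channel matrices, computes I(X; Y) and I(X; Y') exactly and the margin
#' I(X; Y) - I(X; Y'). The data processing inequality guarantees the
#' margin is non-negative: downstream processing cannot create
#' information about X. A margin below \code{-1e-10} (numerically
#' impossible for a valid chain) raises an error.
#'
#' @param px prior probability vector over the states of X.
#' @param channel_xy stochastic matrix P(Y | X), rows = states of X.
#' @param channel_yy stochastic matrix P(Y' | Y), rows = states of Y.
#' @param base logarithm base.
#' @return A list with \code{I_XY}, \code{I_XYprime} and \code{margin}.
#' @export
dpi_audit <- function(px, channel_xy, channel_yy, base = 2) {
  px <- as.numeric(px)
  channel_xy <- as.matrix(channel_xy); channel_yy <- as.matrix(channel_yy)
  check_stochastic <- function(m, nm) {
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
      stop(sprintf("%s must have non-negative rows summing to 1", nm))
  }
  if (any(px < 0) || abs(sum(px) - 1) > 1e-9) stop("px must be a probability vector")
  check_stochastic(channel_xy, "channel_xy")
  check_stochastic(channel_yy, "channel_yy")
  if (nrow(channel_xy) != length(px) || nrow(channel_yy) != ncol(channel_xy))
    stop("chain dimensions are inconsistent")
  jxy <- px * channel_xy                 # P(X = x, Y = y), rows scaled
  jxyp <- px * (channel_xy %*% channel_yy)
  I1 <- entropy_terms(discrete_joint(jxy / sum(jxy)), base)$I_XY
  I2 <- entropy_terms(discrete_joint(jxyp / sum(jxyp)), base)$I_XY
  margin <- I1 - I2
  if (margin < -1e-10)
    stop(sprintf("data processing inequality violated: margin %.3g", margin))
  list(I_XY = I1, I_XYprime = I2, margin = margin)
}
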