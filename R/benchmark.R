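#' Cohen's kappa for agreement between labels and predictions
#'
#' Chance-corrected agreement
#' \deqn{\kappa = \frac{p_o - p_e}{1 - p_e},}
#' where \eqn{p_o} is the observed agreement rate and \eqn{p_e} the
#' agreement expected from the two marginal label frequencies. The
#' degenerate case \eqn{p_e = 1} only occurs when both sequences are
#' constant and equal, where perfect agreement gives \eqn{\kappa = 1} by
#' convention.
#'
#' @param truth,predicted equal-length label vectors over a shared finite
#'   label set.
#' @return A list with \code{kappa} (in \[-1, 1\]), \code{po} and
#'   \code{pe}.
#' @export
#' @examples
#' # confusion table [[20, 5], [10, 15]]: po = 0.7, pe = 0.5, kappa = 0.4
#' cohen_kappa(rep(c("a", "b"), c(25, 25)),
#'             rep(c("a", "b", "a", "b"), c(20, 5, 10, 15)))$kappa
cohen_kappa <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  n <- length(truth)
  if (n == 0 || length(predicted) != n)
    stop("truth and predicted must be non-empty and of equal length")
  lev <- sort(unique(c(truth, predicted)))
  po <- mean(truth == predicted)
  pt <- tabulate(match(truth, lev), length(lev)) / n
  pp <- tabulate(match(predicted, lev), length(lev)) / n
  pe <- sum(pt * pp)
  if (pe >= 1) {
    if (po == 1) return(list(kappa = 1, po = po, pe = pe))
    stop("chance agreement is 1 but observed agreement is not; kappa undefined")
  }
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe)
}

#' Paired bootstrap 50/50 splits
#'
#' Generates \code{n_boot} seeded train/test splits of the voxel pool.
#' Split b uses RNG seed \code{seed + b}, so re-running with the same
#' configuration reproduces the exact index lists — and, crucially, the
#' identical splits are reused for every classifier and every data
#' representation, making all benchmark comparisons paired. Each split
#' puts \code{floor(n * split)} samples in training and the rest in
#' testing (disjoint); a split whose training half misses a class is
#' redrawn (up to \code{max_retry} times, with the retry count recorded).
#'
#' @param n number of samples (>= 4).
#' @param labels class labels used for the class-presence check (optional
#'   but recommended).
#' @param n_boot number of bootstrap repetitions.
#' @param split training fraction in (0, 1).
#' @param seed master seed.
#' @param groups optional group ids (e.g. pseudo-subjects); when given,
#'   the training quota is allocated across groups by largest remainder
#'   and sampled within each group, stratifying the splits.
#' @param replace draw the training half with replacement instead of
#'   re-splitting (the alternative reading of "bootstrapped samples");
#'   test is then the set of samples never drawn.
#' @param max_retry redraw budget per split.
#' @return A list of \code{n_boot} lists with integer vectors
#'   \code{train}, \code{test} and \code{retries}.
#' @export
paired_bootstrap_splits <- function(n, labels = NULL, n_boot = 30,
                                    split = 0.5, seed = 0, groups = NULL,
                                    replace = FALSE, max_retry = 100) {
  if (n < 4) stop("need at least 4 samples to split")
  if (split <= 0 || split >= 1) stop("split fraction must be in (0, 1)")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(labels) && length(labels) != n)
    stop("labels length must equal n")
  n_train <- floor(n * split)
  draw <- function() {
    if (is.null(groups)) {
      if (replace) {
        tr <- sort(sample.int(n, n_train, replace = TRUE))
        list(train = tr, test = setdiff(seq_len(n), unique(tr)))
      } else {
        tr <- sort(sample.int(n, n_train))
        list(train = tr, test = setdiff(seq_len(n), tr))
      }
    } else {
      gsp <- split(seq_len(n), groups)
      quota <- lengths(gsp) * split
      base <- floor(quota)
      extra <- order(quota - base, decreasing = TRUE)[seq_len(n_train - sum(base))]
      base[extra] <- base[extra] + 1
      tr <- sort(unlist(mapply(function(ix, m) {
        if (m == 0) integer(0) else sample(ix, m, replace = replace)
      }, gsp, base, SIMPLIFY = FALSE), use.names = FALSE))
      list(train = tr, test = setdiff(seq_len(n), unique(tr)))
    }
  }
  lapply(seq_len(n_boot), function(b) {
    with_seed(seed + b, {
      for (r in 0:max_retry) {
        sp <- draw()
        ok <- is.null(labels) ||
          setequal(unique(labels), unique(labels[sp$train]))
        if (ok) return(c(sp, list(retries = r)))
      }
      stop(sprintf("split %d: a class was absent from training after %d redraws",
                   b, max_retry))
    })
  })
}

#' Benchmark configuration
#'
#' @param n_boot bootstrap repetitions (default 30).
#' @param split training fraction (default 0.5).
#' @param seed master seed; split b and any stochastic fit in bootstrap b
#'   use \code{seed + b}.
#' @param methods subset of \code{c("2-NN", "MLP", "LDA", "NLCS")}.
#' @param representations subset of
#'   \code{c("T1-D", "T2-D", "T1-T2", "signal")}.
#' @param nlcs_k,nlcs_p NLCS neighbourhood size and norm order.
#' @param mlp hyperparameters for the multilayer perceptron: hidden layer
#'   \code{size}, weight \code{decay}, \code{maxit} and BFGS convergence
#'   tolerance \code{reltol}.
#' @param lda_gamma shrinkage intensity used by the fallback regularized
#'   LDA when the pooled within-class covariance is singular.
#' @param replace,stratify_by_subject passed to
#'   [paired_bootstrap_splits()] (\code{stratify_by_subject} uses the
#'   dataset's pseudo-subject ids as groups).
#' @return An object of class \code{benchmark_config}.
#' @export
benchmark_config <- function(n_boot = 30, split = 0.5, seed = 0,
                             methods = c("2-NN", "MLP", "LDA", "NLCS"),
                             representations = c("T1-D", "T2-D", "T1-T2",
                                                 "signal"),
                             nlcs_k = 5, nlcs_p = 2,
                             mlp = list(size = 8, decay = 1e-4, maxit = 500,
                                        reltol = 1e-5),
                             lda_gamma = 0.1,
                             replace = FALSE, stratify_by_subject = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  representations <- match.arg(representations, several.ok = TRUE)
  stopifnot(n_boot >= 1, split > 0, split < 1)
  structure(list(n_boot = n_boot, split = split, seed = as.integer(seed),
                 methods = methods, representations = representations,
                 nlcs_k = nlcs_k, nlcs_p = nlcs_p, mlp = mlp,
                 lda_gamma = lda_gamma, replace = replace,
                 stratify_by_subject = stratify_by_subject),
            class = "benchmark_config")
}

# Deterministic k-nearest-neighbour vote: distance ties keep the lower
# training index; vote ties go to the class of the nearest tied-vote
# neighbour.
knn_predict <- function(train_x, train_y, test_x, k = 2) {
  train_y <- factor(train_y)
  lev <- levels(train_y)
  pred <- character(nrow(test_x))
  for (r in seq_len(nrow(test_x))) {
    d2 <- colSums((t(train_x) - test_x[r, ])^2)
    nb <- order(d2)[seq_len(min(k, length(d2)))]   # stable order
    cls <- as.integer(train_y[nb])
    votes <- tabulate(cls, length(lev))
    winners <- which(votes == max(votes))
    pick <- if (length(winners) == 1) winners else
      cls[which(cls %in% winners)[1]]              # nearest tied class
    pred[r] <- lev[pick]
  }
  factor(pred, levels = lev)
}

# Regularized LDA used when the pooled covariance is singular (e.g. more
# features than samples, or zero within-class variance): shrink toward a
# scaled identity and classify by linear discriminant score.
shrinkage_lda_fit <- function(x, y, gamma) {
  y <- factor(y)
  p <- ncol(x)
  means <- t(vapply(levels(y), function(l) colMeans(x[y == l, , drop = FALSE]),
                    numeric(p)))
  S <- matrix(0, p, p)
  for (l in levels(y)) {
    xc <- scale(x[y == l, , drop = FALSE], center = TRUE, scale = FALSE)
    S <- S + crossprod(xc)
  }
  S <- S / max(nrow(x) - nlevels(y), 1)
  tr <- sum(diag(S))
  S <- (1 - gamma) * S + gamma * max(tr / p, 1e-12) * diag(p)
  W <- solve(S, t(means))                          # p x C
  const <- -0.5 * colSums(t(means) * W) + log(as.numeric(table(y)) / nrow(x))
  list(W = W, const = const, levels = levels(y))
}

shrinkage_lda_predict <- function(model, x) {
  sc <- x %*% model$W + rep(model$const, each = nrow(x))
  factor(model$levels[max.col(sc, ties.method = "first")],
         levels = model$levels)
}

#' Baseline classifiers behind a common fit/predict contract
#'
#' Wraps the comparison methods (2-nearest-neighbour, a one-hidden-layer
#' multilayer perceptron, linear discriminant analysis) and the package's
#' own NLCS classifier behind one interface, so the benchmark can treat
#' them uniformly. LDA uses \code{MASS::lda}; when that fails on a
#' singular within-class covariance the wrapper falls back to shrinkage
#' LDA and flags it. The MLP (\code{nnet}) is seeded from the bootstrap
#' seed, so identical seeds give identical fits.
#'
#' @param name one of \code{"2-NN"}, \code{"MLP"}, \code{"LDA"},
#'   \code{"NLCS"}.
#' @param config a [benchmark_config()] supplying hyperparameters.
#' @return A list with functions \code{fit(x, y, seed)} and
#'   \code{predict(model, x)}, plus \code{hyperparameters}.
#' @export
baseline_classifier <- function(name = c("2-NN", "MLP", "LDA", "NLCS"),
                                config = benchmark_config()) {
  name <- match.arg(name)
  switch(name,
    "2-NN" = list(
      fit = function(x, y, seed = NULL) list(x = x, y = factor(y)),
      predict = function(model, x) knn_predict(model$x, model$y, x, k = 2),
      hyperparameters = list(k = 2, metric = "euclidean")),
    "MLP" = list(
      fit = function(x, y, seed = NULL) {
        y <- factor(y)
        net <- with_seed(seed %||% 1L,
          nnet::nnet(x, nnet::class.ind(y), size = config$mlp$size,
                     softmax = TRUE, decay = config$mlp$decay,
                     maxit = config$mlp$maxit,
                     reltol = config$mlp$reltol %||% 1e-5,
                     MaxNWts = 1e6, trace = FALSE))
        list(net = net, levels = levels(y))
      },
      predict = function(model, x) {
        pr <- stats::predict(model$net, x)
        factor(model$levels[max.col(pr, ties.method = "first")],
               levels = model$levels)
      },
      hyperparameters = config$mlp),
    "LDA" = list(
      fit = function(x, y, seed = NULL) {
        fit <- tryCatch(suppressWarnings(MASS::lda(x, grouping = factor(y))),
                        error = function(e) NULL)
        if (is.null(fit))
          list(shrunk = shrinkage_lda_fit(x, factor(y), config$lda_gamma),
               shrinkage = TRUE)
        else list(lda = fit, shrinkage = FALSE)
      },
      predict = function(model, x) {
        if (model$shrinkage) shrinkage_lda_predict(model$shrunk, x)
        else stats::predict(model$lda, x)$class
      },
      hyperparameters = list(solver = "MASS::lda",
                             fallback_shrinkage_gamma = config$lda_gamma)),
    "NLCS" = list(
      fit = function(x, y, seed = NULL)
        nlcs_fit(x, y, k = config$nlcs_k, p = config$nlcs_p),
      predict = function(model, x) predict(model, x),
      hyperparameters = list(k = config$nlcs_k, p = config$nlcs_p)))
}

#' Run the paired-bootstrap classifier benchmark
#'
#' The comparison protocol: for each of \code{n_boot} seeded 50/50
#' train/test splits of the voxel pool, every requested classifier is fit
#' on every requested data representation and scored on the test half
#' with Cohen's kappa. The split indices are computed once per bootstrap
#' and reused across all (method, representation) cells, so each cell's
#' kappa distribution is paired with every other's. Voxels with failed
#' inversions are excluded from the pool up front; a classifier failure
#' in one cell is counted and the cell's mean is taken over the
#' successful bootstraps, never silently dropped.
#'
#' @param dataset a [realize_dataset()] result.
#' @param config a [benchmark_config()].
#' @return An object of class \code{kappa_report}: a list with
#'   \code{kappa} (n_boot x method x representation array), \code{mean}
#'   and \code{sd} tables, \code{failures}, the reused \code{splits} and
#'   the configuration.
#' @export
run_benchmark <- function(dataset, config = benchmark_config()) {
  stopifnot(inherits(dataset, "voxel_dataset"),
            inherits(config, "benchmark_config"))
  keep <- setdiff(seq_along(dataset$labels), dataset$failed)
  labels <- droplevels(factor(dataset$labels[keep]))
  feats <- lapply(config$representations, function(rp)
    dataset_features(dataset, rp)[keep, , drop = FALSE])
  names(feats) <- config$representations
  groups <- if (config$stratify_by_subject) dataset$subjects[keep] else NULL
  splits <- paired_bootstrap_splits(length(keep), labels = labels,
                                    n_boot = config$n_boot,
                                    split = config$split,
                                    seed = config$seed, groups = groups,
                                    replace = config$replace)
  classifiers <- lapply(config$methods, baseline_classifier, config = config)
  names(classifiers) <- config$methods
  kap <- array(NA_real_,
               dim = c(config$n_boot, length(config$methods),
                       length(config$representations)),
               dimnames = list(NULL, config$methods, config$representations))
  failures <- matrix(0L, length(config$methods), length(config$representations),
                     dimnames = list(config$methods, config$representations))
  for (b in seq_len(config$n_boot)) {
    sp <- splits[[b]]
    for (rp in config$representations) {
      xtr <- feats[[rp]][sp$train, , drop = FALSE]
      xte <- feats[[rp]][sp$test, , drop = FALSE]
      ytr <- labels[sp$train]; yte <- labels[sp$test]
      for (mth in config$methods) {
        cl <- classifiers[[mth]]
        k <- tryCatch({
          model <- cl$fit(xtr, ytr, seed = config$seed + b)
          cohen_kappa(yte, cl$predict(model, xte))$kappa
        }, error = function(e) NA_real_)
        if (is.na(k)) failures[mth, rp] <- failures[mth, rp] + 1L
        kap[b, mth, rp] <- k
      }
    }
  }
  structure(list(kappa = kap,
                 mean = apply(kap, c(2, 3), mean, na.rm = TRUE),
                 sd = apply(kap, c(2, 3), stats::sd, na.rm = TRUE),
                 failures = failures, splits = splits, config = config,
                 n = length(keep)),
            class = "kappa_report")
}

#' @export
print.kappa_report <- function(x, digits = 3, ...) {
  m <- x$mean
  cat(sprintf("Average Cohen's kappa over %d paired bootstrap splits (n = %d voxels)\n",
              x$config$n_boot, x$n))
  disp <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    tag <- paste0(if (m[i, j] == max(m[, j])) "*" else "",
                  if (m[i, j] == max(m[i, ])) "^" else "")
    disp[i, j] <- sprintf("%.*f (%.*f)%s", digits, m[i, j], digits,
                          x$sd[i, j], tag)
  }
  print(disp, quote = FALSE)
  cat("* column-wise maximum, ^ row-wise maximum; (sd) in parentheses\n")
  if (any(x$failures > 0)) {
    cat("fit failures per cell:\n"); print(x$failures)
  }
  invisible(x)
}

#' Export a kappa report as CSV tables
#'
#' Writes \code{kappa_table.csv} (cell means, methods x representations)
#' and \code{kappa_raw.csv} (one row per bootstrap x cell) into a
#' directory.
#'
#' @param report a [run_benchmark()] result.
#' @param dir output directory (created if missing).
#' @export
write_kappa_report <- function(report, dir) {
  stopifnot(inherits(report, "kappa_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$mean, file.path(dir, "kappa_table.csv"))
  dn <- dimnames(report$kappa)
  raw <- expand.grid(bootstrap = seq_len(dim(report$kappa)[1]),
                     method = dn[[2]], representation = dn[[3]],
                     stringsAsFactors = FALSE)
  raw$kappa <- as.numeric(report$kappa)
  utils::write.csv(raw, file.path(dir, "kappa_raw.csv"), row.names = FALSE)
  invisible(dir)
}
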