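#' Compartment of a multi-compartment tissue model
#'
#' One water pool: a location in (T1, T2, D) space, its mean volume
#' fraction within the voxel and the voxel-to-voxel variability of that
#' fraction, modelled as a logit-normal jitter.
#'
#' @param t1,t2 relaxation times in seconds.
#' @param d diffusivity in \eqn{\mu m^2}/ms.
#' @param fraction mean volume fraction in \[0, 1\].
#' @param jitter standard deviation of the logit-scale perturbation
#'   applied per voxel (0 = identical voxels).
#' @return An object of class \code{compartment}.
#' @export
compartment <- function(t1, t2, d, fraction, jitter = 0.3) {
  stopifnot(t1 > 0, t2 > 0, d > 0, fraction >= 0, fraction <= 1, jitter >= 0)
  structure(list(t1 = t1, t2 = t2, d = d, fraction = fraction,
                 jitter = jitter), class = "compartment")
}

#' Default two-class tissue model
#'
#' Both classes share three compartments typical of fixed brain tissue: a
#' myelin-like pool (short T1/T2, restricted diffusion), an
#' intra/extra-cellular pool and a free-water-like pool. The lesion class
#' ("gliosis-like") shifts \code{effect_size} of volume fraction from the
#' free-water pool into the cellular pool relative to the control class,
#' mimicking the densification that reactive tissue produces.
#'
#' @param effect_size fraction moved between pools (default 0.15); must
#'   leave all fractions in \[0, 1\].
#' @param jitter per-voxel logit-normal fraction jitter (applied to every
#'   compartment).
#' @return Named list of two classes (\code{control}, \code{lesion}), each
#'   a list of [compartment()]s.
#' @export
default_phantom_classes <- function(effect_size = 0.15, jitter = 0.3) {
  stopifnot(effect_size >= 0, effect_size <= 0.2)
  base <- list(myelin = c(t1 = 0.25, t2 = 0.015, d = 0.25),
               cellular = c(t1 = 0.9, t2 = 0.07, d = 0.8),
               free_water = c(t1 = 3.0, t2 = 0.3, d = 2.0))
  mk <- function(fr) {
    out <- mapply(function(loc, f) compartment(loc["t1"], loc["t2"], loc["d"],
                                               f, jitter),
                  base, fr, SIMPLIFY = FALSE)
    names(out) <- names(base)
    out
  }
  list(control = mk(c(0.25, 0.55, 0.20)),
       lesion = mk(c(0.25, 0.55 + effect_size, 0.20 - effect_size)))
}

#' Configuration of a synthetic two-class phantom
#'
#' Bundles everything needed to generate a labelled voxel dataset with the
#' statistical structure of a lesion-vs-control tissue study: per-class
#' compartment models, voxel counts, the acquisition scheme and spectral
#' grid, the noise model and a master seed. Per-voxel random streams are
#' derived as \code{seed + voxel index}, so generation is reproducible
#' voxel by voxel.
#'
#' @param classes named list of classes, each a list of [compartment()]s.
#' @param voxels_per_class voxels simulated per class.
#' @param grid [parameter_grid()] for truth spectra and inversion. The
#'   default 10-node-per-axis grid keeps multi-voxel inversion desk-scale.
#' @param scheme [acquisition_scheme()].
#' @param snr signal-to-noise ratio for [simulate_signal()].
#' @param noise_model \code{"rician"} (default), \code{"gaussian"} or
#'   \code{"none"}.
#' @param n_subjects optional even number of pseudo-subjects; voxels are
#'   tagged round-robin with subject ids (half per class) usable for
#'   stratified splitting. Metadata only: voxels stay independent.
#' @param seed master integer seed.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(classes = default_phantom_classes(),
                           voxels_per_class = 50,
                           grid = default_grid(10, 10, 10),
                           scheme = default_scheme(),
                           snr = 30,
                           noise_model = c("rician", "gaussian", "none"),
                           n_subjects = 14,
                           seed = 0) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(classes) >= 2, all(lengths(classes) >= 1),
            voxels_per_class >= 1)
  for (cl in classes) {
    fr <- sum(vapply(cl, `[[`, numeric(1), "fraction"))
    if (abs(fr - 1) > 1e-9)
      stop("compartment fractions of each class must sum to 1")
  }
  structure(list(classes = classes, voxels_per_class = voxels_per_class,
                 grid = grid, scheme = scheme, snr = snr,
                 noise_model = noise_model, n_subjects = n_subjects,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Draw ground-truth voxel spectra from a phantom configuration
#'
#' For every voxel, each compartment's fraction is perturbed on the logit
#' scale by its jitter, fractions are renormalized to sum to 1, and the
#' mass is placed on the grid nodes nearest (in log coordinates) to the
#' compartment locations. Two compartments snapping to the same node are
#' merged with a warning.
#'
#' @param config a [phantom_config()].
#' @return A list with \code{spectra} (list of normalized
#'   [md_spectrum()]s), \code{labels} (factor of class names),
#'   \code{subjects} (integer pseudo-subject ids or NULL) and
#'   \code{config}.
#' @export
make_truth_spectra <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$grid
  snap <- function(x, nodes) which.min(abs(log(nodes) - log(x)))
  class_nodes <- lapply(config$classes, function(cl) {
    fl <- vapply(cl, function(cp) grid_index(g, snap(cp$t1, g$t1),
                                             snap(cp$t2, g$t2),
                                             snap(cp$d, g$d)), numeric(1))
    if (anyDuplicated(fl))
      warning("compartments snapped to the same grid node; masses merged")
    fl
  })
  labels <- factor(rep(names(config$classes),
                       each = config$voxels_per_class),
                   levels = names(config$classes))
  spectra <- vector("list", length(labels))
  v <- 0L
  for (ci in seq_along(config$classes)) {
    cl <- config$classes[[ci]]
    fr0 <- vapply(cl, `[[`, numeric(1), "fraction")
    jit <- vapply(cl, `[[`, numeric(1), "jitter")
    for (k in seq_len(config$voxels_per_class)) {
      v <- v + 1L
      fr <- with_seed(config$seed + v, {
        f <- inv_logit(logit(pmin(pmax(fr0, 1e-9), 1 - 1e-9)) +
                         stats::rnorm(length(fr0), 0, jit))
        f / sum(f)
      })
      w <- numeric(grid_size(g))
      for (j in seq_along(fr))
        w[class_nodes[[ci]][j]] <- w[class_nodes[[ci]][j]] + fr[j]
      spectra[[v]] <- md_spectrum(g, w, normalized = TRUE)
    }
  }
  subjects <- NULL
  if (!is.null(config$n_subjects) && config$n_subjects >= 2) {
    per_class <- config$n_subjects %/% length(config$classes)
    subjects <- as.integer(unlist(lapply(seq_along(config$classes), function(ci)
      (ci - 1) * per_class + rep_len(seq_len(per_class),
                                     config$voxels_per_class))))
  }
  list(spectra = spectra, labels = labels, subjects = subjects,
       config = config)
}

#' Realize a labelled voxel dataset: signals, spectra and 2D features
#'
#' Composes the full observation chain for each voxel: the truth spectrum
#' is projected through the Fredholm kernel and corrupted with noise
#' (representation Y, the raw signal), then inverted back to an estimated
#' spectrum and marginalized to the three 2D correlation maps
#' (representations Y'). Because every spectral feature is computed from
#' the noisy signal alone (truth is never consulted), the Markov chain
#' X -> Y -> Y' holds by construction, which is what makes
#' data-processing-inequality arguments about the benchmark literal
#' rather than approximate.
#'
#' Per-voxel noise seeds are \code{seed + 10000 + voxel index}. Voxels
#' whose inversion fails are recorded in \code{failed} and their spectral
#' features set to NA; they are never silently imputed.
#'
#' @param truth a [make_truth_spectra()] result (or a list with elements
#'   \code{spectra}, \code{labels}, \code{config}).
#' @param lambda Tikhonov weight used for all voxel inversions (one fixed
#'   value keeps the representation comparable across voxels).
#' @param seed overrides the config's master seed when given.
#' @return An object of class \code{voxel_dataset}: a list with matrices
#'   \code{signal} (n x d), \code{t1t2}, \code{t1d}, \code{t2d} (n x
#'   cells), factor \code{labels}, \code{subjects}, the truth spectra,
#'   \code{failed} (integer voxel indices) and provenance (config,
#'   lambda, seed).
#' @export
realize_dataset <- function(truth, lambda = 0.01, seed = NULL) {
  config <- truth$config
  stopifnot(inherits(config, "phantom_config"))
  seed <- as.integer(seed %||% config$seed)
  K <- build_kernel(config$grid, config$scheme)
  n <- length(truth$spectra)
  d <- nrow(config$scheme)
  pairs <- c("T1-T2", "T1-D", "T2-D")
  Y <- matrix(NA_real_, n, d)
  feats <- lapply(pairs, function(p) NULL)
  names(feats) <- pairs
  ncell <- c("T1-T2" = length(config$grid$t1) * length(config$grid$t2),
             "T1-D" = length(config$grid$t1) * length(config$grid$d),
             "T2-D" = length(config$grid$t2) * length(config$grid$d))
  for (p in pairs) feats[[p]] <- matrix(NA_real_, n, ncell[[p]])
  failed <- integer(0)
  for (v in seq_len(n)) {
    sig <- simulate_signal(truth$spectra[[v]], K, snr = config$snr,
                           noise_model = config$noise_model,
                           seed = seed + 10000L + v)
    Y[v, ] <- as.numeric(sig)
    fhat <- tryCatch(invert_signal(sig, K, lambda = lambda),
                     error = function(e) e)
    if (inherits(fhat, "error")) {
      failed <- c(failed, v)
      next
    }
    for (p in pairs)
      feats[[p]][v, ] <- vectorize_features(marginalize(fhat, p))
  }
  if (length(failed))
    warning(sprintf("inversion failed for %d voxel(s): %s",
                    length(failed), paste(failed, collapse = ", ")))
  structure(list(signal = Y, t1t2 = feats[["T1-T2"]], t1d = feats[["T1-D"]],
                 t2d = feats[["T2-D"]], labels = truth$labels,
                 subjects = truth$subjects, truth = truth$spectra,
                 failed = failed, config = config, lambda = lambda,
                 seed = seed),
            class = "voxel_dataset")
}

#' Extract one feature representation from a voxel dataset
#'
#' @param dataset a [realize_dataset()] result.
#' @param representation \code{"signal"}, \code{"T1-T2"}, \code{"T1-D"} or
#'   \code{"T2-D"}.
#' @return The n x p feature matrix for that representation.
#' @export
dataset_features <- function(dataset,
                             representation = c("signal", "T1-T2", "T1-D",
                                                "T2-D")) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  representation <- match.arg(representation)
  switch(representation, signal = dataset$signal, "T1-T2" = dataset$t1t2,
         "T1-D" = dataset$t1d, "T2-D" = dataset$t2d)
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf("Synthetic voxel dataset: %d voxels (%s), d = %d signal features\n",
              nrow(x$signal),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              ncol(x$signal)))
  cat(sprintf("  spectral features: T1-T2 %d, T1-D %d, T2-D %d cells; lambda = %g; %d failed inversions\n",
              ncol(x$t1t2), ncol(x$t1d), ncol(x$t2d), x$lambda,
              length(x$failed)))
  invisible(x)
}

#' Random discrete Markov chain fixture
#'
#' Generates a prior P(X) and two stochastic channels P(Y|X), P(Y'|Y)
#' with Dirichlet(1) rows — a discrete analogue of the label -> signal ->
#' spectrum chain, convenient for exercising [dpi_audit()] and the error
#' bounds exactly.
#'
#' @param sizes integer vector of the three support sizes (each >= 2).
#' @param seed integer seed.
#' @param deterministic if \code{TRUE}, channels are random permutation
#'   matrices (noise-free processing).
#' @return A list with \code{px}, \code{channel_xy}, \code{channel_yy}.
#' @export
make_chain_fixture <- function(sizes = c(2, 2, 2), seed = 0,
                               deterministic = FALSE) {
  stopifnot(length(sizes) == 3, all(sizes >= 2))
  with_seed(seed, {
    rdir <- function(n, m) {
      g <- matrix(stats::rgamma(n * m, 1), n, m)
      g / rowSums(g)
    }
    perm <- function(n, m) {
      stopifnot(n == m)   # permutation channels need square matrices
      diag(m)[sample(m), , drop = FALSE]
    }
    px <- as.numeric(rdir(1, sizes[1]))
    if (deterministic) {
      list(px = px, channel_xy = perm(sizes[1], sizes[2]),
           channel_yy = perm(sizes[2], sizes[3]))
    } else {
      list(px = px, channel_xy = rdir(sizes[1], sizes[2]),
           channel_yy = rdir(sizes[2], sizes[3]))
    }
  })
}
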