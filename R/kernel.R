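#' Build the discretized Fredholm kernel matrix
#'
#' The forward model links a voxel's T1-T2-D spectrum f to its measured
#' signal through a Fredholm integral of the first kind,
#' \deqn{s(\beta) = \int f(\alpha)\, k(\alpha; \beta)\, d\alpha,}
#' discretized as \code{s = K0 f}. The kernel is the product of an
#' inversion-recovery T1 factor, a spin-echo T2 decay and an isotropic
#' Gaussian diffusion decay:
#' \deqn{k(\alpha;\beta) = (1 - 2 e^{-\tau_I/T_1})\, e^{-\tau_E/T_2}\,
#'       e^{-b D}.}
#' With b in ms/\eqn{\mu m^2} and D in \eqn{\mu m^2}/ms the product
#' \code{b * D} is dimensionless.
#'
#' Magnitude acquisitions record the modulus of the signal, so the default
#' \code{sign_mode = "magnitude"} takes the absolute value of the
#' inversion-recovery factor entry-wise; \code{"signed"} keeps the raw
#' factor, which is negative for \eqn{\tau_I < T_1 \ln 2}. The
#' inversion-recovery null at \eqn{\tau_I = T_1 \ln 2} gives exact zeros
#' in both modes.
#'
#' @param grid a [parameter_grid()].
#' @param scheme an [acquisition_scheme()].
#' @param sign_mode \code{"magnitude"} (default) or \code{"signed"}.
#' @return A \code{kernel_matrix}: a d x N numeric matrix (d acquisitions,
#'   N grid nodes, columns in the grid's flat order) with the grid, scheme
#'   and sign mode attached as attributes. Every entry has modulus at
#'   most 1.
#' @export
#' @examples
#' K <- build_kernel(default_grid(5, 5, 5), default_scheme())
#' dim(K)
build_kernel <- function(grid, scheme, sign_mode = c("magnitude", "signed")) {
  stopifnot(inherits(grid, "parameter_grid"),
            inherits(scheme, "acquisition_scheme"))
  sign_mode <- match.arg(sign_mode)
  if (nrow(scheme) < 1 || grid_size(grid) < 1)
    stop("empty grid or scheme")
  if (max(scheme$b) * max(grid$d) > 1e3)
    warning("b * D exceeds 1e3; check units (b in ms/um^2, D in um^2/ms)")
  nodes <- grid_nodes(grid)
  # d x N: outer products over acquisitions (rows) and nodes (columns)
  ir <- 1 - 2 * exp(-outer(scheme$ti, nodes[, "t1"], "/"))
  if (sign_mode == "magnitude") ir <- abs(ir)
  K <- ir * exp(-outer(scheme$te, nodes[, "t2"], "/")) *
    exp(-outer(scheme$b, nodes[, "d"]))
  structure(K, grid = grid, scheme = scheme, sign_mode = sign_mode,
            class = c("kernel_matrix", "matrix", "array"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("Fredholm kernel matrix: %d acquisitions x %d grid nodes (%s mode)\n",
              nrow(x), ncol(x), attr(x, "sign_mode")))
  invisible(x)
}

#' Simulate MD-MRI signals from a spectrum
#'
#' Computes the noiseless forward projection \code{K0 f} and optionally
#' adds measurement noise. The signal-to-noise ratio is defined as the
#' maximum noiseless signal divided by the noise standard deviation
#' \eqn{\sigma}. Noise models:
#' \describe{
#'   \item{none}{returns \code{K0 f} exactly.}
#'   \item{gaussian}{adds i.i.d. \eqn{N(0, \sigma^2)} to each entry.}
#'   \item{rician}{magnitude of the complex signal
#'     \eqn{|K_0 f + n_1 + i\, n_2|} with independent Gaussian quadrature
#'     channels; the standard model for magnitude MRI. Rician signals are
#'     always non-negative.}
#' }
#'
#' @param spectrum an [md_spectrum()] on the kernel's grid.
#' @param kernel a [build_kernel()] result.
#' @param snr positive signal-to-noise ratio; required unless
#'   \code{noise_model = "none"}.
#' @param noise_model \code{"none"}, \code{"gaussian"} or \code{"rician"}.
#' @param seed integer seed for the noise draw; the caller's RNG state is
#'   left untouched and the same seed reproduces the signal bit for bit.
#' @return A \code{signal_vector}: numeric of length d with the scheme and
#'   noise metadata attached as attributes.
#' @export
simulate_signal <- function(spectrum, kernel, snr = NULL,
                            noise_model = c("none", "gaussian", "rician"),
                            seed = NULL) {
  stopifnot(inherits(spectrum, "md_spectrum"), inherits(kernel, "kernel_matrix"))
  noise_model <- match.arg(noise_model)
  if (!grids_identical(spectrum$grid, attr(kernel, "grid")))
    stop("spectrum and kernel are defined on different grids")
  s0 <- as.numeric(unclass(kernel) %*% spectrum$weights)
  if (noise_model == "none") {
    s <- s0
  } else {
    if (is.null(snr) || !is.finite(snr) || snr <= 0)
      stop("snr must be a positive number when noise is simulated")
    sigma <- max(abs(s0)) / snr
    s <- with_seed(seed, {
      if (noise_model == "gaussian") {
        s0 + stats::rnorm(length(s0), 0, sigma)
      } else {
        sqrt((s0 + stats::rnorm(length(s0), 0, sigma))^2 +
               stats::rnorm(length(s0), 0, sigma)^2)
      }
    })
  }
  structure(s, scheme = attr(kernel, "scheme"),
            noise = list(model = noise_model, snr = snr, seed = seed),
            class = "signal_vector")
}

#' @export
print.signal_vector <- function(x, ...) {
  nz <- attr(x, "noise")
  cat(sprintf("MD-MRI signal vector: d = %d, noise = %s%s\n",
              length(x), nz$model,
              if (!is.null(nz$snr)) sprintf(" (SNR %.3g)", nz$snr) else ""))
  invisible(x)
}
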