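#' Joint T1-T2-D spectrum
#'
#' A spectrum is the discretized joint distribution f(T1, T2, D) of
#' relaxation and diffusion values within a voxel: a non-negative weight
#' for each node of a [parameter_grid()], flattened in the grid's
#' canonical order (T1 slowest, D fastest).
#'
#' @param grid a [parameter_grid()].
#' @param weights non-negative numeric vector of length
#'   \code{grid_size(grid)}.
#' @param normalized logical; if \code{TRUE} the weights are checked to
#'   sum to 1 (within 1e-9). Normalized spectra are probability
#'   distributions; unnormalized ones carry signal amplitude.
#' @return An object of class \code{md_spectrum}.
#' @seealso [delta_spectrum()], [simulate_signal()], [invert_signal()],
#'   [marginalize()]
#' @export
md_spectrum <- function(grid, weights, normalized = FALSE) {
  stopifnot(inherits(grid, "parameter_grid"))
  weights <- as.numeric(weights)
  if (length(weights) != grid_size(grid))
    stop(sprintf("weights length %d does not match grid size %d",
                 length(weights), grid_size(grid)))
  if (anyNA(weights) || any(weights < 0))
    stop("spectrum weights must be finite and non-negative")
  if (normalized && abs(sum(weights) - 1) > 1e-9)
    stop("normalized spectrum weights must sum to 1 within 1e-9")
  structure(list(grid = grid, weights = weights, normalized = normalized),
            class = "md_spectrum")
}

#' Point-mass spectrum at a single grid node
#'
#' @param grid a [parameter_grid()].
#' @param i1,i2,id node index along each axis, or
#' @param flat the flat node index (overrides the per-axis indices).
#' @param weight mass placed at the node (default 1).
#' @return An [md_spectrum()] that is zero except at one node.
#' @export
delta_spectrum <- function(grid, i1 = 1, i2 = 1, id = 1, flat = NULL,
                           weight = 1) {
  if (is.null(flat)) flat <- grid_index(grid, i1, i2, id)
  w <- numeric(grid_size(grid))
  w[flat] <- weight
  md_spectrum(grid, w, normalized = isTRUE(all.equal(weight, 1)))
}

#' Flat-index argmax of a spectrum
#' @param spectrum an [md_spectrum()].
#' @return The flat index of the largest weight (first on ties).
#' @export
spectrum_argmax <- function(spectrum) {
  stopifnot(inherits(spectrum, "md_spectrum"))
  which.max(spectrum$weights)
}

#' @export
print.md_spectrum <- function(x, ...) {
  cat(sprintf("T1-T2-D spectrum on %d nodes; total mass %.6g%s\n",
              grid_size(x$grid), sum(x$weights),
              if (x$normalized) " (normalized)" else ""))
  nz <- sum(x$weights > 0)
  cat(sprintf("  %d non-zero weights; argmax at flat index %d\n",
              nz, spectrum_argmax(x)))
  invisible(x)
}

#' 2D correlation spectrum
#'
#' The marginal of a 3D spectrum over one dropped axis, as produced by
#' [marginalize()]: a non-negative matrix over the two retained axes.
#'
#' @param pair one of \code{"T1-T2"}, \code{"T1-D"}, \code{"T2-D"}.
#' @param axis1,axis2 node vectors of the retained axes, in the order
#'   named by \code{pair}.
#' @param weights non-negative matrix, \code{length(axis1)} rows by
#'   \code{length(axis2)} columns.
#' @return An object of class \code{md_spectrum2d}.
#' @export
md_spectrum2d <- function(pair, axis1, axis2, weights) {
  pair <- match.arg(pair, c("T1-T2", "T1-D", "T2-D"))
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == length(axis1), ncol(weights) == length(axis2))
  if (anyNA(weights) || any(weights < 0))
    stop("2D spectrum weights must be finite and non-negative")
  structure(list(pair = pair, axis1 = as.numeric(axis1),
                 axis2 = as.numeric(axis2), weights = weights),
            class = "md_spectrum2d")
}

#' @export
print.md_spectrum2d <- function(x, ...) {
  cat(sprintf("%s correlation spectrum: %d x %d cells, total mass %.6g\n",
              x$pair, nrow(x$weights), ncol(x$weights), sum(x$weights)))
  invisible(x)
}

#' Export a 2D spectrum as CSV
#'
#' Writes a matrix CSV whose first row holds the second-axis nodes and
#' whose first column holds the first-axis nodes (corner cell = pair tag).
#'
#' @param spectrum2d an [md_spectrum2d()].
#' @param path output file.
#' @export
write_spectrum2d <- function(spectrum2d, path) {
  stopifnot(inherits(spectrum2d, "md_spectrum2d"))
  m <- cbind(spectrum2d$axis1, spectrum2d$weights)
  colnames(m) <- c(spectrum2d$pair, format(spectrum2d$axis2, digits = 6))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
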