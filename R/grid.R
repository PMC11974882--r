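#' Discretization grid for T1-T2-D spectra
#'
#' A parameter grid discretizes the continuous relaxation-diffusion domain
#' into the Cartesian product of three strictly increasing node vectors:
#' longitudinal relaxation time T1 (s), transverse relaxation time T2 (s)
#' and apparent diffusivity D (\eqn{\mu m^2}/ms). A spectrum is a
#' non-negative weight per grid node.
#'
#' @section Flat indexing:
#' Grid nodes are flattened to a single vector of length
#' \code{N = n1 * n2 * nd} with T1 varying slowest, T2 in the middle and D
#' fastest: node \code{(i1, i2, id)} (1-based along each axis) maps to flat
#' index \code{((i1 - 1) * n2 + (i2 - 1)) * nd + id}. [grid_index()] and
#' [grid_unindex()] implement the bijection; every flat vector in the
#' package (spectra, kernel columns) uses this order.
#'
#' @param t1 strictly increasing, positive T1 nodes in seconds.
#' @param t2 strictly increasing, positive T2 nodes in seconds.
#' @param d strictly increasing, positive diffusivity nodes in
#'   \eqn{\mu m^2}/ms.
#' @return An object of class \code{parameter_grid}.
#' @seealso [default_grid()], [build_kernel()], [md_spectrum()]
#' @export
parameter_grid <- function(t1, t2, d) {
  check_axis <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) < 1 || anyNA(x) || any(x <= 0))
      stop(sprintf("%s nodes must be positive finite numbers", nm))
    if (is.unsorted(x, strictly = TRUE))
      stop(sprintf("%s nodes must be strictly increasing", nm))
    x
  }
  g <- list(t1 = check_axis(t1, "T1"), t2 = check_axis(t2, "T2"),
            d = check_axis(d, "D"))
  class(g) <- "parameter_grid"
  g
}

#' Default log-spaced grid
#'
#' Log-spaced nodes spanning fixed-tissue values: T1 in 0.05--5 s, T2 in
#' 5--500 ms, D in 0.01--3 \eqn{\mu m^2}/ms. The default 20 nodes per axis
#' (N = 8000) suits single-voxel inversion; coarser grids (e.g. 10 per
#' axis) keep multi-voxel benchmarks desk-scale.
#'
#' @param n1,n2,nd number of nodes per axis.
#' @param t1_range,t2_range,d_range axis ranges (length-2 numeric).
#' @return A [parameter_grid()].
#' @export
default_grid <- function(n1 = 20, n2 = 20, nd = 20,
                         t1_range = c(0.05, 5),
                         t2_range = c(0.005, 0.5),
                         d_range = c(0.01, 3)) {
  logseq <- function(r, n) exp(seq(log(r[1]), log(r[2]), length.out = n))
  parameter_grid(logseq(t1_range, n1), logseq(t2_range, n2), logseq(d_range, nd))
}

#' Size of a parameter grid
#' @param grid a [parameter_grid()].
#' @return Total number of nodes \code{N = n1 * n2 * nd}.
#' @export
grid_size <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  length(grid$t1) * length(grid$t2) * length(grid$d)
}

#' Flat index bijection for grid nodes
#'
#' @param grid a [parameter_grid()].
#' @param i1,i2,id 1-based node indices along the T1, T2 and D axes
#'   (vectorized).
#' @return \code{grid_index} returns flat indices; \code{grid_unindex}
#'   returns a matrix with columns \code{i1}, \code{i2}, \code{id}.
#' @export
grid_index <- function(grid, i1, i2, id) {
  n2 <- length(grid$t2); nd <- length(grid$d)
  stopifnot(all(i1 >= 1 & i1 <= length(grid$t1)),
            all(i2 >= 1 & i2 <= n2), all(id >= 1 & id <= nd))
  ((i1 - 1) * n2 + (i2 - 1)) * nd + id
}

#' @rdname grid_index
#' @param flat flat node indices in \code{1:grid_size(grid)}.
#' @export
grid_unindex <- function(grid, flat) {
  n2 <- length(grid$t2); nd <- length(grid$d)
  stopifnot(all(flat >= 1 & flat <= grid_size(grid)))
  flat0 <- flat - 1
  id <- flat0 %% nd
  rest <- flat0 %/% nd
  cbind(i1 = rest %/% n2 + 1, i2 = rest %% n2 + 1, id = id + 1)
}

#' Node coordinates for flat indices
#' @inheritParams grid_unindex
#' @return Matrix with columns \code{t1}, \code{t2}, \code{d} (node values).
#' @export
grid_nodes <- function(grid, flat = seq_len(grid_size(grid))) {
  ix <- grid_unindex(grid, flat)
  cbind(t1 = grid$t1[ix[, "i1"]], t2 = grid$t2[ix[, "i2"]],
        d = grid$d[ix[, "id"]])
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("T1-T2-D grid: %d x %d x %d = %d nodes\n",
              length(x$t1), length(x$t2), length(x$d), grid_size(x)))
  cat(sprintf("  T1: [%.4g, %.4g] s  T2: [%.4g, %.4g] s  D: [%.4g, %.4g] um^2/ms\n",
              min(x$t1), max(x$t1), min(x$t2), max(x$t2), min(x$d), max(x$d)))
  invisible(x)
}
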