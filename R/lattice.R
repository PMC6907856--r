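#' Finite triangular-lattice window of binary cell states
#'
#' A `lattice_window` holds the on/off signaling states of cells packed on a
#' finite six-neighbor (triangular) lattice, realized as a brick-like offset
#' grid: cells are 2:1 rectangles with the long axis along the signaling (y)
#' direction, stacked in columns, with every other column shifted by half a
#' cell length.  Each interior cell therefore touches the cells directly
#' above and below it plus two overlapping cells in each adjacent column.
#' Row 1 is the biofilm-interior side (the signal source); the signal
#' propagates down the rows.
#'
#' @param states integer matrix of 0/1 values, one row per lattice row.
#' @param phi optional generating on-fraction, stored as metadata.
#'
#' @return An object of class `lattice_window`: a list with elements
#'   `states` (0/1 integer matrix), `n_rows`, `n_cols`, `parity` (which
#'   columns are offset; `"even"` means columns 2, 4, ... are shifted down
#'   by half a cell length) and `phi` (generating on-fraction or `NA`).
#' @export
lattice_window <- function(states, phi = NA_real_) {
  states <- as.matrix(states)
  if (nrow(states) < 1L || ncol(states) < 1L)
    stop("lattice dimensions must be strictly positive")
  storage.mode(states) <- "integer"
  if (anyNA(states) || !all(states == 0L | states == 1L))
    stop("states must contain only 0/1 values")
  structure(
    list(states = states, n_rows = nrow(states), n_cols = ncol(states),
         parity = "even", phi = phi),
    class = "lattice_window"
  )
}

#' @export
print.lattice_window <- function(x, ...) {
  cat(sprintf("<lattice_window> %d x %d cells, on-fraction %.4f\n",
              x$n_rows, x$n_cols, on_fraction(x)))
  invisible(x)
}

#' Fraction of on-cells in a lattice window
#'
#' @param lattice a [lattice_window()].
#' @return The fraction of cells with state 1.
#' @export
on_fraction <- function(lattice) {
  stopifnot(inherits(lattice, "lattice_window"))
  mean(lattice$states)
}

#' Six-neighborhood of a lattice site
#'
#' Returns the in-bounds neighbors of a site on the offset triangular grid.
#' Interior sites have exactly six neighbors: the sites directly above and
#' below in the same column, and two sites in each adjacent column whose
#' rows depend on the column parity (columns 2, 4, ... are shifted down by
#' half a cell length).
#'
#' @param site length-2 integer vector `c(row, col)`, 1-based.
#' @param dims length-2 integer vector `c(n_rows, n_cols)`.
#' @return Integer matrix with columns `row`, `col`, one neighbor per row,
#'   in a fixed deterministic order.
#' @examples
#' neighbors(c(5, 5), c(10, 10))   # interior: 6 neighbors
#' neighbors(c(1, 1), c(10, 10))   # corner: fewer
#' @export
neighbors <- function(site, dims) {
  site <- as.integer(site); dims <- as.integer(dims)
  if (length(site) != 2L || length(dims) != 2L)
    stop("site and dims must each have length 2")
  if (site[1] < 1L || site[1] > dims[1] || site[2] < 1L || site[2] > dims[2])
    stop("site is outside the lattice")
  nb <- neighbor_sites_cpp(site[1] - 1L, site[2] - 1L, dims[1], dims[2]) + 1L
  colnames(nb) <- c("row", "col")
  nb
}

#' Uncorrelated random lattice (basic site percolation)
#'
#' Fills an `n_rows` x `n_cols` window with independent Bernoulli(`phi`)
#' states, the null model of basic site percolation.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param phi on-cell probability in `[0, 1]`.
#' @return A [lattice_window()].
#' @export
random_fill <- function(n_rows, n_cols, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi < 0 || phi > 1)
    stop("phi must be a probability in [0, 1]")
  states <- matrix(as.integer(runif(n_rows * n_cols) < phi), n_rows, n_cols)
  lattice_window(states, phi = phi)
}

#' Row-profile random lattice
#'
#' Fills each row independently with its own Bernoulli probability.  This is
#' the direct sampling route for spatially decaying on-fractions (mutant
#' model with no inheritance correlation).
#'
#' @param phi_rows vector of per-row on-probabilities.
#' @param n_cols number of columns.
#' @return A [lattice_window()].
#' @export
random_fill_profile <- function(phi_rows, n_cols) {
  if (any(phi_rows < 0 | phi_rows > 1)) stop("row probabilities must lie in [0, 1]")
  n_rows <- length(phi_rows)
  states <- matrix(as.integer(runif(n_rows * n_cols) <
                                rep(phi_rows, times = n_cols)),
                   n_rows, n_cols)
  lattice_window(states, phi = mean(phi_rows))
}

#' Label connected on-cell clusters
#'
#' Partitions the on-cells into maximal connected components under the
#' six-neighbor relation (union-find).  A lattice spans if some component
#' touches both the first and the last row, i.e. a connected path of
#' on-cells crosses the window along the signaling direction.
#'
#' @param lattice a [lattice_window()].
#' @return An object of class `cluster_summary`: list with `sizes` (integer
#'   vector of component cell counts), `spanning` (logical), `n_on`,
#'   `n_total`, and `labels` (integer matrix, 0 for off-cells).
#' @export
label_clusters <- function(lattice) {
  stopifnot(inherits(lattice, "lattice_window"))
  res <- label_clusters_cpp(lattice$states)
  structure(
    list(sizes = as.integer(res$sizes), spanning = res$spanning,
         n_on = sum(lattice$states), n_total = length(lattice$states),
         labels = res$labels),
    class = "cluster_summary"
  )
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("<cluster_summary> %d clusters, %d/%d on-cells, spanning: %s\n",
              length(x$sizes), x$n_on, x$n_total, x$spanning))
  invisible(x)
}

#' Does a connected on-path cross the window?
#'
#' @param lattice a [lattice_window()].
#' @return `TRUE` iff a connected path of on-cells runs from the first to
#'   the last row.
#' @export
is_spanning <- function(lattice) {
  label_clusters(lattice)$spanning
}
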