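#' Render a synthetic fluorescence image of a lattice
#'
#' Stand-in for microscope output with known ground truth: each cell is
#' drawn as a rectangle (`pixel_scale` pixels wide, `2 * pixel_scale` tall,
#' shifted columns offset down by half a cell length), its pixels set to
#' the cell-state mean intensity plus i.i.d. Gaussian noise.  Intensities are
#' bimodal by construction; a per-pixel cell-identifier mask and the
#' per-cell truth table are recorded.
#'
#' @param lattice a [lattice_window()].
#' @param pixel_scale pixels per cell width (>= 1; default 4, so a 2-pixel
#'   median-filter radius is meaningful relative to cell size).
#' @param on_mean,off_mean mean intensities of on/off cells (arbitrary
#'   units; `on_mean > off_mean`).
#' @param noise_sd Gaussian pixel-noise sd (>= 0); the defaults give a
#'   4-sd mode separation.
#' @return Object of class `synthetic_image`: list with `intensity` (pixel
#'   matrix; the staggered half-cell margins are cropped so every pixel
#'   belongs to a cell), `mask` (integer cell ids), `truth`
#'   (data.frame `cell`, `row`, `col`, `state`), `pixel_scale`, `on_mean`,
#'   `off_mean`, `noise_sd`.
#' @export
render_image <- function(lattice, pixel_scale = 4L, on_mean = 1,
                         off_mean = 0.5, noise_sd = 0.125) {
  stopifnot(inherits(lattice, "lattice_window"))
  s <- as.integer(pixel_scale)
  if (s < 1L) stop("pixel_scale must be >= 1")
  if (on_mean <= off_mean) stop("on_mean must exceed off_mean")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  nr <- lattice$n_rows; nc <- lattice$n_cols
  mask <- matrix(0L, nr * 2L * s + s, nc * s)
  intensity <- matrix(off_mean, nr * 2L * s + s, nc * s)
  for (j in seq_len(nc)) {
    o <- if (j %% 2L == 0L) s else 0L
    cols <- ((j - 1L) * s + 1L):(j * s)
    for (i in seq_len(nr)) {
      rows <- ((i - 1L) * 2L * s + 1L + o):(i * 2L * s + o)
      mask[rows, cols] <- i + (j - 1L) * nr
      intensity[rows, cols] <-
        if (lattice$states[i, j] == 1L) on_mean else off_mean
    }
  }
  # crop the staggered half-cell margins so the frame is full of cells,
  # like the experimental window
  keep <- (s + 1L):(nr * 2L * s)
  mask <- mask[keep, , drop = FALSE]
  intensity <- intensity[keep, , drop = FALSE]
  if (noise_sd > 0)
    intensity <- intensity + matrix(rnorm(length(intensity), 0, noise_sd),
                                    nrow(intensity), ncol(intensity))
  truth <- data.frame(cell = as.vector(outer(seq_len(nr), seq_len(nc) - 1L,
                                             function(i, j) i + j * nr)),
                      row = rep(seq_len(nr), nc),
                      col = rep(seq_len(nc), each = nr),
                      state = as.vector(lattice$states))
  structure(list(intensity = intensity, mask = mask, truth = truth,
                 pixel_scale = s, on_mean = on_mean, off_mean = off_mean,
                 noise_sd = noise_sd),
            class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("<synthetic_image> %d x %d px, %d cells, noise sd %.3g\n",
              nrow(x$intensity), ncol(x$intensity), nrow(x$truth),
              x$noise_sd))
  invisible(x)
}

#' Threshold and median-filter an image
#'
#' The first two steps of the imaging pipeline: pixelwise thresholding to a
#' binary field, then a median filter of the given pixel radius so that
#' clusters of on-cells become contiguous white regions.  The default
#' threshold is the midpoint between the two intensity modes.
#'
#' @param image a [render_image()] object.
#' @param threshold intensity cutoff; default midpoint of the on/off means.
#' @param median_radius disc radius of the median filter in pixels
#'   (default 2; 0 skips filtering).
#' @return Binary integer matrix aligned with `image$mask`.
#' @export
threshold_and_filter <- function(image, threshold = NULL, median_radius = 2) {
  stopifnot(inherits(image, "synthetic_image"))
  if (is.null(threshold)) threshold <- (image$on_mean + image$off_mean) / 2
  binary <- matrix(as.integer(image$intensity > threshold),
                   nrow(image$intensity), ncol(image$intensity))
  if (median_radius > 0)
    binary <- median_filter_binary_cpp(binary, median_radius)
  binary
}

#' Cluster sizes (in cells) from a binary image
#'
#' Enumerates contiguous white regions of the binary field (8-connected
#' pixels) and counts, for each region, the segmented cells having the
#' strict majority (> 50%) of their mask pixels inside it.  Regions
#' containing no majority cell are dropped.  This is the image-side
#' counterpart of [label_clusters()].
#'
#' @param binary binary pixel matrix (from [threshold_and_filter()]).
#' @param mask integer cell-id mask of the same dimensions.
#' @return Integer vector of per-region cell counts.
#' @export
clusters_from_image <- function(binary, mask) {
  if (!all(dim(binary) == dim(mask)))
    stop("binary field and mask dimensions differ")
  labels <- label_pixels8_cpp(binary)
  px <- which(mask > 0L)
  cell <- mask[px]; lab <- labels[px]
  npix <- tabulate(cell)
  sel <- lab > 0L
  if (!any(sel)) return(integer(0))
  cell <- cell[sel]; lab <- lab[sel]
  K <- max(lab)
  idx <- (cell - 1L) * K + lab          # (cell, region) pair key
  cnt <- tabulate(idx, nbins = max(idx))
  nz <- which(cnt > 0L)
  pair_cell <- (nz - 1L) %/% K + 1L
  pair_lab <- (nz - 1L) %% K + 1L
  majority <- cnt[nz] > npix[pair_cell] / 2
  sizes <- tabulate(pair_lab[majority], nbins = K)
  as.integer(sizes[sizes > 0L])
}

#' Synthetic lineage table
#'
#' Draws mother states at the stationary on-fraction of the inheritance
#' chain and daughter states through the conditionals — a synthetic
#' stand-in for lineage-tracing measurements of the division correlation.
#'
#' @param probs a `conditional_probs` object.
#' @param n_records number of division events (>= 1).
#' @return data.frame with 0/1 columns `mother`, `daughter` and a `time`
#'   column (event index, arbitrary units).
#' @export
make_lineage_table <- function(probs, n_records) {
  stopifnot(inherits(probs, "conditional_probs"))
  n_records <- as.integer(n_records)
  if (n_records < 1L) stop("n_records must be >= 1")
  # perfectly correlated chain: any on-fraction is stationary; use 1/2
  phi <- if (1 + probs$p_on_off - probs$p_on_on <= .Machine$double.eps) 0.5
         else stationary_phi(probs)
  mother <- as.integer(runif(n_records) < phi)
  p <- ifelse(mother == 1L, probs$p_on_on, probs$p_on_off)
  daughter <- as.integer(runif(n_records) < p)
  data.frame(mother = mother, daughter = daughter,
             time = seq_len(n_records))
}
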