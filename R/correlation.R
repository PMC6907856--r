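#' Rasterize a lattice window into a binary pixel field
#'
#' Renders each cell as a rectangle of `pixel_scale` pixels across by
#' `2 * pixel_scale` pixels along the signaling direction (aspect ratio 2,
#' long axis along y), with shifted columns offset down by half a cell
#' length (`pixel_scale` pixels).  Pixel rows run along y, pixel columns
#' along x.  The staggered half-cell margins at the top and bottom (where
#' only alternate columns carry a cell) are cropped away, so every
#' returned pixel belongs to a cell — like the experimental window, which
#' is full of cells.
#'
#' @param lattice a [lattice_window()].
#' @param pixel_scale pixels per cell width (>= 1).
#' @return Binary integer matrix of pixels.
#' @export
rasterize_lattice <- function(lattice, pixel_scale = 2L) {
  stopifnot(inherits(lattice, "lattice_window"))
  s <- as.integer(pixel_scale)
  if (s < 1L) stop("pixel_scale must be >= 1")
  nr <- lattice$n_rows; nc <- lattice$n_cols
  field <- matrix(0L, nr * 2L * s + s, nc * s)
  for (j in seq_len(nc)) {
    o <- if (j %% 2L == 0L) s else 0L
    cols <- ((j - 1L) * s + 1L):(j * s)
    for (i in seq_len(nr)) {
      if (lattice$states[i, j] == 1L)
        field[((i - 1L) * 2L * s + 1L + o):(i * 2L * s + o), cols] <- 1L
    }
  }
  field[(s + 1L):(nr * 2L * s), , drop = FALSE]
}

#' Spatial autocorrelation surface of a binary field
#'
#' Mean-subtracted autocorrelation of a binary pixel or cell field,
#' \deqn{C(\Delta) = \langle (s_i - \bar s)(s_j - \bar s)\rangle_\Delta,}
#' averaged over every in-window pair at displacement \eqn{\Delta} (per-lag
#' pair counts as denominators, no periodic wrap), and normalized so the
#' origin equals 1 when `normalize = TRUE`.  Computed via FFT; the
#' `"direct"` method is the brute-force pair sum (identical values, for
#' small fields and verification).
#'
#' @param field numeric/integer matrix with values in `{0, 1}`; rows run
#'   along the signaling (y) direction.
#' @param method `"fft"` (default) or `"direct"`.
#' @param normalize divide by the origin value (the field variance).
#' @return Object of class `correlation_surface`: numeric matrix indexed by
#'   y lag (rows, `-(m-1) ... m-1`) and x lag (columns), with attributes
#'   `lag_y`, `lag_x`.
#' @export
autocorrelation <- function(field, method = c("fft", "direct"),
                            normalize = TRUE) {
  method <- match.arg(method)
  field <- as.matrix(field)
  if (!all(field %in% c(0, 1))) stop("field must be binary (0/1)")
  if (min(field) == max(field)) stop("constant field: zero variance")
  m <- nrow(field); n <- ncol(field)
  f <- field - mean(field)
  if (method == "fft") {
    M <- stats::nextn(2L * m - 1L); N <- stats::nextn(2L * n - 1L)
    fp <- matrix(0, M, N); fp[1:m, 1:n] <- f
    Ff <- stats::fft(fp)
    S <- Re(stats::fft(Ff * Conj(Ff), inverse = TRUE)) / (M * N)
    dy <- -(m - 1L):(m - 1L); dx <- -(n - 1L):(n - 1L)
    surf <- S[(dy %% M) + 1L, (dx %% N) + 1L, drop = FALSE]
  } else {
    dy <- -(m - 1L):(m - 1L); dx <- -(n - 1L):(n - 1L)
    surf <- matrix(0, length(dy), length(dx))
    for (a in seq_along(dy)) {
      for (b in seq_along(dx)) {
        u <- dy[a]; v <- dx[b]
        ri <- max(1L, 1L - u):min(m, m - u)
        ci <- max(1L, 1L - v):min(n, n - v)
        surf[a, b] <- sum(f[ri, ci] * f[ri + u, ci + v])
      }
    }
  }
  counts <- outer(m - abs(-(m - 1L):(m - 1L)), n - abs(-(n - 1L):(n - 1L)))
  surf <- surf / counts
  if (normalize) surf <- surf / surf[m, n]
  structure(surf, lag_y = -(m - 1L):(m - 1L), lag_x = -(n - 1L):(n - 1L),
            class = "correlation_surface")
}

#' Correlation profile and integrated correlation length
#'
#' Reduces a 2D correlation surface to a 1D profile: the radial average
#' over annuli of unit width, or the axis profiles along x (perpendicular
#' to signaling) or y (parallel).  The correlation length is the
#' trapezoidal integral of the profile from lag 0 to the maximal available
#' lag (no tail truncation).
#'
#' @param surface a [autocorrelation()] surface.
#' @param axis `"radial"`, `"x"` or `"y"`.
#' @return Object of class `correlation_profile`: data.frame with columns
#'   `lag`, `value`; attributes `axis` and `xi` (integrated correlation
#'   length, same units as the lags).
#' @export
correlation_profile <- function(surface, axis = c("radial", "x", "y")) {
  axis <- match.arg(axis)
  stopifnot(inherits(surface, "correlation_surface"))
  lag_y <- attr(surface, "lag_y"); lag_x <- attr(surface, "lag_x")
  o_y <- which(lag_y == 0L); o_x <- which(lag_x == 0L)
  if (axis == "x") {
    lag <- lag_x[lag_x >= 0L]
    value <- as.numeric(surface[o_y, lag_x >= 0L])
  } else if (axis == "y") {
    lag <- lag_y[lag_y >= 0L]
    value <- as.numeric(surface[lag_y >= 0L, o_x])
  } else {
    r <- round(sqrt(outer(lag_y^2, lag_x^2, `+`)))
    lag <- 0:max(r)
    value <- vapply(lag, function(k) mean(surface[r == k]), numeric(1))
  }
  xi <- trapezoid(lag, value)
  structure(data.frame(lag = lag, value = value),
            axis = axis, xi = xi,
            class = c("correlation_profile", "data.frame"))
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Integrated correlation length of a profile
#'
#' @param profile a [correlation_profile()].
#' @return The trapezoidal integral of the profile over its lags.
#' @export
correlation_length <- function(profile) {
  stopifnot(inherits(profile, "correlation_profile"))
  attr(profile, "xi")
}

#' Randomize on-cell locations (percolation-theory control)
#'
#' Retains the cell locations and the number of on-cells, but randomly
#' permutes which cells are on — the state-randomized control against
#' which spatial correlations are judged.
#'
#' @param lattice a [lattice_window()].
#' @return A [lattice_window()] with the same state multiset.
#' @export
randomize_states <- function(lattice) {
  stopifnot(inherits(lattice, "lattice_window"))
  states <- matrix(sample(as.vector(lattice$states)),
                   lattice$n_rows, lattice$n_cols)
  lattice_window(states, phi = lattice$phi)
}

#' Adjacent-cell order parameter
#'
#' The correlation order parameter \eqn{\rho = p(on|on) - p(on|off)}
#' estimated over adjacent cell pairs.  With `axis = "y"` (default, the
#' experimental definition) the pairs are adjacent in the signaling
#' direction: same column, consecutive rows, `p(on|on)` being the
#' probability that a cell is on given the cell above it is on.  With
#' `axis = "x"` the pairs are the lattice neighbors in adjacent columns
#' (two per cell), measuring the transverse correlation produced by
#' sideways daughter placement and displacement.
#'
#' @param lattice a [lattice_window()].
#' @param axis `"y"` (signaling direction) or `"x"` (transverse).
#' @return The estimated order parameter.
#' @export
estimate_rho_adj <- function(lattice, axis = c("y", "x")) {
  stopifnot(inherits(lattice, "lattice_window"))
  axis <- match.arg(axis)
  s <- lattice$states
  if (axis == "y") {
    first <- s[-nrow(s), , drop = FALSE]
    second <- s[-1L, , drop = FALSE]
  } else {
    nr <- nrow(s); nc <- ncol(s)
    first <- integer(0); second <- integer(0)
    for (j in seq_len(nc - 1L)) {
      p <- as.integer(j %% 2L == 0L)  # shifted column
      for (di in c(p - 1L, p)) {
        rows <- max(1L, 1L - di):min(nr, nr - di)
        first <- c(first, s[rows, j])
        second <- c(second, s[rows + di, j + 1L])
      }
    }
  }
  if (!any(first == 1L) || !any(first == 0L))
    stop("conditional probabilities undefined: conditioning cells all one state")
  mean(second[first == 1L]) - mean(second[first == 0L])
}

#' Division order parameter from lineage records
#'
#' \eqn{\rho_{div} = p(on|on) - p(on|off)} tabulated over mother-daughter
#' division events.
#'
#' @param records data.frame with 0/1 columns `mother` and `daughter` (one
#'   row per division), as produced by [grow_lattice()] or
#'   [make_lineage_table()].
#' @return The estimated division correlation.
#' @export
estimate_rho_div <- function(records) {
  if (!all(c("mother", "daughter") %in% names(records)))
    stop("records must have columns 'mother' and 'daughter'")
  m <- records$mother; d <- records$daughter
  if (!any(m == 1L) || !any(m == 0L))
    stop("both mother states required to estimate rho_div")
  mean(d[m == 1L]) - mean(d[m == 0L])
}

#' Compare correlation lengths against the randomized control
#'
#' For an ensemble of lattices, computes the integrated correlation lengths
#' along x and y on rasterized pixel fields, repeats the computation with
#' on-cell locations randomized, and tests the difference of ensemble means
#' with a two-sample z-test (Gaussian-error assumption).
#'
#' @param lattices list of [lattice_window()]s (>= 2).
#' @param pixel_scale pixels per cell width for rasterization.
#' @return data.frame with one row per axis (`x`, `y`): mean and standard
#'   error of the actual and randomized correlation lengths (pixel units),
#'   the z statistic and two-sided p-value.
#' @export
compare_correlation_lengths <- function(lattices, pixel_scale = 2L) {
  if (length(lattices) < 2L) stop("need an ensemble of at least 2 lattices")
  xi <- function(l) {
    surf <- autocorrelation(rasterize_lattice(l, pixel_scale))
    c(x = attr(correlation_profile(surf, "x"), "xi"),
      y = attr(correlation_profile(surf, "y"), "xi"))
  }
  act <- t(vapply(lattices, xi, numeric(2)))
  rnd <- t(vapply(lattices, function(l) xi(randomize_states(l)), numeric(2)))
  n <- length(lattices)
  out <- do.call(rbind, lapply(c("x", "y"), function(ax) {
    ma <- mean(act[, ax]); sa <- sd(act[, ax]) / sqrt(n)
    mr <- mean(rnd[, ax]); sr <- sd(rnd[, ax]) / sqrt(n)
    z <- (ma - mr) / sqrt(sa^2 + sr^2)
    data.frame(axis = ax, xi_actual = ma, se_actual = sa,
               xi_random = mr, se_random = sr,
               z = z, p_value = 2 * pnorm(-abs(z)))
  }))
  out
}
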