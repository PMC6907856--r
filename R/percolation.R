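#' Spanning-probability (connectivity) curve
#'
#' Estimates, for each on-fraction in `phi_grid`, the probability that a
#' connected path of on-cells crosses the window from the first to the last
#' row, over `n_reps` independently generated lattices per point.
#'
#' @param lattice_source function of one argument `phi` returning a
#'   [lattice_window()]; e.g. `function(p) random_fill(35, 230, p)` for the
#'   uncorrelated model, or a [grow_lattice()] wrapper for the mechanistic
#'   model.
#' @param phi_grid strictly increasing vector of on-fractions.
#' @param n_reps lattices per grid point.
#' @return Object of class `connectivity_curve`: data.frame with columns
#'   `phi`, `spanning_prob`, `n_reps` and `ci_halfwidth` (binomial standard
#'   error).
#' @export
connectivity_curve <- function(lattice_source, phi_grid, n_reps = 100L) {
  if (length(phi_grid) < 1L) stop("phi_grid must be non-empty")
  if (is.unsorted(phi_grid, strictly = TRUE))
    stop("phi_grid must be strictly increasing")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  p_hat <- vapply(phi_grid, function(phi) {
    mean(vapply(seq_len(n_reps),
                function(i) is_spanning(lattice_source(phi)), logical(1)))
  }, numeric(1))
  structure(
    data.frame(phi = phi_grid, spanning_prob = p_hat, n_reps = n_reps,
               ci_halfwidth = sqrt(p_hat * (1 - p_hat) / n_reps)),
    class = c("connectivity_curve", "data.frame")
  )
}

#' Connectivity threshold (50% spanning crossing)
#'
#' The finite-size connectivity threshold is the on-fraction at which the
#' spanning probability equals 50%.  The empirical curve is made monotone
#' by isotonic regression (pool-adjacent-violators) and the crossing is
#' located by linear interpolation.
#'
#' @param curve a [connectivity_curve()].
#' @param level crossing level (default 0.5).
#' @return The interpolated on-fraction at the crossing.
#' @export
connectivity_threshold <- function(curve, level = 0.5) {
  stopifnot(inherits(curve, "connectivity_curve"))
  p <- monotone_fit(curve$spanning_prob)
  phi <- curve$phi
  if (max(p) < level || min(p) > level)
    stop("connectivity curve does not bracket the crossing level")
  above <- which(p >= level)[1L]
  if (p[above] == level) return(phi[above])
  below <- max(which(p[seq_len(above - 1L)] < level))
  # interpolate between the last strictly-below point and the first at/above
  phi[below] + (level - p[below]) * (phi[above] - phi[below]) /
    (p[above] - p[below])
}

# pool-adjacent-violators isotonic regression (nondecreasing, equal weights)
monotone_fit <- function(y) {
  n <- length(y)
  val <- as.numeric(y); w <- rep(1, n)
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1L] + 1e-15) {
      newv <- (w[i] * val[i] + w[i + 1L] * val[i + 1L]) / (w[i] + w[i + 1L])
      val[i] <- newv; w[i] <- w[i] + w[i + 1L]
      val <- val[-(i + 1L)]; w <- w[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  rep(val, times = w)
}

#' Logarithmically binned cluster-size distribution
#'
#' Normalized estimate of the cluster-size distribution P(n) using bins at
#' powers of `base` (default 2).  Probabilities are reported per bin
#' (`prob`, summing to 1) and as densities (`density`, probability divided
#' by the integer width of the bin), the convention for log-log plots.
#' Raw sizes are retained: maximum-likelihood fitting always uses them,
#' never the binned values.
#'
#' @param sizes positive integer cluster sizes pooled over an ensemble.
#' @param base log-bin base (> 1).
#' @return Object of class `size_distribution`: data.frame with columns
#'   `lower`, `upper` (inclusive integer bin edges), `center` (geometric),
#'   `count`, `prob`, `density`; attribute `sizes` holds the raw data.
#' @export
size_distribution <- function(sizes, base = 2) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L) stop("no cluster sizes supplied")
  if (any(sizes < 1L)) stop("cluster sizes must be positive integers")
  if (base <= 1) stop("base must exceed 1")
  kmax <- ceiling(log(max(sizes) + 1) / log(base))
  lower <- unique(pmax(1L, as.integer(floor(base^(0:kmax)))))
  upper <- c(lower[-1L] - 1L, max(sizes))
  keep <- lower <= upper
  lower <- lower[keep]; upper <- upper[keep]
  counts <- vapply(seq_along(lower), function(k)
    sum(sizes >= lower[k] & sizes <= upper[k]), integer(1))
  width <- upper - lower + 1L
  out <- data.frame(lower = lower, upper = upper,
                    center = sqrt(lower * upper),
                    count = counts,
                    prob = counts / length(sizes),
                    density = counts / length(sizes) / width)
  attr(out, "sizes") <- sizes
  class(out) <- c("size_distribution", "data.frame")
  out
}

# Hurwitz zeta sum_{k>=0} (xmin + k)^(-a) by direct summation with an
# Euler-Maclaurin tail; accurate to ~1e-12 for a > 1.
hurwitz_zeta <- function(a, xmin, n_direct = 1000L) {
  k <- seq.int(xmin, xmin + n_direct - 1L)
  tail_from <- xmin + n_direct
  sum(k^(-a)) + tail_from^(1 - a) / (a - 1) + 0.5 * tail_from^(-a) +
    a * tail_from^(-a - 1) / 12
}

#' Discrete power-law fit by maximum likelihood
#'
#' Fits `P(n) = n^(-alpha) / zeta(alpha, xmin)` to the tail `n >= xmin` of
#' a sample of positive integers, maximizing the discrete (Hurwitz-zeta)
#' likelihood.  With `xmin = "auto"` the cutoff
#' is chosen by minimizing the Kolmogorov-Smirnov distance between the
#' fitted model and the empirical tail distribution; the default `xmin = 1`
#' fits the whole distribution.
#'
#' @param sizes positive integer sample (cluster sizes).
#' @param xmin integer cutoff, or `"auto"`.
#' @return Object of class `powerlaw_fit`: list with `alpha`, `xmin`,
#'   `n_tail`, `loglik` and `se` (asymptotic standard error from the
#'   observed information).
#' @export
powerlaw_mle <- function(sizes, xmin = 1L) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("sizes must be positive integers")
  if (identical(xmin, "auto")) {
    cands <- sort(unique(sizes))
    cands <- cands[cands <= stats::quantile(sizes, 0.9)]
    fits <- lapply(cands, function(xm) {
      tail_s <- sizes[sizes >= xm]
      if (length(tail_s) < 2L || length(unique(tail_s)) < 2L) return(NULL)
      f <- powerlaw_mle_fixed(tail_s, xm)
      f$ks <- powerlaw_ks(tail_s, f$alpha, xm)
      f
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0L) stop("no feasible xmin candidate")
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
    return(best)
  }
  xmin <- as.integer(xmin)
  if (xmin < 1L) stop("xmin must be >= 1")
  powerlaw_mle_fixed(sizes[sizes >= xmin], xmin)
}

powerlaw_mle_fixed <- function(tail_sizes, xmin) {
  n <- length(tail_sizes)
  if (n < 2L) stop("need at least 2 samples >= xmin")
  if (length(unique(tail_sizes)) < 2L)
    stop("all tail sizes identical: degenerate likelihood")
  slog <- sum(log(tail_sizes))
  nll <- function(a) n * log(hurwitz_zeta(a, xmin)) + a * slog
  opt <- optimize(nll, interval = c(1 + 1e-6, 25), tol = 1e-8)
  a <- opt$minimum
  h <- 1e-4
  d2 <- (nll(a + h) - 2 * nll(a) + nll(a - h)) / h^2
  structure(list(alpha = a, xmin = xmin, n_tail = n, loglik = -opt$objective,
                 se = if (d2 > 0) 1 / sqrt(d2) else NA_real_),
            class = "powerlaw_fit")
}

powerlaw_ks <- function(tail_sizes, alpha, xmin) {
  xs <- sort(unique(tail_sizes))
  z <- hurwitz_zeta(alpha, xmin)
  pmf <- (seq.int(xmin, max(xs)))^(-alpha) / z
  cdf_model <- cumsum(pmf)[xs - xmin + 1L]
  ecdf_vals <- cumsum(tabulate(tail_sizes - xmin + 1L,
                               nbins = max(xs) - xmin + 1L))[xs - xmin + 1L] /
    length(tail_sizes)
  max(abs(ecdf_vals - cdf_model))
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha = %.3f (se %.3f), xmin = %d, n_tail = %d\n",
              x$alpha, x$se, x$xmin, x$n_tail))
  invisible(x)
}

#' Binomial standard deviation of the on-fraction
#'
#' Under basic (uncorrelated) percolation the across-lattice standard
#' deviation of the on-fraction is `sqrt(phi (1 - phi) / n_cells)`.
#'
#' @param phi on-fraction.
#' @param n_cells number of cells in the window.
#' @return The binomial standard deviation.
#' @export
binomial_sd <- function(phi, n_cells) {
  check_prob(phi, "phi")
  if (n_cells < 1) stop("n_cells must be >= 1")
  sqrt(phi * (1 - phi) / n_cells)
}

#' Across-lattice standard deviation of the on-fraction
#'
#' @param lattices list of [lattice_window()]s.
#' @return Sample standard deviation of the per-lattice on-fractions.
#' @export
ensemble_phi_sd <- function(lattices) {
  if (length(lattices) < 2L) stop("need at least 2 lattices")
  sd(vapply(lattices, on_fraction, numeric(1)))
}

#' Pool cluster sizes over an ensemble
#'
#' @param lattices list of [lattice_window()]s.
#' @return Integer vector of all on-cluster sizes.
#' @export
pooled_cluster_sizes <- function(lattices) {
  unlist(lapply(lattices, function(l) label_clusters(l)$sizes))
}
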