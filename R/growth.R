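#' Mother-to-daughter inheritance probabilities
#'
#' Conditional probabilities that a daughter cell is on given the mother's
#' state, parameterized by the target on-fraction `phi` and the division
#' correlation `rho`.  Requiring that the on-fraction stays at `phi`
#' throughout growth gives
#' \deqn{q = p(on|on) = \phi + \rho - \phi\rho, \qquad
#'       r = p(on|off) = \phi - \phi\rho,}
#' so that `q - r = rho` exactly: `rho = 0` is uncorrelated inheritance and
#' `rho = 1` perfect phenotype copying.
#'
#' @param phi target on-fraction in `[0, 1]`.
#' @param rho division correlation in `[0, 1]`.
#' @return An object of class `conditional_probs`: list with `p_on_on` (q),
#'   `p_on_off` (r), `rho` and `phi`.
#' @export
inheritance_probs <- function(phi, rho) {
  check_prob(phi, "phi"); check_prob(rho, "rho")
  conditional_probs(p_on_on = phi + rho - phi * rho,
                    p_on_off = phi - phi * rho)
}

conditional_probs <- function(p_on_on, p_on_off) {
  check_prob(p_on_on, "p(on|on)"); check_prob(p_on_off, "p(on|off)")
  structure(list(p_on_on = p_on_on, p_on_off = p_on_off,
                 rho = p_on_on - p_on_off),
            class = "conditional_probs")
}

#' @export
print.conditional_probs <- function(x, ...) {
  cat(sprintf("<conditional_probs> q = p(on|on) = %.6f, r = p(on|off) = %.6f, rho = %.6f\n",
              x$p_on_on, x$p_on_off, x$rho))
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a probability in [0, 1]", name))
  invisible(x)
}

#' Stationary on-fraction of the inheritance chain
#'
#' Inverts the inheritance probabilities: the on-fraction preserved by a
#' mother-daughter chain with conditionals `(q, r)` is
#' \deqn{\phi = r / (1 + r - q).}
#'
#' @param probs a `conditional_probs` object (see [inheritance_probs()]).
#' @return The stationary on-fraction.
#' @export
stationary_phi <- function(probs) {
  stopifnot(inherits(probs, "conditional_probs"))
  den <- 1 + probs$p_on_off - probs$p_on_on
  if (den <= .Machine$double.eps)
    stop("degenerate chain (q = 1, r = 0): stationary fraction undefined")
  probs$p_on_off / den
}

#' Inheritance probabilities under differential growth rates
#'
#' When on-cells divide more slowly than off-cells (mean division time
#' `tau/gamma` vs `tau`, growth-rate ratio `gamma <= 1`), maintaining the
#' on-fraction at `phi` requires corrected conditionals
#' \deqn{q = \phi + \frac{\rho(1-\phi)}{1-(1-\gamma)\phi}, \qquad
#'       r = \phi - \frac{\gamma\phi\rho}{1-(1-\gamma)\phi},}
#' which still satisfy `q - r = rho` and make the dominant-eigenvector
#' on-fraction of the two-type growth dynamics equal `phi`
#' (see [growth_eigen()]).  `gamma = 1` recovers [inheritance_probs()].
#'
#' @inheritParams inheritance_probs
#' @param gamma on/off growth-rate ratio in `(0, 1]`.
#' @return A `conditional_probs` object.
#' @export
inheritance_probs_gamma <- function(phi, rho, gamma) {
  check_prob(phi, "phi"); check_prob(rho, "rho")
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]")
  D <- 1 - (1 - gamma) * phi
  q <- phi + rho * (1 - phi) / D
  r <- phi - gamma * phi * rho / D
  if (q > 1 + 1e-12)
    stop(sprintf("infeasible (phi, rho, gamma): p(on|on) = %.4f exceeds 1", q))
  if (r < -1e-12)
    stop(sprintf("infeasible (phi, rho, gamma): p(on|off) = %.4f below 0", r))
  conditional_probs(min(q, 1), max(r, 0))
}

#' Long-time growth rate and on-fraction of the two-type dynamics
#'
#' Deterministic dynamics of the on/off cell counts with growth-rate ratio
#' `gamma` (time in units of the off-cell division time):
#' \deqn{\dot n_{on} = \gamma q\, n_{on} + r\, n_{off}, \qquad
#'       \dot n_{off} = \gamma (1-q)\, n_{on} + (1-r)\, n_{off}.}
#' The dominant eigenvalue is
#' \deqn{\lambda_+ = \tfrac12\left[1 + \gamma q - r +
#'   \sqrt{(1+\gamma q - r)^2 - 4\gamma(q-r)}\right]}
#' and the corresponding eigenvector gives the long-time on-fraction
#' \deqn{\phi = r / (\lambda_+ + r - \gamma q).}
#'
#' @param probs a `conditional_probs` object.
#' @param gamma on/off growth-rate ratio in `(0, 1]`.
#' @return List with `lambda_plus` and `phi_steady`.
#' @export
growth_eigen <- function(probs, gamma) {
  stopifnot(inherits(probs, "conditional_probs"))
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  q <- probs$p_on_on; r <- probs$p_on_off
  disc <- (1 + gamma * q - r)^2 - 4 * gamma * (q - r)
  if (disc < 0) stop("negative discriminant: invalid (q, r, gamma)")
  lp <- 0.5 * (1 + gamma * q - r + sqrt(disc))
  list(lambda_plus = lp, phi_steady = r / (lp + r - gamma * q))
}

#' Draw an on-fraction for one lattice
#'
#' Gaussian draw with mean `phi_mean` and sd `phi_sd`, redrawn until it
#' falls in `[0, 1]` (across-lattice variability of the signaling fraction).
#'
#' @param phi_mean mean on-fraction in `[0, 1]`.
#' @param phi_sd across-lattice standard deviation (>= 0).
#' @return A single on-fraction in `[0, 1]`.
#' @export
sample_phi <- function(phi_mean, phi_sd) {
  check_prob(phi_mean, "phi_mean")
  if (phi_sd < 0) stop("phi_sd must be >= 0")
  if (phi_sd == 0) return(phi_mean)
  repeat {
    x <- rnorm(1L, phi_mean, phi_sd)
    if (x >= 0 && x <= 1) return(x)
  }
}

#' Exponentially decaying on-fraction profile
#'
#' Per-row on-fractions \eqn{\phi(y) = \phi_0 e^{-y/\lambda}} for rows
#' `y = 0 ... n_rows - 1`, with \eqn{\phi_0} normalized so the spatial
#' average over the rows equals `phi_mean`.  Models a signal dying out
#' along the propagation direction (mutant strain with low participation).
#'
#' @param phi_mean target spatial-average on-fraction.
#' @param lam decay length in cell lengths (`Inf` gives a uniform profile).
#' @param n_rows number of rows.
#' @param saturate if `TRUE`, clip per-row values at 1 when the required
#'   \eqn{\phi_0} exceeds 1 (the profile then saturates near the source and
#'   its mean falls below `phi_mean`); if `FALSE` (default), such profiles
#'   are an error.
#' @return Numeric vector of length `n_rows`; mean exactly `phi_mean`
#'   unless saturated.
#' @export
decayed_phi_profile <- function(phi_mean, lam, n_rows, saturate = FALSE) {
  check_prob(phi_mean, "phi_mean")
  if (!is.numeric(lam) || lam <= 0) stop("decay length must be > 0")
  if (is.infinite(lam)) return(rep(phi_mean, n_rows))
  w <- exp(-(seq_len(n_rows) - 1) / lam)
  phi0 <- phi_mean * n_rows / sum(w)
  if (phi0 > 1) {
    if (!saturate)
      stop(sprintf("profile infeasible: required phi_0 = %.3f exceeds 1", phi0))
    return(pmin(phi0 * w, 1))
  }
  phi0 * w
}

#' Growth-model configuration
#'
#' Bundles all parameters of the mechanistic correlated-growth model.
#' Defaults are the wild-type biofilm values: target on-fraction 0.43 with
#' across-lattice sd 0.07, division correlation 0.38, equal growth rates,
#' no spatial decay; lattices are generated 100 rows deep by 230 columns
#' and cropped to the 35 x 230 observation window by removing the top 55
#' and bottom 10 rows (growth reaches statistical steady state before the
#' window).
#'
#' @param phi_mean target on-fraction.
#' @param phi_sd across-lattice sd of the on-fraction (0 = fixed phi).
#' @param rho_div division correlation in `[0, 1]`.
#' @param tau_mean mean division time (time unit; 1 by convention).
#' @param tau_sd_ratio division-time sd as a fraction of `tau_mean`;
#'   `NULL` (default) draws it uniformly on (0, 1) per lattice, realizing
#'   an average over the insensitive range.
#' @param gamma on/off growth-rate ratio in `(0, 1]`; on-cells divide with
#'   mean time `tau_mean / gamma`.
#' @param decay_length spatial decay length of phi in cell lengths
#'   (`Inf` = uniform).
#' @param gen_rows,crop_top,crop_bottom,n_cols generation and cropping
#'   geometry; `gen_rows - crop_top - crop_bottom` is the window height.
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(phi_mean = 0.43, phi_sd = 0.07, rho_div = 0.38,
                          tau_mean = 1, tau_sd_ratio = NULL, gamma = 1,
                          decay_length = Inf, gen_rows = 100L,
                          crop_top = 55L, crop_bottom = 10L, n_cols = 230L) {
  check_prob(phi_mean, "phi_mean"); check_prob(rho_div, "rho_div")
  if (phi_sd < 0) stop("phi_sd must be >= 0")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  if (tau_mean <= 0) stop("tau_mean must be > 0")
  if (!is.null(tau_sd_ratio) && (tau_sd_ratio < 0 || tau_sd_ratio >= 1))
    stop("tau_sd_ratio must lie in [0, 1)")
  if (decay_length <= 0) stop("decay_length must be > 0")
  gen_rows <- as.integer(gen_rows); crop_top <- as.integer(crop_top)
  crop_bottom <- as.integer(crop_bottom); n_cols <- as.integer(n_cols)
  if (gen_rows - crop_top - crop_bottom < 1L)
    stop("cropping removes all generated rows")
  structure(list(phi_mean = phi_mean, phi_sd = phi_sd, rho_div = rho_div,
                 tau_mean = tau_mean, tau_sd_ratio = tau_sd_ratio,
                 gamma = gamma, decay_length = decay_length,
                 gen_rows = gen_rows, crop_top = crop_top,
                 crop_bottom = crop_bottom, n_cols = n_cols),
            class = "growth_config")
}

#' @export
print.growth_config <- function(x, ...) {
  cat(sprintf(paste0("<growth_config> phi = %.3f (sd %.3f), rho_div = %.2f, ",
                     "gamma = %.2f, lambda = %s, %d x %d -> %d x %d\n"),
              x$phi_mean, x$phi_sd, x$rho_div, x$gamma,
              format(x$decay_length), x$gen_rows, x$n_cols,
              x$gen_rows - x$crop_top - x$crop_bottom, x$n_cols))
  invisible(x)
}

# Per generated row, the on-fraction used for daughters born in that row.
# With finite decay length the profile is defined over the cropped window
# (y = 0 at the window's first row); generated rows above the window use
# the profile's first value, rows below its last.
phi_rows_for <- function(config, phi_this) {
  n_win <- config$gen_rows - config$crop_top - config$crop_bottom
  if (is.infinite(config$decay_length)) return(rep(phi_this, config$gen_rows))
  prof <- decayed_phi_profile(phi_this, config$decay_length, n_win,
                              saturate = TRUE)
  idx <- pmin(pmax(seq_len(config$gen_rows) - config$crop_top, 1L), n_win)
  prof[idx]
}

#' Grow one correlated lattice
#'
#' Event-driven simulation of biofilm-edge growth.  The first row is seeded
#' i.i.d. Bernoulli(`phi`); every cell divides after a Gaussian waiting time
#' (mean `tau_mean` for off-cells and `tau_mean / gamma` for on-cells,
#' sd `tau_sd_ratio * tau_mean`, resampled while non-positive).  At each
#' division the daughter is placed uniformly at random among the eligible
#' neighbor sites of the mother: empty sites, plus occupied sites whose
#' occupant can be displaced one step further along the same lattice
#' direction into an empty site (displaced cells keep their state and
#' pending division time; at most one level of displacement).  The daughter
#' inherits the mother's state through [inheritance_probs()] (or the
#' gamma-corrected [inheritance_probs_gamma()] when `gamma < 1`), evaluated
#' at the row-local on-fraction when `decay_length` is finite.  Growth
#' stops when the `gen_rows` x `n_cols` grid is full; the window is then
#' cropped.
#'
#' @param config a [growth_config()].
#' @param phi_this on-fraction for this lattice; default draws it via
#'   [sample_phi()] from `config`.
#' @return List of class `grown_lattice` with `window` (cropped
#'   [lattice_window()]), `full` (uncropped), `lineage` (data.frame with
#'   columns `mother`, `daughter`, `time`; one row per division) and `phi`
#'   (the on-fraction used).
#' @export
grow_lattice <- function(config, phi_this = NULL) {
  stopifnot(inherits(config, "growth_config"))
  if (is.null(phi_this)) phi_this <- sample_phi(config$phi_mean, config$phi_sd)
  check_prob(phi_this, "phi_this")
  phi_rows <- phi_rows_for(config, phi_this)
  pr <- if (config$gamma < 1) {
    lapply(phi_rows, inheritance_probs_gamma, rho = config$rho_div,
           gamma = config$gamma)
  } else {
    lapply(phi_rows, inheritance_probs, rho = config$rho_div)
  }
  q_row <- vapply(pr, `[[`, numeric(1), "p_on_on")
  r_row <- vapply(pr, `[[`, numeric(1), "p_on_off")
  ratio <- if (is.null(config$tau_sd_ratio)) runif(1) else config$tau_sd_ratio
  res <- grow_lattice_cpp(config$gen_rows, config$n_cols, phi_rows,
                          q_row, r_row,
                          tau_mean_off = config$tau_mean,
                          tau_mean_on = config$tau_mean / config$gamma,
                          tau_sd = ratio * config$tau_mean)
  keep <- seq.int(config$crop_top + 1L, config$gen_rows - config$crop_bottom)
  window <- lattice_window(res$states[keep, , drop = FALSE], phi = phi_this)
  structure(
    list(window = window,
         full = lattice_window(res$states, phi = phi_this),
         lineage = data.frame(mother = res$lineage[, 1],
                              daughter = res$lineage[, 2],
                              time = res$times),
         phi = phi_this),
    class = "grown_lattice"
  )
}

#' Grow an ensemble of correlated lattices
#'
#' Repeated [grow_lattice()] runs from a single RNG stream; per-lattice
#' on-fractions are drawn from `(phi_mean, phi_sd)` unless `phi_this` is
#' given.  Set the seed once before calling for reproducible ensembles.
#'
#' @inheritParams grow_lattice
#' @param n_lattices ensemble size.
#' @param windows_only if `TRUE` (default) keep only the cropped windows,
#'   discarding full grids and lineage tables to save memory.
#' @return A list of `grown_lattice` objects (or of [lattice_window()]s if
#'   `windows_only`).
#' @export
grow_ensemble <- function(config, n_lattices, phi_this = NULL,
                          windows_only = TRUE) {
  lapply(seq_len(n_lattices), function(i) {
    g <- grow_lattice(config, phi_this)
    if (windows_only) g$window else g
  })
}

#' Mutant-model ensemble (spatial decay, no inheritance correlation)
#'
#' Direct row-wise Bernoulli sampling of window lattices with an
#' exponentially decaying on-fraction profile: for each lattice a mean
#' fraction is drawn from `(phi_mean, phi_sd)` (redrawn into `[0, 1]`),
#' the per-row profile [decayed_phi_profile()] is formed (saturating at 1
#' near the source for large draws, so the across-lattice variability is
#' not truncated), and sites are filled independently.  This is the exact
#' shortcut for growth with `rho_div = 0`, where inheritance carries no
#' correlation.
#'
#' @param phi_mean mean spatial-average on-fraction (mutant default 0.13).
#' @param phi_sd across-lattice sd of the spatial average (default 0.1).
#' @param lam decay length in cell lengths (default 7).
#' @param n_lattices ensemble size.
#' @param n_rows,n_cols window dimensions.
#' @return List of [lattice_window()]s.
#' @export
mutant_ensemble <- function(n_lattices, phi_mean = 0.13, phi_sd = 0.1,
                            lam = 7, n_rows = 35L, n_cols = 230L) {
  lapply(seq_len(n_lattices), function(i) {
    phi_i <- sample_phi(phi_mean, phi_sd)
    prof <- decayed_phi_profile(phi_i, lam, n_rows, saturate = TRUE)
    random_fill_profile(prof, n_cols)
  })
}
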