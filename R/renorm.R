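#' One round of site decimation of the inheritance chain
#'
#' Removing every other cell along the mother-daughter chain replaces the
#' conditional probabilities by the two-step (grandmother-to-daughter)
#' probabilities.  Under the spatial Markov assumption (daughter
#' conditionally independent of the grandmother given the mother),
#' \deqn{q_1 = q^2 + r(1-q), \qquad r_1 = qr + r(1-r),}
#' so the order parameter transforms as \eqn{\rho_1 = q_1 - r_1 =
#' (q - r)^2 = \rho^2} while the stationary on-fraction is unchanged.
#'
#' @param probs a `conditional_probs` object (see [inheritance_probs()]).
#' @return The decimated `conditional_probs`.
#' @export
decimate_probs <- function(probs) {
  stopifnot(inherits(probs, "conditional_probs"))
  q <- probs$p_on_on; r <- probs$p_on_off
  conditional_probs(p_on_on = q * q + r * (1 - q),
                    p_on_off = q * r + r * (1 - r))
}

#' Order parameter after repeated decimation
#'
#' After `j` rounds of decimation the correlation parameter is
#' \eqn{\rho_j = \rho^{j+1}}; any `rho < 1` therefore flows to zero, which
#' is why short-range (Markovian) correlations do not alter the critical
#' cluster statistics.  Here a round increases the survivor spacing by one
#' cell, so \eqn{\rho_j} is the correlation between cells `j + 1` apart;
#' one application of [decimate_probs()] is `j = 1`.  (Iterating
#' [decimate_probs()] doubles the spacing each time and therefore gives
#' \eqn{\rho^{2^j}}; both flows vanish for `rho < 1`.)
#'
#' @param rho order parameter in `[0, 1]`.
#' @param j number of decimation rounds (>= 0).
#' @return `rho^(j + 1)`.
#' @export
rho_after_decimations <- function(rho, j) {
  check_prob(rho, "rho")
  if (j < 0) stop("j must be >= 0")
  rho^(j + 1)
}

#' Simulate a two-state inheritance (Markov) column
#'
#' Generates a binary sequence with transition structure `(q, r)`, started
#' from the stationary on-fraction — the 1D caricature of a lattice column
#' under correlated inheritance.
#'
#' @param probs a `conditional_probs` object.
#' @param n sequence length.
#' @return Integer 0/1 vector of length `n`.
#' @export
simulate_markov_column <- function(probs, n) {
  stopifnot(inherits(probs, "conditional_probs"))
  n <- as.integer(n)
  phi <- stationary_phi(probs)
  s <- integer(n)
  u <- runif(n)
  s[1L] <- as.integer(u[1L] < phi)
  for (t in 2:n) {
    p <- if (s[t - 1L] == 1L) probs$p_on_on else probs$p_on_off
    s[t] <- as.integer(u[t] < p)
  }
  s
}

#' Empirical decimation of a simulated column
#'
#' Estimates the order parameter on a binary sequence and on its
#' every-other-site subsequence.  For a Markov chain the decimated estimate
#' should approach the square of the full-sequence estimate, while the
#' on-fraction is preserved.
#'
#' @param column integer 0/1 vector (length >= 1000 recommended).
#' @return List with `rho_before`, `rho_after`, `phi_before`, `phi_after`,
#'   and normal-approximation standard errors `se_before`, `se_after`.
#' @export
empirical_decimation <- function(column) {
  column <- as.integer(column)
  if (length(column) < 10L) stop("sequence too short")
  if (length(unique(column)) < 2L) stop("degenerate (constant) sequence")
  est <- function(s) {
    a <- s[-length(s)]; b <- s[-1L]
    if (!any(a == 1L) || !any(a == 0L))
      stop("degenerate sequence: conditionals undefined")
    n1 <- sum(a == 1L); n0 <- sum(a == 0L)
    p1 <- mean(b[a == 1L]); p0 <- mean(b[a == 0L])
    list(rho = p1 - p0,
         se = sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0))
  }
  dec <- column[seq(1L, length(column), by = 2L)]
  e1 <- est(column); e2 <- est(dec)
  list(rho_before = e1$rho, rho_after = e2$rho,
       phi_before = mean(column), phi_after = mean(dec),
       se_before = e1$se, se_after = e2$se)
}

#' Decimation flow table
#'
#' Iterates [decimate_probs()] and tabulates the order parameter against
#' the closed form round by round.  Each iteration doubles the survivor
#' spacing, so after `j` iterations the closed form is `rho^(2^j)`.
#'
#' @param probs a `conditional_probs` object.
#' @param rounds number of decimation rounds.
#' @return data.frame with columns `j`, `q`, `r`, `rho`, `rho_closed_form`,
#'   `phi` (stationary fraction, constant along the flow).
#' @export
decimation_table <- function(probs, rounds = 5L) {
  rho0 <- probs$rho
  out <- data.frame(j = 0L, q = probs$p_on_on, r = probs$p_on_off,
                    rho = probs$rho, rho_closed_form = rho0,
                    phi = stationary_phi(probs))
  p <- probs
  for (j in seq_len(rounds)) {
    p <- decimate_probs(p)
    out <- rbind(out, data.frame(j = j, q = p$p_on_on, r = p$p_on_off,
                                 rho = p$rho,
                                 rho_closed_form = rho0^(2^j),
                                 phi = stationary_phi(p)))
  }
  out
}
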