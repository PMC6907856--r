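# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths wherever they check one.

# Recursive flood fill over the exported neighbors() relation: the
# reference clustering against which the union-find labeling is checked.
flood_fill_clusters <- function(lattice) {
  s <- lattice$states
  dims <- dim(s)
  seen <- matrix(FALSE, dims[1], dims[2])
  sizes <- integer(0)
  spanning <- FALSE
  for (j in seq_len(dims[2])) {
    for (i in seq_len(dims[1])) {
      if (s[i, j] == 0L || seen[i, j]) next
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      size <- 0L; touches_top <- FALSE; touches_bottom <- FALSE
      while (length(stack) > 0L) {
        site <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        if (site[1] == 1L) touches_top <- TRUE
        if (site[1] == dims[1]) touches_bottom <- TRUE
        nb <- neighbors(site, dims)
        for (k in seq_len(nrow(nb))) {
          a <- nb[k, 1]; b <- nb[k, 2]
          if (s[a, b] == 1L && !seen[a, b]) {
            seen[a, b] <- TRUE
            stack[[length(stack) + 1L]] <- c(a, b)
          }
        }
      }
      sizes <- c(sizes, size)
      if (touches_top && touches_bottom) spanning <- TRUE
    }
  }
  list(sizes = sizes, spanning = spanning)
}

# Inverse-CDF sampler for a discrete power law p(k) ~ k^(-alpha),
# k = 1 .. kmax (kmax large enough that truncation bias is negligible for
# the tolerances used).
sample_discrete_powerlaw <- function(n, alpha, kmax = 1e6L) {
  k <- seq_len(kmax)
  cdf <- cumsum(k^(-alpha))
  cdf <- cdf / cdf[kmax]
  findInterval(runif(n), cdf) + 1L
}

# Dominant eigenvalue / stationary fraction of the two-type growth
# dynamics via base eigen(): an independent route to growth_eigen().
eigen_oracle <- function(q, r, gamma) {
  A <- matrix(c(gamma * q, gamma * (1 - q), r, 1 - r), 2, 2)
  e <- eigen(A)
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  list(lambda_plus = Re(e$values[i]), phi_steady = v[1] / sum(v))
}

# Solve for the gamma-corrected conditionals numerically: find r such that
# the eigenvector fraction equals phi with q = r + rho (independent of the
# closed form under test).
gamma_probs_oracle <- function(phi, rho, gamma) {
  f <- function(r) eigen_oracle(r + rho, r, gamma)$phi_steady - phi
  r <- uniroot(f, c(max(0, phi - rho), phi), tol = 1e-12)$root
  c(q = r + rho, r = r)
}

# Transition matrix of the two-state daughter-given-mother chain
# (rows: mother off/on; columns: daughter off/on).
chain_matrix <- function(q, r) {
  matrix(c(1 - r, 1 - q, r, q), 2, 2)
}

# Discrete power law truncated to [xmin, xmax], fitted by MLE; used to
# extrapolate a mid-range fit into the far tail.
truncated_powerlaw_mle <- function(sizes, xmin, xmax) {
  x <- sizes[sizes >= xmin & sizes <= xmax]
  ks <- seq.int(xmin, xmax)
  nll <- function(a) length(x) * log(sum(ks^(-a))) + a * sum(log(x))
  optimize(nll, c(1.01, 6))$minimum
}

# Build a conditional_probs object directly from (q, r).
conditional_probs_for_test <- function(q, r) {
  corrperc:::conditional_probs(q, r)
}
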