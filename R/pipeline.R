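#' Regenerate the numbers behind a simulated figure panel
#'
#' Recomputes, at a reduced replicate count, the simulated quantities shown
#' in the main figure panels: `"fig3"` the mechanistic-model adjacency
#' correlation and correlation-length excess; `"fig4"` the connectivity
#' curves and thresholds without and with division correlation; `"fig6"`
#' the cluster-size distributions without and with across-lattice
#' variability; `"fig7"` the mutant-model distribution and its
#' maximum-likelihood exponent.  The scale factor multiplies replicate
#' counts only — lattice dimensions are part of the science and are never
#' scaled.
#'
#' @param figure one of `"fig3"`, `"fig4"`, `"fig6"`, `"fig7"`.
#' @param scale replicate-count multiplier relative to the full-size runs
#'   (10^4 lattices for fig3, 10^3 per panel otherwise).
#' @param seed master seed.
#' @return A list with a `comparison` data.frame (quantity, reference
#'   value, reproduced value, Monte-Carlo standard error where defined)
#'   plus figure-specific tables (curves or binned distributions).
#' @export
reproduce_figure <- function(figure = c("fig3", "fig4", "fig6", "fig7"),
                             scale = 0.1, seed = 1L) {
  figure <- match.arg(figure)
  if (scale <= 0) stop("scale must be > 0")
  set.seed(seed)
  switch(figure,
         fig3 = reproduce_fig3(scale),
         fig4 = reproduce_fig4(scale),
         fig6 = reproduce_fig6(scale),
         fig7 = reproduce_fig7(scale))
}

reproduce_fig3 <- function(scale) {
  n <- max(10L, as.integer(round(1e4 * scale)))
  cfg <- growth_config(phi_sd = 0)
  lats <- grow_ensemble(cfg, n)
  rho <- vapply(lats, estimate_rho_adj, numeric(1))
  n_xi <- min(n, 100L)
  xi_cmp <- compare_correlation_lengths(lats[seq_len(n_xi)])
  comparison <- data.frame(
    quantity = "rho_adj (model, phi = 0.43, rho_div = 0.38)",
    reference = 0.19,
    reproduced = mean(rho),
    se = sd(rho) / sqrt(n))
  list(comparison = comparison, correlation_lengths = xi_cmp,
       n_lattices = n)
}

reproduce_fig4 <- function(scale) {
  n <- max(20L, as.integer(round(1e3 * scale)))
  grid_unc <- seq(0.38, 0.52, by = 0.02)
  curve_unc <- connectivity_curve(function(p) random_fill(35L, 230L, p),
                                  grid_unc, n)
  cfg0 <- growth_config(phi_sd = 0)
  grid_cor <- seq(0.32, 0.48, by = 0.02)
  curve_cor <- connectivity_curve(function(p) {
    grow_lattice(cfg0, phi_this = p)$window
  }, grid_cor, n)
  comparison <- data.frame(
    quantity = c("threshold, uncorrelated 35x230",
                 "threshold, mechanistic rho_div = 0.38"),
    reference = c(0.45, 0.4),
    reproduced = c(connectivity_threshold(curve_unc),
                   connectivity_threshold(curve_cor)),
    se = NA_real_)
  list(comparison = comparison, curve_uncorrelated = curve_unc,
       curve_correlated = curve_cor, n_reps = n)
}

reproduce_fig6 <- function(scale) {
  n <- max(20L, as.integer(round(1e3 * scale)))
  fixed <- replicate(n, random_fill(35L, 230L, 0.43), simplify = FALSE)
  varied <- lapply(seq_len(n), function(i)
    random_fill(35L, 230L, sample_phi(0.43, 0.07)))
  s_fixed <- pooled_cluster_sizes(fixed)
  s_varied <- pooled_cluster_sizes(varied)
  comparison <- data.frame(
    quantity = c("P(n > 500), sigma_phi = 0", "P(n > 500), sigma_phi = 0.07"),
    reference = NA_real_,
    reproduced = c(mean(s_fixed > 500), mean(s_varied > 500)),
    se = NA_real_)
  list(comparison = comparison,
       distribution_fixed = size_distribution(s_fixed),
       distribution_varied = size_distribution(s_varied),
       n_lattices = n)
}

reproduce_fig7 <- function(scale) {
  n <- max(20L, as.integer(round(1e3 * scale)))
  lats <- mutant_ensemble(n)
  sizes <- pooled_cluster_sizes(lats)
  fit <- powerlaw_mle(sizes, xmin = 1L)
  comparison <- data.frame(
    quantity = "power-law exponent, mutant model (xmin = 1)",
    reference = 2.08,
    reproduced = fit$alpha,
    se = fit$se)
  list(comparison = comparison, fit = fit,
       distribution = size_distribution(sizes), n_lattices = n)
}
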