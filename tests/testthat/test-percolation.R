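test_that("connectivity curve hits its deterministic endpoints", {
  set.seed(20)
  cur <- connectivity_curve(function(p) random_fill(10, 20, p),
                            c(0, 0.5, 1), n_reps = 5)
  expect_equal(cur$spanning_prob[1], 0)
  expect_equal(cur$spanning_prob[3], 1)
  expect_error(connectivity_curve(function(p) random_fill(5, 5, p),
                                  numeric(0), 5))
  expect_error(connectivity_curve(function(p) random_fill(5, 5, p),
                                  c(0.5, 0.4), 5))
})

test_that("threshold interpolation is exact on synthetic curves", {
  curve <- structure(
    data.frame(phi = c(0.3, 0.4, 0.5, 0.6),
               spanning_prob = c(0.1, 0.3, 0.7, 0.9),
               n_reps = 10, ci_halfwidth = 0),
    class = c("connectivity_curve", "data.frame"))
  # linear crossing between 0.4 and 0.5: 0.4 + 0.1 * (0.5-0.3)/(0.7-0.3)
  expect_equal(connectivity_threshold(curve), 0.45, tolerance = 1e-12)
  # non-monotone curves are pooled by isotonic regression first
  curve$spanning_prob <- c(0.35, 0.25, 0.7, 0.9)
  expect_equal(connectivity_threshold(curve), 0.45, tolerance = 1e-12)
  curve$spanning_prob <- c(0.1, 0.2, 0.3, 0.4)
  expect_error(connectivity_threshold(curve), "bracket")
})

test_that("size_distribution bins at powers of two and normalizes", {
  d1 <- size_distribution(rep(1L, 50))
  expect_equal(d1$prob[1], 1)
  expect_error(size_distribution(integer(0)))
  expect_error(size_distribution(c(0L, 2L)))
  # sampling oracle: binned estimate within multinomial error of truth
  set.seed(21)
  probs <- c(0.5, 0.25, 0.15, 0.1)   # sizes 1..4
  x <- sample(1:4, 2e4, replace = TRUE, prob = probs)
  d <- size_distribution(x)
  # bins: [1], [2,3], [4,...]
  expect_equal(d$prob[1], 0.5, tolerance = 0.05)
  expect_equal(d$prob[2], 0.4, tolerance = 0.05)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("discrete power-law MLE recovers a known exponent", {
  set.seed(22)
  x <- sample_discrete_powerlaw(1e5, 2.5)
  fit <- powerlaw_mle(x, xmin = 1L)
  expect_lt(abs(fit$alpha - 2.5), 0.02)
  expect_equal(fit$n_tail, 1e5L)
  # subsampling equivariance: halving the sample moves alpha < 3 se
  half <- powerlaw_mle(x[seq(1, 1e5, by = 2)], xmin = 1L)
  expect_lt(abs(half$alpha - fit$alpha), 3 * half$se)
  # smoke: two distinct values give a finite fit
  sm <- powerlaw_mle(c(rep(1L, 30), rep(2L, 10)), xmin = 1L)
  expect_true(is.finite(sm$alpha) && sm$alpha > 1)
  expect_equal(sm$n_tail, 40L)
  expect_error(powerlaw_mle(rep(3L, 10), xmin = 1L), "identical")
})

test_that("auto xmin selection recovers a tail-only power law", {
  set.seed(23)
  # exact power law only from 5 upward; arbitrary head below
  k <- 1:200000
  pmf <- c(0.2, 0.15, 0.1, 0.05, 0.5 * k[k >= 5]^(-2.2) / sum(k[k >= 5]^(-2.2)))
  x <- sample(k, 5e4, replace = TRUE, prob = pmf)
  fit <- powerlaw_mle(x, xmin = "auto")
  expect_gte(fit$xmin, 5L)
  expect_lt(abs(fit$alpha - 2.2), 0.1)
})

test_that("binomial and ensemble standard deviations agree with theory", {
  expect_equal(binomial_sd(0.43, 8050), sqrt(0.43 * 0.57 / 8050),
               tolerance = 1e-12)
  expect_equal(signif(binomial_sd(0.43, 8050), 1), 0.006)
  expect_equal(binomial_sd(0, 100), 0)
  expect_equal(binomial_sd(0.5, 100), 0.05)
  l <- random_fill(5, 5, 0.5)
  expect_equal(ensemble_phi_sd(list(l, l, l)), 0)
  expect_error(ensemble_phi_sd(list(l)))
  set.seed(24)
  lats <- replicate(200, random_fill(35, 230, 0.43), simplify = FALSE)
  expect_equal(ensemble_phi_sd(lats), binomial_sd(0.43, 8050),
               tolerance = 0.15)
})

test_that("connectivity threshold decreases with the division correlation", {
  set.seed(25)
  grid <- seq(0.25, 0.50, by = 0.05)
  thr <- vapply(c(0, 0.4, 0.8), function(rho) {
    cfg <- growth_config(phi_sd = 0, rho_div = rho)
    cur <- connectivity_curve(function(p) grow_lattice(cfg, phi_this = p)$window,
                              grid, n_reps = 60)
    connectivity_threshold(cur)
  }, numeric(1))
  expect_true(all(diff(thr) < 0))
})

test_that("variability removes the exponential rolloff of P(n)", {
  set.seed(26)
  n <- 150
  fixed <- replicate(n, random_fill(35, 230, 0.43), simplify = FALSE)
  varied <- lapply(seq_len(n), function(i)
    random_fill(35, 230, sample_phi(0.43, 0.07)))
  s_fixed <- pooled_cluster_sizes(fixed)
  s_varied <- pooled_cluster_sizes(varied)
  # extrapolate a mid-range power-law fit into the far tail; without
  # variability the observed tail falls far short of the extrapolation,
  # with variability it does not
  expected_tail <- function(sizes) {
    a <- truncated_powerlaw_mle(sizes, 8L, 128L)
    n_mid <- sum(sizes >= 8 & sizes <= 128)
    n_mid * sum((501:20000)^(-a)) / sum((8:128)^(-a))
  }
  ratio_fixed <- sum(s_fixed > 500) / expected_tail(s_fixed)
  ratio_varied <- sum(s_varied > 500) / expected_tail(s_varied)
  expect_lt(ratio_fixed, 0.05)      # two orders below the extrapolation
  expect_gt(ratio_varied, 0.2)      # rolloff removed to within a factor ~2
  expect_gt(ratio_varied / ratio_fixed, 20)
})
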