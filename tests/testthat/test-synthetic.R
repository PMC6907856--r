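test_that("rendering is bimodal with a complete mask", {
  set.seed(60)
  lat <- random_fill(8, 12, 0.5)
  img <- render_image(lat, pixel_scale = 4L, noise_sd = 0)
  vals <- sort(unique(as.vector(img$intensity[img$mask > 0])))
  expect_equal(vals, c(0.5, 1))
  expect_equal(length(unique(img$mask[img$mask > 0])), 8 * 12)
  expect_equal(nrow(img$truth), 8 * 12)
  expect_error(render_image(lat, pixel_scale = 0L))
  expect_error(render_image(lat, on_mean = 0.4, off_mean = 0.5))
})

test_that("midpoint threshold misclassifies few cells at 4-sd separation", {
  set.seed(61)
  lat <- random_fill(20, 30, 0.43)
  img <- render_image(lat, noise_sd = 0.125)  # separation 4 sd
  # per-cell mean intensity classified at the midpoint
  cellmean <- tapply(img$intensity[img$mask > 0], img$mask[img$mask > 0], mean)
  called <- as.integer(cellmean[as.character(img$truth$cell)] > 0.75)
  expect_lt(mean(called != img$truth$state), 0.03)
})

test_that("threshold_and_filter reproduces the truth rasterization", {
  set.seed(62)
  lat <- random_fill(10, 15, 0.4)
  img <- render_image(lat, noise_sd = 0)
  binary <- threshold_and_filter(img, median_radius = 0)
  expect_identical(binary, rasterize_lattice(lat, 4L))
  all_off <- render_image(lattice_window(matrix(0L, 5, 5)), noise_sd = 0)
  expect_equal(sum(threshold_and_filter(all_off)), 0)
})

test_that("the radius-2 median filter removes isolated pixel errors", {
  set.seed(63)
  lat <- random_fill(10, 15, 0.4)
  img <- render_image(lat, noise_sd = 0)
  clean <- threshold_and_filter(img, median_radius = 0)
  noisy <- clean
  flip <- sample(length(noisy), round(0.01 * length(noisy)))
  noisy[flip] <- 1L - noisy[flip]
  # filtering the corrupted field recovers the filtered clean field almost
  # everywhere (the filter also rounds cluster corners, so the comparison
  # is filter-to-filter); flips whose clean 5x5 neighborhood is uniform
  # are healed without exception
  filtered <- corrperc:::median_filter_binary_cpp(noisy, 2)
  reference <- corrperc:::median_filter_binary_cpp(clean, 2)
  expect_gt(mean(filtered == reference), 0.995)
  expect_gt(mean(reference == clean), 0.95)
  idx <- arrayInd(flip, dim(clean))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ri <- max(1, i - 2):min(nrow(clean), i + 2)
    rj <- max(1, j - 2):min(ncol(clean), j + 2)
    if (min(clean[ri, rj]) == max(clean[ri, rj]))
      expect_equal(filtered[i, j], clean[i, j])
  }
})

test_that("image clusters equal lattice clusters at zero noise", {
  set.seed(64)
  for (phi in c(0.2, 0.43, 0.6)) {
    lat <- random_fill(15, 40, phi)
    img <- render_image(lat, noise_sd = 0)
    binary <- threshold_and_filter(img)
    sizes_img <- clusters_from_image(binary, img$mask)
    sizes_lat <- label_clusters(lat)$sizes
    expect_equal(sort(sizes_img), sort(as.integer(sizes_lat)))
  }
  expect_equal(length(clusters_from_image(matrix(0L, 10, 10),
                                          matrix(1L, 10, 10))), 0L)
  expect_error(clusters_from_image(matrix(0L, 5, 5), matrix(0L, 4, 4)))
})

test_that("end-to-end closure survives moderate noise", {
  set.seed(65)
  lat <- random_fill(15, 40, 0.43)
  img <- render_image(lat, noise_sd = 0.125)
  sizes_img <- clusters_from_image(threshold_and_filter(img), img$mask)
  sizes_lat <- label_clusters(lat)$sizes
  # multiset divergence below 2%
  tab_i <- table(factor(sizes_img, levels = 1:600))
  tab_l <- table(factor(sizes_lat, levels = 1:600))
  divergence <- sum(abs(tab_i - tab_l)) / (2 * length(sizes_lat))
  expect_lt(divergence, 0.02)
})

test_that("a cell split evenly between two regions is assigned to neither", {
  # two white regions, each covering exactly half of the single cell
  mask <- matrix(1L, 4, 4)
  binary <- matrix(0L, 4, 4)
  binary[, 1] <- 1L   # region A: 4 px
  binary[, 4] <- 1L   # region B: 4 px (separated by two black columns)
  expect_equal(length(clusters_from_image(binary, mask)), 0L)
})

test_that("synthetic lineages hit the experimental sampling precision", {
  p <- inheritance_probs(0.43, 0.38)
  set.seed(66)
  t1 <- make_lineage_table(conditional_probs_for_test(1, 0), 100)
  expect_true(all(t1$mother == t1$daughter))
  # at the experimental sample size (49 divisions) the recovery se ~ 0.13
  ests <- replicate(300, estimate_rho_div(make_lineage_table(p, 49)))
  expect_gt(sd(ests), 0.09)
  expect_lt(sd(ests), 0.17)
})

test_that("correlation analysis on synthetic images matches cell-level xi anisotropy", {
  set.seed(67)
  xi <- sapply(1:25, function(i) {
    lat <- random_fill(35, 230, 0.5)
    img <- render_image(lat, pixel_scale = 2L, noise_sd = 0)
    surf <- autocorrelation(threshold_and_filter(img, median_radius = 0))
    c(x = attr(correlation_profile(surf, "x"), "xi"),
      y = attr(correlation_profile(surf, "y"), "xi"))
  })
  ratio <- mean(xi["y", ]) / mean(xi["x", ])
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})
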