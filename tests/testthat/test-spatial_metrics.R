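test_that("pairwise distances are Euclidean and match a formula loop", {
  expect_equal(pairwise_distances(rbind(c(0, 0)), rbind(c(3, 4)))[1, 1], 5)
  a <- matrix(runif(6, 0, 100), 3)
  expect_equal(diag(pairwise_distances(a, a)), rep(0, 3))
  expect_equal(dim(pairwise_distances(matrix(numeric(), 0, 2), a)),
               c(0L, 3L))

  set.seed(31)
  x <- matrix(runif(40, 0, 500), 20)
  y <- matrix(runif(40, 0, 500), 20)
  got <- pairwise_distances(x, y)
  want <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    want[i, j] <- sqrt(sum((x[i, ] - y[j, ])^2))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("nearest tumour distance matches the brute-force minimum", {
  expect_equal(nearest_tumour_distance(rbind(c(0, 0)),
                                       rbind(c(3, 4), c(6, 8))), 5)
  expect_equal(nearest_tumour_distance(rbind(c(2, 2)), rbind(c(2, 2))), 0)
  expect_true(all(is.na(nearest_tumour_distance(rbind(c(1, 1)),
                                                matrix(numeric(), 0, 2)))))
  set.seed(32)
  im <- matrix(runif(60, 0, 930), 30)
  tu <- matrix(runif(30, 0, 930), 15)
  brute <- apply(pairwise_distances(im, tu), 1, min)
  expect_equal(nearest_tumour_distance(im, tu, "kdtree"), brute,
               tolerance = 1e-12)
  expect_equal(nearest_tumour_distance(im, tu, "brute"), brute,
               tolerance = 1e-12)
})

test_that("the effective score counts paired immune cells", {
  im <- rbind(c(0, 0), c(15, 0), c(100, 100), c(30, 0))
  tu <- rbind(c(10, 0), c(50, 50), c(12, 0))
  es <- effective_score(im, tu, 20)
  expect_equal(es$n_paired, 3)
  expect_equal(es$effective_score, 0.75)

  # single immune cell 5 um from a tumour cell
  expect_equal(effective_score(rbind(c(0, 0)), rbind(c(5, 0)),
                               10)$effective_score, 1)
  # monotone in radius
  expect_lte(effective_score(im, tu, 10)$effective_score,
             effective_score(im, tu, 30)$effective_score)
  # the pairing interval is closed: a tie at exactly r counts
  expect_equal(effective_score(rbind(c(0, 0)), rbind(c(20, 0)),
                               20)$effective_score, 1)
  # zero immune cells -> missing, never 0
  none <- effective_score(matrix(numeric(), 0, 2), tu, 20)
  expect_true(is.na(none$effective_score))
  expect_equal(none$n_immune, 0)
})

test_that("pooling across ROIs is counts-then-divide", {
  im <- list(rbind(c(0, 0), c(5, 0)), rbind(c(0, 0)))
  tu <- list(rbind(c(1, 0)), matrix(numeric(), 0, 2))
  es <- effective_score(im, tu, 10)
  # ROI 2 has no tumour cells: its immune cell is unpaired but counted
  expect_equal(es$n_immune, 3)
  expect_equal(es$n_paired, 2)
  expect_equal(es$effective_score, 2 / 3)
})

test_that("effective density divides paired count by area", {
  im <- rbind(c(0, 0), c(15, 0), c(100, 100), c(30, 0))
  tu <- rbind(c(10, 0), c(50, 50), c(12, 0))
  expect_equal(effective_density(im, tu, 20, area_mm2 = 1), 3)
  expect_equal(effective_density(im, matrix(numeric(), 0, 2), 20,
                                 area_mm2 = 1), 0)
  expect_error(effective_density(im, tu, 20, area_mm2 = 0), "positive")
})

test_that("spatial statistics are translation and rotation invariant", {
  set.seed(33)
  im <- matrix(runif(40, 100, 400), 20)
  tu <- matrix(runif(20, 100, 400), 10)
  base <- effective_score(im, tu, 25)
  shift <- cbind(im[, 1] + 111, im[, 2] - 57)
  tshift <- cbind(tu[, 1] + 111, tu[, 2] - 57)
  expect_equal(effective_score(shift, tshift, 25), base)
  th <- 0.7; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(effective_score(im %*% R, tu %*% R, 25)$n_paired,
               base$n_paired)
})

test_that("accelerated and brute-force routes agree on random instances", {
  set.seed(34)
  for (k in 1:25) {
    n_im <- sample(1:300, 1); n_tu <- sample(0:200, 1)
    im <- cbind(runif(n_im, 0, 930), runif(n_im, 0, 700))
    tu <- cbind(runif(n_tu, 0, 930), runif(n_tu, 0, 700))
    r <- sample(c(10, 20, 30), 1)
    fast <- effective_score(im, tu, r, "kdtree")
    slow <- effective_score(im, tu, r, "brute")
    expect_identical(fast$n_paired, slow$n_paired)
    # score x n_immune recovers the integer paired count
    if (!is.na(fast$effective_score))
      expect_equal(fast$effective_score * fast$n_immune, fast$n_paired,
                   tolerance = 1e-12)
  }
})

test_that("effective density never exceeds plain density", {
  set.seed(35)
  for (k in 1:50) {
    n_im <- sample(1:200, 1); n_tu <- sample(0:100, 1)
    im <- cbind(runif(n_im, 0, 930), runif(n_im, 0, 700))
    tu <- cbind(runif(n_tu, 0, 930), runif(n_tu, 0, 700))
    area <- 0.651
    expect_lte(effective_density(im, tu, 20, area), n_im / area)
  }
})

test_that("spatial_table pools a patient's TC ROIs and summarises", {
  df1 <- toy_cell_df(6, roi = "P1_TC_1", x = c(0, 15, 100, 30, 5, 7),
                     y = c(0, 0, 100, 0, 5, 7),
                     tumour = c(rep(FALSE, 4), TRUE, TRUE))
  df2 <- toy_cell_df(2, roi = "P1_TC_2", x = c(10, 500), y = c(10, 500))
  d <- validate_cell_table(rbind(df1, df2))
  reg <- phenotype_registry(list(phenotype_rule("CD8")))
  tab <- spatial_table(d, reg, radii_um = c(10, 20), roi_class = "TC")
  expect_equal(nrow(tab), 2)
  expect_equal(unique(tab$n_immune), 6L) # 4 + 2 immune CD8 cells
  r20 <- tab[tab$radius_um == 20, ]
  expect_equal(r20$effective_density, r20$n_paired / r20$area_mm2)
  # monotone across the table's radii
  expect_lte(tab$effective_score[tab$radius_um == 10],
             tab$effective_score[tab$radius_um == 20])
  # nearest distances only defined where a tumour cell exists in the ROI
  expect_true(is.finite(tab$mean_nearest_um[1]))
})
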