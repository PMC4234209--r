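mask_from <- function(arr) binary_mask(arr)

test_that("dice has the documented range semantics and formula", {
  a <- array(FALSE, c(6, 6, 6)); a[2:3, 2:3, 2] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[2:3, 3:4, 2] <- TRUE
  disj <- array(FALSE, c(6, 6, 6)); disj[5, 5, 5] <- TRUE

  expect_equal(dice(mask_from(a), mask_from(a)), 1.0)
  expect_equal(dice(mask_from(a), mask_from(disj)), 0.0)
  # |A| = 4, |B| = 4, |A∩B| = 2 -> 0.5
  expect_equal(dice(mask_from(a), mask_from(b)), 0.5)
  expect_equal(dice(mask_from(b), mask_from(a)), 0.5)  # symmetric

  expect_error(dice(mask_from(a), mask_from(array(FALSE, c(5, 5, 5)))),
               "shapes differ")
  e <- array(FALSE, c(6, 6, 6))
  expect_error(dice(mask_from(e), mask_from(e)), "empty")
})

test_that("dice decreases monotonically along a translation sweep", {
  base <- array(FALSE, c(20, 20, 20)); base[5:10, 5:10, 5:10] <- TRUE
  d <- vapply(0:5, function(s) {
    sh <- array(FALSE, c(20, 20, 20))
    sh[5:10 + s, 5:10, 5:10] <- TRUE
    dice(mask_from(base), mask_from(sh))
  }, 0)
  expect_equal(d[1], 1)
  expect_true(all(diff(d) < 0))
})

test_that("p90 follows the linear-interpolation percentile convention", {
  expect_equal(distance_summary(1:10)$p90, 9.1)
  s <- distance_summary(c(0.1, 0.5, 0.2))
  expect_true(s$min <= s$median && s$median <= s$p90 && s$p90 <= s$max)
})

test_that("surface distance is zero against itself and symmetric in order", {
  sph <- uv_sphere(5, 24, 48)
  self <- surface_distance(sph, sph)
  expect_equal(self$median, 0)
  expect_equal(self$p90, 0)
  expect_equal(self$max, 0)

  sph2 <- uv_sphere(5.4, 24, 48)
  ab <- surface_distance(sph, sph2)
  ba <- surface_distance(sph2, sph)
  expect_equal(ab$median, ba$median)
  expect_equal(ab$p90, ba$p90)
})

test_that("parallel planes at 0.25 mm give constant distance 0.25", {
  sq <- function(z) surface_mesh(
    rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z), c(0, 1, z)),
    rbind(c(1, 2, 3), c(1, 3, 4)))
  s <- surface_distance(sq(0), sq(0.25), samples_per_mm2 = 9)
  expect_equal(s$median, 0.25, tolerance = 1e-12)
  expect_equal(s$min, 0.25, tolerance = 1e-12)
  expect_equal(s$max, 0.25, tolerance = 1e-12)
})

test_that("concentric spheres 5.0 and 5.4 mm have median distance ~0.4", {
  a <- uv_sphere(5, 48, 96)
  b <- uv_sphere(5.4, 48, 96)
  s <- surface_distance(a, b, samples_per_mm2 = 2)
  expect_lt(abs(s$median - 0.4), 0.02)
  d <- surface_distance(a, b, mode = "directed", samples_per_mm2 = 2)
  expect_lt(abs(d$median - 0.4), 0.02)
})

test_that("ICC is 1 for perfectly agreeing raters and matches hand ANOVA", {
  tab <- cbind(c(900, 1200, 1500, 1800), c(900, 1200, 1500, 1800))
  expect_equal(icc_absolute_agreement(tab), 1.0)

  # hand-computed: values [[1,2],[2,4]] -> MSR = MSC = 2.25, MSE = 0.25,
  # ICC = 2 / 4.5 = 4/9
  expect_equal(icc_absolute_agreement(rbind(c(1, 2), c(2, 4))), 4 / 9,
               tolerance = 1e-12)

  expect_error(icc_absolute_agreement(matrix(1, 1, 2)), "at least 2")
  expect_error(icc_absolute_agreement(matrix(5, 3, 2)), "constant")
})

test_that("ICC equals the brute-force sums-of-squares oracle on random tables", {
  set.seed(77)
  for (rep in 1:25) {
    tab <- matrix(rnorm(12, 1600, 300), 6, 2)
    expect_lt(abs(icc_absolute_agreement(tab) - oracle_icc(tab)), 1e-10)
  }
})

test_that("simulated rater tables with realistic magnitudes give high ICC", {
  # subject volumes ~ N(1670, 340^2), rater noise ~ N(0, 30^2): the
  # between-subject spread dwarfs the rater error, so ICC should be
  # excellent in nearly all replicates
  set.seed(88)
  hits <- 0L
  for (rep in 1:200) {
    subj <- rnorm(10, 1670, 340)
    tab <- cbind(subj + rnorm(10, 0, 30), subj + rnorm(10, 0, 30))
    tab <- pmax(tab, 1)
    if (icc_absolute_agreement(tab) > 0.95) hits <- hits + 1L
  }
  expect_gte(hits, 190)
})

test_that("volume difference statistics match a direct loop", {
  expect_equal(volume_difference_stats(c(100, 200), c(100, 200)),
               list(mean_abs_diff = 0, mean_abs_diff_percent = 0))
  s <- volume_difference_stats(100, 110)
  expect_equal(s$mean_abs_diff, 10)
  expect_equal(s$mean_abs_diff_percent, 100 * 10 / 105, tolerance = 1e-12)

  set.seed(9)
  a <- runif(20, 1000, 2500); b <- runif(20, 1000, 2500)
  got <- volume_difference_stats(a, b)
  md <- 0; mp <- 0
  for (i in 1:20) {
    md <- md + abs(a[i] - b[i]) / 20
    mp <- mp + abs(a[i] - b[i]) / ((a[i] + b[i]) / 2) / 20 * 100
  }
  expect_equal(got$mean_abs_diff, md, tolerance = 1e-12)
  expect_equal(got$mean_abs_diff_percent, mp, tolerance = 1e-12)
  expect_error(volume_difference_stats(1:3, 1:4), "equal length")
})

test_that("volume tables validate their invariants", {
  expect_error(volume_table(matrix(c(1, -1, 2, 3), 2, 2)), "positive")
  vt <- volume_table(matrix(c(1000, 1200, 1010, 1190), 2, 2))
  expect_s3_class(vt, "volume_table")
})
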