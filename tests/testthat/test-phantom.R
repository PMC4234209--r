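test_that("phantoms are bit-identical for a fixed seed and vary across seeds", {
  a <- generate_phantom(phantom_spec(rng_seed = 4))
  b <- generate_phantom(phantom_spec(rng_seed = 4))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$data, b$truth$data)
  c_ <- generate_phantom(phantom_spec(rng_seed = 5))
  expect_false(identical(a$volume$data, c_$volume$data))
})

test_that("the phantom generator leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_phantom(phantom_spec(rng_seed = 9)))
  after <- runif(3)
  expect_identical(before, after)
})

noiseless_spec <- function(...) {
  phantom_spec(noise_sd = 0, psf_sigma = 0, drift_per_slice = 0,
               n_bridges = 0L, size_jitter_sd = 0, ...)
}

test_that("the noiseless limit is piecewise constant at the stated intensities", {
  ph <- generate_phantom(noiseless_spec())
  expect_true(all(ph$volume$data[ph$truth$data] == 200))
  expect_true(all(ph$volume$data[ph$fossa$data] == 200))
  background <- !ph$truth$data & !ph$fossa$data
  expect_true(all(ph$volume$data[background] == 60))
})

test_that("ground-truth volume is within 5% of the closed-form solid volume", {
  ph <- generate_phantom(noiseless_spec())
  analytic <- phantom_solid_volume(a = 5, b = 4.5, r = 2.2, L = 10)
  expect_lt(abs(mask_volume_mm3(ph$truth) - analytic) / analytic, 0.05)
})

test_that("a ~40-slice condyle yields 8-9 annotations at spacing five", {
  ph <- generate_phantom(noiseless_spec())
  occ <- apply(ph$truth$data, 1, any)
  n_slices <- sum(occ)
  expect_gte(n_slices, 36)
  expect_lte(n_slices, 46)
  ann <- simulate_observer(ph$volume, ph$truth,
                           observer_params(seed_jitter = 0L,
                                           threshold_noise_sd = 0,
                                           rng_seed = 1))
  n_ann <- length(ann$annotations)
  expect_equal(n_ann, floor((n_slices - 1) / 5) + 1)
  expect_gte(n_ann, 8)
  expect_lte(n_ann, 9)
})

test_that("noiseless observer thresholds separate soft tissue from bone", {
  ph <- generate_phantom(noiseless_spec())
  ann <- simulate_observer(ph$volume, ph$truth,
                           observer_params(seed_jitter = 0L,
                                           threshold_noise_sd = 0,
                                           rng_seed = 2))
  thr <- vapply(ann$annotations, `[[`, 0, "threshold")
  expect_true(all(thr > 60 & thr < 200))
})

test_that("two observers differ in thresholds yet both recover the condyle", {
  ph <- generate_phantom(phantom_spec(rng_seed = 6))
  a1 <- simulate_observer(ph$volume, ph$truth, observer_params(rng_seed = 21))
  a2 <- simulate_observer(ph$volume, ph$truth, observer_params(rng_seed = 22))
  t1 <- vapply(a1$annotations, `[[`, 0, "threshold")
  t2 <- vapply(a2$annotations, `[[`, 0, "threshold")
  expect_false(identical(t1, t2))
  m1 <- run_protocol(ph$volume, a1)$mask
  m2 <- run_protocol(ph$volume, a2)$mask
  expect_gt(dice(m1, ph$truth), 0.9)
  expect_gt(dice(m2, ph$truth), 0.9)
})

test_that("the protocol is deterministic end to end", {
  ph <- generate_phantom(phantom_spec(rng_seed = 7))
  ann <- simulate_observer(ph$volume, ph$truth, observer_params(rng_seed = 3))
  r1 <- run_protocol(ph$volume, ann)
  r2 <- run_protocol(ph$volume, ann)
  expect_identical(r1$mask$data, r2$mask$data)
  expect_identical(r1$log, r2$log)
})

test_that("bridges connect the fossa without opening; opening removes it", {
  spec <- phantom_spec(rng_seed = 8, n_bridges = 3L)
  ph <- generate_phantom(spec)
  ann <- simulate_observer(ph$volume, ph$truth, observer_params(rng_seed = 4))
  plain <- run_protocol(ph$volume, ann, open_element = NULL,
                        keep_component = FALSE)
  expect_gt(mask_volume_mm3(plain$mask), mask_volume_mm3(ph$truth))
  expect_gt(sum(plain$mask$data & ph$fossa$data), 0)
  cleaned <- run_protocol(ph$volume, ann)
  expect_equal(sum(cleaned$mask$data & ph$fossa$data), 0)
  expect_gt(dice(cleaned$mask, ph$truth), 0.95)
})

test_that("local interpolated thresholds beat a single global threshold under drift", {
  spec <- phantom_spec(rng_seed = 12, drift_per_slice = 2, noise_sd = 5,
                       n_bridges = 0L)
  ph <- generate_phantom(spec)
  ann <- simulate_observer(ph$volume, ph$truth,
                           observer_params(threshold_noise_sd = 0,
                                           seed_jitter = 0L, rng_seed = 5))
  local_mask <- run_protocol(ph$volume, ann, open_element = NULL,
                             keep_component = FALSE)$mask
  central <- ann$annotations[[ann$central_index]]
  global_ann <- annotation_set(ann$axis, list(central), ann$voi)
  global_mask <- run_protocol(ph$volume, global_ann, open_element = NULL,
                              keep_component = FALSE)$mask
  expect_gt(dice(local_mask, ph$truth), dice(global_mask, ph$truth))
})

test_that("size-3 opening removes under 2% of a phantom condyle's voxels", {
  for (s in c(2, 9)) {
    ph <- generate_phantom(phantom_spec(rng_seed = s))
    opened <- morphological_open(ph$truth)
    lost <- sum(ph$truth$data) - sum(opened$data)
    expect_lt(lost / sum(ph$truth$data), 0.02)
  }
})

test_that("geometry that overflows the grid is rejected", {
  expect_error(phantom_spec(shape = c(24L, 24L, 24L)), "does not fit")
  expect_error(phantom_spec(neck_radius = -1), "positive")
})

test_that("a small bench run is reproducible and internally consistent", {
  b1 <- bench_experiment(n_phantoms = 2, seed = 7)
  b2 <- bench_experiment(n_phantoms = 2, seed = 7)
  expect_identical(b1$results, b2$results)
  expect_true(all(b1$results$dice_inter >= 0 & b1$results$dice_inter <= 1))
  expect_true(all(b1$results$med_inter >= 0))
})
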