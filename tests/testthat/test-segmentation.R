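test_that("grow_2d fills a constant slice and isolates disconnected blocks", {
  const <- matrix(100, 7, 7)
  expect_true(all(grow_2d(const, c(4, 4), 50)))

  grid <- matrix(0, 5, 5)
  grid[1:2, 1:2] <- 200   # block A
  grid[4:5, 4:5] <- 200   # block B, diagonal gap of background
  reg <- grow_2d(grid, c(1, 1), 100)
  expected <- grid >= 100
  expected[4:5, 4:5] <- FALSE  # block B is not connected to the seed
  expect_identical(reg, expected)
  expect_equal(sum(reg), 4)

  expect_error(grow_2d(grid, c(1, 1), 201), "below threshold")
  expect_error(grow_2d(grid, c(99, 1), 100), "out of slice bounds")
})

test_that("grow_2d equals the brute-force flood-fill oracle", {
  set.seed(101)
  for (rep in 1:25) {
    dm <- sample(4:20, 2, replace = TRUE)
    img <- matrix(sample(0:255, prod(dm), replace = TRUE), dm[1], dm[2])
    thr <- sample(40:200, 1)
    adm <- img >= thr
    if (!any(adm)) next
    pick <- which(adm, arr.ind = TRUE)
    seed <- pick[sample(nrow(pick), 1), ]
    expect_identical(grow_2d(img, seed, thr), oracle_flood2d(adm, seed))
  }
})

test_that("trace_outline returns boundary pixels matching the erosion oracle", {
  single <- matrix(FALSE, 5, 5)
  single[3, 3] <- TRUE
  out <- trace_outline(single)
  expect_identical(unname(out), matrix(c(3L, 3L), 1))

  block <- matrix(FALSE, 6, 6)
  block[2:5, 2:5] <- TRUE
  out <- trace_outline(block)
  expect_equal(nrow(out), 12)  # 4x4 block: 12 perimeter, 4 interior
  expect_false(any(out[, 1] %in% 3:4 & out[, 2] %in% 3:4))

  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(runif(15 * 12) > 0.45, 15, 12)
    if (!any(m)) next
    got <- trace_outline(m)
    # oracle: mask AND NOT erode4(mask)
    pad <- matrix(FALSE, 17, 14)
    pad[2:16, 2:13] <- m
    er <- m & pad[1:15, 2:13] & pad[3:17, 2:13] &
      pad[2:16, 1:12] & pad[2:16, 3:14]
    want <- which(m & !er, arr.ind = TRUE)
    expect_setequal(paste(got[, 1], got[, 2]),
                    paste(want[, 1], want[, 2]))
  }
  expect_error(trace_outline(matrix(FALSE, 3, 3)), "empty")
})

test_that("threshold interpolation is exact at annotations and linear between", {
  v20 <- voi(c(1, 1, 1), c(20, 9, 9))
  one <- annotation_set("axial", list(slice_annotation(7, c(5, 5), 120)),
                        v20)
  p <- interpolate_thresholds(one)
  expect_equal(p$threshold, rep(120, 20))

  two <- annotation_set("axial",
                        list(slice_annotation(1, c(5, 5), 100),
                             slice_annotation(6, c(5, 5), 200)), v20)
  p <- interpolate_thresholds(two)
  expect_equal(p$threshold[p$slice == 3], 140)
  expect_equal(p$threshold[p$slice == 5], 180)

  three <- annotation_set("axial",
                          list(slice_annotation(1, c(5, 5), 100),
                               slice_annotation(6, c(5, 5), 200),
                               slice_annotation(11, c(5, 5), 150)), v20)
  p <- interpolate_thresholds(three)
  expect_equal(p$threshold[p$slice == 9], 170)
  expect_equal(p$threshold[p$slice == 13], 150)  # beyond last: constant
})

test_that("interpolated profiles match the independent piecewise evaluator", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    slices <- sort(sample(1:30, n))
    thr <- runif(n, 80, 220)
    anns <- Map(function(s, t) slice_annotation(s, c(5, 5), t), slices, thr)
    a <- annotation_set("axial", anns, voi(c(1, 1, 1), c(30, 9, 9)))
    p <- interpolate_thresholds(a)
    expect_equal(p$threshold, oracle_piecewise_linear(slices, thr, 1:30),
                 tolerance = 1e-12)
    # annotated slices are reproduced exactly
    expect_identical(p$threshold[match(slices, p$slice)], thr)
    # piecewise linearity: zero second differences strictly between
    # consecutive annotations
    if (n >= 2)
      for (i in seq_len(n - 1))
        if (slices[i + 1] - slices[i] >= 3) {
          seg <- p$threshold[(slices[i] + 1):(slices[i + 1] - 1)]
          if (length(seg) >= 3)
            expect_equal(max(abs(diff(seg, differences = 2))), 0,
                         tolerance = 1e-9)
        }
  }
})

make_two_cube_volume <- function(corner_touch = FALSE) {
  arr <- array(0, c(12, 12, 12))
  arr[3:5, 3:5, 3:5] <- 200
  if (corner_touch) arr[6:8, 6:8, 6:8] <- 200
  else {
    arr[3:5, 8:10, 3:5] <- 200
    arr[4, 6, 4] <- 200; arr[4, 7, 4] <- 200  # bridge through slice 4
  }
  image_volume(arr)
}

test_that("grow_3d segments a homogeneous cube completely", {
  arr <- array(0, c(10, 10, 10))
  arr[3:8, 3:8, 3:8] <- 200
  v <- image_volume(arr)
  a <- annotation_set("axial", list(slice_annotation(5, c(5, 5), 100)),
                      full_voi(v))
  m <- grow_3d(v, a)
  expect_equal(sum(m$data), 216)
  expect_identical(m$data, arr >= 100)
})

test_that("a local threshold above the bridge intensity disconnects two cubes", {
  v <- make_two_cube_volume()
  v$data[4, 6, 4] <- 150; v$data[4, 7, 4] <- 150  # weaker bridge voxels
  # constant threshold 100 keeps the bridge
  low <- annotation_set("axial", list(slice_annotation(4, c(4, 4), 100)),
                        full_voi(v))
  m_low <- grow_3d(v, low)
  expect_true(m_low$data[4, 9, 4])  # second cube reached
  # raising slice 4's local threshold above 150 severs the bridge
  hi <- annotation_set("axial",
                       list(slice_annotation(3, c(4, 4), 100),
                            slice_annotation(4, c(4, 4), 160),
                            slice_annotation(5, c(4, 4), 100)),
                       full_voi(v))
  m_hi <- grow_3d(v, hi)
  expect_false(any(m_hi$data[, 8:10, ]))
  expect_true(all(m_hi$data[3:5, 3:5, 3:5] | v$data[3:5, 3:5, 3:5] < 160))
})

test_that("corner-touching cubes merge under 26- but not 6-connectivity", {
  v <- make_two_cube_volume(corner_touch = TRUE)
  a6 <- annotation_set("axial", list(slice_annotation(4, c(4, 4), 100)),
                       full_voi(v), connectivity = 6L)
  m6 <- grow_3d(v, a6)
  expect_equal(sum(m6$data), 27)
  a26 <- annotation_set("axial", list(slice_annotation(4, c(4, 4), 100)),
                        full_voi(v), connectivity = 26L)
  m26 <- grow_3d(v, a26)
  expect_equal(sum(m26$data), 54)
})

test_that("grow_3d equals the component-labelling oracle on random volumes", {
  set.seed(31)
  for (rep in 1:20) {
    cs <- random_grow3d_case()
    m <- grow_3d(cs$volume, cs$ann, cs$conn)
    prof <- oracle_piecewise_linear(cs$slices, cs$thr, seq_len(cs$dm[cs$axis]))
    adm <- cs$volume$data >= prof[slice.index(cs$volume$data, cs$axis)]
    expect_identical(m$data, oracle_component3d(adm, cs$seed, cs$conn))
  }
})

test_that("grow_3d respects thresholds, keeps its seed, and shrinks as thresholds rise", {
  set.seed(41)
  for (rep in 1:10) {
    cs <- random_grow3d_case(maxdim = 14)
    m <- grow_3d(cs$volume, cs$ann, cs$conn)
    expect_true(m$data[cs$seed[1], cs$seed[2], cs$seed[3]])
    prof <- interpolate_thresholds(cs$ann)
    thr_of <- prof$threshold[slice.index(cs$volume$data, cs$axis)]
    expect_true(all(cs$volume$data[m$data] >=
                      array(thr_of, dim(cs$volume$data))[m$data]))
    # raising one annotated threshold never adds voxels
    a2 <- cs$ann
    pick <- sample(seq_along(a2$annotations), 1)
    a2$annotations[[pick]]$threshold <-
      a2$annotations[[pick]]$threshold + runif(1, 5, 60)
    seed_thr <- interpolate_thresholds(a2)
    sl <- cs$seed[cs$axis]
    if (cs$volume$data[cs$seed[1], cs$seed[2], cs$seed[3]] >=
          seed_thr$threshold[seed_thr$slice == sl]) {
      m2 <- grow_3d(cs$volume, a2, cs$conn)
      expect_true(all(m$data | !m2$data))  # m2 subset of m
    }
  }
})

test_that("an inadmissible central seed is a precondition error", {
  arr <- array(0, c(8, 8, 8))
  v <- image_volume(arr)
  a <- annotation_set("axial", list(slice_annotation(4, c(4, 4), 100)),
                      full_voi(v))
  expect_error(grow_3d(v, a), "below its local threshold")
})

test_that("the central annotation is the one nearest the median slice", {
  anns <- list(slice_annotation(2, c(5, 5), 100),
               slice_annotation(7, c(5, 5), 100),
               slice_annotation(40, c(5, 5), 100))
  a <- annotation_set("axial", anns, voi(c(1, 1, 1), c(40, 9, 9)))
  expect_equal(a$central_index, 2L)  # median slice 7
  b <- annotation_set("axial", anns, voi(c(1, 1, 1), c(40, 9, 9)),
                      central_index = 3L)
  expect_equal(b$central_index, 3L)
  expect_equal(seed_voxel(b), c(40L, 5L, 5L))
})
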