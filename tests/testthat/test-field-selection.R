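test_that("window enumeration tiles the frame and respects the band", {
  # full-frame band, field = exactly a quarter of the frame, stride = w
  m <- matrix(1L, 41, 41)
  band <- zone_band(m, "inner_tumor", 1000, mpp = 10)  # 400 x 400 um frame
  win <- enumerate_windows(band, field_dims_um = c(200, 100),
                          stride_um = 200)
  # orientation 1: x in {0, 200}, y in {0, 200} -> but y + 100 <= 400
  # gives y in {0, 200}; orientation 2 analogous
  expect_true(all(win$orientation %in% 1:2))
  expect_equal(nrow(win[win$orientation == 1, ]), 4)
  expect_equal(nrow(win[win$orientation == 2, ]), 4)
  # all window centres lie inside the band
  cr <- round((win$y + win$h / 2) / 10) + 1
  cc <- round((win$x + win$w / 2) / 10) + 1
  expect_true(all(band$values[cbind(cr, cc)] == 1L))

  # stride larger than the frame: at most one candidate per orientation
  win1 <- enumerate_windows(band, field_dims_um = c(200, 100),
                           stride_um = 10000)
  expect_lte(nrow(win1[win1$orientation == 1, ]), 1L)
  expect_error(enumerate_windows(zone_band(matrix(0L, 5, 5),
                                           "itf", 1000, mpp = 10)),
               "empty")
})

test_that("border checks look at all four margin strips", {
  mpp <- 10
  full <- tumor_mask(matrix(1L, 30, 30), mpp)
  box <- field_box(0, 0, 200, 150)
  expect_true(border_has_tumor(full, box, margin_um = 20))

  # empty top strip
  m <- matrix(1L, 30, 30); m[1:5, ] <- 0L
  expect_false(border_has_tumor(tumor_mask(m, mpp), box, margin_um = 20))

  # one-pixel tumor ring along the border is enough
  ring <- matrix(0L, 30, 30)
  ring[1, 1:21] <- 1L; ring[16, 1:21] <- 1L
  ring[1:16, 1] <- 1L; ring[1:16, 21] <- 1L
  expect_true(border_has_tumor(tumor_mask(ring, mpp), box, margin_um = 20))

  expect_error(border_has_tumor(full, box, margin_um = 100), "margin")
})

test_that("selection matches exhaustive brute force on toy grids", {
  set.seed(31)
  mpp <- 10
  # 40 x 40 px toy mask with two low-density pockets in a dense field
  m <- matrix(rbinom(1600, 1, 0.7), 40, 40)
  m[5:12, 5:12] <- rbinom(64, 1, 0.15)
  m[25:33, 20:30] <- rbinom(99, 1, 0.1)
  m[1, ] <- 1L; m[40, ] <- 1L; m[, 1] <- 1L; m[, 40] <- 1L
  mask <- tumor_mask(m, mpp)
  band <- zone_band(matrix(1L, 40, 40), "itf", 1000, mpp)

  dims <- c(150, 100)
  got <- select_fields(mask, band, k = 3, field_dims_um = dims,
                       stride_um = 30, margin_um = 20)
  want <- brute_select_fields(mask, band, k = 3, field_dims_um = dims,
                              stride_um = 30, margin_um = 20)
  expect_equal(fields_to_df(got)$fraction, want$fraction, tolerance = 1e-12)
  expect_equal(fields_to_df(got)[, c("x", "y", "w", "h")],
               want[, c("x", "y", "w", "h")],
               ignore_attr = TRUE)
})

test_that("ties are broken by scan order on a uniform checkerboard", {
  mpp <- 10
  m <- matrix(0L, 30, 30)
  m[(row(m) + col(m)) %% 2 == 0] <- 1L  # 50% checkerboard
  mask <- tumor_mask(m, mpp)
  band <- zone_band(matrix(1L, 30, 30), "inner_tumor", 1000, mpp)
  got <- select_fields(mask, band, k = 3, field_dims_um = c(150, 110),
                       stride_um = 20, margin_um = 20)
  df <- fields_to_df(got)
  expect_equal(df$fraction, rep(0.5, 3), tolerance = 1e-12)
  # first k candidates in scan order: y = 0, x = 0, 20, 40
  expect_equal(df$x, c(0, 20, 40))
  expect_equal(df$y, rep(0, 3))
})

test_that("selection errors without tumor and warns when k is short", {
  mpp <- 10
  empty <- tumor_mask(matrix(0L, 30, 30), mpp)
  band <- zone_band(matrix(1L, 30, 30), "itf", 1000, mpp)
  expect_error(select_fields(empty, band, field_dims_um = c(150, 100)),
               "border")

  # only one valid placement: a single tumor ring in one corner
  m <- matrix(0L, 30, 30)
  m[1:11, 1:16] <- 1L
  one <- tumor_mask(m, mpp)
  expect_warning(
    got <- select_fields(one, band, k = 3, field_dims_um = c(150, 100),
                         stride_um = 300, margin_um = 20),
    "valid field")
  expect_lt(length(got), 3L)
  expect_true(isTRUE(attr(got, "incomplete")))
})

test_that("finer strides can only improve the minimum fraction", {
  ph <- small_phantom()
  mask <- ph$truth$tumor_mask
  band <- ph$truth$bands$itf
  f_coarse <- select_fields(mask, band, k = 1, stride_um = 200)
  f_fine <- select_fields(mask, band, k = 1, stride_um = 100)
  expect_lte(f_fine[[1]]$tumor_fraction, f_coarse[[1]]$tumor_fraction)
  # reproducible bit-exactly
  again <- select_fields(mask, band, k = 1, stride_um = 100)
  expect_identical(fields_to_df(f_fine), fields_to_df(again))
})
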