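test_that("optical density transform matches its closed form", {
  px <- array(0, dim = c(1, 3, 3))
  px[1, 1, ] <- 255   # blank
  px[1, 2, ] <- 0     # black
  px[1, 3, ] <- 127   # mid grey
  od <- rgb_to_optical_density(px)
  expect_equal(od[1, 1, ], rep(0, 3), tolerance = 1e-12)
  expect_equal(od[1, 2, ], rep(-log10(1 / 256), 3), tolerance = 1e-12)
  # halving intensity increases OD in every channel
  half <- rgb_to_optical_density(px[, 3, , drop = FALSE] / 2)
  expect_true(all(half > od[1, 3, ]))
  expect_error(rgb_to_optical_density(px - 1), "\\[0, 255\\]")
})

test_that("deconvolution is the exact inverse of the stain basis", {
  v <- hdab_stain_vectors()
  expect_equal(unname(rowSums(v^2)), rep(1, 3), tolerance = 1e-12)

  # pixel whose OD is exactly the DAB unit vector
  od <- array(rep(v["dab", ], each = 1), dim = c(1, 1, 3))
  conc <- deconvolve_hdab(od)
  expect_equal(as.numeric(conc), c(0, 1, 0), tolerance = 1e-9)
  # zero OD -> zero concentrations
  expect_equal(as.numeric(deconvolve_hdab(array(0, c(2, 2, 3)))),
               rep(0, 12), tolerance = 1e-12)

  # round trip on a random raster
  set.seed(1)
  od <- array(runif(5 * 4 * 3, 0, 2), dim = c(5, 4, 3))
  conc <- deconvolve_hdab(od)
  rebuilt <- array(matrix(conc, ncol = 3) %*% v, dim = dim(od))
  expect_lt(max(abs(rebuilt - od)), 1e-6)

  singular <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_error(deconvolve_hdab(od, singular), "singular")
})

test_that("threshold classification behaves at the extremes and on phantoms", {
  ph <- small_phantom()
  conc <- deconvolve_hdab(rgb_to_optical_density(ph$image))
  expect_true(all(threshold_classify(conc, -1e6, mpp = 16)$values == 1L))
  expect_true(all(threshold_classify(conc,
                                     max(conc[, , "dab"]) + 1,
                                     mpp = 16)$values == 0L))
  mask <- segment_image(ph$image)
  expect_gte(mean(mask$values == ph$truth$tumor_mask$values), 0.95)
})

test_that("segmentation survives noise up to 8 intensity units", {
  for (sd in c(4, 8)) {
    ph <- small_phantom(noise_sd = sd, seed = 21)
    acc <- mean(segment_image(ph$image)$values ==
                  ph$truth$tumor_mask$values)
    expect_gte(acc, 0.95)
  }
})

test_that("trained classifier reaches phantom ground truth", {
  ph <- small_phantom(noise_sd = 6, seed = 5)
  scr <- truth_scribbles(ph, 200)
  clf <- train_pixel_classifier(ph$image, scr)
  pred <- predict_mask(clf)
  truth <- ph$truth$tumor_mask$values

  # training-set refit >= 99%
  pix <- (scr$col - 1) * nrow(truth) + scr$row
  expect_gte(mean(pred$values[pix] == (scr$class == "tumor")), 0.99)
  # whole-image accuracy >= 95%
  expect_gte(mean(pred$values == truth), 0.95)
  # idempotent re-prediction (no inference randomness)
  expect_identical(pred$values, predict_mask(clf)$values)
})

test_that("classifier training validates scribbles and stays deterministic", {
  ph <- small_phantom()
  scr <- truth_scribbles(ph, 50)
  expect_error(train_pixel_classifier(ph$image,
                                      scr[scr$class == "tumor", ]),
               "stroma")
  expect_error(train_pixel_classifier(ph$image,
                                      scr[scr$class == "stroma", ]),
               "tumor")
  a <- train_pixel_classifier(ph$image, scr, seed = 3)
  b <- train_pixel_classifier(ph$image, scr, seed = 3)
  expect_identical(predict_mask(a)$values, predict_mask(b)$values)
})

test_that("refinement fixes mislabeled pixels and is stable under no-ops", {
  ph <- small_phantom(noise_sd = 6, seed = 5)
  scr <- truth_scribbles(ph, 30, seed = 4)
  clf <- train_pixel_classifier(ph$image, scr)
  truth <- ph$truth$tumor_mask$values
  pred <- predict_mask(clf)

  # no-op refinements leave predictions unchanged
  expect_identical(predict_mask(refine_classifier(clf, scr))$values,
                   pred$values)
  empty <- scr[0, ]
  expect_identical(predict_mask(refine_classifier(clf, empty))$values,
                   pred$values)

  mis <- which(pred$values != truth)
  if (length(mis) > 0) {
    h <- nrow(truth)
    add <- data.frame(row = (mis - 1) %% h + 1, col = (mis - 1) %/% h + 1,
                      class = ifelse(truth[mis] == 1L, "tumor", "stroma"))
    refined <- refine_classifier(clf, add)
    pred2 <- predict_mask(refined)
    expect_gte(mean(pred2$values[mis] == truth[mis]), 0.95)
  }
})

test_that("prediction on constant-colour images yields a single class", {
  px <- array(200, dim = c(20, 20, 3))
  img <- calibrated_image(px, 16)
  ph <- small_phantom()
  clf <- train_pixel_classifier(ph$image, truth_scribbles(ph, 50))
  expect_lte(length(unique(as.integer(predict_mask(clf, img)$values))), 1L)
  expect_error(predict_mask(structure(list(trained = FALSE),
                                      class = "pixel_classifier")),
               "untrained")
})
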