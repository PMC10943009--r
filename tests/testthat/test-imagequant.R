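draw_disk <- function(img, cy, cx, r, value = 1) {
  ys <- seq_len(nrow(img)); xs <- seq_len(ncol(img))
  img[outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2] <- value
  img
}

test_that("watershed segmentation finds separated nuclei and drops small ones", {
  img <- matrix(0, 120, 120)
  img <- draw_disk(img, 35, 35, 14, 100)
  img <- draw_disk(img, 85, 85, 14, 100)
  labs <- segment_nuclei_watershed(img, smoothing_sigma = 2,
                                   min_area_px = 50)
  expect_equal(max(labs), 2)
  cy <- tapply(row(labs)[labs > 0], labs[labs > 0], mean)
  cx <- tapply(col(labs)[labs > 0], labs[labs > 0], mean)
  expect_equal(sort(as.numeric(cy)), c(35, 85), tolerance = 0.05)
  expect_equal(sort(as.numeric(cx)), c(35, 85), tolerance = 0.05)

  # blank image: zero labels with a warning
  expect_warning(empty <- segment_nuclei_watershed(matrix(0, 50, 50)),
                 "foreground")
  expect_equal(max(empty), 0)

  # area floor: a disk below min_area_px is discarded
  one <- draw_disk(matrix(0, 80, 80), 40, 40, 10, 100)  # area ~314 px
  area <- sum(one > 0)
  kept <- segment_nuclei_watershed(one, smoothing_sigma = 0,
                                   min_area_px = area)
  dropped <- segment_nuclei_watershed(one, smoothing_sigma = 0,
                                      min_area_px = area + 1)
  expect_equal(max(kept), 1)
  expect_equal(max(dropped), 0)
})

test_that("phase correlation registers periodic translations exactly", {
  set.seed(11)
  img <- matrix(runif(96 * 96), 96, 96)
  shift_per <- function(im, dy, dx) {
    im[((seq_len(nrow(im)) - 1 - dy) %% nrow(im)) + 1,
       ((seq_len(ncol(im)) - 1 - dx) %% ncol(im)) + 1]
  }
  expect_equal(register_image(img, img), c(dy = 0, dx = 0))
  expect_equal(register_image(shift_per(img, 7, -3), img),
               c(dy = 7, dx = -3))
  # subpixel: Fourier-shifted by half a pixel, recovered within 0.1
  fshift <- function(im, dy, dx) {
    ky <- modulefish:::fft_freq(nrow(im)); kx <- modulefish:::fft_freq(ncol(im))
    ph <- exp(-2i * pi * (outer(ky / nrow(im), rep(1, ncol(im))) * dy +
                            outer(rep(1, nrow(im)), kx / ncol(im)) * dx))
    Re(stats::fft(stats::fft(im) * ph, inverse = TRUE)) / length(im)
  }
  sub <- register_image(fshift(img, 0.5, 0.5), img)
  expect_lt(max(abs(sub - c(0.5, 0.5))), 0.1)
  expect_error(register_image(matrix(0, 8, 8), img[1:8, 1:8]),
               class = "modulefish_undefined_error")
})

test_that("align_image inverts a registered shift up to border exclusion", {
  set.seed(3)
  img <- matrix(runif(60 * 60), 60, 60)
  moved <- align_image(img, c(-4, 6))   # sample img at (y - 4, x + 6)
  back <- align_image(moved, c(4, -6))
  core <- 11:50
  expect_equal(back[core, core], img[core, core])
  # integer shifts leave values untouched (no interpolation smear)
  expect_equal(moved[10, 10], img[6, 16])
  # out-of-bounds source pixels become NA, not zero
  expect_true(all(is.na(align_image(img, c(70, 0)))))
})

test_that("shift_policy filters outliers before averaging", {
  sh <- rbind(c(3, 4), c(60, 0), c(5, 6))
  out <- shift_policy(sh, max_abs_px = 50, mode = "fov_average")
  expect_equal(unname(out), matrix(c(4, 5), 3, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(attr(out, "discarded"), 2)
  # boundary: |dx| = 51 discarded, 50 kept
  out2 <- shift_policy(rbind(c(0, -51), c(0, 50)), mode = "fov_average")
  expect_equal(attr(out2, "discarded"), 1)
  expect_equal(unname(out2[1, ]), c(0, 50))

  # single shift passes through in both modes
  single <- matrix(c(2, -1), 1, 2)
  expect_equal(unname(shift_policy(single, mode = "per_image")),
               single, ignore_attr = TRUE)
  expect_equal(unname(shift_policy(single, mode = "fov_average")),
               single, ignore_attr = TRUE)
  expect_error(shift_policy(matrix(c(80, 80), 1, 2), mode = "fov_average"),
               class = "modulefish_empty_error")
})

test_that("background subtraction clamps at zero", {
  img <- matrix(c(5, 10, 0, 3), 2, 2)
  expect_equal(subtract_background(img, img), matrix(0, 2, 2))
  expect_equal(subtract_background(img, matrix(0, 2, 2)), img)
  expect_equal(subtract_background(matrix(5, 1, 1), matrix(8, 1, 1)),
               matrix(0, 1, 1))
  expect_error(subtract_background(img, matrix(0, 3, 3)))
})

test_that("illumination_correct subtracts the off-mask percentile", {
  img <- matrix(7, 10, 10)
  masks <- matrix(0L, 10, 10); masks[1:3, 1:3] <- 1L
  expect_equal(illumination_correct(img, masks, 60), matrix(0, 10, 10))
  # off-mask values 1..100: 60th percentile by linear interpolation = 60.4
  img2 <- matrix(0, 10, 20)
  img2[, 11:20] <- 300
  masks2 <- matrix(0L, 10, 20); masks2[, 11:20] <- 1L
  img2[masks2 == 0] <- 1:100
  out <- illumination_correct(img2, masks2, 60)
  expect_equal(out[masks2 == 1][1], 300 - 60.4)
  # zero off-mask offset leaves the image unchanged
  img3 <- matrix(0, 5, 5); img3[1:2, 1:2] <- 9
  masks3 <- matrix(0L, 5, 5); masks3[1:2, 1:2] <- 1L
  expect_equal(illumination_correct(img3, masks3, 60), img3)
  expect_error(illumination_correct(img, matrix(1L, 10, 10), 60),
               class = "modulefish_empty_error")
})

test_that("dilate_masks grows labels by Euclidean distance with nearest-nucleus ties", {
  # identity at zero dilation
  labs <- matrix(0L, 40, 40)
  labs[18:22, 18:22] <- 1L
  expect_identical(dilate_masks(labs, 0), labs)

  # isolated disk of radius r grows to the analytic area of radius r + d
  disk <- matrix(0L, 80, 80)
  ys <- seq_len(80)
  disk[outer((ys - 40)^2, (ys - 40)^2, `+`) <= 8^2] <- 1L
  grown <- dilate_masks(disk, 10)
  expect_equal(sum(grown > 0), pi * 18^2, tolerance = 0.03)

  # two nuclei 12 px apart with dilation 10: labels never merge and the
  # boundary is equidistant
  two <- matrix(0L, 60, 72)
  two[29:31, 24:26] <- 1L
  two[29:31, 36:38] <- 2L
  g2 <- dilate_masks(two, 10)
  expect_setequal(unique(as.vector(g2)), c(0L, 1L, 2L))
  left <- col(g2)[g2 == 1]; right <- col(g2)[g2 == 2]
  expect_lte(max(left), 31)   # boundary sits at the equidistant midline
  expect_gte(min(right), 31)
  expect_lt(abs(length(left) - length(right)) / length(left), 0.1)
})

test_that("normalize_image divides by the stated percentile", {
  img <- matrix(4, 6, 6)
  expect_equal(normalize_image(img, 99), matrix(1, 6, 6))
  set.seed(2)
  img2 <- matrix(runif(100, 1, 10), 10, 10)
  expect_equal(normalize_image(img2 * 2), normalize_image(img2))
  # divisor equals the sorted-percentile recomputation
  v <- sort(as.vector(img2))
  q <- stats::quantile(v, 0.99, type = 7, names = FALSE)
  expect_equal(normalize_image(img2), img2 / q)
  expect_error(normalize_image(matrix(0, 3, 3)),
               class = "modulefish_undefined_error")
})

test_that("intensity_matrix averages aligned rounds over cell masks", {
  masks <- matrix(0L, 30, 30)
  masks[5:9, 5:9] <- 1L
  masks[20:24, 20:26] <- 2L
  stack <- image_stack(list(M1 = matrix(7, 30, 30),
                            DAPI = matrix(1, 30, 30)))
  cbm <- intensity_matrix(stack, masks)
  expect_equal(unname(cbm$values[, "M1"]), c(7, 7))
  expect_equal(cbm$cells$y_px, c(7, 22))
  expect_equal(cbm$cells$x_px, c(7, 23))

  # label order equivariance: permuting labels permutes rows identically
  masks_p <- masks
  masks_p[masks == 1L] <- 2L
  masks_p[masks == 2L] <- 1L
  grad <- matrix(seq_len(900), 30, 30)
  s2 <- image_stack(list(M1 = grad, DAPI = matrix(1, 30, 30)))
  a <- intensity_matrix(s2, masks)$values
  b <- intensity_matrix(s2, masks_p)$values
  expect_equal(a[c(1, 2), ], b[c(2, 1), ])

  # pipeline linearity: scaling the round scales the matrix
  s3 <- image_stack(list(M1 = grad * 3, DAPI = matrix(1, 30, 30)))
  expect_equal(intensity_matrix(s3, masks)$values, 3 * a)

  # a cell pushed fully out of bounds by the shift is flagged, not dropped
  s4 <- image_stack(list(M1 = grad, DAPI = matrix(1, 30, 30)))
  cbm4 <- intensity_matrix(s4, masks, shifts = matrix(c(40, 0), 1, 2))
  expect_equal(nrow(cbm4$values), 2)
  expect_true(all(cbm4$cells$qc_flag))
  expect_true(all(cbm4$cells$qc_reason == "empty_mask"))
})

test_that("qc_cells flags by total percentile or per-module band with reasons", {
  set.seed(8)
  totals_mode <- list(
    values = matrix(c(seq_len(100)), 100, 1) %*% t(c(1, 1)),
    cells = tibble::tibble(cell = 1:100, qc_flag = FALSE,
                           qc_reason = NA_character_))
  class(totals_mode) <- "cell_by_module"
  out <- qc_cells(totals_mode, "total_percentile", percentile = 15)
  expect_equal(sum(out$cells$qc_flag), 15)
  expect_true(all(which(out$cells$qc_flag) <= 16))
  expect_true(all(out$cells$qc_reason[out$cells$qc_flag] == "low_total"))

  # all-equal matrix: warning, nothing flagged
  flat <- totals_mode
  flat$values <- matrix(5, 100, 2)
  expect_warning(out_flat <- qc_cells(flat, "total_percentile"), "degenerate")
  expect_equal(sum(out_flat$cells$qc_flag), 0)

  # band mode: a cell above the 98th percentile in 31 of 53 modules is
  # flagged when the limit is 30; one bright in 30 modules is not
  n_mod <- 53
  vals <- matrix(stats::runif(200 * n_mod), 200, n_mod)
  vals[1, 1:31] <- 2   # above every per-module 98th percentile
  vals[2, 1:30] <- 2
  band <- totals_mode
  band$values <- vals
  band$cells <- tibble::tibble(cell = 1:200, qc_flag = FALSE,
                               qc_reason = NA_character_)
  out_b <- qc_cells(band, "band", low_percentile = 0.2,
                    high_percentile = 98, max_high_modules = 30)
  expect_true(out_b$cells$qc_flag[1])
  expect_false(out_b$cells$qc_flag[2])
  expect_equal(out_b$cells$qc_reason[1], "high_many_modules")
  # a uniformly dark cell is flagged for being below the low band everywhere
  vals2 <- vals
  vals2[3, ] <- -1
  band2 <- band
  band2$values <- vals2
  out_b2 <- qc_cells(band2, "band", low_percentile = 2,
                     high_percentile = 98, max_high_modules = 30)
  expect_true(out_b2$cells$qc_flag[3])
  expect_equal(out_b2$cells$qc_reason[3], "low_all_modules")
})

test_that("quantify_stack applies preset corrections and QC end to end", {
  sim <- small_sim(n_cells = 150, seed = 14)
  td <- simulate_tissue_images(sim$truth, image_shape = c(230, 230),
                               cell_radius_px = 5, background_level = 12,
                               noise_sd = 2, background_round = TRUE,
                               seed = 9)
  cbm <- quantify_stack(td$stack, nuclei = td$labels, preset = "fig3")
  expect_s3_class(cbm, "cell_by_module")
  expect_equal(nrow(cbm$values), 150)
  # fig3 flags the lowest 15% of totals
  expect_equal(sum(cbm$cells$qc_flag), 23)  # floor(0.15 * 150) + boundary
  # each cell's own-type module clearly dominates its other modules
  passed <- qc_pass(cbm)
  types <- sim$truth$cell_type_labels[passed$cells$cell]
  own <- passed$values[cbind(seq_len(nrow(passed$values)),
                             match(sub("type", "M", types),
                                   colnames(passed$values)))]
  other <- (rowSums(passed$values) - own) / (ncol(passed$values) - 1)
  expect_gt(stats::median(own / other), 3)
  # tidy/glance round trip
  tl <- tidy(cbm)
  expect_s3_class(tl, "tbl_df")
  expect_equal(nrow(tl), 150 * 4)
  expect_equal(glance(cbm)$n_cells, 150)
})
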