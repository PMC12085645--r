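# Preprocessing chain: each operation against direct arithmetic or
# brute-force oracles, plus the tiling/augmentation contracts.

test_that("background subtraction matches a brute-force median filter", {
  expect_true(all(subtract_background_dic(matrix(7, 50, 50)) == 0))
  cfgg <- preprocess_config(dic_background = "gaussian_subtract")
  expect_true(all(abs(subtract_background_dic(matrix(7, 50, 50), cfgg)) < 1e-9))

  img <- matrix(0, 9, 9); img[5, 5] <- 100
  cfg3 <- preprocess_config(median_kernel_px = 3L)
  out <- subtract_background_dic(img, cfg3)
  expect_equal(out[5, 5], 100)
  expect_true(all(out[-41] == 0))

  set.seed(2)
  x <- matrix(runif(30 * 25, 0, 1000), 30, 25)
  for (k in c(3L, 5L)) {
    cfg <- preprocess_config(median_kernel_px = k)
    expect_equal(subtract_background_dic(x, cfg),
                 pmax(x - naive_median_filter(x, k), 0), tolerance = 1e-10)
  }
  expect_error(subtract_background_dic(matrix(0, 10, 10),
                                       preprocess_config(median_kernel_px = 40L)),
               "kernel larger")
  expect_equal(preprocess_config()$median_kernel_px, 40L)
})

test_that("contrast enhancement saturates the configured tail fractions", {
  ramp <- matrix(seq(0, 255, length.out = 256), 16, 16)
  expect_equal(enhance_contrast(ramp, 0), ramp, tolerance = 1e-10)

  x <- matrix(1:100, 10, 10)
  out <- enhance_contrast(x, 0.20)
  p10 <- quantile(x, 0.10); p90 <- quantile(x, 0.90)
  expect_true(all(out[x <= p10] == min(x)))
  expect_true(all(out[x >= p90] == max(x)))
  mid <- x > p10 & x < p90
  expect_equal(out[mid], (x[mid] - p10) / (p90 - p10) * 99 + 1, tolerance = 1e-9)

  expect_warning(enhance_contrast(matrix(5, 4, 4)), "constant")
  expect_equal(preprocess_config()$dic_saturate_frac, 0.35)
})

test_that("dataset-level 8-bit scaling follows the outlier-percentile arithmetic", {
  imgs <- list(matrix(0:499, 25, 20), matrix(500:999, 25, 20))
  out0 <- scale_dataset_8bit(imgs, outlier_frac = 0)
  expect_equal(min(out0[[1]]), 0)
  expect_equal(max(out0[[2]]), 255)

  pool <- matrix(seq(0, 1000, length.out = 1001), 7, 143)
  out <- scale_dataset_8bit(list(pool), outlier_frac = 0.10)
  sp <- attr(out, "scale_params")
  expect_equal(sp, c(100, 900), tolerance = 0.5)
  v500 <- out[[1]][which.min(abs(pool - 500))]
  expect_equal(v500, round(255 * (500 - 100) / 800))  # = 128
  expect_true(all(out[[1]] >= 0 & out[[1]] <= 255))

  expect_error(scale_dataset_8bit(list(matrix(3, 5, 5))), "degenerate")
  expect_equal(preprocess_config()$fluor_outlier_frac, 0.10)
})

test_that("resize-and-patch tiles every channel identically with floor counts", {
  f <- list(a = matrix(runif(1024^2), 1024), b = matrix(runif(1024^2), 1024))
  rp <- resize_and_patch(f, preprocess_config(patch_size = 256L))
  expect_length(rp$tiles, 4L)   # 1024 -> 512 -> 2x2 tiles of 256
  expect_equal(dim(rp$tiles[[1]]), c(256L, 256L, 2L))

  f2 <- list(a = matrix(runif(300 * 300), 300))
  rp2 <- resize_and_patch(f2, preprocess_config(patch_size = 128L))
  expect_length(rp2$tiles, 1L)  # 300 -> 150 -> one 128 tile

  # co-registration: every channel's tile comes from identical coordinates
  r <- resize_bilinear(f$a, 0.5); r2 <- resize_bilinear(f$b, 0.5)
  expect_equal(rp$tiles[[2]][, , 1], r[1:256, 257:512], ignore_attr = TRUE)
  expect_equal(rp$tiles[[2]][, , 2], r2[1:256, 257:512], ignore_attr = TRUE)

  expect_warning(resize_and_patch(list(a = matrix(0, 100, 100)),
                                  preprocess_config(patch_size = 128L)), "0 tiles")
  # patch tiling covers floor(H/P)*floor(W/P)*P^2 pixels exactly once
  expect_equal(length(rp$tiles) * 256^2, 4 * 256^2)
})

test_that("flip augmentation emits exactly four orientations per tile", {
  set.seed(3)
  tiles <- lapply(1:10, function(i) array(runif(16 * 16 * 2), c(16, 16, 2)))
  out <- augment_flips(tiles)
  expect_length(out, 40L)
  # flip o flip = identity
  again <- augment_flips(out[2])
  expect_equal(again[[2]], out[1][[1]])  # horizontal flip applied twice
  # symmetric tiles are still emitted 4x (no dedup)
  sym <- array(1, c(8, 8, 1))
  expect_length(augment_flips(list(sym)), 4L)
  # all channels flipped jointly
  expect_equal(out[[2]][, , 2], tiles[[1]][, rev(1:16), 2])
})

test_that("model-range normalisation is exact and clips on inversion", {
  expect_equal(to_model_range(0), -0.5)
  expect_equal(to_model_range(255), 0.5)
  x <- matrix(sample(0:255, 100, TRUE), 10)
  expect_equal(from_model_range(to_model_range(x)), x)
  expect_equal(from_model_range(-0.7), 0)   # tanh overshoot clipped
  expect_equal(from_model_range(0.7), 255)
})

test_that("preprocessing a dataset is deterministic and keeps channel identity", {
  ps <- pb_test_patchset()
  expect_s3_class(ps, "pb_patchset")
  # 128-px fields, half resize, 64-px patches -> one tile per field
  expect_equal(length(ps$tiles), nrow(ps$meta))
  expect_equal(length(ps$tiles), 12L * 3L)
  tl <- ps$tiles[[1]]
  expect_true(all(c("DIC", "DNA", "Actin", "Junction") %in% dimnames(tl)[[3]]))
  expect_true(all(tl >= 0 & tl <= 255))
  # per-channel scale params recorded for every fluorescence channel
  expect_true(all(c("DNA", "Actin", "Junction") %in% names(ps$scale_params)))
})
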