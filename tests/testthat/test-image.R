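test_that("split_channels scales by bit depth and validates shapes", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, 3] <- 255  # pure blue, 8-bit
  ch <- split_channels(img)
  expect_equal(ch$blue[1, 1], 1)
  expect_equal(ch$red[1, 1], 0)
  expect_equal(ch$green[1, 1], 0)
  img16 <- array(0, c(2, 2, 3)); img16[2, 2, 1] <- 65535
  expect_equal(split_channels(img16)$red[2, 2], 1)
  # channel-list input with mapped grayscale planes
  lst <- list(red = matrix(0.2, 2, 2), green = matrix(0.4, 2, 2),
              blue = matrix(1, 2, 2))
  expect_equal(split_channels(lst)$green[1, 1], 0.4)
  lst$green <- matrix(0.4, 3, 2)
  expect_error(split_channels(lst), "shape mismatch")
})

test_that("DAPI map degenerate channels and parameter validation", {
  zero <- matrix(0, 32, 32)
  expect_equal(build_dapi_map(zero)$area, 0)
  ones <- matrix(1, 32, 32)
  full <- build_dapi_map(ones, min_size = 1, disk_radius = 2)
  expect_equal(full$area, length(ones))
  expect_error(build_dapi_map(zero, threshold = 1.5), "threshold")
})

test_that("pre-morphology mask is monotone in the threshold", {
  sim <- simulate_if_image(image_sim_config(seed = 6))
  blue <- split_channels(sim$image)$blue
  prev <- NULL
  for (th in c(0.05, 0.15, 0.35, 0.6)) {
    tm <- build_dapi_map(blue, threshold = th, disk_radius = 0,
                         min_size = 0)
    if (!is.null(prev)) expect_true(all(prev | !tm$premorphology))
    prev <- tm$premorphology
  }
})

test_that("region means partition the global channel mean", {
  sim <- simulate_if_image(image_sim_config(seed = 3))
  ch <- split_channels(sim$image)
  tm <- build_dapi_map(ch$blue)
  for (cc in c("red", "green")) {
    reg <- region_mean_intensity(ch[[cc]], tm)
    recombined <- (reg$inside_mean * reg$inside_n +
                     reg$outside_mean * reg$outside_n) /
      (reg$inside_n + reg$outside_n)
    expect_equal(recombined, mean(ch[[cc]]), tolerance = 1e-9)
    expect_equal(reg$inside_n + reg$outside_n, length(ch[[cc]]))
  }
  # constant channel: inside == outside == the constant
  const <- matrix(0.4, nrow(tm$mask), ncol(tm$mask))
  reg <- region_mean_intensity(const, tm)
  expect_equal(reg$inside_mean, 0.4)
  expect_equal(reg$outside_mean, 0.4)
  # full mask: outside undefined-flagged
  allmask <- matrix(TRUE, 4, 4)
  reg2 <- region_mean_intensity(matrix(0.5, 4, 4), allmask)
  expect_true(is.na(reg2$outside_mean))
  expect_error(region_mean_intensity(matrix(0, 2, 2), matrix(TRUE, 3, 3)),
               "dimensions differ")
})

test_that("normalized signal modes", {
  reg <- structure(list(inside_mean = 0.6, outside_mean = 0.1,
                        inside_n = 100, outside_n = 900),
                   class = "region_intensity")
  ref <- structure(list(inside_mean = 0.3, outside_mean = 0.1,
                        inside_n = 100, outside_n = 900),
                   class = "region_intensity")
  expect_equal(normalized_signal(reg, ref, mode = "reference"), 2)
  expect_equal(normalized_signal(reg, mode = "area"), 0.6)
  empty <- structure(list(inside_mean = NA_real_, outside_mean = 0.1,
                          inside_n = 0, outside_n = 1000),
                     class = "region_intensity")
  expect_true(is.na(normalized_signal(empty, mode = "area")))
  zero_ref <- ref; zero_ref$inside_mean <- 0
  expect_true(is.na(normalized_signal(reg, zero_ref, mode = "reference")))
})

test_that("tissue masks recover the ground truth and signal contrast", {
  sims <- lapply(1:4, function(s) simulate_if_image(image_sim_config(seed = s)))
  report <- run_image_quant(lapply(sims, `[[`, "image"))
  expect_equal(nrow(report$report), 4)
  expect_length(report$masks, 4)
  for (i in 1:4) {
    expect_gte(dice_coefficient(report$masks[[i]]$mask, sims[[i]]$mask), 0.9)
  }
  # configured in/out contrast shows up in the report
  expect_true(all(report$report$red_in > 0.7))
  expect_true(all(report$report$red_out < 0.2))
})

test_that("paired region report feeds the paired t-test", {
  sims <- lapply(10:15,
                 function(s) simulate_if_image(image_sim_config(seed = s)))
  rep_tab <- paired_region_report(lapply(sims, `[[`, "image"),
                                  lapply(sims, `[[`, "mask"))
  expect_equal(nrow(rep_tab), 6 * 2 * 2)  # image x channel x region
  wide_in <- rep_tab$mean[rep_tab$channel == "red" & rep_tab$region == "in"]
  wide_out <- rep_tab$mean[rep_tab$channel == "red" & rep_tab$region == "out"]
  pt_ <- paired_t(wide_out, wide_in)
  expect_lt(pt_$p, 0.01)
  expect_gt(pt_$mean_difference, 0.5)
  # all-empty masks are flagged, not crashed on
  rep2 <- paired_region_report(list(sims[[1]]$image),
                               list(matrix(FALSE, 256, 256)))
  expect_true(all(is.na(rep2$mean[rep2$region == "in"])))
})
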