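test_that("wn_axis enforces a strictly increasing positive grid", {
  expect_s3_class(wn_axis(c(2820, 2900, 3030)), "wn_axis")
  expect_error(wn_axis(c(2900, 2850)), "increasing")
  expect_error(wn_axis(c(2900, 2900)), "increasing")
  expect_error(wn_axis(c(-1, 2900)), "positive")
  expect_error(wn_axis(numeric(0)), "at least one")
  expect_error(wn_axis(c(2900, NA)), "finite")
})

test_that("validate_cube reports violations without erroring", {
  ax <- wn_axis(seq(2820, 2920, length.out = 6))
  good <- hyper_cube(array(runif(4 * 4 * 6), c(4, 4, 6)), ax)
  expect_identical(validate_cube(good), character(0))

  bad_axis <- good
  bad_axis$axis <- wn_axis(seq(2820, 2920, length.out = 5))
  expect_match(validate_cube(bad_axis), "axis length mismatch", all = FALSE)

  bad_val <- good
  bad_val$data[2, 3, 1] <- NaN
  expect_match(validate_cube(bad_val), "non-finite", all = FALSE)
})

test_that("restrict_to_channels slices cubes and composes", {
  ax <- wn_axis(seq(2820, 3030, length.out = 45))
  cube <- hyper_cube(array(runif(3 * 4 * 45), c(3, 4, 45)), ax)

  all_idx <- channel_subset(1:45, ax)
  expect_equal(restrict_to_channels(cube, all_idx)$data, cube$data)

  idx5 <- c(4L, 13L, 19L, 28L, 41L)
  sub5 <- channel_subset(idx5, ax,
                         trace = data.frame(eliminated_index = setdiff(1:45, idx5),
                                            eliminated_shift = as.numeric(ax)[setdiff(1:45, idx5)],
                                            mse = 0))
  r5 <- restrict_to_channels(cube, sub5)
  expect_equal(dim(r5$data), c(3, 4, 5))
  expect_equal(as.numeric(r5$axis), as.numeric(ax)[idx5])

  expect_error(restrict_to_channels(cube, 46L), "out of range")

  # nested restriction equals one-step restriction with composed indices
  outer_idx <- seq(1, 45, by = 2)              # 23 channels
  inner_idx <- c(2L, 5L, 11L)                  # positions within the outer set
  two_step <- restrict_to_channels(restrict_to_channels(cube, outer_idx),
                                   inner_idx)
  one_step <- restrict_to_channels(cube, outer_idx[inner_idx])
  expect_equal(two_step$data, one_step$data)
  expect_equal(as.numeric(two_step$axis), as.numeric(one_step$axis))
})

test_that("channel restriction does not renormalize library spectra", {
  lib <- make_default_library(default_axis())
  rlib <- restrict_to_channels(lib, c(4L, 13L, 19L, 28L, 41L))
  # sliced rows keep their full-spectrum scale: norms strictly below 1
  nrm <- sqrt(rowSums(rlib$spectra^2))
  expect_true(all(nrm < 1))
  expect_identical(rlib$normalization, lib$normalization)
  expect_equal(rlib$spectra, lib$spectra[, c(4, 13, 19, 28, 41)])
})

test_that("channel_subset checks uniqueness, bounds and trace length", {
  ax <- default_axis()
  expect_error(channel_subset(c(3L, 3L), ax), "unique")
  expect_error(channel_subset(46L, ax), "out of range")
  expect_error(channel_subset(1:44, ax,
                              trace = data.frame(eliminated_index = integer(0),
                                                 eliminated_shift = numeric(0),
                                                 mse = numeric(0))),
               "trace length")
  s <- channel_subset(c(9L, 2L), ax,
                      trace = data.frame(eliminated_index = setdiff(1:45, c(2, 9)),
                                         eliminated_shift = 0, mse = 0))
  expect_identical(s$indices, c(2L, 9L))  # stored sorted ascending
  expect_equal(s$shifts, as.numeric(ax)[c(2, 9)])
})

test_that("ref_library normalizes to unit norm and rejects bad input", {
  ax <- wn_axis(c(2850, 2900, 2950, 3000))
  lib <- ref_library(matrix(c(1, 1, 1, 1), 1), ax, names = "flat")
  expect_equal(as.numeric(lib$spectra), rep(0.5, 4))
  expect_identical(lib$normalization, "unit_l2")
  expect_error(ref_library(matrix(-1, 1, 4), ax), "nonnegative")
  expect_error(ref_library(matrix(1, 2, 4), ax, names = c("a", "a")), "unique")
})

test_that("conc_maps rejects negative abundances", {
  expect_error(conc_maps(array(-0.1, c(2, 2, 1)), "water"), "nonnegative")
})
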