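test_that("balanced sampling returns 2100 pixels in 5 groups of 420", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0.02, seed = 17))
  full <- unmix_cube(ph$cube, ph$library, unmix_params())
  smp <- sample_balanced_pixels(ph$cube, full, sampler_params(seed = 17))
  expect_equal(nrow(smp$coordinates), 2100)
  expect_equal(unname(tabulate(smp$dominant_labels, 5)), rep(420L, 5))
  expect_false(any(duplicated(smp$coordinates)))
  # deterministic under a fixed seed, different under another
  smp2 <- sample_balanced_pixels(ph$cube, full, sampler_params(seed = 17))
  expect_identical(smp$coordinates, smp2$coordinates)
  smp3 <- sample_balanced_pixels(ph$cube, full, sampler_params(seed = 18))
  expect_false(identical(smp$coordinates, smp3$coordinates))
})

test_that("sampling errors name the missing component", {
  no_water <- list(
    list(shape = "background", component = "ecm", level = 1),
    list(shape = "disk", component = "unsaturated_lipid", level = 2,
         center = c(0.25, 0.25), radius = 0.2),
    list(shape = "disk", component = "cellular_protein", level = 2,
         center = c(0.25, 0.75), radius = 0.2),
    list(shape = "disk", component = "saturated_lipid", level = 2,
         center = c(0.75, 0.25), radius = 0.2))
  ph <- generate_phantom(phantom_spec(height = 16, width = 16, noise_sd = 0,
                                      scene = no_water))
  full <- unmix_cube(ph$cube, ph$library, unmix_params())
  expect_error(sample_balanced_pixels(ph$cube, full,
                                      sampler_params(n_total = 50, n_subsets = 5)),
               "water")
  expect_error(sampler_params(n_total = 2101, n_subsets = 5), "divisible")
})

test_that("RFE keeps everything when target_k = M", {
  pl <- planted_rfe_instance()
  smp <- structure(list(spectra = pl$Y,
                        full_abundances = srhmap:::lasso_cd_cpp(
                          pl$lib$spectra, pl$Y, 0.01, TRUE, 2000, 1e-10)),
                   class = "pixel_sample")
  sub <- rfe_select(smp, pl$lib, unmix_params(), target_k = 8)
  expect_equal(sub$indices, 1:8)
  expect_equal(nrow(sub$trace), 0)
  expect_error(rfe_select(smp, pl$lib, unmix_params(), target_k = 0),
               "target_k")
})

test_that("RFE recovers the planted contrast channels and matches exhaustive search", {
  pl <- planted_rfe_instance()
  up <- unmix_params()
  smp <- structure(list(spectra = pl$Y,
                        full_abundances = srhmap:::lasso_cd_cpp(
                          pl$lib$spectra, pl$Y, up$lam, up$nonneg,
                          up$max_iters, up$tol)),
                   class = "pixel_sample")
  sub <- rfe_select(smp, pl$lib, up, target_k = 3)
  ex <- exhaustive_subset_oracle(pl$Y, pl$lib, up, 3)
  expect_equal(sub$indices, sort(ex$subset))
  expect_equal(sub$indices, pl$contrast_channels)
  expect_equal(nrow(sub$trace), 5)
  # determinism: identical rerun
  sub2 <- rfe_select(smp, pl$lib, up, target_k = 3)
  expect_identical(sub$indices, sub2$indices)
  expect_identical(sub$trace, sub2$trace)
})

test_that("subset_at_k reconstructs intermediate stages from the trace", {
  pl <- planted_rfe_instance()
  smp <- structure(list(spectra = pl$Y,
                        full_abundances = srhmap:::lasso_cd_cpp(
                          pl$lib$spectra, pl$Y, 0.01, TRUE, 2000, 1e-10)),
                   class = "pixel_sample")
  sub <- rfe_select(smp, pl$lib, unmix_params(), target_k = 3)
  s8 <- subset_at_k(sub, pl$lib$axis, 8)
  expect_equal(s8$indices, 1:8)
  s5 <- subset_at_k(sub, pl$lib$axis, 5)
  expect_equal(length(s5$indices), 5)
  expect_true(all(sub$indices %in% s5$indices))
  expect_equal(nrow(s5$trace), 3)
})

test_that("a full-channel subset evaluates to SSIM 1 against itself", {
  ph <- generate_phantom(phantom_spec(height = 24, width = 24, noise_sd = 0.02,
                                      seed = 3))
  up <- unmix_params()
  full <- unmix_cube(ph$cube, ph$library, up)
  rep <- evaluate_subset(ph$cube, ph$library, up,
                         channel_subset(1:45, ph$library$axis), full)
  expect_equal(rep$mean_ssim, 1)
  expect_true(all(is.infinite(rep$per_component$psnr_db)))
})

test_that("selecting K channels yields a full-rank restricted library", {
  ph <- generate_phantom(phantom_spec(height = 32, width = 32, noise_sd = 0.02,
                                      seed = 6))
  up <- unmix_params()
  full <- unmix_cube(ph$cube, ph$library, up)
  smp <- sample_balanced_pixels(ph$cube, full,
                                sampler_params(n_total = 250, n_subsets = 5,
                                               seed = 6))
  sub <- rfe_select(smp, ph$library, up, target_k = 5)
  rlib <- restrict_to_channels(ph$library, sub)
  expect_equal(qr(rlib$spectra)$rank, 5)
})

test_that("the acquisition cost model gives the 45 -> 5 speed factor of 9", {
  expect_equal(acquisition_speedup(45, 5), 9)
  expect_equal(acquisition_cost(45, n_pixels = 1e6, dwell_s = 10e-6) /
                 acquisition_cost(5, n_pixels = 1e6, dwell_s = 10e-6), 9)
  expect_equal(acquisition_cost(5, 1000, 10e-6), 0.05)
  expect_error(acquisition_cost(0), "positive")
})
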