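test_that("adjustment factors are curated/mapped quotients with nullsets", {
  cur <- make_profile("cal", "control", c(A = 2.0, B = 1.3, C = 0, D = 1.5),
                      method = "curated")
  map <- make_profile("cal", "control", c(A = 4.0, B = 0, C = 2.0, D = 1.5),
                      method = "mapped")
  fac <- compute_adjustment(cur, map)
  expect_equal(unname(fac$factor["A"]), 0.5)
  expect_equal(unname(fac$factor["D"]), 1.0)
  # zero in either method prevents calibration (symmetric nullset)
  expect_true(all(c("B", "C") %in% fac$undefined))
  expect_true(all(is.na(fac$factor[c("B", "C")])))

  other <- make_profile("other", "control", c(A = 1, B = 1, C = 1, D = 1),
                        method = "mapped")
  expect_error(compute_adjustment(cur, other), "different taxa")
  expect_error(compute_adjustment(map, map), "curated and one mapped")
})

test_that("identical profiles give unit factors", {
  cur <- make_profile("cal", "control", c(A = 2, B = 5), method = "curated")
  map <- make_profile("cal", "control", c(A = 2, B = 5), method = "mapped")
  expect_equal(unname(compute_adjustment(cur, map)$factor), c(1, 1))
})

test_that("adjustment rescales mapped profiles and recomputes the total", {
  fac <- structure(list(calibration_taxon = "cal",
                        factor = c(A = 0.5, B = 2, C = NA_real_),
                        undefined = "C"),
                   class = "adjustment_factors")
  mapped <- make_profile("t", "carnivorous", c(A = 4, B = 1, C = 3),
                         method = "mapped")
  adj <- apply_adjustment(mapped, fac)
  expect_equal(unname(adj$per_mille), c(2, 2, 3))  # C (nullset) passes through
  expect_equal(adj$total_per_mille, 7)
  expect_true(adj$adjusted)
  expect_error(apply_adjustment(adj, fac), "already adjusted")

  zeroed <- apply_adjustment(mapped, fac, zero_undefined = TRUE)
  expect_equal(unname(zeroed$per_mille), c(2, 2, 0))
  expect_equal(zeroed$total_per_mille, 4)

  curated <- make_profile("t", "carnivorous", c(A = 4, B = 1, C = 3),
                          method = "curated")
  adj_cur <- apply_adjustment(curated, fac)
  expect_equal(adj_cur$per_mille, curated$per_mille)
  expect_true(adj_cur$adjusted)
})

test_that("self-calibration reproduces the curated profile exactly", {
  ref <- carnivory_reference()
  cfg <- simulation_config(genes_per_taxon = 20000, baseline_rate = 0.002,
                           method_bias = 0.6, taxon_noise_sd = 0.2, seed = 31)
  dual <- generate_dual_annotated(cfg)
  cur <- to_profile(count_functions(dual$curated, ref), "control")
  map <- to_profile(count_functions(dual$mapped, ref), "control")
  fac <- compute_adjustment(cur, map)
  adj <- apply_adjustment(map, fac)
  defined <- !is.na(fac$factor)
  expect_true(any(defined))
  expect_equal(adj$per_mille[defined], cur$per_mille[defined],
               tolerance = 1e-12)
})

test_that("estimated factors recover the inverse detection bias", {
  ref <- carnivory_reference()
  cfg <- simulation_config(genes_per_taxon = 1e5, assigned_fraction = 1,
                           baseline_rate = 0.01, method_bias = 0.5,
                           taxon_noise_sd = 0.1, seed = 12)
  dual <- generate_dual_annotated(cfg)
  cur <- to_profile(count_functions(dual$curated, ref), "control")
  map <- to_profile(count_functions(dual$mapped, ref), "control")
  fac <- compute_adjustment(cur, map)
  est <- fac$factor[!is.na(fac$factor)]
  expect_gt(length(est), 30)
  # binomial noise at ~1000/500 detected genes per function
  expect_true(all(abs(est - 2) < 0.45))
  expect_lt(abs(mean(est) - 2), 0.05)
})

test_that("forced nullset: zero bias makes a function uncalibratable", {
  ref <- carnivory_reference()
  cfg <- simulation_config(genes_per_taxon = 5000, baseline_rate = 0.01,
                           method_bias = c(AltOx = 0), taxon_noise_sd = 0,
                           seed = 3)
  dual <- generate_dual_annotated(cfg)
  cur <- to_profile(count_functions(dual$curated, ref), "control")
  map <- to_profile(count_functions(dual$mapped, ref), "control")
  expect_equal(unname(map$per_mille["AltOx"]), 0)
  fac <- compute_adjustment(cur, map)
  expect_true("AltOx" %in% fac$undefined)
})

test_that("factor tables round-trip through TSV", {
  fac <- structure(list(calibration_taxon = "cal",
                        factor = c(A = 0.5, B = 2.25, C = NA_real_),
                        undefined = "C"),
                   class = "adjustment_factors")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_adjustment_factors(fac, path)
  back <- read_adjustment_factors(path)
  expect_identical(back$calibration_taxon, "cal")
  expect_equal(back$factor, fac$factor)
  expect_identical(back$undefined, "C")
})
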