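test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(genes_per_taxon = 1500, seed = 19)
  s1 <- generate_taxa(cfg)
  s2 <- generate_taxa(cfg)
  expect_identical(lapply(s1$tables, write_simple),
                   lapply(s2$tables, write_simple))
  expect_identical(s1$truth$rates, s2$truth$rates)
  s3 <- generate_taxa(simulation_config(genes_per_taxon = 1500, seed = 20))
  expect_false(identical(write_simple(s1$tables[[1]]),
                         write_simple(s3$tables[[1]])))
})

test_that("the null configuration has identical class expectations", {
  cfg <- simulation_config()
  e_ctrl <- expected_profile(cfg, "control", "curated")
  e_carn <- expected_profile(cfg, "carnivorous", "curated")
  expect_identical(e_ctrl, e_carn)
  expect_identical(expected_profile(cfg, "control", "mapped"), e_ctrl)
})

test_that("expected profiles scale linearly with enrichment and bias", {
  cfg <- simulation_config(enrichment = c(AltOx = 2),
                           method_bias = c(BGal = 0.5))
  e_ctrl <- expected_profile(cfg, "control", "curated")
  e_carn <- expected_profile(cfg, "carnivorous", "curated")
  expect_equal(unname(e_carn["AltOx"]), 2 * unname(e_ctrl["AltOx"]))
  expect_equal(e_carn[names(e_carn) != "AltOx"],
               e_ctrl[names(e_ctrl) != "AltOx"])
  e_map <- expected_profile(cfg, "control", "mapped")
  expect_equal(unname(e_map["BGal"]), 0.5 * unname(e_ctrl["BGal"]))
})

test_that("realised counts sit within binomial bounds of the expectation", {
  ref <- carnivory_reference()
  n <- 10000L
  cfg <- simulation_config(genes_per_taxon = n, assigned_fraction = 1,
                           baseline_rate = 0.002, taxon_noise_sd = 0,
                           n_control = 2, n_carnivorous = 2,
                           calibration_taxon_included = FALSE, seed = 47)
  sim <- generate_taxa(cfg)
  fc <- count_functions(sim$tables[["ctrl_01"]], ref)
  expect_identical(fc$n_assigned, n)
  expected <- n * 0.002
  bound <- 4 * sqrt(n * 0.002 * 0.998)
  expect_true(all(abs(fc$counts - expected) < bound))
  p <- to_profile(fc, "control")
  expect_true(all(abs(p$per_mille - 2) < 1000 * bound / n))
})

test_that("Monte-Carlo per-mille means match the closed-form oracle", {
  ref <- carnivory_reference()
  reps <- 60
  rate <- 0.004
  n <- 2000
  vals <- matrix(NA_real_, reps, length(ref))
  for (r in seq_len(reps)) {
    cfg <- simulation_config(genes_per_taxon = n, assigned_fraction = 1,
                             baseline_rate = rate, taxon_noise_sd = 0,
                             n_control = 1, n_carnivorous = 1,
                             calibration_taxon_included = FALSE,
                             seed = 5000 + r)
    sim <- generate_taxa(cfg)
    vals[r, ] <- to_profile(count_functions(sim$tables[["ctrl_01"]], ref),
                            "control")$per_mille
  }
  expected <- expected_profile(cfg, "control", "curated")
  se <- 1000 * sqrt(rate * (1 - rate) / n) / sqrt(reps)
  expect_true(all(abs(colMeans(vals) - expected) < 3.5 * se))
})

test_that("dual annotation with unit bias matches in expectation", {
  ref <- carnivory_reference()
  cfg <- simulation_config(genes_per_taxon = 30000, assigned_fraction = 1,
                           baseline_rate = 0.005, method_bias = 1,
                           taxon_noise_sd = 0, seed = 61)
  dual <- generate_dual_annotated(cfg)
  cur <- to_profile(count_functions(dual$curated, ref), "control")
  map <- to_profile(count_functions(dual$mapped, ref), "control")
  # identical latent gene set, no thinning: the views coincide
  expect_equal(map$per_mille, cur$per_mille)
})

test_that("enriched functions are flagged and nulls are not, end to end", {
  ref <- carnivory_reference()
  hot <- c("AltOx", "Phoslip", "NHTrans")
  cfg <- simulation_config(genes_per_taxon = 20000, baseline_rate = 0.002,
                           enrichment = structure(rep(3, 3), names = hot),
                           taxon_noise_sd = 0.1, method_bias = 0.7,
                           seed = 83)
  sim <- generate_taxa(cfg)
  profs <- lapply(sim$manifest$taxon_id, function(id) {
    to_profile(count_functions(sim$tables[[id]], ref),
               sim$manifest$class[sim$manifest$taxon_id == id])
  })
  a1 <- suppressWarnings(run_analysis_1(profs))
  hits <- a1$fn[a1$q < 0.05]
  expect_true(all(hot %in% hits))
  null_fns <- setdiff(a1$fn, c(hot, "Total"))
  expect_gt(mean(a1$q[a1$fn %in% null_fns] > 0.05), 0.9)
})
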