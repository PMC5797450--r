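test_that("group t-test is upper-tailed with location/scale invariance", {
  same <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 0.5)

  below <- group_ttest(c(1, 2, 3), c(4, 5, 7))
  expect_lt(below$statistic, 0)
  expect_gt(below$p, 0.5)

  set.seed(8)
  carn <- rnorm(4, 1); ctrl <- rnorm(6)
  base <- group_ttest(carn, ctrl)
  shifted <- group_ttest(carn + 7, ctrl + 7)
  scaled <- group_ttest(carn * 3.5, ctrl * 3.5)
  expect_equal(shifted$p, base$p, tolerance = 1e-12)
  expect_equal(scaled$p, base$p, tolerance = 1e-12)
  # Welch vs pooled differ with unequal spreads
  expect_false(isTRUE(all.equal(
    group_ttest(carn, ctrl * 4)$p,
    group_ttest(carn, ctrl * 4, var_equal = TRUE)$p)))
  expect_error(group_ttest(1, c(1, 2)), "at least two")
})

test_that("reference distributions use the control median and sample SD", {
  d <- build_reference_distribution(c(1, 2, 3))
  expect_equal(d$location, 2)
  expect_equal(d$scale, 1)
  d2 <- build_reference_distribution(c(0, 0, 0, 4))
  expect_equal(d2$location, 0)
  expect_equal(d2$scale, 2)
  set.seed(21)
  for (i in 1:10) {
    v <- rnorm(6)
    d <- build_reference_distribution(v)
    expect_equal(d$location, median(v))
    expect_equal(d$scale, sd(v))
  }
  expect_error(build_reference_distribution(c(2, 2, 2)), "all equal")
  expect_error(build_reference_distribution(1), "at least two")
})

test_that("Z-tests report standard-normal upper tails", {
  d <- build_reference_distribution(c(1, 2, 3), fn = "f")
  at_loc <- ztest(2, d)
  expect_equal(at_loc$statistic, 0)
  expect_equal(at_loc$p, 0.5)
  z <- ztest(2 + 2.76, d)
  expect_equal(z$statistic, 2.76)
  expect_equal(z$p, 2.89e-3, tolerance = 1e-3)
  # p strictly decreasing in the tested value
  vals <- seq(0, 5, by = 0.5)
  ps <- vapply(vals, function(v) ztest(v, d)$p, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("with pi0 fixed at 1 Storey q-values equal Benjamini-Hochberg", {
  set.seed(33)
  for (i in 1:50) {
    m <- sample(2:80, 1)
    p <- runif(m)^sample(c(1, 2, 0.5), 1)
    p <- pmax(p, 1e-12)
    q <- storey_qvalues(p, pi0_method = "fixed", pi0 = 1)
    expect_equal(as.numeric(q), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  expect_equal(as.numeric(storey_qvalues(0.03, pi0_method = "fixed")), 0.03)
})

test_that("q-values are monotone in p and lie in (0, 1]", {
  set.seed(34)
  for (method in c("bootstrap", "smoother", "fixed")) {
    p <- runif(40)^2 + 1e-9
    q <- suppressWarnings(storey_qvalues(p, pi0_method = method))
    expect_true(all(q > 0 & q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("small families fall back to pi0 = 1 and wild estimates clamp", {
  p <- c(0.01, 0.2, 0.9, 0.04, 0.5)
  expect_equal(as.numeric(storey_qvalues(p, pi0_method = "bootstrap")),
               p.adjust(p, method = "BH"))
  # p mass piled near 1 pushes the raw estimate above 1
  high <- rep(c(0.96, 0.97, 0.98), each = 5)
  expect_warning(q <- storey_qvalues(high, pi0_method = "bootstrap"),
                 "clamped")
  expect_true(all(q <= 1))
})

test_that("tied p-values share their maximum rank", {
  p <- c(0.01, 0.01, 0.5)
  q <- storey_qvalues(p, pi0_method = "fixed", pi0 = 1)
  expect_equal(as.numeric(q), c(0.015, 0.015, 0.5))
})

test_that("significance codes bin q strictly, boundaries less significant", {
  expect_identical(significance_level(c(0.5, 0.047, 0.05, 0.10, 0.099,
                                        0.009, 0.0009, 0.00009)),
                   c("NS", "*", ".", "NS", ".", "**", "***", "****"))
})

test_that("change summaries count level moves and big jumps", {
  a <- data.frame(comparison = c("g", "g", "t1"), fn = c("A", "B", "A"),
                  level = c("NS", "*", "."), stringsAsFactors = FALSE)
  b <- a
  same <- compare_significance(a, b)
  expect_equal(same$n_no_change, 3)
  expect_equal(same$n_increase + same$n_decrease + same$n_change_gt1, 0)

  b$level <- c("**", "NS", ".")
  ch <- compare_significance(a, b)
  expect_equal(ch$n_increase, 1)
  expect_equal(ch$n_decrease, 1)
  expect_equal(ch$n_no_change, 1)
  expect_equal(ch$n_change_gt1, 2)  # NS->** (+2) and *->NS (-2)

  expect_error(compare_significance(a, b[-1, ]), "not paired")
})

test_that("detectable effect sizes follow the normal-approximation formula", {
  expect_equal(round(power_effect_size(6, 4, 0.05, beta = 0.50), 2), 1.06)
  expect_equal(round(power_effect_size(6, 4, 0.05, beta = 0.05), 2), 2.12)
  expect_equal(power_effect_size(3, 3, 0.5, beta = 0.5), 0)
})

test_that("analyses emit one corrected family per design unit", {
  ref <- carnivory_reference()
  cfg <- simulation_config(genes_per_taxon = 4000, seed = 77)
  sim <- generate_taxa(cfg)
  profs <- lapply(sim$manifest$taxon_id, function(id) {
    to_profile(count_functions(sim$tables[[id]], ref),
               sim$manifest$class[sim$manifest$taxon_id == id])
  })
  fns <- tested_functions(profs)
  a1 <- run_analysis_1(profs, functions = fns)
  expect_identical(nrow(a1), length(fns) + 1L)
  expect_identical(a1$fn[nrow(a1)], "Total")
  expect_true(all(a1$level %in% c("NS", ".", "*", "**", "***", "****")))

  a2 <- run_analysis_2(profs, functions = fns)
  expect_identical(length(a2), 4L)
  expect_identical(unname(vapply(a2, nrow, 0L)),
                   rep(length(fns) + 1L, 4))
  expect_identical(sum(vapply(a2, nrow, 0L)), 4L * (length(fns) + 1L))

  ctrl_only <- profs[sim$manifest$class == "control"]
  expect_error(run_analysis_1(ctrl_only), "two taxa per class")
})

test_that("null synthetic data rejects at roughly the nominal rate", {
  ref <- carnivory_reference()
  cfg <- simulation_config(genes_per_taxon = 4000, seed = 55)
  sim <- generate_taxa(cfg)
  profs <- lapply(sim$manifest$taxon_id, function(id) {
    to_profile(count_functions(sim$tables[[id]], ref),
               sim$manifest$class[sim$manifest$taxon_id == id])
  })
  a1 <- run_analysis_1(profs)
  # no enrichment: raw p roughly uniform, very small p should be rare
  expect_lt(mean(a1$p < 0.05), 0.25)
  expect_gt(mean(a1$p > 0.1), 0.4)
})

test_that("tested-function exclusion drops nullsets and undetected entries", {
  profs <- list(make_profile("c1", "control", c(A = 1, B = 0, C = 2, D = 0)),
                make_profile("c2", "control", c(A = 1, B = 0, C = 0, D = 0)))
  fac <- structure(list(calibration_taxon = "c1",
                        factor = c(A = 1, B = 1, C = NA_real_, D = 1),
                        undefined = "C"),
                   class = "adjustment_factors")
  expect_identical(tested_functions(profs), c("A", "C"))
  expect_identical(tested_functions(profs, fac), "A")
  rep <- exclusion_report(profs, fac)
  expect_identical(rep$tested, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(rep$reason[rep$abbreviation == "C"], "nullset")
  expect_match(rep$reason[rep$abbreviation == "B"], "not detected")
})
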