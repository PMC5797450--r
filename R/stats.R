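SIG_LEVELS <- c("NS", ".", "*", "**", "***", "****")

test_result <- function(comparison, fn, kind, statistic, p) {
  data.frame(comparison = comparison, fn = fn, statistic_kind = kind,
             statistic = statistic, p = p, q = NA_real_,
             level = NA_character_, stringsAsFactors = FALSE)
}

#' Upper-tailed two-sample t-test of group overrepresentation
#'
#' Tests whether the study group's values exceed the controls'. The default
#' is the unequal-variance (Welch) form with Welch-Satterthwaite degrees of
#' freedom; a pooled-variance Student form is available via `var_equal`.
#'
#' @param carn_values numeric values for the study (carnivorous) taxa.
#' @param ctrl_values numeric values for the control taxa.
#' @param fn function label carried into the result row.
#' @param var_equal use the pooled-variance Student t-test.
#' @return a one-row test-result data frame (statistic, upper-tail p).
#' @export
group_ttest <- function(carn_values, ctrl_values, fn = NA_character_,
                        var_equal = FALSE) {
  if (length(carn_values) < 2L || length(ctrl_values) < 2L) {
    stop("group_ttest() needs at least two values per group", call. = FALSE)
  }
  ht <- stats::t.test(carn_values, ctrl_values, alternative = "greater",
                      var.equal = var_equal)
  test_result("group", fn, "t", unname(ht$statistic), unname(ht$p.value))
}

#' Build a control-derived reference distribution
#'
#' A normal reference for single-taxon testing, located at the median of the
#' control values with scale equal to their sample (n-1) standard deviation.
#'
#' @param ctrl_values at least two control values, not all equal.
#' @param fn function label carried along.
#' @return an object of class `reference_distribution` with fields
#'   `location`, `scale`, `n`, `fn`.
#' @export
build_reference_distribution <- function(ctrl_values, fn = NA_character_) {
  if (length(ctrl_values) < 2L) {
    stop("reference distribution needs at least two control values",
         call. = FALSE)
  }
  s <- stats::sd(ctrl_values)
  if (!is.finite(s) || s <= 0) {
    stop("control values are all equal: reference scale would be zero",
         call. = FALSE)
  }
  structure(list(fn = fn, location = stats::median(ctrl_values), scale = s,
                 n = length(ctrl_values)),
            class = "reference_distribution")
}

#' Upper-tailed Z-test of one value against a reference distribution
#'
#' @param value the study taxon's value.
#' @param dist a `reference_distribution`.
#' @param comparison comparison label (normally the taxon id).
#' @return a one-row test-result data frame with
#'   `Z = (value - location) / scale` and the standard-normal upper-tail p.
#' @export
ztest <- function(value, dist, comparison = "taxon") {
  stopifnot(inherits(dist, "reference_distribution"))
  z <- (value - dist$location) / dist$scale
  test_result(comparison, dist$fn, "Z", z, stats::pnorm(z, lower.tail = FALSE))
}

#' Estimate the proportion of true null hypotheses
#'
#' Storey's pi0, estimated from the p-value distribution over a lambda grid.
#' `"bootstrap"` (the default) picks the grid point minimising the
#' closed-form bootstrap mean-squared-error estimate of Storey, Taylor &
#' Siegmund; `"smoother"` fits a df-3 smoothing spline to pi0(lambda) and
#' evaluates it at the largest lambda. Estimates outside (0, 1] are clamped
#' to 1 with a warning.
#'
#' @param p p-values in (0, 1].
#' @param lambda strictly increasing grid in \[0, 1).
#' @param method `"bootstrap"` or `"smoother"`.
#' @return the pi0 estimate, with the per-lambda raw estimates as attribute
#'   `"pi0_lambda"`.
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                       method = c("bootstrap", "smoother")) {
  method <- match.arg(method)
  stopifnot(length(p) > 0L, all(p > 0 & p <= 1),
            all(lambda >= 0 & lambda < 1), !is.unsorted(lambda, strictly = TRUE))
  m <- length(p)
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  pi0 <- if (method == "smoother") {
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    stats::predict(fit, x = max(lambda))$y
  } else {
    min_pi0 <- stats::quantile(pi0_lambda, 0.1, names = FALSE)
    W <- vapply(lambda, function(l) sum(p >= l), 0L)
    mse <- (W / (m^2 * (1 - lambda)^2)) * (1 - W / m) +
      (pi0_lambda - min_pi0)^2
    pi0_lambda[which.min(mse)]
  }
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) {
    warning(warningCondition(
      sprintf("pi0 estimate %.3g outside (0,1]; clamped to 1", pi0),
      class = "goconverge_pi0_clamp"))
    pi0 <- 1
  }
  attr(pi0, "pi0_lambda") <- pi0_lambda
  pi0
}

#' Storey q-values
#'
#' Converts a family of p-values to q-values: `q_i` is the minimum over
#' `p_j >= p_i` of `pi0 * m * p_j / rank(p_j)`, with tied p-values sharing
#' their maximum rank so that q is monotone in p. With `pi0_method =
#' "fixed"` and `pi0 = 1` this reduces to the Benjamini-Hochberg adjustment.
#' Families smaller than `min_m` fall back to `pi0 = 1`, since pi0 cannot be
#' estimated stably from a handful of p-values.
#'
#' @param p p-values in (0, 1].
#' @param pi0_method `"bootstrap"` (default), `"smoother"`, or `"fixed"`.
#' @param pi0 the value used when `pi0_method = "fixed"`.
#' @param lambda grid passed to [storey_pi0()].
#' @param min_m smallest family size for which pi0 is estimated.
#' @return numeric vector of q-values in the order of `p`, with the pi0 used
#'   as attribute `"pi0"`.
#' @export
storey_qvalues <- function(p, pi0_method = c("bootstrap", "smoother", "fixed"),
                           pi0 = 1, lambda = seq(0.05, 0.95, by = 0.05),
                           min_m = 10L) {
  pi0_method <- match.arg(pi0_method)
  if (length(p) == 0L) stop("empty p-value list", call. = FALSE)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  use_pi0 <- if (pi0_method == "fixed") {
    stopifnot(pi0 > 0, pi0 <= 1)
    pi0
  } else if (m < min_m) {
    1
  } else {
    as.numeric(storey_pi0(p, lambda = lambda, method = pi0_method))
  }
  o <- order(p)
  qo <- use_pi0 * m * p[o] / seq_len(m)
  qo <- rev(cummin(rev(qo)))
  q <- numeric(m)
  q[o] <- qo
  q <- pmin(q, 1)
  attr(q, "pi0") <- use_pi0
  q
}

#' Six-level significance coding of q-values
#'
#' Bins: `NS` (q > 0.10), `.` (q < 0.10), `*` (q < 0.05), `**` (q < 0.01),
#' `***` (q < 0.001), `****` (q < 0.0001). Inequalities are strict, so a q
#' sitting exactly on a threshold falls in the less significant bin.
#'
#' @param q numeric vector of q-values in (0, 1].
#' @return character vector of level codes.
#' @export
significance_level <- function(q) {
  stopifnot(all(q > 0 & q <= 1))
  breaks <- c(0.0001, 0.001, 0.01, 0.05, 0.10)
  idx <- vapply(q, function(x) sum(x < breaks), 0L)  # 0 = NS ... 5 = ****
  SIG_LEVELS[idx + 1L]
}

level_index <- function(level) {
  i <- match(level, SIG_LEVELS)
  if (anyNA(i)) stop("unknown significance level", call. = FALSE)
  i
}

#' Compare significance levels between two paired result sets
#'
#' Pairs results by comparison and function and counts changes in the
#' six-level significance coding from `results_a` (baseline, e.g. raw data)
#' to `results_b` (e.g. calibrated data).
#'
#' @param results_a,results_b test-result data frames with `q` and `level`
#'   filled in; every (comparison, fn) pair must appear in both.
#' @return an object of class `change_summary`: overall counts
#'   (`n_no_change`, `n_increase`, `n_decrease`, `n_change_gt1`), a
#'   `by_comparison` data frame, and the paired per-test table.
#' @export
compare_significance <- function(results_a, results_b) {
  key_a <- paste(results_a$comparison, results_a$fn, sep = "\r")
  key_b <- paste(results_b$comparison, results_b$fn, sep = "\r")
  if (anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stop("duplicate (comparison, function) rows", call. = FALSE)
  }
  if (!setequal(key_a, key_b)) {
    stop("result sets are not paired: (comparison, function) keys differ",
         call. = FALSE)
  }
  j <- match(key_a, key_b)
  delta <- level_index(results_b$level[j]) - level_index(results_a$level)
  pairs <- data.frame(comparison = results_a$comparison, fn = results_a$fn,
                      level_a = results_a$level,
                      level_b = results_b$level[j],
                      delta = delta, stringsAsFactors = FALSE)
  count <- function(d) c(n_no_change = sum(d == 0), n_increase = sum(d > 0),
                         n_decrease = sum(d < 0), n_change_gt1 = sum(abs(d) > 1))
  by_cmp <- do.call(rbind, lapply(split(pairs$delta, pairs$comparison),
                                  function(d) as.data.frame(as.list(count(d)))))
  by_cmp <- cbind(comparison = rownames(by_cmp), by_cmp,
                  stringsAsFactors = FALSE)
  rownames(by_cmp) <- NULL
  structure(c(as.list(count(pairs$delta)),
              list(by_comparison = by_cmp, pairs = pairs)),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  n <- x$n_no_change + x$n_increase + x$n_decrease
  cat(sprintf(paste0("change_summary over %d paired tests: %d unchanged, ",
                     "%d increased, %d decreased, %d changed by >1 level\n"),
              n, x$n_no_change, x$n_increase, x$n_decrease, x$n_change_gt1))
  invisible(x)
}

#' Detectable effect size of the two-group design
#'
#' Normal-approximation (known-variance) solution for the mean shift, in
#' control standard-deviation units, at which a one-sided two-sample
#' comparison of `n1` vs `n2` attains power `1 - beta` at level `alpha`:
#' `d = (z_{1-alpha} + z_{1-beta}) * sqrt(1/n1 + 1/n2)`.
#'
#' @param n1,n2 group sizes.
#' @param alpha one-sided test level.
#' @param beta type-II error rate (power is `1 - beta`).
#' @return the effect size `d` in standard-deviation units.
#' @examples
#' power_effect_size(6, 4, alpha = 0.05, beta = 0.50)
#' @export
power_effect_size <- function(n1, n2, alpha = 0.05, beta) {
  stopifnot(n1 >= 1, n2 >= 1, alpha > 0, alpha < 1, beta > 0, beta < 1)
  (stats::qnorm(1 - alpha) + stats::qnorm(1 - beta)) * sqrt(1 / n1 + 1 / n2)
}

#' Which reference functions enter testing
#'
#' A function is tested when it was detected (nonzero genes-per-thousand) in
#' at least one taxon and, when adjustment factors are supplied, its factor
#' is defined (not a nullset entry). The remaining entries are excluded and
#' reported by [exclusion_report()].
#'
#' @param profiles list of `representation_profile` objects.
#' @param factors optional `adjustment_factors`.
#' @return character vector of tested abbreviations, in reference order.
#' @export
tested_functions <- function(profiles, factors = NULL) {
  stopifnot(length(profiles) > 0L)
  abbrs <- names(profiles[[1L]]$per_mille)
  mat <- vapply(profiles, function(p) p$per_mille[abbrs], numeric(length(abbrs)))
  keep <- apply(matrix(mat, nrow = length(abbrs)), 1L, function(v) any(v > 0))
  if (!is.null(factors)) keep <- keep & !is.na(factors$factor[abbrs])
  abbrs[keep]
}

#' @rdname tested_functions
#' @export
exclusion_report <- function(profiles, factors = NULL) {
  abbrs <- names(profiles[[1L]]$per_mille)
  tested <- tested_functions(profiles, factors)
  mat <- vapply(profiles, function(p) p$per_mille[abbrs], numeric(length(abbrs)))
  detected <- apply(matrix(mat, nrow = length(abbrs)), 1L, function(v) any(v > 0))
  reason <- rep("", length(abbrs))
  reason[!detected] <- "not detected in any taxon"
  if (!is.null(factors)) {
    nullset <- is.na(factors$factor[abbrs])
    reason[nullset & detected] <- "nullset: adjustment factor undefined"
    reason[nullset & !detected] <- "not detected; adjustment factor undefined"
  }
  data.frame(abbreviation = abbrs, tested = abbrs %in% tested,
             reason = reason, stringsAsFactors = FALSE)
}

profile_matrix <- function(profiles, fns) {
  vals <- vapply(profiles, function(p) c(p$per_mille[fns], Total = p$total_per_mille),
                 numeric(length(fns) + 1L))
  matrix(vals, nrow = length(fns) + 1L,
         dimnames = list(c(fns, "Total"),
                         vapply(profiles, `[[`, "", "taxon_id")))
}

split_classes <- function(profiles) {
  cls <- vapply(profiles, `[[`, "", "class_label")
  carn <- profiles[cls == "carnivorous"]
  ctrl <- profiles[cls == "control"]
  if (length(carn) < 2L || length(ctrl) < 2L) {
    stop(sprintf(
      "need at least two taxa per class for testing (got %d carnivorous, %d control)",
      length(carn), length(ctrl)), call. = FALSE)
  }
  list(carnivorous = carn, control = ctrl)
}

#' Group-level analysis: carnivorous vs control taxa
#'
#' Runs one upper-tailed t-test per tested function plus the syndrome total
#' (one family of tests), then applies Storey correction across the family
#' and codes significance levels.
#'
#' @param profiles list of `representation_profile` objects of both classes.
#' @param functions abbreviations to test; defaults to
#'   [tested_functions()] of the profiles (with `factors` if given).
#' @param factors optional `adjustment_factors` used for the exclusion rule.
#' @param var_equal use the pooled-variance t-test.
#' @param pi0_method,min_m passed to [storey_qvalues()].
#' @return a test-result data frame with one row per function plus `Total`,
#'   with `q`, `level`, and attribute `"pi0"`.
#' @export
run_analysis_1 <- function(profiles, functions = NULL, factors = NULL,
                           var_equal = FALSE,
                           pi0_method = c("bootstrap", "smoother", "fixed"),
                           min_m = 10L) {
  pi0_method <- match.arg(pi0_method)
  groups <- split_classes(profiles)
  fns <- if (is.null(functions)) tested_functions(profiles, factors) else functions
  carn <- profile_matrix(groups$carnivorous, fns)
  ctrl <- profile_matrix(groups$control, fns)
  res <- do.call(rbind, lapply(rownames(carn), function(fn) {
    group_ttest(carn[fn, ], ctrl[fn, ], fn = fn, var_equal = var_equal)
  }))
  q <- storey_qvalues(res$p, pi0_method = pi0_method, min_m = min_m)
  res$q <- as.numeric(q)
  res$level <- significance_level(res$q)
  attr(res, "pi0") <- attr(q, "pi0")
  res
}

#' Taxon-level analysis: each carnivorous taxon against the control range
#'
#' For every carnivorous taxon, Z-tests each tested function plus the
#' syndrome total against a reference distribution built from the control
#' taxa (location = median, scale = sample SD), with Storey correction
#' applied separately within each taxon's family of tests.
#'
#' @inheritParams run_analysis_1
#' @return a named list (one element per carnivorous taxon) of test-result
#'   data frames, each with attribute `"pi0"`.
#' @export
run_analysis_2 <- function(profiles, functions = NULL, factors = NULL,
                           pi0_method = c("bootstrap", "smoother", "fixed"),
                           min_m = 10L) {
  pi0_method <- match.arg(pi0_method)
  groups <- split_classes(profiles)
  fns <- if (is.null(functions)) tested_functions(profiles, factors) else functions
  ctrl <- profile_matrix(groups$control, fns)
  dists <- lapply(rownames(ctrl), function(fn) {
    build_reference_distribution(ctrl[fn, ], fn = fn)
  })
  names(dists) <- rownames(ctrl)
  out <- lapply(groups$carnivorous, function(p) {
    vals <- c(p$per_mille[fns], Total = p$total_per_mille)
    res <- do.call(rbind, lapply(names(dists), function(fn) {
      ztest(vals[[fn]], dists[[fn]], comparison = p$taxon_id)
    }))
    q <- storey_qvalues(res$p, pi0_method = pi0_method, min_m = min_m)
    res$q <- as.numeric(q)
    res$level <- significance_level(res$q)
    attr(res, "pi0") <- attr(q, "pi0")
    res
  })
  names(out) <- vapply(groups$carnivorous, `[[`, "", "taxon_id")
  out
}

#' Round a test-result table the way report tables print it
#'
#' Statistics to two decimals, p and q to three significant figures.
#'
#' @param results a test-result data frame.
#' @return a data frame of formatted strings.
#' @export
format_test_table <- function(results) {
  data.frame(comparison = results$comparison, fn = results$fn,
             statistic = sprintf("%.2f", results$statistic),
             p = signif(results$p, 3), q = signif(results$q, 3),
             level = results$level, stringsAsFactors = FALSE)
}
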