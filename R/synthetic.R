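#' Configure the synthetic annotated-genome generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' per-taxon gene sets in which a fraction of genes receive GO codes at all,
#' assigned genes carry each reference function's code with a small
#' per-function rate, carnivorous taxa multiply those rates by per-function
#' enrichment factors, rates jitter between taxa on the log scale, and the
#' mapped annotation method distorts detection by per-function bias
#' multipliers. Filler (non-reference) codes from a synthetic pool make
#' unique-GO summaries non-trivial.
#'
#' Defaults mirror the motivating study design: 6 control and 4 carnivorous
#' taxa, a calibration taxon annotated by both methods, and baseline rates
#' sized so that the syndrome total sits in the few-percent range observed
#' in real plant genomes.
#'
#' @param reference a `go_refset`; rates, enrichment and bias are per entry.
#' @param n_control,n_carnivorous taxa per class.
#' @param genes_per_taxon genes per taxon (scalar or vector, recycled).
#' @param assigned_fraction probability a gene receives at least one GO code.
#' @param baseline_rate per-assigned-gene probability of carrying a code of
#'   each entry; scalar or named vector over abbreviations.
#' @param enrichment multiplier applied to rates in carnivorous taxa; scalar
#'   or named vector; 1 = null model.
#' @param taxon_noise_sd SD of the lognormal between-taxon rate jitter
#'   (log scale); 0 disables jitter.
#' @param method_bias detection multiplier of the mapped method; scalar or
#'   named vector; 1 = unbiased.
#' @param calibration_taxon_included give the first control taxon a second,
#'   mapped-method annotation table for calibration.
#' @param mean_filler_codes mean number of filler codes per assigned gene
#'   (at least 1, so assigned genes are guaranteed a code).
#' @param n_filler_pool size of the synthetic non-reference code pool.
#' @param seed integer seed; all generation is deterministic given it.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(reference = carnivory_reference(),
                              n_control = 6L, n_carnivorous = 4L,
                              genes_per_taxon = 30000L,
                              assigned_fraction = 0.5,
                              baseline_rate = 0.001,
                              enrichment = 1,
                              taxon_noise_sd = 0.25,
                              method_bias = 1,
                              calibration_taxon_included = TRUE,
                              mean_filler_codes = 2,
                              n_filler_pool = 3000L,
                              seed = 1L) {
  stopifnot(inherits(reference, "go_refset"), length(reference) > 0L,
            n_control >= 1L, n_carnivorous >= 1L,
            all(genes_per_taxon >= 1L),
            assigned_fraction >= 0, assigned_fraction <= 1,
            taxon_noise_sd >= 0, mean_filler_codes >= 1,
            n_filler_pool >= 1L, abs(seed) < 2^31)
  abbrs <- ref_abbreviations(reference)
  expand <- function(x, what, lower = 0) {
    if (is.null(names(x))) {
      stopifnot(length(x) == 1L)
      x <- structure(rep(as.numeric(x), length(abbrs)), names = abbrs)
    } else {
      full <- structure(rep(1, length(abbrs)), names = abbrs)
      if (!all(names(x) %in% abbrs)) {
        stop(sprintf("unknown function name(s) in %s", what), call. = FALSE)
      }
      full[names(x)] <- as.numeric(x)
      x <- full
    }
    if (any(x < lower)) stop(sprintf("%s must be >= %g", what, lower),
                             call. = FALSE)
    x
  }
  baseline_rate <- expand(baseline_rate, "baseline_rate")
  if (any(baseline_rate > 1)) stop("baseline_rate must be <= 1", call. = FALSE)
  structure(list(reference = reference,
                 n_control = as.integer(n_control),
                 n_carnivorous = as.integer(n_carnivorous),
                 genes_per_taxon = as.integer(genes_per_taxon),
                 assigned_fraction = assigned_fraction,
                 baseline_rate = baseline_rate,
                 enrichment = expand(enrichment, "enrichment"),
                 taxon_noise_sd = taxon_noise_sd,
                 method_bias = expand(method_bias, "method_bias"),
                 calibration_taxon_included = isTRUE(calibration_taxon_included),
                 mean_filler_codes = mean_filler_codes,
                 n_filler_pool = as.integer(n_filler_pool),
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_taxon_ids <- function(cfg) {
  c(sprintf("ctrl_%02d", seq_len(cfg$n_control)),
    sprintf("carn_%02d", seq_len(cfg$n_carnivorous)))
}

sim_filler_pool <- function(cfg) sprintf("GO:8%06d", seq_len(cfg$n_filler_pool))

# Latent per-gene truth for one taxon: which genes are assigned, which carry
# each reference function (at `rates`, before any detection bias), the alias
# code chosen for each carried function, and the filler codes.
sim_latent <- function(cfg, n) {
  abbrs <- ref_abbreviations(cfg$reference)
  assigned <- stats::runif(n) < cfg$assigned_fraction
  n_assigned <- sum(assigned)
  carriers <- vector("list", length(abbrs))
  names(carriers) <- abbrs
  filler <- vector("list", n)
  if (n_assigned > 0L) {
    pool <- sim_filler_pool(cfg)
    k <- 1L + stats::rpois(n_assigned, cfg$mean_filler_codes - 1)
    drawn <- sample(pool, sum(k), replace = TRUE)
    filler[assigned] <- split(drawn, rep.int(seq_len(n_assigned), k))
  }
  list(gene_id = sprintf("g%06d", seq_len(n)), assigned = assigned,
       carriers = carriers, filler = filler)
}

# Fill latent carriers at the given per-function rates (assigned genes only).
sim_carriers <- function(latent, cfg, rates) {
  idx_assigned <- which(latent$assigned)
  for (f in names(latent$carriers)) {
    r <- min(1, rates[[f]])
    hit <- idx_assigned[stats::runif(length(idx_assigned)) < r]
    codes_f <- cfg$reference$codes[[f]]
    latent$carriers[[f]] <- list(
      gene = hit,
      code = if (length(codes_f) == 1L) rep(codes_f, length(hit))
             else sample(codes_f, length(hit), replace = TRUE))
  }
  latent
}

# Materialise an annotation_table from a latent taxon, optionally keeping
# each carried function with probability keep[f] (detection thinning).
sim_materialize <- function(latent, cfg, taxon_id, method, keep = NULL) {
  n <- length(latent$gene_id)
  gene <- integer(0)
  code <- character(0)
  for (f in names(latent$carriers)) {
    cr <- latent$carriers[[f]]
    sel <- seq_along(cr$gene)
    if (length(sel) && !is.null(keep) && is.finite(keep[[f]]) && keep[[f]] < 1) {
      sel <- sel[stats::runif(length(sel)) < keep[[f]]]
    }
    gene <- c(gene, cr$gene[sel])
    code <- c(code, cr$code[sel])
  }
  codes <- latent$filler
  codes[vapply(codes, is.null, TRUE)] <- list(character(0))
  if (length(gene)) {
    extra <- split(code, gene)
    at <- as.integer(names(extra))
    codes[at] <- Map(c, codes[at], extra)
  }
  annotation_table(taxon_id, method, latent$gene_id, codes,
                   n_total_predicted = n)
}

#' Generate a full synthetic study: annotation tables plus ground truth
#'
#' Draws every taxon's annotated gene set under the configuration. Each
#' taxon's per-function rate is `baseline * enrichment` (carnivorous taxa
#' only) `* lognormal jitter`; mapped-method taxa detect each carried
#' function with probability scaled by `method_bias`. When the calibration
#' taxon is included, the first control taxon receives both a curated and a
#' mapped table built from the same underlying gene set. Output is
#' deterministic given `cfg$seed` (each taxon draws from its own sub-seed).
#'
#' @param cfg a `sim_config`.
#' @return a list: `tables` (named list of `annotation_table`s; the
#'   calibration taxon's mapped twin is named `"<taxon>.mapped"`),
#'   `manifest` (a [taxon_manifest()]-shaped data frame), and `truth`
#'   (realised biological rates, detection rates, enrichment, bias, seed).
#' @export
generate_taxa <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_taxon_ids(cfg)
  classes <- rep(c("control", "carnivorous"), c(cfg$n_control, cfg$n_carnivorous))
  methods <- ifelse(classes == "control", "curated", "mapped")
  sizes <- rep_len(cfg$genes_per_taxon, length(ids))
  abbrs <- ref_abbreviations(cfg$reference)
  tables <- list()
  rates_mat <- matrix(NA_real_, length(ids), length(abbrs),
                      dimnames = list(ids, abbrs))
  detect_mat <- rates_mat
  for (i in seq_along(ids)) {
    set.seed(cfg$seed + i)
    jitter <- if (cfg$taxon_noise_sd > 0) {
      exp(stats::rnorm(length(abbrs), 0, cfg$taxon_noise_sd))
    } else rep(1, length(abbrs))
    rates <- cfg$baseline_rate * jitter
    if (classes[i] == "carnivorous") rates <- rates * cfg$enrichment
    rates <- pmin(rates, 1)
    names(rates) <- abbrs
    is_calib <- cfg$calibration_taxon_included && i == 1L
    bias <- if (methods[i] == "mapped" || is_calib) cfg$method_bias else NULL
    # latent carriage at the envelope rate so biased views can be thinned
    envelope <- if (is.null(bias)) rates else pmin(rates * pmax(1, bias), 1)
    latent <- sim_latent(cfg, sizes[i])
    latent <- sim_carriers(latent, cfg, envelope)
    rates_mat[i, ] <- rates
    if (is_calib) {
      keep_cur <- rates / envelope
      keep_map <- pmin(rates * bias, 1) / envelope
      tables[[ids[i]]] <-
        sim_materialize(latent, cfg, ids[i], "curated", keep_cur)
      tables[[paste0(ids[i], ".mapped")]] <-
        sim_materialize(latent, cfg, ids[i], "mapped", keep_map)
      detect_mat[i, ] <- rates
    } else if (methods[i] == "mapped") {
      keep <- pmin(rates * bias, 1) / envelope
      tables[[ids[i]]] <- sim_materialize(latent, cfg, ids[i], "mapped", keep)
      detect_mat[i, ] <- pmin(rates * bias, 1)
    } else {
      tables[[ids[i]]] <- sim_materialize(latent, cfg, ids[i], "curated")
      detect_mat[i, ] <- rates
    }
  }
  manifest <- data.frame(
    taxon_id = ids, class = classes, method = methods,
    is_calibration = cfg$calibration_taxon_included & seq_along(ids) == 1L,
    stringsAsFactors = FALSE)
  truth <- list(rates = rates_mat, detect = detect_mat,
                enrichment = cfg$enrichment, method_bias = cfg$method_bias,
                assigned_fraction = cfg$assigned_fraction,
                classes = structure(classes, names = ids),
                methods = structure(methods, names = ids), seed = cfg$seed)
  list(tables = tables, manifest = manifest, truth = truth)
}

#' Closed-form expected representation profile under a configuration
#'
#' The generator's oracle: the expected genes-per-thousand value of each
#' function for a taxon of the given class and method, with the lognormal
#' jitter held at its median (1).
#'
#' @param cfg a `sim_config`.
#' @param taxon_class `"carnivorous"` or `"control"`.
#' @param method `"curated"` or `"mapped"`.
#' @return named numeric vector of expected per-mille values.
#' @export
expected_profile <- function(cfg, taxon_class = c("control", "carnivorous"),
                             method = c("curated", "mapped")) {
  stopifnot(inherits(cfg, "sim_config"))
  taxon_class <- match.arg(taxon_class)
  method <- match.arg(method)
  rate <- cfg$baseline_rate
  if (taxon_class == "carnivorous") rate <- rate * cfg$enrichment
  if (method == "mapped") rate <- rate * cfg$method_bias
  1000 * pmin(rate, 1)
}

#' Generate a dual-annotated calibration taxon
#'
#' One control-class gene set materialised twice: a curated view at the
#' taxon's true rates and a mapped view in which each carried function is
#' detected with probability scaled by `method_bias`. Used to exercise the
#' calibration stage with known bias.
#'
#' @param cfg a `sim_config` with `calibration_taxon_included = TRUE`.
#' @param taxon_id identifier for the pair.
#' @return list with elements `curated` and `mapped` (two
#'   `annotation_table`s over the same genes) and `rates` (the realised
#'   per-function rates).
#' @export
generate_dual_annotated <- function(cfg, taxon_id = "calib") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$calibration_taxon_included) {
    stop("calibration_taxon_included is FALSE", call. = FALSE)
  }
  abbrs <- ref_abbreviations(cfg$reference)
  set.seed(cfg$seed + 999L)
  jitter <- if (cfg$taxon_noise_sd > 0) {
    exp(stats::rnorm(length(abbrs), 0, cfg$taxon_noise_sd))
  } else rep(1, length(abbrs))
  rates <- pmin(cfg$baseline_rate * jitter, 1)
  names(rates) <- abbrs
  bias <- cfg$method_bias
  envelope <- pmin(rates * pmax(1, bias), 1)
  latent <- sim_latent(cfg, rep_len(cfg$genes_per_taxon, 1L))
  latent <- sim_carriers(latent, cfg, envelope)
  list(curated = sim_materialize(latent, cfg, taxon_id, "curated",
                                 rates / envelope),
       mapped = sim_materialize(latent, cfg, taxon_id, "mapped",
                                pmin(rates * bias, 1) / envelope),
       rates = rates)
}
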