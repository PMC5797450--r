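#' Build and validate a taxon manifest
#'
#' The manifest drives [run_pipeline()]: one row per input table, naming the
#' taxon, its class, the annotation method of the input, the input path, the
#' input format, and whether the taxon is the calibration taxon (annotated
#' by both methods). At most one calibration taxon is allowed, and it must
#' provide both a curated and a mapped input; at least two taxa per class
#' are required for testing.
#'
#' @param taxon_id,class,method,path character vectors, one element per
#'   input table; `class` in `carnivorous`/`control`, `method` in
#'   `curated`/`mapped`.
#' @param format input format per row: `"simple"`, `"gbff"` or `"mapping"`.
#' @param is_calibration logical; mark both rows of the calibration taxon.
#' @return a validated `data.frame` of class `taxon_manifest`.
#' @export
taxon_manifest <- function(taxon_id, class, method, path,
                           format = "simple", is_calibration = FALSE) {
  m <- data.frame(taxon_id = as.character(taxon_id),
                  class = as.character(class),
                  method = as.character(method),
                  path = as.character(path),
                  format = rep_len(as.character(format), length(taxon_id)),
                  is_calibration = rep_len(as.logical(is_calibration),
                                           length(taxon_id)),
                  stringsAsFactors = FALSE)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  stopifnot(is.data.frame(m),
            all(c("taxon_id", "class", "method", "path") %in% names(m)))
  if (is.null(m$format)) m$format <- "simple"
  if (is.null(m$is_calibration)) m$is_calibration <- FALSE
  if (!all(m$class %in% c("carnivorous", "control"))) {
    stop("manifest class must be 'carnivorous' or 'control'", call. = FALSE)
  }
  if (!all(m$method %in% c("curated", "mapped"))) {
    stop("manifest method must be 'curated' or 'mapped'", call. = FALSE)
  }
  if (!all(m$format %in% c("simple", "gbff", "mapping"))) {
    stop("manifest format must be 'simple', 'gbff' or 'mapping'", call. = FALSE)
  }
  if (anyDuplicated(paste(m$taxon_id, m$method))) {
    stop("duplicate (taxon_id, method) rows in manifest", call. = FALSE)
  }
  dup <- unique(m$taxon_id[duplicated(m$taxon_id)])
  calib <- unique(m$taxon_id[m$is_calibration])
  if (length(calib) > 1L) {
    stop("at most one calibration taxon is allowed", call. = FALSE)
  }
  if (!all(dup %in% calib)) {
    stop("only the calibration taxon may appear with two inputs", call. = FALSE)
  }
  if (length(calib) == 1L) {
    have <- sort(m$method[m$taxon_id == calib])
    if (!identical(have, c("curated", "mapped"))) {
      stop("calibration taxon needs exactly one curated and one mapped input",
           call. = FALSE)
    }
  }
  n_class <- table(factor(m$class[!duplicated(m$taxon_id)],
                          levels = c("carnivorous", "control")))
  if (any(n_class < 2L)) {
    stop(sprintf("need >= 2 taxa per class (got %d carnivorous, %d control)",
                 n_class[["carnivorous"]], n_class[["control"]]),
         call. = FALSE)
  }
  class(m) <- c("taxon_manifest", "data.frame")
  m
}

read_manifest_row <- function(row) {
  tab <- switch(row$format,
                simple = read_simple(row$path),
                gbff = parse_gbff_annotations(row$path, row$taxon_id),
                mapping = parse_mapping_export(row$path, row$taxon_id))
  tab$taxon_id <- row$taxon_id
  if (tab$method != row$method) {
    stop(sprintf("taxon %s: input declares method '%s' but manifest says '%s'",
                 row$taxon_id, tab$method, row$method), call. = FALSE)
  }
  tab
}

#' Run the full convergence-testing pipeline
#'
#' Ingests every manifest input, scores it against the reference set,
#' computes cross-method adjustment factors from the calibration taxon,
#' applies them, and runs both the group-level t-test analysis and the
#' per-taxon Z-test analysis on the adjusted and the raw profiles, with
#' Storey correction and the change accounting between the two. All outputs
#' are deterministic functions of the inputs. If mapped inputs are present
#' but no calibration taxon is given, a warning is issued and only the raw
#' analyses are run.
#'
#' @param manifest a [taxon_manifest()] (or a data frame with its columns).
#' @param reference a `go_refset`; defaults to the packaged
#'   carnivory-associated set.
#' @param var_equal use pooled-variance t-tests instead of Welch.
#' @param pi0_method Storey pi0 estimation method (see [storey_qvalues()]).
#' @param zero_undefined zero out nullset functions when adjusting instead
#'   of passing raw values through.
#' @param out_dir optional directory; when given, profile tables, factor
#'   table, report tables, exclusion report and a log are written as TSV.
#' @return a list: `profiles_raw`, `profiles_adjusted`, `factors`,
#'   `summaries` (annotation summary table), `group_tests` /
#'   `taxon_tests` (adjusted-data analyses), `group_tests_raw` /
#'   `taxon_tests_raw`, `changes` (a `change_summary` across all paired
#'   tests, or `NULL` in raw-only mode), `exclusions`, `log`.
#' @export
run_pipeline <- function(manifest, reference = carnivory_reference(),
                         var_equal = FALSE,
                         pi0_method = c("bootstrap", "smoother", "fixed"),
                         zero_undefined = FALSE, out_dir = NULL) {
  pi0_method <- match.arg(pi0_method)
  manifest <- validate_manifest(manifest)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  tables <- lapply(seq_len(nrow(manifest)),
                   function(i) read_manifest_row(manifest[i, ]))
  summaries <- do.call(rbind, lapply(tables, summarize_annotation))
  counts <- lapply(tables, count_functions, ref = reference)
  cls <- manifest$class
  profiles <- lapply(seq_along(counts), function(i) {
    to_profile(counts[[i]], cls[i])
  })
  note("scored %d input tables against %d reference functions",
       length(profiles), length(reference))

  calib_rows <- which(manifest$is_calibration)
  factors <- NULL
  if (length(calib_rows)) {
    cur <- profiles[[calib_rows[manifest$method[calib_rows] == "curated"]]]
    map <- profiles[[calib_rows[manifest$method[calib_rows] == "mapped"]]]
    factors <- compute_adjustment(cur, map)
    note("adjustment factors from %s: %d defined, %d nullset (%s)",
         factors$calibration_taxon, sum(!is.na(factors$factor)),
         length(factors$undefined), paste(factors$undefined, collapse = ", "))
  } else if (any(manifest$method == "mapped")) {
    warning("mapped inputs present but no calibration taxon: raw-only mode",
            call. = FALSE)
    note("WARNING: mapped inputs without calibration taxon; raw-only mode")
  }

  # one profile per taxon for testing: drop the calibration taxon's mapped
  # twin (its curated profile represents the taxon)
  keep <- !(manifest$is_calibration & manifest$method == "mapped")
  profiles_raw <- profiles[keep]
  names(profiles_raw) <- manifest$taxon_id[keep]

  fns <- tested_functions(profiles_raw, factors)
  excl <- exclusion_report(profiles_raw, factors)
  note("testing %d functions (+ Total); %d reference entries excluded",
       length(fns), sum(!excl$tested))

  run_both <- function(prof) {
    # pi0 clamping is routine under null-like data; record it in the log
    # rather than raising warnings for every family
    log_clamps <- function(expr) {
      withCallingHandlers(expr, goconverge_pi0_clamp = function(w) {
        note("NOTE: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    }
    a1 <- log_clamps(run_analysis_1(prof, functions = fns,
                                    var_equal = var_equal,
                                    pi0_method = pi0_method))
    a2 <- log_clamps(run_analysis_2(prof, functions = fns,
                                    pi0_method = pi0_method))
    note("group family pi0 = %.3f; taxon family pi0: %s",
         attr(a1, "pi0"),
         paste(sprintf("%s %.3f", names(a2),
                       vapply(a2, attr, 0, "pi0")), collapse = ", "))
    list(group = a1, taxon = a2)
  }

  raw <- run_both(profiles_raw)
  adjusted <- NULL
  changes <- NULL
  profiles_adj <- NULL
  if (!is.null(factors)) {
    profiles_adj <- lapply(profiles_raw, apply_adjustment, factors = factors,
                           zero_undefined = zero_undefined)
    adjusted <- run_both(profiles_adj)
    all_raw <- rbind(raw$group, do.call(rbind, raw$taxon))
    all_adj <- rbind(adjusted$group, do.call(rbind, adjusted$taxon))
    changes <- compare_significance(all_raw, all_adj)
    note("adjustment changed %d of %d significance codes",
         changes$n_increase + changes$n_decrease,
         nrow(changes$pairs))
  }

  out <- list(profiles_raw = profiles_raw, profiles_adjusted = profiles_adj,
              factors = factors, summaries = summaries,
              group_tests = if (is.null(adjusted)) NULL else adjusted$group,
              taxon_tests = if (is.null(adjusted)) NULL else adjusted$taxon,
              group_tests_raw = raw$group, taxon_tests_raw = raw$taxon,
              changes = changes, exclusions = excl, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, file) {
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_profile_table(profiles_raw, file.path(out_dir, "profiles_raw.tsv"))
    wt(summaries, "annotation_summary.tsv")
    wt(excl, "exclusions.tsv")
    main <- if (is.null(adjusted)) raw else adjusted
    wt(format_test_table(main$group), "group_tests.tsv")
    wt(format_test_table(do.call(rbind, main$taxon)), "taxon_tests.tsv")
    if (!is.null(factors)) {
      write_adjustment_factors(factors,
                               file.path(out_dir, "adjustment_factors.tsv"))
      write_profile_table(profiles_adj,
                          file.path(out_dir, "profiles_adjusted.tsv"))
      wt(format_test_table(raw$group), "group_tests_raw.tsv")
      wt(format_test_table(do.call(rbind, raw$taxon)), "taxon_tests_raw.tsv")
      wt(changes$by_comparison, "change_summary.tsv")
    }
    writeLines(log, file.path(out_dir, "pipeline_log.txt"))
  }
  out
}

#' Load a deposited per-taxon representation table (reproduction mode)
#'
#' Skips ingestion and scoring: consumes a TSV whose rows are taxa and whose
#' columns are function abbreviations (genes per thousand) plus `Total` and
#' `Class`, the layout of deposited representation tables and of
#' [write_profile_table()]. `Taxon`, `Method` and `Adjusted` columns are
#' recognised; other unknown columns are a schema error. Functions absent
#' from the table are filled with zero. The `Total` column is kept as
#' deposited (it is itself a tested criterion).
#'
#' @param path TSV path.
#' @param reference a `go_refset` used to resolve the function columns.
#' @return a named list of `representation_profile` objects.
#' @export
load_profile_table <- function(path, reference = carnivory_reference()) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  abbrs <- ref_abbreviations(reference)
  special <- c("Taxon", "Total", "Class", "Method", "Adjusted")
  unknown <- setdiff(names(df), c(abbrs, special))
  if (length(unknown)) {
    stop("unknown profile table column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("Taxon", "Total", "Class")) {
    if (!col %in% names(df)) {
      stop(sprintf("profile table lacks required column '%s'", col),
           call. = FALSE)
    }
  }
  if (!all(df$Class %in% c("carnivorous", "control"))) {
    stop("profile table Class must be 'carnivorous' or 'control'",
         call. = FALSE)
  }
  profiles <- lapply(seq_len(nrow(df)), function(i) {
    pm <- structure(numeric(length(abbrs)), names = abbrs)
    present <- intersect(abbrs, names(df))
    pm[present] <- as.numeric(unlist(df[i, present, drop = TRUE]))
    new_profile(as.character(df$Taxon[i]),
                if ("Method" %in% names(df)) df$Method[i] else "curated",
                df$Class[i], pm,
                adjusted = if ("Adjusted" %in% names(df)) {
                  as.logical(df$Adjusted[i])
                } else TRUE,
                total_per_mille = as.numeric(df$Total[i]))
  })
  names(profiles) <- df$Taxon
  profiles
}
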