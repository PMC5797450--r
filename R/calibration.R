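#' Compute per-function cross-method adjustment factors
#'
#' Annotation methods differ in their tendency to detect particular
#' functions. Factors are estimated from one calibration taxon annotated by
#' both routes, as the ratio of the curated to the mapped genes-per-thousand
#' value for each function. Functions for which either method detected zero
#' instances cannot be calibrated and are flagged as the undefined
#' ("nullset") set.
#'
#' @param curated_profile the calibration taxon's `representation_profile`
#'   from curated annotation.
#' @param mapped_profile the same taxon's profile from mapped annotation.
#' @return an object of class `adjustment_factors`: `factor` (named numeric,
#'   `NA` where undefined), `undefined` (character vector of abbreviations),
#'   `calibration_taxon`.
#' @export
compute_adjustment <- function(curated_profile, mapped_profile) {
  stopifnot(inherits(curated_profile, "representation_profile"),
            inherits(mapped_profile, "representation_profile"))
  if (!identical(curated_profile$taxon_id, mapped_profile$taxon_id)) {
    stop(sprintf("calibration profiles refer to different taxa: %s vs %s",
                 curated_profile$taxon_id, mapped_profile$taxon_id),
         call. = FALSE)
  }
  if (curated_profile$method != "curated" || mapped_profile$method != "mapped") {
    stop("compute_adjustment() needs one curated and one mapped profile",
         call. = FALSE)
  }
  cur <- curated_profile$per_mille
  map <- mapped_profile$per_mille
  stopifnot(identical(names(cur), names(map)))
  fac <- ifelse(cur > 0 & map > 0, cur / map, NA_real_)
  names(fac) <- names(cur)
  structure(list(calibration_taxon = curated_profile$taxon_id,
                 factor = fac,
                 undefined = names(fac)[is.na(fac)]),
            class = "adjustment_factors")
}

#' @export
print.adjustment_factors <- function(x, ...) {
  cat(sprintf("adjustment_factors from %s: %d defined, %d undefined (nullset)\n",
              x$calibration_taxon, sum(!is.na(x$factor)),
              length(x$undefined)))
  invisible(x)
}

#' Apply adjustment factors to a representation profile
#'
#' Mapped-method profiles have each defined function multiplied by its
#' factor, with the syndrome total recomputed as the sum of the
#' post-adjustment per-function values; undefined (nullset) functions pass
#' through unchanged unless `zero_undefined` is set. Curated profiles need
#' no correction and are returned unchanged apart from the `adjusted` flag.
#'
#' @param profile an unadjusted `representation_profile`.
#' @param factors an `adjustment_factors` object.
#' @param zero_undefined set undefined functions to zero instead of passing
#'   their raw values through.
#' @return the adjusted `representation_profile`.
#' @export
apply_adjustment <- function(profile, factors, zero_undefined = FALSE) {
  stopifnot(inherits(profile, "representation_profile"),
            inherits(factors, "adjustment_factors"))
  if (isTRUE(profile$adjusted)) {
    stop(sprintf("profile for %s is already adjusted", profile$taxon_id),
         call. = FALSE)
  }
  if (profile$method == "curated") {
    profile$adjusted <- TRUE
    return(profile)
  }
  fac <- factors$factor
  stopifnot(identical(names(profile$per_mille), names(fac)))
  pm <- profile$per_mille
  defined <- !is.na(fac)
  pm[defined] <- pm[defined] * fac[defined]
  if (zero_undefined) pm[!defined] <- 0
  new_profile(profile$taxon_id, profile$method, profile$class_label, pm,
              adjusted = TRUE, n_assigned = profile$n_assigned)
}

#' Read and write adjustment-factor tables
#'
#' TSV with columns `abbreviation`, `factor` (empty for nullset entries) and
#' `defined`.
#'
#' @param factors an `adjustment_factors` object.
#' @param path file path.
#' @return `write_adjustment_factors()` returns `path` invisibly;
#'   `read_adjustment_factors()` returns an `adjustment_factors` object.
#' @export
write_adjustment_factors <- function(factors, path) {
  stopifnot(inherits(factors, "adjustment_factors"))
  df <- data.frame(abbreviation = names(factors$factor),
                   factor = ifelse(is.na(factors$factor), "",
                                   format(factors$factor, digits = 15)),
                   defined = !is.na(factors$factor),
                   stringsAsFactors = FALSE)
  header <- sprintf("#calibration_taxon=%s", factors$calibration_taxon)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjustment_factors
#' @export
read_adjustment_factors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^#calibration_taxon=", lines[[1L]])) {
    stop("factor table: missing '#calibration_taxon=' header", call. = FALSE)
  }
  taxon <- sub("^#calibration_taxon=", "", lines[[1L]])
  df <- utils::read.delim(text = paste(lines[-1L], collapse = "\n"),
                          stringsAsFactors = FALSE)
  fac <- suppressWarnings(as.numeric(df$factor))
  fac[!df$defined] <- NA_real_
  names(fac) <- df$abbreviation
  structure(list(calibration_taxon = taxon, factor = fac,
                 undefined = names(fac)[is.na(fac)]),
            class = "adjustment_factors")
}
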