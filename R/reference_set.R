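#' @keywords internal
"_PACKAGE"

GO_CODE_PATTERN <- "GO:[0-9]{7}"

#' Validate and normalise Gene Ontology codes
#'
#' A GO code is the string `"GO:"` followed by exactly seven digits.
#' Normalisation upper-cases the `"GO"` prefix and trims surrounding
#' whitespace; comparison everywhere in the package is on normalised codes.
#'
#' @param x character vector of candidate codes.
#' @return `normalize_go_code()` returns the normalised codes, erroring on
#'   malformed input; `is_go_code()` returns a logical vector.
#' @examples
#' is_go_code(c("GO:0009916", "go:0004620", "GO:12345"))
#' @export
is_go_code <- function(x) {
  grepl(paste0("^[Gg][Oo]:[0-9]{7}$"), trimws(x))
}

#' @rdname is_go_code
#' @export
normalize_go_code <- function(x) {
  x <- trimws(x)
  ok <- is_go_code(x)
  if (!all(ok)) {
    stop("malformed GO code token(s): ", paste(x[!ok], collapse = ", "),
         call. = FALSE)
  }
  sub("^[Gg][Oo]:", "GO:", x)
}

new_go_refset <- function(labels, abbreviations, codes) {
  stopifnot(length(labels) == length(abbreviations),
            length(labels) == length(codes))
  entries <- data.frame(label = as.character(labels),
                        abbreviation = as.character(abbreviations),
                        stringsAsFactors = FALSE)
  names(codes) <- entries$abbreviation
  code_to_abbr <- character(0)
  if (length(codes)) {
    code_to_abbr <- structure(rep(entries$abbreviation, lengths(codes)),
                              names = unlist(codes, use.names = FALSE))
  }
  structure(list(entries = entries, codes = codes,
                 code_to_abbr = code_to_abbr),
            class = "go_refset")
}

#' Load a reference set of syndrome-associated GO functions
#'
#' Reads a tab-separated table with columns `label`, `abbreviation` and
#' `codes` (the latter a `";"`-separated list of GO codes) into a reference
#' set. Entries listing several codes treat them as aliases of one function:
#' a gene matching any of them counts for the entry. Each code may belong to
#' at most one entry.
#'
#' @param path path to a UTF-8 tab-separated file with header
#'   `label<TAB>abbreviation<TAB>codes`.
#' @return an object of class `go_refset`.
#' @seealso [carnivory_reference()] for the packaged carnivory-associated
#'   set, [function_of()] for code lookup.
#' @export
load_reference_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(new_go_refset(character(0), character(0), list()))
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("label", "abbreviation", "codes")
  if (!all(need %in% header)) {
    stop("reference set header must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  body <- lines[-1L]
  if (length(body) == 0L) return(new_go_refset(character(0), character(0), list()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  labels <- character(length(body))
  abbrs <- character(length(body))
  codes <- vector("list", length(body))
  for (i in seq_along(body)) {
    row <- fields[[i]]
    if (length(row) < length(need)) {
      stop(sprintf("reference set row %d: expected %d tab-separated fields",
                   i, length(need)), call. = FALSE)
    }
    names(row)[seq_along(header)] <- header
    labels[i] <- trimws(row[["label"]])
    abbrs[i] <- trimws(row[["abbreviation"]])
    toks <- trimws(strsplit(row[["codes"]], ";", fixed = TRUE)[[1L]])
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) {
      stop(sprintf("reference set row %d (%s): no GO code given", i, labels[i]),
           call. = FALSE)
    }
    bad <- !is_go_code(toks)
    if (any(bad)) {
      stop(sprintf("reference set row %d (%s): malformed GO code token(s): %s",
                   i, labels[i], paste(toks[bad], collapse = ", ")),
           call. = FALSE)
    }
    codes[[i]] <- unique(normalize_go_code(toks))
    if (!nzchar(labels[i]) || !nzchar(abbrs[i])) {
      stop(sprintf("reference set row %d: empty label or abbreviation", i),
           call. = FALSE)
    }
  }
  if (anyDuplicated(labels)) {
    stop("duplicate entry label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(abbrs)) {
    stop("duplicate abbreviation(s): ",
         paste(unique(abbrs[duplicated(abbrs)]), collapse = ", "),
         call. = FALSE)
  }
  flat <- unlist(codes, use.names = FALSE)
  if (anyDuplicated(flat)) {
    stop("GO code(s) assigned to more than one entry: ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "),
         call. = FALSE)
  }
  new_go_refset(labels, abbrs, codes)
}

#' Serialise a reference set back to its tabular text form
#'
#' @param ref a `go_refset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(ref, path) {
  stopifnot(inherits(ref, "go_refset"))
  lines <- c("label\tabbreviation\tcodes",
             if (nrow(ref$entries)) {
               paste(ref$entries$label, ref$entries$abbreviation,
                     vapply(ref$codes, paste, "", collapse = "; "),
                     sep = "\t")
             })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' The packaged carnivory-associated function set
#'
#' The literature-derived reference set of 36 carnivory-associated functions
#' (digestive enzymes, nutrient transporters, and trap-related activities)
#' and their 39 GO codes, shipped with the package. Multi-code entries list
#' codes that are equivalent to, or deprecated from, the best-matching
#' current term.
#'
#' @return a `go_refset` with 36 entries.
#' @examples
#' ref <- carnivory_reference()
#' length(ref)
#' function_of(ref, "GO:0009916")$label
#' @export
carnivory_reference <- function() {
  load_reference_set(system.file("extdata", "carnivory_functions.tsv",
                                 package = "goconverge", mustWork = TRUE))
}

#' Look up the function entry owning a GO code
#'
#' @param ref a `go_refset`.
#' @param code one GO code (case-insensitive on the `"GO"` prefix).
#' @return a list with elements `label`, `abbreviation` and `codes`, or
#'   `NULL` when the code belongs to no entry.
#' @export
function_of <- function(ref, code) {
  stopifnot(inherits(ref, "go_refset"), length(code) == 1L)
  code <- normalize_go_code(code)
  abbr <- ref$code_to_abbr[code]
  if (is.na(abbr)) return(NULL)
  i <- match(abbr, ref$entries$abbreviation)
  list(label = ref$entries$label[i],
       abbreviation = ref$entries$abbreviation[i],
       codes = ref$codes[[abbr]])
}

#' @export
length.go_refset <- function(x) nrow(x$entries)

#' @export
print.go_refset <- function(x, ...) {
  cat(sprintf("GO function reference set: %d entries, %d codes\n",
              nrow(x$entries), length(x$code_to_abbr)))
  if (nrow(x$entries)) {
    cat(paste0("  ", x$entries$abbreviation, " (", x$entries$label, "): ",
               vapply(x$codes, paste, "", collapse = "; "), "\n"), sep = "")
  }
  invisible(x)
}

ref_abbreviations <- function(ref) ref$entries$abbreviation
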