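#' Count genes matching each reference function
#'
#' Scans an annotation table against a reference set. A gene counts for a
#' function entry when it carries at least one of the entry's codes; a gene
#' counts at most once per entry but may count for several entries. The
#' denominator recorded alongside is the number of genes with at least one
#' GO code of any kind ("function-assigned" genes), not only reference
#' codes.
#'
#' @param table an `annotation_table`.
#' @param ref a `go_refset`.
#' @return an object of class `function_counts`: named integer vector
#'   `counts` over all reference abbreviations, `n_assigned`, and the
#'   taxon/method tags.
#' @export
count_functions <- function(table, ref) {
  stopifnot(inherits(table, "annotation_table"), inherits(ref, "go_refset"))
  abbrs <- ref_abbreviations(ref)
  counts <- structure(integer(length(abbrs)), names = abbrs)
  lens <- lengths(table$codes)
  if (sum(lens) > 0L) {
    gene_idx <- rep.int(seq_along(table$gene_id), lens)
    code <- unlist(table$codes, use.names = FALSE)
    abbr <- ref$code_to_abbr[code]
    keep <- !is.na(abbr)
    if (any(keep)) {
      pairs <- unique(data.frame(gene = gene_idx[keep], abbr = abbr[keep],
                                 stringsAsFactors = FALSE))
      tab <- table(factor(pairs$abbr, levels = abbrs))
      counts[] <- as.integer(tab)
    }
  }
  structure(list(taxon_id = table$taxon_id, method = table$method,
                 counts = counts, n_assigned = sum(lens > 0L)),
            class = "function_counts")
}

#' Convert function counts to a genes-per-thousand representation profile
#'
#' Each function's count is expressed per thousand function-assigned genes;
#' the syndrome total is the sum of the per-function values (so that a
#' recalibrated total can be recomputed from recalibrated per-function
#' values, and share decompositions are additive).
#'
#' @param counts a `function_counts` object.
#' @param class_label `"carnivorous"` (study group) or `"control"`.
#' @return an object of class `representation_profile` with fields
#'   `per_mille` (named numeric), `total_per_mille`, `class_label`,
#'   `adjusted` (`FALSE`), and the taxon/method tags.
#' @export
to_profile <- function(counts, class_label) {
  stopifnot(inherits(counts, "function_counts"))
  class_label <- match.arg(class_label, c("carnivorous", "control"))
  if (counts$n_assigned == 0L) {
    stop(sprintf("taxon %s: no function-assigned genes; profile undefined",
                 counts$taxon_id), call. = FALSE)
  }
  per_mille <- 1000 * counts$counts / counts$n_assigned
  new_profile(counts$taxon_id, counts$method, class_label, per_mille,
              adjusted = FALSE, n_assigned = counts$n_assigned)
}

new_profile <- function(taxon_id, method, class_label, per_mille,
                        adjusted, n_assigned = NA_integer_,
                        total_per_mille = NULL) {
  structure(list(taxon_id = taxon_id, method = method,
                 class_label = class_label,
                 per_mille = per_mille,
                 total_per_mille = if (is.null(total_per_mille)) sum(per_mille)
                                   else total_per_mille,
                 adjusted = adjusted, n_assigned = n_assigned),
            class = "representation_profile")
}

#' @export
print.representation_profile <- function(x, ...) {
  cat(sprintf(
    "representation_profile: %s (%s, %s%s) total %.2f per mille over %d functions\n",
    x$taxon_id, x$method, x$class_label,
    if (isTRUE(x$adjusted)) ", adjusted" else "", x$total_per_mille,
    length(x$per_mille)))
  invisible(x)
}

#' Decompose a profile into per-function shares of the syndrome total
#'
#' @param profile a `representation_profile` with a positive total.
#' @return named numeric vector of fractions summing to 1.
#' @export
function_shares <- function(profile) {
  stopifnot(inherits(profile, "representation_profile"))
  if (profile$total_per_mille <= 0) {
    stop(sprintf("taxon %s: syndrome total is zero; shares undefined",
                 profile$taxon_id), call. = FALSE)
  }
  profile$per_mille / profile$total_per_mille
}

#' Tabulate representation profiles, one row per taxon
#'
#' The layout used for deposited per-taxon representation tables: one row
#' per taxon, one column per function abbreviation (values in genes per
#' thousand), plus `Total`, `Class`, `Method` and `Adjusted` columns.
#'
#' @param profiles list of `representation_profile` objects sharing one
#'   function set.
#' @param path optional file; when given the table is written as TSV.
#' @return the data frame, invisibly when `path` is given.
#' @export
profiles_to_table <- function(profiles, path = NULL) {
  stopifnot(length(profiles) > 0L)
  abbrs <- names(profiles[[1L]]$per_mille)
  rows <- lapply(profiles, function(p) {
    stopifnot(identical(names(p$per_mille), abbrs))
    cbind(data.frame(Taxon = p$taxon_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(p$per_mille), check.names = FALSE),
          data.frame(Total = p$total_per_mille, Class = p$class_label,
                     Method = p$method, Adjusted = p$adjusted,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @rdname profiles_to_table
#' @export
write_profile_table <- function(profiles, path) {
  invisible(profiles_to_table(profiles, path))
}
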