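#' Construct a per-taxon gene-to-GO annotation table
#'
#' The common container produced by all ingestion routes: one row per
#' putative gene, each carrying a (possibly empty) set of GO codes, plus the
#' annotation method that produced the table. `method = "curated"` marks
#' annotations shipped with a genome record; `method = "mapped"` marks
#' annotations transferred by sequence similarity.
#'
#' @param taxon_id non-empty taxon identifier.
#' @param method `"curated"` or `"mapped"`.
#' @param gene_id character vector of unique gene identifiers.
#' @param codes list of character vectors of GO codes, parallel to
#'   `gene_id`; empty vectors are allowed and kept.
#' @param n_total_predicted optional count of putative genes before any GO
#'   filtering (for genome-summary reporting).
#' @return an object of class `annotation_table`.
#' @export
annotation_table <- function(taxon_id, method, gene_id, codes,
                             n_total_predicted = NA_integer_) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L, nzchar(taxon_id))
  method <- match.arg(method, c("curated", "mapped"))
  gene_id <- as.character(gene_id)
  if (length(codes) != length(gene_id)) {
    stop("codes must be a list parallel to gene_id", call. = FALSE)
  }
  if (any(!nzchar(gene_id))) stop("empty gene_id", call. = FALSE)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  codes <- lapply(codes, function(x) {
    if (length(x) == 0L) character(0) else unique(normalize_go_code(x))
  })
  structure(list(taxon_id = taxon_id, method = method,
                 gene_id = gene_id, codes = codes,
                 n_total_predicted = as.integer(n_total_predicted)),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("annotation_table: taxon %s (%s), %d genes, %d with GO codes\n",
              x$taxon_id, x$method, length(x$gene_id),
              sum(lengths(x$codes) > 0L)))
  invisible(x)
}

read_input_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
}

extract_go_tokens <- function(text) {
  m <- regmatches(text, gregexpr(GO_CODE_PATTERN, text))
  unique(unlist(m, use.names = FALSE))
}

#' Extract gene-to-GO annotations from a GenBank flat file
#'
#' Scans the feature table of each GBFF record for `gene` and `CDS`
#' features. Any qualifier value containing a token matching `GO:` + seven
#' digits contributes that code, which covers the `/db_xref`,
#' `/GO_function`, `/GO_process` and `/GO_component` encodings used by
#' different submitters. Features sharing an identifier (a CDS and its gene)
#' are merged by code-set union; features carrying no GO token are retained
#' with an empty code set, so that genome summaries can report the fraction
#' of genes with at least one assigned function.
#'
#' @param input path to a GBFF file, or its content as a character vector.
#' @param taxon_id taxon identifier for the resulting table.
#' @return an `annotation_table` with `method = "curated"`.
#' @export
parse_gbff_annotations <- function(input, taxon_id) {
  lines <- read_input_lines(input)
  if (length(lines) == 0L || !any(grepl("^LOCUS", lines))) {
    stop("not a GBFF stream: no LOCUS line found", call. = FALSE)
  }
  rec_start <- grep("^LOCUS", lines)
  rec_end <- c(rec_start[-1L] - 1L, length(lines))
  ids <- character(0)
  codes <- list()
  seen <- new.env(parent = emptyenv())
  anon <- 0L
  for (r in seq_along(rec_start)) {
    rec <- lines[rec_start[r]:rec_end[r]]
    feat_at <- grep("^FEATURES", rec)
    if (length(feat_at) == 0L) {
      stop(sprintf("GBFF record %d (starting line %d): no FEATURES table",
                   r, rec_start[r]), call. = FALSE)
    }
    stop_at <- grep("^(ORIGIN|CONTIG|//)", rec)
    stop_at <- if (length(stop_at)) min(stop_at[stop_at > feat_at[1L]]) else length(rec) + 1L
    feat <- rec[(feat_at[1L] + 1L):(stop_at - 1L)]
    if (length(feat) == 0L) next
    # feature keys sit at column 6; qualifier lines are indented further
    is_key <- grepl("^     \\S", feat)
    key_idx <- which(is_key)
    if (length(key_idx) == 0L) next
    keys <- sub("^\\s*(\\S+).*$", "\\1", feat[key_idx])
    blk_end <- c(key_idx[-1L] - 1L, length(feat))
    for (k in seq_along(key_idx)) {
      if (!keys[k] %in% c("gene", "CDS")) next
      block <- feat[key_idx[k]:blk_end[k]]
      txt <- paste(block, collapse = " ")
      id <- NA_character_
      for (qual in c("locus_tag", "gene", "protein_id")) {
        m <- regmatches(txt, regexpr(sprintf('/%s="[^"]*"', qual), txt))
        if (length(m)) {
          id <- sub(sprintf('/%s="([^"]*)"', qual), "\\1", m[[1L]])
          break
        }
      }
      if (is.na(id)) {
        anon <- anon + 1L
        id <- sprintf("feature_%05d", anon)
      }
      gos <- extract_go_tokens(txt)
      if (is.null(seen[[id]])) {
        ids <- c(ids, id)
        seen[[id]] <- length(ids)
        codes[[length(ids)]] <- gos
      } else {
        i <- seen[[id]]
        codes[[i]] <- unique(c(codes[[i]], gos))
      }
    }
  }
  annotation_table(taxon_id, "curated", ids, codes)
}

#' Parse a GO-mapping export table
#'
#' Reads the tab-separated export of a sequence-similarity GO mapping run:
#' one row per query sequence, first field the sequence identifier, the
#' remainder zero or more GO codes (any separators; codes are token-matched).
#' Rows repeating an identifier are merged by code-set union; rows with no
#' GO token yield genes with empty code sets.
#'
#' @param input path to the export file, or its content as a character
#'   vector.
#' @param taxon_id taxon identifier for the resulting table.
#' @return an `annotation_table` with `method = "mapped"`.
#' @export
parse_mapping_export <- function(input, taxon_id) {
  lines <- read_input_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines)]
  ids <- character(0)
  codes <- list()
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    id <- trimws(fields[[1L]])
    if (!nzchar(id)) {
      stop(sprintf("mapping export line %d: missing sequence identifier", i),
           call. = FALSE)
    }
    rest <- if (length(fields) > 1L) paste(fields[-1L], collapse = " ") else ""
    gos <- extract_go_tokens(rest)
    if (is.null(seen[[id]])) {
      ids <- c(ids, id)
      seen[[id]] <- length(ids)
      codes[[length(ids)]] <- gos
    } else {
      j <- seen[[id]]
      codes[[j]] <- unique(c(codes[[j]], gos))
    }
  }
  annotation_table(taxon_id, "mapped", ids, codes)
}

#' Read and write the simplified annotation text format
#'
#' The diff-friendly intermediate format shared by all pipeline stages:
#' a header line `#taxon=<id> method=<curated|mapped>` (optionally carrying
#' `n_total_predicted=<k>`), then one gene per line as
#' `gene_id<TAB>code;code;...`, with an empty code field allowed.
#'
#' @param table an `annotation_table`.
#' @param path file to write, or `NULL` to return the lines only.
#' @param input path to a simple-format file, or its content as a character
#'   vector.
#' @return `write_simple()` returns the file lines invisibly; `read_simple()`
#'   returns an `annotation_table`.
#' @export
write_simple <- function(table, path = NULL) {
  stopifnot(inherits(table, "annotation_table"))
  header <- sprintf("#taxon=%s method=%s", table$taxon_id, table$method)
  if (!is.na(table$n_total_predicted)) {
    header <- sprintf("%s n_total_predicted=%d", header, table$n_total_predicted)
  }
  lines <- c(header,
             if (length(table$gene_id)) {
               paste(table$gene_id,
                     vapply(table$codes, paste, "", collapse = ";"),
                     sep = "\t")
             })
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' @rdname write_simple
#' @export
read_simple <- function(input) {
  lines <- read_input_lines(input)
  if (length(lines) == 0L || !grepl("^#taxon=", lines[[1L]])) {
    stop("simple format: missing '#taxon=... method=...' header", call. = FALSE)
  }
  header <- lines[[1L]]
  grab <- function(key) {
    m <- regmatches(header, regexpr(sprintf("%s=\\S+", key), header))
    if (length(m) == 0L) NA_character_ else sub(sprintf("%s=", key), "", m)
  }
  taxon_id <- sub("^#taxon=", "", grab("#taxon"))
  method <- grab("method")
  if (is.na(method)) stop("simple format: header lacks method=", call. = FALSE)
  n_total <- suppressWarnings(as.integer(grab("n_total_predicted")))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  ids <- character(length(body))
  codes <- vector("list", length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 1L || !nzchar(trimws(fields[[1L]])) || length(fields) > 2L) {
      stop(sprintf("simple format line %d: expected 'gene_id<TAB>codes'", i + 1L),
           call. = FALSE)
    }
    ids[i] <- trimws(fields[[1L]])
    toks <- if (length(fields) == 2L) {
      trimws(strsplit(fields[[2L]], ";", fixed = TRUE)[[1L]])
    } else character(0)
    toks <- toks[nzchar(toks)]
    bad <- !is_go_code(toks)
    if (any(bad)) {
      stop(sprintf("simple format line %d: malformed GO code token(s): %s",
                   i + 1L, paste(toks[bad], collapse = ", ")), call. = FALSE)
    }
    codes[[i]] <- toks
  }
  annotation_table(taxon_id, method, ids, codes, n_total)
}

#' Summarise an annotation table
#'
#' Genome-level annotation statistics: gene count, the percentage of genes
#' carrying at least one GO code (the "% Results" of genome annotation
#' summaries), total gene-GO assignments, and the number of distinct codes.
#'
#' @param table an `annotation_table`.
#' @return a one-row data frame with columns `taxon_id`, `method`,
#'   `n_genes`, `n_total_predicted`, `n_assigned`, `pct_results`, `go_hits`,
#'   `unique_gos`.
#' @export
summarize_annotation <- function(table) {
  stopifnot(inherits(table, "annotation_table"))
  n_genes <- length(table$gene_id)
  n_assigned <- sum(lengths(table$codes) > 0L)
  data.frame(
    taxon_id = table$taxon_id,
    method = table$method,
    n_genes = n_genes,
    n_total_predicted = table$n_total_predicted,
    n_assigned = n_assigned,
    pct_results = if (n_genes == 0L) 0 else 100 * n_assigned / n_genes,
    go_hits = sum(lengths(table$codes)),
    unique_gos = length(unique(unlist(table$codes, use.names = FALSE))),
    stringsAsFactors = FALSE)
}
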