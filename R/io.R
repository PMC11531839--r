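#' Build a validated differential-expression table
#'
#' A DE table is the pipeline's basic input: one row per gene with its log2
#' fold-change and adjusted p-value for a single contrast (e.g. treated vs
#' mock). `as_de_table()` validates an in-memory data frame;
#' [read_de_table()] is the file-reading front end.
#'
#' Validation enforces the table's invariants: gene identifiers are unique
#' (after whitespace stripping; comparison is case-sensitive because locus
#' codes are canonical), `log2fc` is finite and numeric, and `adj_p` lies in
#' \[0, 1\] where present. Rows with a missing adjusted p-value (the usual
#' convention for independent-filtering casualties in DE output) are retained
#' and flagged via `missing_p`; they never pass DEG thresholds but still count
#' toward the gene universe.
#'
#' @param data A data frame with (at least) the mapped columns.
#' @param contrast_label Free-text label for the contrast (e.g. `"HF_vs_NM"`).
#' @param dialect Named character vector mapping the semantic column names
#'   `gene_id`, `log2fc`, `adj_p` to the column names present in `data`.
#' @return A tibble of class `de_table` with columns `gene_id`, `log2fc`,
#'   `adj_p`, `missing_p`, and a `contrast_label` attribute.
#' @examples
#' as_de_table(
#'   data.frame(gene_id = c("AT1G01010", "AT1G01020"),
#'              log2fc = c(1.2, -0.7), adj_p = c(0.001, 0.2)),
#'   contrast_label = "NF_vs_NM"
#' )
#' @export
as_de_table <- function(data,
                        contrast_label = "contrast",
                        dialect = c(gene_id = "gene_id",
                                    log2fc = "log2fc",
                                    adj_p = "adj_p")) {
  stopifnot(is.data.frame(data))
  dialect <- check_dialect(dialect)
  missing_cols <- setdiff(unname(dialect), names(data))
  if (length(missing_cols) > 0) {
    stop("mapped column(s) not found in input: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(
    gene_id = trimws(as.character(data[[dialect[["gene_id"]]]])),
    log2fc = data[[dialect[["log2fc"]]]],
    adj_p = data[[dialect[["adj_p"]]]]
  )

  if (is.character(out$log2fc)) {
    suppressWarnings(num <- as.numeric(out$log2fc))
    if (anyNA(num) && !all(is.na(out$log2fc[is.na(num)]))) {
      stop("non-numeric log2fc value(s), e.g. ",
           out$log2fc[which(is.na(num) & !is.na(out$log2fc))[1]],
           call. = FALSE)
    }
    out$log2fc <- num
  }
  out$log2fc <- as.double(out$log2fc)
  if (is.character(out$adj_p)) {
    out$adj_p[out$adj_p %in% c("NA", "")] <- NA_character_
    suppressWarnings(out$adj_p <- as.numeric(out$adj_p))
  }
  out$adj_p <- as.double(out$adj_p)

  if (anyNA(out$gene_id) || any(out$gene_id == "")) {
    stop("empty gene_id", call. = FALSE)
  }
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(out$log2fc) || any(!is.finite(out$log2fc))) {
    stop("log2fc must be finite for every row", call. = FALSE)
  }
  bad_p <- !is.na(out$adj_p) & (out$adj_p < 0 | out$adj_p > 1)
  if (any(bad_p)) {
    stop("adj_p outside [0, 1] for gene(s): ",
         paste(utils::head(out$gene_id[bad_p], 5), collapse = ", "),
         call. = FALSE)
  }

  out$missing_p <- is.na(out$adj_p)
  structure(out,
            contrast_label = as.character(contrast_label)[1],
            class = c("de_table", class(tibble::tibble())))
}

check_dialect <- function(dialect) {
  needed <- c("gene_id", "log2fc", "adj_p")
  if (is.null(names(dialect))) names(dialect) <- needed[seq_along(dialect)]
  if (!all(needed %in% names(dialect))) {
    stop("dialect must map all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  dialect[needed]
}

#' Read a differential-expression table from delimited text
#'
#' Reads a tab-separated file with a header row and validates it with
#' [as_de_table()]. Column names are configurable through `dialect`, so
#' DESeq2-style output (`log2FoldChange`, `padj`) can be ingested directly.
#'
#' @param path Path to a TSV file.
#' @param contrast_label Contrast label; defaults to the file name.
#' @inheritParams as_de_table
#' @return A `de_table` tibble.
#' @seealso [write_de_table()]
#' @export
read_de_table <- function(path,
                          contrast_label = NULL,
                          dialect = c(gene_id = "gene_id",
                                      log2fc = "log2fc",
                                      adj_p = "adj_p")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(contrast_label)) {
    contrast_label <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  as_de_table(raw, contrast_label = contrast_label, dialect = dialect)
}

#' Write a differential-expression table to TSV
#'
#' Writes the semantic columns (`gene_id`, `log2fc`, `adj_p`) so that
#' [read_de_table()] round-trips the records exactly.
#'
#' @param x A `de_table`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_de_table <- function(x, path) {
  stopifnot(inherits(x, "de_table"))
  readr::write_tsv(x[, c("gene_id", "log2fc", "adj_p")], path, na = "NA",
                   progress = FALSE)
  invisible(x)
}

#' @export
print.de_table <- function(x, ...) {
  cat("# DE table for contrast:", attr(x, "contrast_label"), "\n")
  NextMethod()
}

#' Read a one-identifier-per-line gene list
#'
#' Blank lines are dropped, surrounding whitespace is stripped, and duplicates
#' are removed. Useful for gene universes and query sets.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[ids != ""])
}

#' Read a GMT gene-set file into a term map
#'
#' Each GMT line is `term_id <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Members are de-duplicated per term (set semantics). A line with fewer than
#' three fields is a parse error that names the offending line, and a term
#' with no members after cleaning is rejected.
#'
#' @param path Path to a GMT file.
#' @return A tibble of class `term_map` with columns `term_id`, `term_name`,
#'   and list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0) stop("empty GMT file: ", path, call. = FALSE)
  parsed <- lapply(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 fields", call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[members != ""]
    if (length(members) == 0) {
      stop("malformed GMT line ", i, ": term ", fields[1], " has no members",
           call. = FALSE)
    }
    tibble::tibble(term_id = fields[1], term_name = fields[2],
                   genes = list(members))
  })
  out <- dplyr::bind_rows(parsed)
  dup <- unique(out$term_id[duplicated(out$term_id)])
  if (length(dup) > 0) {
    stop("duplicate term_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(out, class = c("term_map", class(out)))
}

#' Build a term map from a named list of gene vectors
#'
#' @param sets Named list; each element is a character vector of member genes.
#' @param term_names Optional descriptions (defaults to the term ids).
#' @return A `term_map` tibble.
#' @export
term_map <- function(sets, term_names = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(names(sets) != ""))
  members <- lapply(sets, function(g) unique(trimws(as.character(g))))
  if (any(vapply(members, length, 1L) == 0)) {
    stop("terms with zero members are not allowed", call. = FALSE)
  }
  out <- tibble::tibble(term_id = names(sets),
                        term_name = as.character(term_names),
                        genes = unname(members))
  structure(out, class = c("term_map", class(out)))
}

#' Gene universe from one or more DE tables
#'
#' The default background for overlap and enrichment testing: the union of all
#' gene identifiers present in the supplied tables. The universe can also be
#' supplied explicitly wherever it is consumed, for sensitivity analysis.
#'
#' @param ... `de_table` objects (or character vectors of gene ids).
#' @return Character vector of unique gene identifiers.
#' @export
gene_universe <- function(...) {
  parts <- lapply(list(...), function(x) {
    if (inherits(x, "de_table")) x$gene_id else as.character(x)
  })
  ids <- unique(unlist(parts, use.names = FALSE))
  if (length(ids) == 0) stop("gene universe is empty", call. = FALSE)
  ids
}
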