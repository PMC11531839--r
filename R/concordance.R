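#' Directionality concordance between two signed DEG sets
#'
#' For the genes called in both conditions (direction-blind membership on the
#' union of up and down), counts how many move in the same direction — both up
#' or both down. This is the comparison behind statements such as "55 of the
#' 59 DEGs shared by all conditions changed in the same direction".
#'
#' @param a,b `deg_sets` objects.
#' @param restrict_to Optional character vector; the comparison is restricted
#'   to these genes, which must all be common to `a` and `b`.
#' @return A list of class `concordance_report` with `n_common`,
#'   `n_same_direction`, `fraction_same` (`NA` when no genes are common,
#'   rather than a fabricated 0), and a `per_gene` tibble with each gene's
#'   direction in the two sets.
#' @examples
#' a <- deg_sets("A", up = c("g1", "g2"), down = "g3")
#' b <- deg_sets("B", up = "g1", down = c("g2", "g3"))
#' directionality_concordance(a, b)  # 2 of 3 concordant
#' @export
directionality_concordance <- function(a, b, restrict_to = NULL) {
  stopifnot(inherits(a, "deg_sets"), inherits(b, "deg_sets"))
  common <- intersect(all_degs(a), all_degs(b))
  if (!is.null(restrict_to)) {
    restrict_to <- unique(as.character(restrict_to))
    outside <- setdiff(restrict_to, common)
    if (length(outside) > 0) {
      stop("restrict_to contains genes not common to both sets: ",
           paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
    }
    common <- restrict_to
  }
  sign_a <- ifelse(common %in% a$up, "up", "down")
  sign_b <- ifelse(common %in% b$up, "up", "down")
  per_gene <- tibble::tibble(gene_id = common, sign_a = sign_a,
                             sign_b = sign_b, same = sign_a == sign_b)
  n_common <- length(common)
  n_same <- sum(per_gene$same)
  structure(list(
    label_a = a$condition_label,
    label_b = b$condition_label,
    n_common = n_common,
    n_same_direction = n_same,
    fraction_same = if (n_common > 0) n_same / n_common else NA_real_,
    per_gene = per_gene
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Directionality concordance:", x$label_a, "vs", x$label_b, "\n")
  cat(sprintf("  %d common genes, %d same direction (fraction %s)\n",
              x$n_common, x$n_same_direction,
              ifelse(is.na(x$fraction_same), "undefined",
                     format(x$fraction_same, digits = 3))))
  invisible(x)
}

#' @method tidy concordance_report
#' @export
tidy.concordance_report <- function(x, ...) x$per_gene

#' @method glance concordance_report
#' @export
glance.concordance_report <- function(x, ...) {
  tibble::tibble(label_a = x$label_a, label_b = x$label_b,
                 n_common = x$n_common,
                 n_same_direction = x$n_same_direction,
                 fraction_same = x$fraction_same)
}

#' Mean expression amplitude of a gene set across contrasts
#'
#' Arithmetic mean and standard deviation of log2 fold-change over a fixed
#' gene set, one row per DE table — the quantity plotted when asking whether a
#' combined treatment amplifies the response of the genes shared by all
#' conditions. Every gene must be present in every table.
#'
#' @param gene_ids Character vector of genes to average.
#' @param tables List of `de_table` objects (names become contrast labels).
#' @return Tibble with columns `contrast`, `n_genes`, `mean_log2fc`,
#'   `sd_log2fc` (0 for a single gene).
#' @export
mean_amplitude <- function(gene_ids, tables) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0) stop("empty gene set", call. = FALSE)
  if (inherits(tables, "de_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, TRUE, "de_table")))
  labels <- names(tables)
  if (is.null(labels)) {
    labels <- vapply(tables, function(t) attr(t, "contrast_label"), "")
  }
  rows <- purrr::map2(tables, labels, function(tab, lab) {
    missing <- setdiff(gene_ids, tab$gene_id)
    if (length(missing) > 0) {
      stop("gene(s) absent from table ", lab, ": ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    fc <- tab$log2fc[match(gene_ids, tab$gene_id)]
    tibble::tibble(contrast = lab, n_genes = length(gene_ids),
                   mean_log2fc = mean(fc),
                   sd_log2fc = if (length(fc) > 1) stats::sd(fc) else 0)
  })
  dplyr::bind_rows(rows)
}

#' Transcriptome-proteome fold-change concordance
#'
#' Pairs per-gene mRNA log2 fold-changes with protein log2 fold-changes on the
#' shared identifiers, classifies each gene into a sign quadrant (both up,
#' both down, or one of the two discordant quadrants, e.g. lower mRNA with
#' higher protein), and summarises agreement with a Spearman rank correlation.
#'
#' @param mrna A `de_table` of mRNA fold-changes.
#' @param protein Data frame with columns `gene_id` and `log2fc` (protein).
#' @return List of class `omic_concordance`: `per_gene` tibble (`gene_id`,
#'   `mrna_log2fc`, `protein_log2fc`, `quadrant`), `n_common`,
#'   `spearman_rho`, and `quadrant_counts`.
#' @export
omic_fc_concordance <- function(mrna, protein) {
  stopifnot(inherits(mrna, "de_table"), is.data.frame(protein))
  if (!all(c("gene_id", "log2fc") %in% names(protein))) {
    stop("protein table needs columns gene_id and log2fc", call. = FALSE)
  }
  protein <- dplyr::distinct(tibble::as_tibble(protein), .data$gene_id,
                             .keep_all = TRUE)
  common <- intersect(mrna$gene_id, protein$gene_id)
  if (length(common) == 0) {
    stop("no shared gene identifiers between mRNA and protein tables",
         call. = FALSE)
  }
  m <- mrna$log2fc[match(common, mrna$gene_id)]
  p <- protein$log2fc[match(common, protein$gene_id)]
  quadrant <- dplyr::case_when(
    m > 0 & p > 0 ~ "both_up",
    m < 0 & p < 0 ~ "both_down",
    m > 0 & p < 0 ~ "mrna_up_protein_down",
    m < 0 & p > 0 ~ "mrna_down_protein_up",
    TRUE ~ "neutral"
  )
  per_gene <- tibble::tibble(gene_id = common, mrna_log2fc = m,
                             protein_log2fc = p, quadrant = quadrant)
  rho <- if (length(common) > 1) {
    stats::cor(m, p, method = "spearman")
  } else NA_real_
  structure(list(per_gene = per_gene,
                 n_common = length(common),
                 spearman_rho = rho,
                 quadrant_counts = table(quadrant)),
            class = "omic_concordance")
}

#' @export
print.omic_concordance <- function(x, ...) {
  cat("mRNA vs protein fold-change concordance:", x$n_common,
      "shared genes\n  Spearman rho:", format(x$spearman_rho, digits = 3), "\n")
  print(x$quadrant_counts)
  invisible(x)
}

#' @method tidy omic_concordance
#' @export
tidy.omic_concordance <- function(x, ...) x$per_gene

#' @method glance omic_concordance
#' @export
glance.omic_concordance <- function(x, ...) {
  qc <- as.list(x$quadrant_counts)
  tibble::tibble(n_common = x$n_common, spearman_rho = x$spearman_rho,
                 n_both_up = qc[["both_up"]] %||% 0L,
                 n_both_down = qc[["both_down"]] %||% 0L,
                 n_discordant = x$n_common -
                   (qc[["both_up"]] %||% 0L) - (qc[["both_down"]] %||% 0L))
}

#' Relative expression from qPCR crossing points
#'
#' Computes, per sample, `deltaCp = Cp(reference) - Cp(gene)` and relative
#' expression `2^deltaCp` against a reference gene, assuming a PCR efficiency
#' of 2.
#'
#' @param data Data frame with columns `sample`, `gene`, `cp`.
#' @param reference_gene Name of the reference gene (must be measured in every
#'   sample).
#' @return Tibble with `sample`, `gene`, `delta_cp`, `rel_expr` for the
#'   non-reference genes.
#' @export
relative_expression <- function(data, reference_gene) {
  stopifnot(is.data.frame(data),
            all(c("sample", "gene", "cp") %in% names(data)))
  data <- tibble::as_tibble(data)
  ref <- dplyr::filter(data, .data$gene == reference_gene)
  if (nrow(ref) == 0) {
    stop("reference gene not found: ", reference_gene, call. = FALSE)
  }
  missing_ref <- setdiff(unique(data$sample), ref$sample)
  if (length(missing_ref) > 0) {
    stop("reference gene missing in sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  data |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::left_join(dplyr::select(ref, "sample", ref_cp = "cp"),
                     by = "sample") |>
    dplyr::mutate(delta_cp = .data$ref_cp - .data$cp,
                  rel_expr = 2^.data$delta_cp) |>
    dplyr::select("sample", "gene", "delta_cp", "rel_expr")
}
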