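#' Call signed DEG sets from a DE table
#'
#' Splits a contrast's genes into up- and down-regulated DEG sets using strict
#' inequalities: a gene is *up* iff `log2fc > fc_threshold` and
#' `adj_p < p_threshold`, and *down* iff `log2fc < -fc_threshold` and
#' `adj_p < p_threshold`. The defaults (0.585 on the log2 scale, i.e. a 1.5-fold
#' change, and adjusted p 0.05) are the cutoffs used throughout the combined
#' hypoxia/flg22 analysis this package supports. The fold-change cutoff is
#' treated as the literal printed value, not recomputed as `log2(1.5)`.
#'
#' Genes with a missing adjusted p-value never pass either threshold; genes
#' sitting exactly on a threshold are excluded (strict inequality).
#'
#' @param table A `de_table` (see [as_de_table()]).
#' @param fc_threshold Positive log2 fold-change cutoff. Default 0.585.
#' @param p_threshold Adjusted-p cutoff in (0, 1]. Default 0.05.
#' @param condition_label Label for the resulting set; defaults to the table's
#'   contrast label.
#' @return An object of class `deg_sets`: a list with `condition_label`,
#'   character vectors `up` and `down`, and `thresholds`.
#' @examples
#' tab <- as_de_table(data.frame(
#'   gene_id = c("g1", "g2", "g3"),
#'   log2fc = c(0.60, 0.585, -1.2),
#'   adj_p = c(0.01, 0.001, 0.04)))
#' call_degs(tab)  # g1 up, g2 excluded on the boundary, g3 down
#' @export
call_degs <- function(table, fc_threshold = 0.585, p_threshold = 0.05,
                      condition_label = NULL) {
  stopifnot(inherits(table, "de_table"))
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1 ||
      fc_threshold <= 0) {
    stop("fc_threshold must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must be a single number in (0, 1]", call. = FALSE)
  }
  if (is.null(condition_label)) {
    condition_label <- attr(table, "contrast_label") %||% "condition"
  }
  sig <- !is.na(table$adj_p) & table$adj_p < p_threshold
  up <- table$gene_id[sig & table$log2fc > fc_threshold]
  down <- table$gene_id[sig & table$log2fc < -fc_threshold]
  new_deg_sets(condition_label, up, down,
               list(fc_threshold = fc_threshold, p_threshold = p_threshold))
}

#' Call DEGs at the external-dataset cutoff
#'
#' Convenience wrapper for the stricter cutoff used when comparing against
#' published hypoxia datasets: `|log2(FC)| > 1.0` and FDR < 0.05. The resulting
#' sets are always subsets of those called by [call_degs()] at the default
#' 0.585 cutoff on the same table.
#'
#' @inheritParams call_degs
#' @return A `deg_sets` object.
#' @export
hypoxia_style_degs <- function(table, p_threshold = 0.05,
                               condition_label = NULL) {
  call_degs(table, fc_threshold = 1.0, p_threshold = p_threshold,
            condition_label = condition_label)
}

new_deg_sets <- function(condition_label, up, down, thresholds) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  clash <- intersect(up, down)
  if (length(clash) > 0) {
    stop("genes cannot be both up and down: ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(condition_label = as.character(condition_label)[1],
                 up = up, down = down, thresholds = thresholds),
            class = "deg_sets")
}

#' Construct a signed DEG set directly from gene vectors
#'
#' Mostly useful for tests and for published gene lists that arrive without an
#' underlying DE table. `up` and `down` must be disjoint.
#'
#' @param condition_label Label for the condition.
#' @param up,down Character vectors of gene identifiers.
#' @param thresholds Optional record of the cutoffs that produced the sets.
#' @return A `deg_sets` object.
#' @export
deg_sets <- function(condition_label, up = character(), down = character(),
                     thresholds = list(fc_threshold = NA_real_,
                                       p_threshold = NA_real_)) {
  new_deg_sets(condition_label, up, down, thresholds)
}

#' All DEGs of a signed set, direction-blind
#'
#' @param x A `deg_sets` object.
#' @return Character vector, the union of the up and down sets.
#' @export
all_degs <- function(x) {
  stopifnot(inherits(x, "deg_sets"))
  union(x$up, x$down)
}

#' @export
print.deg_sets <- function(x, ...) {
  cat("Signed DEG set:", x$condition_label, "\n",
      " up: ", length(x$up), " genes; down: ", length(x$down),
      " genes; all: ", length(all_degs(x)), "\n", sep = "")
  if (!is.na(x$thresholds$fc_threshold)) {
    cat("  cutoffs: |log2FC| > ", x$thresholds$fc_threshold,
        ", adj p < ", x$thresholds$p_threshold, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a signed DEG set into a long tibble
#'
#' @param x A `deg_sets` object.
#' @param ... Unused.
#' @return Tibble with columns `condition`, `gene_id`, `direction`.
#' @method tidy deg_sets
#' @export
tidy.deg_sets <- function(x, ...) {
  tibble::tibble(
    condition = x$condition_label,
    gene_id = c(x$up, x$down),
    direction = rep(c("up", "down"), c(length(x$up), length(x$down)))
  )
}

#' One-row summary of a signed DEG set
#'
#' @param x A `deg_sets` object.
#' @param ... Unused.
#' @return Tibble with the condition label, per-direction counts and cutoffs.
#' @method glance deg_sets
#' @export
glance.deg_sets <- function(x, ...) {
  tibble::tibble(
    condition = x$condition_label,
    n_up = length(x$up),
    n_down = length(x$down),
    n_all = length(all_degs(x)),
    fc_threshold = x$thresholds$fc_threshold,
    p_threshold = x$thresholds$p_threshold
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
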