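#' Chi-squared test of overlap between two gene sets
#'
#' Tests whether two gene sets overlap more (or less) than expected by chance
#' within a common universe, via a 2x2 contingency table of membership
#' indicators (in both, A only, B only, neither) and a Pearson chi-squared
#' test with 1 df. No continuity correction by default; set `correct = TRUE`
#' for Yates' correction.
#'
#' @param set_a,set_b Character vectors of gene identifiers; both must be
#'   contained in `universe`.
#' @param universe Character vector, the background gene collection (see
#'   [gene_universe()]).
#' @param correct Apply Yates' continuity correction? Default `FALSE`.
#' @return A list of class `overlap_test`: `table` (2x2 matrix),
#'   `chi2_stat`, `df`, `p_value`, `n_overlap`, `expected_overlap`,
#'   `universe_size`.
#' @examples
#' u <- sprintf("g%03d", 1:500)
#' overlap_chisq(u[1:60], u[41:120], u)
#' @export
overlap_chisq <- function(set_a, set_b, universe, correct = FALSE) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) > 0 || length(out_b) > 0) {
    stop("set not contained in universe; e.g. ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "),
         call. = FALSE)
  }
  n11 <- length(intersect(set_a, set_b))
  n10 <- length(set_a) - n11
  n01 <- length(set_b) - n11
  n00 <- length(universe) - n11 - n10 - n01
  tab <- matrix(c(n11, n10, n01, n00), nrow = 2, byrow = TRUE,
                dimnames = list(in_a = c("yes", "no"),
                                in_b = c("yes", "no")))
  ht <- stats::chisq.test(tab, correct = correct)
  structure(list(
    table = tab,
    chi2_stat = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    n_overlap = n11,
    expected_overlap = length(set_a) * length(set_b) / length(universe),
    universe_size = length(universe),
    correct = correct
  ), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Chi-squared overlap test (1 df",
      if (x$correct) ", Yates-corrected" else "", ")\n", sep = "")
  cat(sprintf("  overlap %d (expected %.1f) in universe of %d\n",
              x$n_overlap, x$expected_overlap, x$universe_size))
  cat(sprintf("  X-squared = %.4g, p = %.4g\n", x$chi2_stat, x$p_value))
  invisible(x)
}

#' @method tidy overlap_test
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::tibble(n_overlap = x$n_overlap,
                 expected_overlap = x$expected_overlap,
                 statistic = x$chi2_stat, df = x$df, p.value = x$p_value,
                 universe_size = x$universe_size)
}

#' Hypergeometric term enrichment with BH correction
#'
#' For each term, tests over-representation of its members in the query set
#' with a one-sided (upper-tail) hypergeometric test — the classical
#' GO-enrichment model — and adjusts p-values across terms with the
#' Benjamini-Hochberg procedure. Term membership is intersected with the
#' universe before testing.
#'
#' @param query Character vector of query genes; must be contained in
#'   `universe`.
#' @param universe Character vector, the background gene collection.
#' @param terms A `term_map` (see [read_gmt()], [term_map()]).
#' @param alpha Significance level for the `significant` flag. Default 0.05.
#' @return A tibble of class `enrichment_result`, sorted by adjusted p:
#'   `term_id`, `term_name`, `k` (overlap), `K` (term size in universe),
#'   `n` (query size), `N` (universe size), `p_value`, `adjusted_p`,
#'   `significant`.
#' @export
enrich_terms <- function(query, universe, terms, alpha = 0.05) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  stopifnot(inherits(terms, "term_map"))
  if (length(query) == 0) stop("empty query set", call. = FALSE)
  if (nrow(terms) == 0) stop("empty term map", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop("query not contained in universe; e.g. ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::pmap(list(terms$term_id, terms$term_name, terms$genes),
                      function(id, name, genes) {
    members <- intersect(genes, universe)
    K <- length(members)
    k <- length(intersect(members, query))
    # upper tail: P(X >= k) for X ~ Hypergeom(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term_id = id, term_name = name,
                   k = k, K = K, n = n, N = N, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < alpha
  out <- dplyr::arrange(out, .data$adjusted_p, .data$p_value)
  structure(out, class = c("enrichment_result", class(out)))
}
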