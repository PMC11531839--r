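#' Crosstalk scores between single and combined stress programs
#'
#' Three metrics characterise how a combined treatment's transcriptional
#' program (AB) relates to the programs of the two stresses applied alone
#' (A and B):
#'
#' * **Similarity** of the two single-stress programs:
#'   `|A ∩ B| / |A ∪ B|` (Jaccard index). 1 iff the programs are identical
#'   and non-empty; 0 iff disjoint.
#' * **Suppression**: `|B ∩ AB| / |B| - |A ∩ AB| / |A|`, the difference in
#'   how completely each single-stress program is retained under the combined
#'   treatment. Ranges over \[-1, 1\] and is antisymmetric in (A, B). With the
#'   convention A = dominating (abiotic) stress and B = suppressed (biotic)
#'   stress, a negative score means A suppresses B's program.
#' * **Novel interaction**: `|AB \\ (A ∪ B)| / |AB|`, the fraction of the
#'   combined program seen under neither single stress. 1 iff AB is non-empty
#'   and entirely new.
#'
#' The formula behind each score can be swapped via the `formula` argument of
#' the individual score functions, should a variant definition be preferred.
#'
#' @param a,b Character vectors: DEG sets of the two single stresses
#'   (A = dominating, B = suppressed by convention).
#' @param ab Character vector: DEG set of the combined stress.
#' @param formula Optional replacement function implementing a variant score;
#'   it receives the same sets and must return a scalar.
#' @return A single numeric score.
#' @examples
#' similarity_score(c("a", "b", "c"), c("b", "c", "d"))      # 0.5
#' suppression_score(a = "x", b = c("p", "q"), ab = c("x"))  # -1
#' novel_interaction_score("a", "b", ab = c("a", "n1", "n2"))
#' @export
similarity_score <- function(a, b, formula = NULL) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) {
    stop("similarity undefined: both sets empty", call. = FALSE)
  }
  if (!is.null(formula)) return(formula(a, b))
  length(intersect(a, b)) / length(union(a, b))
}

#' @rdname similarity_score
#' @export
suppression_score <- function(a, b, ab, formula = NULL) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  ab <- unique(as.character(ab))
  if (length(a) == 0 || length(b) == 0) {
    stop("suppression undefined: empty single-stress set", call. = FALSE)
  }
  if (!is.null(formula)) return(formula(a, b, ab))
  length(intersect(b, ab)) / length(b) - length(intersect(a, ab)) / length(a)
}

#' @rdname similarity_score
#' @export
novel_interaction_score <- function(a, b, ab, formula = NULL) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  ab <- unique(as.character(ab))
  if (length(ab) == 0) {
    stop("novel-interaction undefined: empty combined set", call. = FALSE)
  }
  if (!is.null(formula)) return(formula(a, b, ab))
  length(setdiff(ab, union(a, b))) / length(ab)
}

#' Crosstalk scores from summary counts
#'
#' Count-level forms of the three scores, for use with published region
#' counts when the underlying gene lists are unavailable.
#'
#' @param n_a,n_b Set sizes `|A|`, `|B|`.
#' @param n_overlap Intersection size `|A ∩ B|`.
#' @param n_a_ab,n_b_ab Overlaps of each single-stress set with the combined
#'   set, `|A ∩ AB|` and `|B ∩ AB|`.
#' @param n_novel Count of combined-only genes, `|AB \\ (A ∪ B)|`.
#' @param n_ab Combined-set size `|AB|`.
#' @return A single numeric score.
#' @examples
#' # printed all-DEG counts: hypoxia 145, flg22 1906, combined 2612
#' suppression_from_counts(n_a = 145, n_b = 1906, n_a_ab = 131, n_b_ab = 1601)
#' novel_from_counts(n_novel = 939, n_ab = 2612)
#' @export
similarity_from_counts <- function(n_a, n_b, n_overlap) {
  check_count(n_a); check_count(n_b); check_count(n_overlap)
  if (n_overlap > min(n_a, n_b)) {
    stop("overlap exceeds a set size", call. = FALSE)
  }
  if (n_a + n_b == 0) stop("similarity undefined: both sets empty",
                           call. = FALSE)
  n_overlap / (n_a + n_b - n_overlap)
}

#' @rdname similarity_from_counts
#' @export
suppression_from_counts <- function(n_a, n_b, n_a_ab, n_b_ab) {
  check_count(n_a); check_count(n_b); check_count(n_a_ab); check_count(n_b_ab)
  if (n_a == 0 || n_b == 0) {
    stop("suppression undefined: empty single-stress set", call. = FALSE)
  }
  if (n_a_ab > n_a || n_b_ab > n_b) {
    stop("overlap exceeds a set size", call. = FALSE)
  }
  n_b_ab / n_b - n_a_ab / n_a
}

#' @rdname similarity_from_counts
#' @export
novel_from_counts <- function(n_novel, n_ab) {
  check_count(n_novel); check_count(n_ab)
  if (n_ab == 0) stop("novel-interaction undefined: empty combined set",
                      call. = FALSE)
  if (n_novel > n_ab) stop("novel count exceeds combined-set size",
                           call. = FALSE)
  n_novel / n_ab
}

check_count <- function(x) {
  nm <- deparse(substitute(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != round(x)) {
    stop(nm, " must be a single non-negative integer", call. = FALSE)
  }
  invisible(x)
}

#' Full crosstalk report across directions
#'
#' Computes similarity, suppression and novel-interaction scores separately
#' for the up-regulated sets, the down-regulated sets, and all DEGs
#' (direction-blind), together with the component counts each score used.
#' Per-direction scores compare like with like (up with up, down with down);
#' genes that flip direction between conditions enter only the direction-blind
#' row. Because the field has used "similarity" both for the two single
#' stresses and for each single stress against the combined one, all three
#' pairings are reported (`similarity`, `similarity_a_ab`, `similarity_b_ab`).
#'
#' @param a,b `deg_sets` for the single stresses (A = dominating,
#'   B = suppressed by convention).
#' @param ab `deg_sets` for the combined stress.
#' @return A tibble of class `crosstalk_scores`, one row per direction
#'   (`up`, `down`, `all`), with score columns and component counts
#'   (`n_a`, `n_b`, `n_ab`, `n_a_ab`, `n_b_ab`, `n_novel`).
#' @examples
#' a <- deg_sets("HM", up = c("g1", "g2"), down = "g3")
#' b <- deg_sets("NF", up = c("g2", "g4"), down = c("g3", "g5"))
#' ab <- deg_sets("HF", up = c("g2", "g4", "g9"), down = "g3")
#' crosstalk_report(a, b, ab)
#' @export
crosstalk_report <- function(a, b, ab) {
  stopifnot(inherits(a, "deg_sets"), inherits(b, "deg_sets"),
            inherits(ab, "deg_sets"))
  labs <- c(a$condition_label, b$condition_label, ab$condition_label)
  if (anyDuplicated(labs)) {
    stop("condition labels must be distinct: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  one_direction <- function(dir) {
    sa <- if (dir == "all") all_degs(a) else a[[dir]]
    sb <- if (dir == "all") all_degs(b) else b[[dir]]
    sab <- if (dir == "all") all_degs(ab) else ab[[dir]]
    tibble::tibble(
      direction = dir,
      similarity = similarity_score(sa, sb),
      similarity_a_ab = similarity_score(sa, sab),
      similarity_b_ab = similarity_score(sb, sab),
      suppression = suppression_score(sa, sb, sab),
      novel_interaction = novel_interaction_score(sa, sb, sab),
      n_a = length(sa), n_b = length(sb), n_ab = length(sab),
      n_a_ab = length(intersect(sa, sab)),
      n_b_ab = length(intersect(sb, sab)),
      n_novel = length(setdiff(sab, union(sa, sb)))
    )
  }
  out <- dplyr::bind_rows(lapply(c("up", "down", "all"), one_direction))
  structure(out,
            conditions = c(a = labs[1], b = labs[2], ab = labs[3]),
            class = c("crosstalk_scores", class(out)))
}

#' @export
print.crosstalk_scores <- function(x, ...) {
  conds <- attr(x, "conditions")
  cat(sprintf("# Crosstalk scores: A = %s, B = %s, combined = %s\n",
              conds[["a"]], conds[["b"]], conds[["ab"]]))
  NextMethod()
}

#' One-row summary of a crosstalk report
#'
#' @param x A `crosstalk_scores` tibble.
#' @param ... Unused.
#' @return Tibble with the direction-blind scores and condition labels.
#' @method glance crosstalk_scores
#' @export
glance.crosstalk_scores <- function(x, ...) {
  conds <- attr(x, "conditions")
  row <- x[x$direction == "all", ]
  tibble::tibble(condition_a = conds[["a"]], condition_b = conds[["b"]],
                 condition_ab = conds[["ab"]],
                 similarity = row$similarity,
                 suppression = row$suppression,
                 novel_interaction = row$novel_interaction)
}
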