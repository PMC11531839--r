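#' Disjoint Venn partition of 2 or 3 labeled gene sets
#'
#' Partitions the union of the input sets into their disjoint membership
#' regions ("A only", "A and B only", ..., triple overlap) with both counts
#' and member lists. Region labels are the set labels joined by `&` in input
#' order; every one of the `2^k - 1` regions is reported, including empty ones.
#'
#' @param sets Named list of 2 or 3 character vectors of gene identifiers.
#'   Names are the set labels and must be distinct.
#' @return A tibble of class `venn_partition` with columns `region` and
#'   `count`, list-column `members`, and attributes `labels` and
#'   `mode = "members"`.
#' @examples
#' venn_partition(list(A = c("a", "b"), B = c("b", "c"), AB = c("b", "c", "d")))
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets))
  k <- length(sets)
  if (k < 2 || k > 3) stop("need 2 or 3 sets", call. = FALSE)
  labels <- names(sets)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    stop("sets must carry distinct non-empty labels", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(g) universe %in% g,
                       logical(length(universe)))
  if (length(universe) == 0) {
    membership <- matrix(logical(0), nrow = 0, ncol = k)
  }
  membership <- matrix(membership, ncol = k)

  regs <- region_patterns(k)
  rows <- lapply(regs, function(pat) {
    in_region <- rep(TRUE, length(universe))
    for (j in seq_len(k)) {
      in_region <- in_region & (membership[, j] == pat[j])
    }
    members <- universe[in_region]
    tibble::tibble(region = paste(labels[pat], collapse = "&"),
                   count = length(members),
                   members = list(members))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, labels = labels, mode = "members",
            class = c("venn_partition", class(out)))
}

# All non-empty membership patterns over k sets, smallest subsets first.
region_patterns <- function(k) {
  pats <- list()
  for (size in 1:k) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      pat <- rep(FALSE, k)
      pat[idx] <- TRUE
      pats[[length(pats) + 1]] <- pat
    }
  }
  pats
}

#' Three-set Venn partition from published summary counts
#'
#' Reconstructs the seven disjoint region counts from the numbers a paper
#' typically prints: the three set totals, the three pairwise overlaps, and
#' the triple overlap. Pairwise overlaps are interpreted as *including* the
#' triple overlap (the standard `|A ∩ B|`); region counts follow by
#' inclusion-exclusion, e.g. C-only `= |C| - |A∩C| - |B∩C| + |A∩B∩C|`. An
#' inconsistent input (any region negative) is an error.
#'
#' @param totals Numeric vector of length 3: `|A|`, `|B|`, `|C|`. Names, if
#'   present, become the set labels.
#' @param pairwise Numeric vector of length 3: `|A∩B|`, `|A∩C|`, `|B∩C|`.
#' @param triple `|A∩B∩C|`.
#' @param labels Set labels; default from `names(totals)` or `c("A","B","C")`.
#' @return A count-only `venn_partition` (no member lists).
#' @examples
#' # printed all-DEG counts for hypoxia (HM), flg22 (NF), combined (HF):
#' venn3_from_counts(c(HM = 145, NF = 1906, HF = 2612),
#'                   pairwise = c(60, 131, 1601), triple = 59)
#' @export
venn3_from_counts <- function(totals, pairwise, triple,
                              labels = names(totals)) {
  stopifnot(length(totals) == 3, length(pairwise) == 3, length(triple) == 1)
  vals <- c(totals, pairwise, triple)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(labels)) labels <- c("A", "B", "C")
  if (anyDuplicated(labels)) stop("duplicate labels", call. = FALSE)
  nA <- totals[[1]]; nB <- totals[[2]]; nC <- totals[[3]]
  nAB <- pairwise[[1]]; nAC <- pairwise[[2]]; nBC <- pairwise[[3]]
  nABC <- triple[[1]]

  counts <- c(
    nA - nAB - nAC + nABC,   # A only
    nB - nAB - nBC + nABC,   # B only
    nC - nAC - nBC + nABC,   # C only
    nAB - nABC,              # A&B only
    nAC - nABC,              # A&C only
    nBC - nABC,              # B&C only
    nABC                     # triple
  )
  if (any(counts < 0)) {
    stop("inconsistent overlap counts: a Venn region would be negative",
         call. = FALSE)
  }
  regions <- vapply(region_patterns(3),
                    function(p) paste(labels[p], collapse = "&"), "")
  # region_patterns orders singles, pairs, triple — same order as `counts`
  out <- tibble::tibble(region = regions, count = as.integer(counts))
  structure(out, labels = labels, mode = "counts",
            class = c("venn_partition", class(out)))
}

#' Summary counts (marginals, pairwise, triple) of a Venn partition
#'
#' Inverse of [venn3_from_counts()]: recovers each set's total and the
#' pairwise/triple intersection sizes from the disjoint region counts.
#'
#' @param x A `venn_partition`.
#' @return A list with `totals`, `pairwise` (for 3 sets, in the order A&B,
#'   A&C, B&C) and `triple` (3 sets only).
#' @export
venn_marginals <- function(x) {
  stopifnot(inherits(x, "venn_partition"))
  labels <- attr(x, "labels")
  k <- length(labels)
  has <- function(lab) vapply(strsplit(x$region, "&", fixed = TRUE),
                              function(r) lab %in% r, TRUE)
  totals <- vapply(labels, function(l) sum(x$count[has(l)]), 0)
  if (k == 2) return(list(totals = totals,
                          pairwise = sum(x$count[has(labels[1]) & has(labels[2])])))
  pair_idx <- utils::combn(k, 2, simplify = FALSE)
  pairwise <- vapply(pair_idx, function(ij) {
    sum(x$count[has(labels[ij[1]]) & has(labels[ij[2]])])
  }, 0)
  names(pairwise) <- vapply(pair_idx,
                            function(ij) paste(labels[ij], collapse = "&"), "")
  triple <- sum(x$count[has(labels[1]) & has(labels[2]) & has(labels[3])])
  list(totals = totals, pairwise = pairwise, triple = triple)
}

#' Count or members of a single Venn region
#'
#' @param x A `venn_partition`.
#' @param region Region label, e.g. `"HF"` or `"NF&HF"`. Order of labels
#'   within the region does not matter.
#' @return `region_count()`: integer. `region_members()`: character vector
#'   (member mode only).
#' @export
region_count <- function(x, region) {
  x$count[match_region(x, region)]
}

#' @rdname region_count
#' @export
region_members <- function(x, region) {
  if (!identical(attr(x, "mode"), "members")) {
    stop("partition was built from counts only; no member lists",
         call. = FALSE)
  }
  x$members[[match_region(x, region)]]
}

match_region <- function(x, region) {
  stopifnot(inherits(x, "venn_partition"), length(region) == 1)
  want <- sort(strsplit(region, "&", fixed = TRUE)[[1]])
  keys <- vapply(strsplit(x$region, "&", fixed = TRUE),
                 function(r) paste(sort(r), collapse = "&"), "")
  i <- match(paste(want, collapse = "&"), keys)
  if (is.na(i)) stop("no such region: ", region, call. = FALSE)
  i
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("# Venn partition of sets:", paste(attr(x, "labels"), collapse = ", "),
      sprintf("(%s mode)\n", attr(x, "mode")))
  NextMethod()
}

#' @method tidy venn_partition
#' @export
tidy.venn_partition <- function(x, ...) {
  tibble::as_tibble(x[, c("region", "count")])
}
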