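#' Specification for a synthetic combined-stress experiment
#'
#' Defines the generative model for three DE tables — two single stresses
#' (A, B) and the combined stress (AB) — with known crosstalk structure, so
#' that DEG calling, set algebra and the crosstalk scores can all be validated
#' against ground truth. The model works at the DE-table level (log2
#' fold-changes and adjusted p-values), not raw counts, because that is the
#' level the crosstalk analysis consumes.
#'
#' The generative steps: `n_deg_b * similarity_overlap` genes are shared
#' between the A and B programs; each A DEG survives into the combined
#' program independently with probability `retention_a`, each B DEG with
#' `retention_b` (a shared gene survives if either of its two chances does);
#' novel combined-only genes are drawn from the null pool in the number that
#' makes the expected novel fraction of AB equal `novelty`. Directions are
#' assigned up with probability `prop_up`, carried by the gene across tables.
#' DEG rows receive `|log2fc|` above the calling threshold and adjusted p
#' below it; null rows receive sub-threshold values — so ground-truth
#' recovery by thresholding is exact unless `noisy_boundary` adds borderline
#' null genes.
#'
#' @param n_genes Universe size. Default 5000.
#' @param n_deg_a,n_deg_b DEG counts of the two single-stress programs.
#'   Default 1000 each.
#' @param similarity_overlap Fraction of B's DEGs shared with A, in \[0, 1\].
#'   Default 0.1.
#' @param retention_a,retention_b Per-gene survival probability of each
#'   program under the combined stress. Defaults 0.9 and 0.8 (the second
#'   stress partially suppressed).
#' @param novelty Target expected fraction of the combined program that is
#'   combined-only, in \[0, 1). Default 0.3.
#' @param prop_up Probability a DEG is up-regulated. Default 0.6.
#' @param effect_size_mean,effect_size_sd Mean and sd (log2 scale) of DEG
#'   effect magnitudes, truncated above the fold-change threshold.
#'   Defaults 2 and 0.75.
#' @param fc_threshold,p_threshold Calling cutoffs the tables are built
#'   around. Defaults 0.585 and 0.05.
#' @param noisy_boundary Add a small fraction of null genes with fold-changes
#'   straddling the threshold (still non-significant by p)? Default `FALSE`.
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 5000,
                           n_deg_a = 1000, n_deg_b = 1000,
                           similarity_overlap = 0.1,
                           retention_a = 0.9, retention_b = 0.8,
                           novelty = 0.3,
                           prop_up = 0.6,
                           effect_size_mean = 2, effect_size_sd = 0.75,
                           fc_threshold = 0.585, p_threshold = 0.05,
                           noisy_boundary = FALSE,
                           seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_deg_a = as.integer(n_deg_a), n_deg_b = as.integer(n_deg_b),
               similarity_overlap = similarity_overlap,
               retention_a = retention_a, retention_b = retention_b,
               novelty = novelty, prop_up = prop_up,
               effect_size_mean = effect_size_mean,
               effect_size_sd = effect_size_sd,
               fc_threshold = fc_threshold, p_threshold = p_threshold,
               noisy_boundary = isTRUE(noisy_boundary),
               seed = as.integer(seed))
  props <- c(spec$similarity_overlap, spec$retention_a, spec$retention_b,
             spec$novelty, spec$prop_up)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  if (spec$novelty >= 1) {
    stop("novelty must be < 1 (a finite novel pool)", call. = FALSE)
  }
  if (spec$n_genes < 1 || spec$n_deg_a < 0 || spec$n_deg_b < 0) {
    stop("gene counts must be non-negative", call. = FALSE)
  }
  n_shared <- round(spec$similarity_overlap * spec$n_deg_b)
  if (n_shared > spec$n_deg_a) {
    stop("infeasible spec: shared genes exceed n_deg_a", call. = FALSE)
  }
  n_single <- spec$n_deg_a + spec$n_deg_b - n_shared
  if (n_single > spec$n_genes) {
    stop("infeasible spec: DEG programs exceed the universe", call. = FALSE)
  }
  if (spec$fc_threshold <= 0 || spec$p_threshold <= 0 ||
      spec$p_threshold > 1) {
    stop("thresholds must be positive (p in (0, 1])", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

# Expected number of single-stress DEGs retained in the combined program.
expected_retained <- function(spec) {
  s <- round(spec$similarity_overlap * spec$n_deg_b)
  q <- 1 - (1 - spec$retention_a) * (1 - spec$retention_b)
  (spec$n_deg_a - s) * spec$retention_a +
    (spec$n_deg_b - s) * spec$retention_b + s * q
}

#' Expectation and sampling error of the crosstalk estimators
#'
#' Closed-form moments of the suppression and novel-interaction estimators
#' under the generative model of [synthetic_spec()], used as the oracle in
#' parameter-recovery tests. With shared genes (`similarity_overlap > 0`) the
#' expected suppression is not exactly `retention_b - retention_a`, because a
#' shared gene survives with probability `1 - (1-r_a)(1-r_b)` and contributes
#' to both retention estimates; the closed form accounts for that, including
#' the covariance the shared genes induce. The novel-fraction moments use a
#' first-order (delta-method) expansion in the retained count.
#'
#' @param spec A `synthetic_spec`.
#' @return Tibble with one row per estimator (`suppression`,
#'   `novel_interaction`, `similarity`) and columns `expectation`, `se`.
#' @export
expected_scores <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  s <- round(spec$similarity_overlap * spec$n_deg_b)
  nA <- spec$n_deg_a; nB <- spec$n_deg_b
  rA <- spec$retention_a; rB <- spec$retention_b
  q <- 1 - (1 - rA) * (1 - rB)

  e_rA <- ((nA - s) * rA + s * q) / nA
  e_rB <- ((nB - s) * rB + s * q) / nB
  v_rA <- ((nA - s) * rA * (1 - rA) + s * q * (1 - q)) / nA^2
  v_rB <- ((nB - s) * rB * (1 - rB) + s * q * (1 - q)) / nB^2
  cov_ab <- s * q * (1 - q) / (nA * nB)
  e_sup <- e_rB - e_rA
  se_sup <- sqrt(v_rB + v_rA - 2 * cov_ab)

  e_R <- expected_retained(spec)
  v_R <- (nA - s) * rA * (1 - rA) + (nB - s) * rB * (1 - rB) +
    s * q * (1 - q)
  m <- round(spec$novelty / (1 - spec$novelty) * e_R)
  e_nov <- m / (m + e_R)
  se_nov <- if (m > 0) m * sqrt(v_R) / (m + e_R)^2 else 0

  e_sim <- s / (nA + nB - s)

  tibble::tibble(
    estimator = c("suppression", "novel_interaction", "similarity"),
    expectation = c(e_sup, e_nov, e_sim),
    se = c(se_sup, se_nov, 0)
  )
}

#' Generate a synthetic combined-stress experiment
#'
#' Realises a [synthetic_spec()] into three validated DE tables (A, B,
#' combined AB) over a common gene universe, plus the per-gene ground truth.
#' Deterministic given the spec's seed: the same spec yields identical
#' tables.
#'
#' @param spec A `synthetic_spec`.
#' @return A list of class `synthetic_experiment`: `tables` (named list of
#'   `de_table`: `A`, `B`, `AB`), `ground_truth` (tibble: `gene_id`, `class`
#'   in A-only / B-only / shared / AB-novel / null, `direction`,
#'   `retained_in_ab`), `region_counts` (realised 7-region Venn counts of the
#'   true DEG sets), and `spec`.
#' @examples
#' exp <- generate_experiment(synthetic_spec(n_genes = 300, n_deg_a = 40,
#'                                           n_deg_b = 60, seed = 7))
#' glance(call_degs(exp$tables$AB))
#' @export
generate_experiment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  child <- sample.int(.Machine$integer.max - 10L, 6)

  width <- max(5, nchar(spec$n_genes))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(spec$n_genes))

  s <- round(spec$similarity_overlap * spec$n_deg_b)
  n_a_only <- spec$n_deg_a - s
  n_b_only <- spec$n_deg_b - s

  set.seed(child[1])
  deg_pool <- sample(genes, n_a_only + n_b_only + s)
  shared <- deg_pool[seq_len(s)]
  a_only <- deg_pool[s + seq_len(n_a_only)]
  b_only <- deg_pool[s + n_a_only + seq_len(n_b_only)]
  a_genes <- c(shared, a_only)
  b_genes <- c(shared, b_only)

  set.seed(child[2])
  direction <- stats::setNames(
    ifelse(stats::runif(length(deg_pool)) < spec$prop_up, "up", "down"),
    deg_pool)

  # survival into the combined program: independent chance per program,
  # a shared gene survives if either chance succeeds
  set.seed(child[3])
  keep_a <- a_genes[stats::runif(length(a_genes)) < spec$retention_a]
  keep_b <- b_genes[stats::runif(length(b_genes)) < spec$retention_b]
  retained <- union(keep_a, keep_b)

  null_pool <- setdiff(genes, deg_pool)
  n_novel <- round(spec$novelty / (1 - spec$novelty) * expected_retained(spec))
  if (n_novel > length(null_pool)) {
    stop("infeasible spec: novelty demands ", n_novel,
         " novel genes but the null pool holds ", length(null_pool),
         call. = FALSE)
  }
  set.seed(child[4])
  novel <- if (n_novel > 0) sample(null_pool, n_novel) else character()
  novel_dir <- stats::setNames(
    ifelse(stats::runif(length(novel)) < spec$prop_up, "up", "down"), novel)
  direction <- c(direction, novel_dir)

  ab_genes <- c(retained, novel)

  class_of <- rep("null", spec$n_genes)
  names(class_of) <- genes
  class_of[shared] <- "shared"
  class_of[a_only] <- "A-only"
  class_of[b_only] <- "B-only"
  class_of[novel] <- "AB-novel"

  dir_col <- rep("none", spec$n_genes)
  names(dir_col) <- genes
  dir_col[names(direction)] <- direction

  ground_truth <- tibble::tibble(
    gene_id = genes,
    class = unname(class_of[genes]),
    direction = unname(dir_col[genes]),
    retained_in_ab = genes %in% ab_genes
  )

  tables <- list(
    A = build_table(genes, a_genes, direction, spec, child[5] + 0L, "A"),
    B = build_table(genes, b_genes, direction, spec, child[5] + 1L, "B"),
    AB = build_table(genes, ab_genes, direction, spec, child[5] + 2L, "AB")
  )

  region_counts <- venn_marginals(venn_partition(
    list(A = a_genes, B = b_genes, AB = ab_genes)))

  structure(list(tables = tables, ground_truth = ground_truth,
                 region_counts = region_counts, spec = spec),
            class = "synthetic_experiment")
}

# One DE table over the full universe: DEG rows strictly beyond both
# thresholds, null rows strictly inside them (unless noisy_boundary).
build_table <- function(genes, deg_genes, direction, spec, seed, label) {
  set.seed(seed)
  n <- length(genes)
  is_deg <- genes %in% deg_genes

  log2fc <- stats::runif(n, -0.85 * spec$fc_threshold,
                         0.85 * spec$fc_threshold)
  adj_p <- stats::runif(n, spec$p_threshold, 1)

  n_deg <- sum(is_deg)
  if (n_deg > 0) {
    mag <- stats::rnorm(n_deg, spec$effect_size_mean, spec$effect_size_sd)
    mag <- pmax(mag, spec$fc_threshold + 0.05)
    sgn <- ifelse(direction[genes[is_deg]] == "up", 1, -1)
    log2fc[is_deg] <- sgn * mag
    adj_p[is_deg] <- stats::runif(n_deg, 0, spec$p_threshold * 0.999)
  }

  if (spec$noisy_boundary) {
    null_idx <- which(!is_deg)
    n_border <- ceiling(0.02 * length(null_idx))
    if (n_border > 0) {
      border <- sample(null_idx, n_border)
      jitter <- stats::runif(n_border, -0.05, 0.05)
      log2fc[border] <- sample(c(-1, 1), n_border, replace = TRUE) *
        (spec$fc_threshold + jitter)
    }
  }

  as_de_table(tibble::tibble(gene_id = genes, log2fc = log2fc,
                             adj_p = adj_p),
              contrast_label = label)
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic combined-stress experiment:", x$spec$n_genes, "genes\n")
  cat("  true DEGs: A =", x$spec$n_deg_a, ", B =", x$spec$n_deg_b,
      ", combined =", sum(x$ground_truth$retained_in_ab), "\n")
  print(table(x$ground_truth$class))
  invisible(x)
}

#' Sweep generator settings and collect crosstalk-score estimates
#'
#' Runs [generate_experiment()] over a grid of spec overrides, with
#' `replicates` independent realisations per cell (seeds derived
#' deterministically from the base seed), calls DEGs on each realisation and
#' computes the crosstalk report, and returns one row per realisation with
#' the direction-blind score estimates and their errors against the
#' closed-form expectations of [expected_scores()].
#'
#' @param grid Data frame whose columns are `synthetic_spec()` argument names
#'   and whose rows are the cells to sweep. An empty-column data frame with
#'   one row sweeps the defaults.
#' @param replicates Realisations per cell. Default 1.
#' @param base A `synthetic_spec` supplying every non-swept setting.
#' @return Tibble: grid columns, `replicate`, `seed`, `similarity`,
#'   `suppression`, `novel_interaction`, and `suppression_error` /
#'   `novelty_error` (estimate minus expectation).
#' @export
sweep_experiments <- function(grid, replicates = 1,
                              base = synthetic_spec()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1, replicates >= 1)
  stopifnot(inherits(base, "synthetic_spec"))
  bad <- setdiff(names(grid), names(base))
  if (length(bad) > 0) {
    stop("unknown spec field(s) in grid: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cells <- seq_len(nrow(grid))
  rows <- purrr::map(cells, function(i) {
    purrr::map(seq_len(replicates), function(r) {
      args <- unclass(base)
      for (f in names(grid)) args[[f]] <- grid[[f]][i]
      args$seed <- (base$seed + (i - 1L) * replicates + (r - 1L)) %%
        .Machine$integer.max
      spec <- do.call(synthetic_spec, args)
      exp <- generate_experiment(spec)
      rep_scores <- crosstalk_report(
        call_degs(exp$tables$A, spec$fc_threshold, spec$p_threshold),
        call_degs(exp$tables$B, spec$fc_threshold, spec$p_threshold),
        call_degs(exp$tables$AB, spec$fc_threshold, spec$p_threshold))
      all_row <- rep_scores[rep_scores$direction == "all", ]
      expect <- expected_scores(spec)
      e_sup <- expect$expectation[expect$estimator == "suppression"]
      e_nov <- expect$expectation[expect$estimator == "novel_interaction"]
      dplyr::bind_cols(
        tibble::as_tibble(grid[i, , drop = FALSE]),
        tibble::tibble(replicate = r, seed = spec$seed,
                       similarity = all_row$similarity,
                       suppression = all_row$suppression,
                       novel_interaction = all_row$novel_interaction,
                       suppression_error = all_row$suppression - e_sup,
                       novelty_error = all_row$novel_interaction - e_nov))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
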