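# Shared fixtures built in code.

# A small well-formed DE table covering up / down / boundary / missing-p rows.
demo_de_table <- function() {
  as_de_table(data.frame(
    gene_id = c("AT1G01010", "AT1G01020", "AT1G01030", "AT1G01040",
                "AT1G01050", "AT1G01060"),
    log2fc  = c(0.60, 0.585, -1.2, 2.5, -0.30, 1.8),
    adj_p   = c(0.01, 0.001, 0.04, 0.20, 0.001, NA)
  ), contrast_label = "demo")
}

# Random gene-set triple over a small universe, for property tests.
random_set_triple <- function(universe_size = 50, p = 0.3) {
  genes <- sprintf("g%03d", seq_len(universe_size))
  list(A = genes[runif(universe_size) < p],
       B = genes[runif(universe_size) < p],
       AB = genes[runif(universe_size) < p])
}

# Brute-force Venn oracle: tally every gene's membership pattern directly.
brute_force_venn <- function(sets) {
  genes <- unique(unlist(sets, use.names = FALSE))
  labels <- names(sets)
  counts <- integer(0)
  patterns <- list()
  for (size in seq_along(sets)) {
    for (idx in utils::combn(length(sets), size, simplify = FALSE)) {
      pat <- rep(FALSE, length(sets))
      pat[idx] <- TRUE
      patterns[[paste(labels[pat], collapse = "&")]] <- pat
    }
  }
  sapply(patterns, function(pat) {
    sum(vapply(genes, function(g) {
      all(vapply(seq_along(sets), function(j) {
        (g %in% sets[[j]]) == pat[j]
      }, TRUE))
    }, TRUE))
  })
}
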