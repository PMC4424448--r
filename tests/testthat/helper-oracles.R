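# Independent naive reference implementations used as oracles. These are
# deliberately written as explicit loops over single edges/samples and never
# call the package's vectorized code paths.

# per-sample consistent instances, as a sorted character key vector
oracle_induce_keys <- function(reg, ind, sample_id) {
  keys <- character(0)
  for (r in seq_len(nrow(reg))) {
    A <- reg$source[r]; B <- reg$target[r]; eff <- reg$effect[r]
    a <- if (A %in% rownames(ind)) ind[A, sample_id] else 0L
    b <- if (B %in% rownames(ind)) ind[B, sample_id] else 0L
    consistent <- if (eff == "activation") a == b else a == -b
    if (a != 0L && b != 0L && consistent)
      keys <- c(keys, paste(A, eff, B, a, b, sep = "|"))
  }
  sort(keys)
}

# instance frequency tally by explicit nested iteration
oracle_freq <- function(key_sets) {
  counts <- list()
  for (ks in key_sets)
    for (k in ks)
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
  n <- length(key_sets)
  out <- data.frame(key = names(counts),
                    count = unlist(counts, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / n
  out[order(out$key), , drop = FALSE]
}

oracle_core_keys <- function(freq_df, T) {
  sort(freq_df$key[freq_df$frequency >= T])
}

# brute-force union-find over the genes of an edge list
oracle_components <- function(src, tgt) {
  genes <- sort(unique(c(src, tgt)))
  parent <- stats::setNames(genes, genes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(src)) {
    ra <- find(src[i]); rb <- find(tgt[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(genes, find, character(1))
  split(genes, roots)
}

# key form matching the package's instance identity, from a dera instance df
inst_keys <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$source, df$effect, df$target, df$source_state,
             df$target_state, sep = "|"))
}

# small random test network + indicator matrix (test-local generator,
# independent of the package's synthetic module)
rand_reg <- function(n_genes, n_edges) {
  genes <- paste0("g", seq_len(n_genes))
  data.frame(source = sample(genes, n_edges, replace = TRUE),
             effect = sample(c("activation", "inhibition"), n_edges,
                             replace = TRUE),
             target = sample(genes, n_edges, replace = TRUE),
             stringsAsFactors = FALSE)
}

rand_indicator <- function(genes, n_samples) {
  m <- matrix(sample(c(-1L, 0L, 1L), length(genes) * n_samples,
                     replace = TRUE, prob = c(0.2, 0.6, 0.2)),
              nrow = length(genes),
              dimnames = list(genes, paste0("s", seq_len(n_samples))))
  m
}

as_network <- function(reg) {
  regulatory_network(reg$source, reg$effect, reg$target)
}
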