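# Fixtures are built in code; no data files.

# Minimal hand-written dataset: 1 genotype, 2 genes, 2 times.
tiny_sep <- function() {
  tibble::tibble(
    genotype = rep("G1", 4),
    gene = rep(c("geneA", "geneB"), each = 2),
    time = rep(c(0, 10), 2),
    expression = c(1, 2, 5, 3)
  )
}

# A 12-genotype, 7-time dataset with one 4-gene noiseless module supported
# everywhere, one 3-gene decoy module supported in 3 genotypes, null genes,
# and planted outlier pairs.
demo_sep <- function(seed = 42, n_null = 20, n_outlier_pairs = 0) {
  generate_sep(sim_spec(
    n_null = n_null,
    modules = list(
      list(size = 4, noise_sd = 0),
      list(size = 3, support = c("D1", "D2", "D3"), noise_sd = 0)
    ),
    n_outlier_pairs = n_outlier_pairs,
    seed = seed
  ))
}

# Independent union-find over an edge list (oracle for connected patterns).
uf_components <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges$gene_i[k]); rj <- find(edges$gene_j[k])
    if (ri != rj) parent[[ri]] <- rj
  }
  vapply(nodes, find, character(1))
}

# Textbook Pearson correlation from raw sums (oracle for cor()-based path).
textbook_r <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Hand step-up FDR adjustment (oracle for q_values()).
stepup_q <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

expect_edge_subset <- function(small, big) {
  key <- function(e) paste(e$gene_i, e$gene_j)
  expect_true(all(key(small) %in% key(big)))
}
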