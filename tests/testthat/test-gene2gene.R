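test_that("a noiseless planted module forms a clique; weakly supported pairs do not", {
  d <- demo_sep(seed = 42)  # module 1: 4 genes everywhere; module 2: 3 genes in 3/12
  g <- gene2gene(d, thresholds = gfn_thresholds(x = 12), name = "demo")
  expect_s3_class(g, "gfn")
  expect_setequal(g$nodes$gene, paste0("M1_0", 1:4))
  expect_equal(nrow(g$edges), 6L)
  expect_true(all(g$edges$support == 12L))
  expect_true(all(g$edges$r_bar == 1))
  expect_equal(max(g$nodes$pattern), 1L)
  # the decoy module (support 3) is absent at any x >= 5
  g5 <- gene2gene(d, thresholds = gfn_thresholds(x = 5), name = "demo")
  expect_false(any(grepl("^M2_", g5$nodes$gene)))
  # ... but is recovered at x = 3
  g3 <- gene2gene(d, thresholds = gfn_thresholds(x = 3), name = "demo")
  expect_true(all(paste0("M2_0", 1:3) %in% g3$nodes$gene))
})

test_that("parameter errors are raised for impossible requests", {
  d <- demo_sep(seed = 1, n_null = 4)
  expect_error(gene2gene(d, thresholds = gfn_thresholds(x = 13)),
               "exceeds")
  expect_error(gene2gene(d, genes = character()), "empty input gene list")
})

test_that("a null dataset yields an explicit empty network", {
  d <- null_sep(a = 6, n_times = 7, g = 8, seed = 99)
  g <- gene2gene(d, thresholds = gfn_thresholds(x = 6), name = "null")
  expect_equal(nrow(g$edges), 0L)
  expect_equal(nrow(g$nodes), 0L)
  s <- glance(g)
  expect_equal(s$n_out, 0L)
  expect_true(is.na(s$r_bar) && is.na(s$q_bar))
  expect_match(paste(capture.output(print(g)), collapse = " "), "null output",
               ignore.case = TRUE)
})

test_that("edge sets nest monotonically in x, f and mr2", {
  for (seed in c(5, 17, 31)) {
    d <- generate_sep(sim_spec(
      a = 6, n_null = 10,
      modules = list(list(size = 3, noise_sd = 0.6),
                     list(size = 3, noise_sd = 1.2)),
      seed = seed))
    base <- list(f = 0.3, mr2 = 0.5, q_out = 0.05, x = 3)
    run <- function(f = base$f, mr2 = base$mr2, x = base$x) {
      gene2gene(d, thresholds = gfn_thresholds(f = f, mr2 = mr2,
                                               q_out = base$q_out, x = x))$edges
    }
    e0 <- run()
    expect_edge_subset(run(x = 5), e0)            # larger x shrinks
    expect_edge_subset(run(mr2 = 0.8), e0)        # larger mr2 shrinks
    expect_edge_subset(run(f = 0.05), e0)         # smaller f shrinks
  }
})

test_that("removing a genotype never increases an edge's support", {
  d <- generate_sep(sim_spec(a = 6, n_null = 6,
                             modules = list(list(size = 4, noise_sd = 0.8)),
                             seed = 23))
  all_g <- sep_genotypes(d)
  full <- gene2gene(d, thresholds = gfn_thresholds(f = 0.3, mr2 = 0.5, x = 1))
  part <- gene2gene(d, genotypes = all_g[-1],
                    thresholds = gfn_thresholds(f = 0.3, mr2 = 0.5, x = 1))
  joined <- dplyr::inner_join(part$edges, full$edges,
                              by = c("gene_i", "gene_j"),
                              suffix = c("_part", "_full"))
  expect_true(all(joined$support_part <= joined$support_full))
})

test_that("network output equals a brute-force filter over exported pair tables", {
  d <- demo_sep(seed = 13, n_null = 10)
  th <- gfn_thresholds(f = 0.1, mr2 = 0.7, q_out = 0.05, x = 10)
  g <- gene2gene(d, thresholds = th, name = "bf")
  # export per-genotype pair tables and refilter them independently (base R)
  s <- pair_stats(d, q_out = th$q_out)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_stats(s, path)
  tab <- read.delim(path, comment.char = "#")
  keep <- tab$testable == "TRUE" | tab$testable == TRUE
  tab <- tab[keep & tab$q <= th$f & tab$r^2 >= th$mr2 &
               !(tab$outlier == "TRUE" | tab$outlier == TRUE) & tab$r > 0, ]
  counts <- aggregate(genotype ~ gene_i + gene_j, tab, length)
  bf_edges <- counts[counts$genotype >= th$x, c("gene_i", "gene_j")]
  bf_edges <- bf_edges[order(bf_edges$gene_i, bf_edges$gene_j), ]
  expect_equal(nrow(bf_edges), nrow(g$edges))
  expect_equal(bf_edges$gene_i, g$edges$gene_i)
  expect_equal(bf_edges$gene_j, g$edges$gene_j)
})

test_that("connected patterns match a union-find oracle and are labelled by size", {
  d <- demo_sep(seed = 77, n_null = 12)
  g <- gene2gene(d, thresholds = gfn_thresholds(x = 3))
  expect_gt(nrow(g$edges), 0)
  roots <- uf_components(g$edges, g$nodes$gene)
  # same-partition iff same root
  for (k in seq_len(nrow(g$edges))) {
    expect_equal(roots[[g$edges$gene_i[k]]], roots[[g$edges$gene_j[k]]])
  }
  part <- split(g$nodes$gene, g$nodes$pattern)
  part_uf <- split(g$nodes$gene, roots[g$nodes$gene])
  expect_setequal(lapply(part, sort), lapply(unname(part_uf), sort))
  # labels ordered by decreasing size
  sizes <- vapply(part, length, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("pattern labels are deterministic: ties break on the smallest member gene", {
  edges <- tibble::tibble(gene_i = c("b", "x"), gene_j = c("c", "y"))
  nodes <- c("b", "c", "x", "y")
  pat <- connected_patterns(edges, nodes)
  expect_equal(pat, c(1L, 1L, 2L, 2L))  # {b,c} before {x,y}
  expect_equal(connected_patterns(edges[0, ], character()), integer())
})

test_that("summaries average r and q over edge-by-genotype observations", {
  d <- demo_sep(seed = 42)
  g <- gene2gene(d, thresholds = gfn_thresholds(x = 12), name = "demo")
  s <- glance(g)
  expect_equal(s$n_in, length(g$genes_in))
  expect_equal(s$n_con, 6L)
  expect_equal(s$pct_out, round(100 * s$n_out / s$n_in))
  expect_equal(s$r_bar, mean(g$observations$r))
  expect_equal(s$q_bar, mean(g$observations$q))
  expect_equal(nrow(g$observations), sum(g$edges$support))
  expect_equal(tidy(g), g$edges)
})

test_that("hand-computed edge averages: supports {0.9, 1.0} give r_bar 0.95", {
  obs <- tibble::tibble(gene_i = "a", gene_j = "b", genotype = c("G1", "G2"),
                        r = c(0.9, 1.0), q = c(0.01, 0.02))
  e <- obs |>
    dplyr::summarise(r_bar = mean(r), q_bar = mean(q),
                     .by = c("gene_i", "gene_j"))
  expect_equal(e$r_bar, 0.95)
  expect_equal(e$q_bar, 0.015)
})

test_that("sign policies control which correlations can support an edge", {
  # gene pair perfectly anti-correlated everywhere
  a <- 6
  base <- generate_sep(sim_spec(a = a, n_null = 2, seed = 8))
  flip <- base[base$gene == "N0001", ]
  flip$gene <- "Z001"
  flip$expression <- -flip$expression
  d <- validate_sep(dplyr::bind_rows(base, flip))
  th_pos <- gfn_thresholds(x = a, sign_policy = "positive")
  th_any <- gfn_thresholds(x = a, sign_policy = "any")
  th_con <- gfn_thresholds(x = a, sign_policy = "consistent")
  e_pos <- gene2gene(d, genes = c("N0001", "Z001"), thresholds = th_pos)$edges
  e_any <- gene2gene(d, genes = c("N0001", "Z001"), thresholds = th_any)$edges
  e_con <- gene2gene(d, genes = c("N0001", "Z001"), thresholds = th_con)$edges
  expect_equal(nrow(e_pos), 0L)
  expect_equal(nrow(e_any), 1L)
  expect_equal(e_any$sign, -1L)
  expect_equal(nrow(e_con), 1L)
  expect_equal(e_con$support, a)
})

test_that("sensitivity grids reuse cached correlations and respect monotonicity", {
  d <- demo_sep(seed = 3, n_null = 8)
  # single-cell grid equals a direct run
  tab1 <- sensitivity_grid(d, f_values = 0.1, mr2_values = 0.7,
                           q_out_values = 0.05, x = 12)
  direct <- gene2gene(d, thresholds = gfn_thresholds(x = 12))
  expect_equal(tab1$n_genes, nrow(direct$nodes))
  expect_equal(tab1$n_edges, nrow(direct$edges))
  tab <- sensitivity_grid(d, f_values = c(0.01, 0.05, 0.1, 0.3),
                          mr2_values = c(0.5, 0.7, 0.9),
                          q_out_values = c(0.01, 0.05), x = 6)
  expect_equal(nrow(tab), 4 * 3 * 2)
  mono <- tab |>
    dplyr::arrange(f) |>
    dplyr::summarise(ok = all(diff(n_edges) >= 0), .by = c("mr2", "q_out"))
  expect_true(all(mono$ok))
  expect_true(is.numeric(attr(tab, "cor_genes_edges")))
})

test_that("identical inputs produce byte-identical edge-list exports", {
  d <- demo_sep(seed = 4, n_null = 6)
  g1 <- gene2gene(d, thresholds = gfn_thresholds(x = 12), name = "det")
  g2 <- gene2gene(d, thresholds = gfn_thresholds(x = 12), name = "det")
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_gfn(g1, p1); write_gfn(g2, p2)
  expect_identical(readLines(paste0(p1, ".edges.tsv"))[-1],
                   readLines(paste0(p2, ".edges.tsv"))[-1])
  expect_identical(tools::md5sum(paste0(p1, ".graphml"))[[1]],
                   tools::md5sum(paste0(p2, ".graphml"))[[1]])
})
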