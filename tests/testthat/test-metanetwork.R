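# Two networks over one dataset: module 1 (4 genes) and module 2 (3 genes)
# overlap via gene lists passed to gene2gene.
mn_fixture <- function(seed = 55) {
  d <- generate_sep(sim_spec(
    n_null = 6,
    modules = list(list(size = 4, noise_sd = 0), list(size = 3, noise_sd = 0)),
    seed = seed))
  th <- gfn_thresholds(x = 12)
  g1 <- gene2gene(d, genes = c(paste0("M1_0", 1:4), paste0("N000", 1:3)),
                  thresholds = th, name = "bpA")
  g2 <- gene2gene(d, genes = c(paste0("M2_0", 1:3), paste0("N000", 1:3)),
                  thresholds = th, name = "bpB")
  list(data = d, g1 = g1, g2 = g2)
}

test_that("disjoint networks join with zero shared genes and unioned patterns", {
  fx <- mn_fixture()
  mn <- build_metanetwork(list(fx$g1, fx$g2))
  expect_s3_class(mn, "meta_network")
  expect_equal(mn$shared_counts$n_shared, 0L)
  expect_equal(nrow(mn$nodes), 7L)
  expect_equal(nrow(mn$edges), choose(4, 2) + choose(3, 2))
  expect_equal(max(mn$nodes$pattern), 2L)
  expect_false(any(mn$nodes$shared))
  s <- glance(mn)
  expect_equal(s$n_patterns, 2L)
  expect_equal(tidy(mn), mn$nodes)
})

test_that("identical single-edge networks merge into one edge with two sources", {
  d <- generate_sep(sim_spec(a = 12, n_null = 2,
                             modules = list(list(size = 2, noise_sd = 0)),
                             seed = 9))
  th <- gfn_thresholds(x = 12)
  gA <- gene2gene(d, genes = c("M1_01", "M1_02"), thresholds = th, name = "A")
  gB <- gene2gene(d, genes = c("M1_01", "M1_02"), thresholds = th, name = "B")
  mn <- build_metanetwork(list(gA, gB))
  expect_equal(nrow(mn$nodes), 2L)
  expect_equal(nrow(mn$edges), 1L)
  expect_equal(mn$edges$sources, "A,B")
  expect_equal(mn$shared_counts$n_shared, 2L)
  expect_true(all(mn$nodes$shared))
  expect_error(build_metanetwork(list(gA, gA)), "duplicate network names")
})

test_that("shared genes link member networks into common patterns", {
  d <- generate_sep(sim_spec(n_null = 4,
                             modules = list(list(size = 5, noise_sd = 0)),
                             seed = 31))
  th <- gfn_thresholds(x = 12)
  # two gene sets overlapping in M1_03: both recover their module slices
  gA <- gene2gene(d, genes = paste0("M1_0", 1:3), thresholds = th, name = "A")
  gB <- gene2gene(d, genes = paste0("M1_0", 3:5), thresholds = th, name = "B")
  mn <- build_metanetwork(list(gA, gB))
  expect_equal(mn$shared_counts$n_shared, 1L)
  expect_true(mn$nodes$shared[mn$nodes$gene == "M1_03"])
  # any member edge implies a shared pattern
  pat <- stats::setNames(mn$nodes$pattern, mn$nodes$gene)
  for (g in list(gA, gB)) {
    expect_true(all(pat[g$edges$gene_i] == pat[g$edges$gene_j]))
  }
  # union node count and per-pair shared counting
  expect_equal(nrow(mn$nodes),
               length(union(gA$nodes$gene, gB$nodes$gene)))
})

test_that("pattern profiles average gene-by-genotype observations with t CIs", {
  fx <- mn_fixture()
  mn <- build_metanetwork(list(fx$g1, fx$g2))
  prof <- pattern_profiles(fx$data, mn)
  expect_s3_class(prof, "pattern_profiles")
  expect_true(all(c("all", "domesticated", "wild", "F1") %in% prof$group))
  expect_true(all(prof$ci_low <= prof$mean & prof$mean <= prof$ci_high,
                  na.rm = TRUE))
  # n = genes-in-pattern x genotypes-in-group
  all1 <- prof[prof$group == "all" & prof$pattern == 1, ]
  expect_equal(unique(all1$n), 4L * 12L)
  # direct recomputation of one cell
  t0 <- sort(unique(fx$data$time))[1]
  genes1 <- mn$nodes$gene[mn$nodes$pattern == 1]
  vals <- fx$data$expression[fx$data$gene %in% genes1 & fx$data$time == t0]
  expect_equal(all1$mean[all1$time == t0], mean(vals))
  half <- qt(0.975, length(vals) - 1) * sd(vals) / sqrt(length(vals))
  expect_equal(all1$ci_high[all1$time == t0] - all1$mean[all1$time == t0], half)
})

test_that("the all-group mean is the size-weighted combination of subgroup means", {
  fx <- mn_fixture()
  mn <- build_metanetwork(list(fx$g1, fx$g2))
  prof <- pattern_profiles(fx$data, mn)
  sub <- prof[prof$group != "all", ]
  comb <- sub |>
    dplyr::summarise(mean = sum(.data$mean * .data$n) / sum(.data$n),
                     .by = c("pattern", "time"))
  allg <- prof[prof$group == "all", c("pattern", "time", "mean")]
  j <- dplyr::inner_join(allg, comb, by = c("pattern", "time"),
                         suffix = c("_all", "_comb"))
  expect_equal(j$mean_all, j$mean_comb, tolerance = 1e-9)
})

test_that("t-based CIs agree with a bootstrap percentile oracle", {
  fx <- mn_fixture(seed = 66)
  mn <- build_metanetwork(list(fx$g1, fx$g2))
  prof <- pattern_profiles(fx$data, mn)
  cell <- prof[prof$group == "all" & prof$pattern == 1, ][1, ]
  genes1 <- mn$nodes$gene[mn$nodes$pattern == 1]
  vals <- fx$data$expression[fx$data$gene %in% genes1 &
                               fx$data$time == cell$time]
  set.seed(1)
  boots <- replicate(10000, mean(sample(vals, replace = TRUE)))
  bci <- unname(quantile(boots, c(0.025, 0.975)))
  expect_lt(abs(cell$ci_low - bci[1]), 0.12)
  expect_lt(abs(cell$ci_high - bci[2]), 0.12)
})

test_that("single-observation groups get flagged (NA) interval bounds", {
  d <- generate_sep(sim_spec(a = 3, n_null = 2,
                             modules = list(list(size = 2, noise_sd = 0)),
                             seed = 2))
  g <- gene2gene(d, genes = c("M1_01", "M1_02"),
                 thresholds = gfn_thresholds(x = 3), name = "A")
  # a "group" containing one genotype but two genes still has n = 2;
  # restrict to one gene via a single-gene pattern to force n = 1
  prof <- pattern_profiles(d, g, groups = c(G01 = "solo"))
  solo <- prof[prof$group == "solo", ]
  expect_equal(unique(solo$n), 2L)  # 2 genes x 1 genotype
  d1 <- d[d$gene == "M1_01", ]
  # degenerate check directly: n = 1 observation per time point
  g1 <- g; g1$nodes <- g$nodes[g$nodes$gene == "M1_01", ]
  prof1 <- pattern_profiles(d1, g1, groups = c(G01 = "solo"))
  expect_true(all(is.na(prof1$ci_low[prof1$group == "solo"])))
})

test_that("meta-network exports round-trip through GraphML", {
  fx <- mn_fixture()
  mn <- build_metanetwork(list(fx$g1, fx$g2))
  prefix <- withr::local_tempfile()
  paths <- write_metanetwork(mn, prefix, profiles = NULL)
  ig <- import_graphml(paths[["graphml"]])
  expect_equal(igraph::gorder(ig), nrow(mn$nodes))
  expect_equal(igraph::gsize(ig), nrow(mn$edges))
  expect_setequal(igraph::V(ig)$name, mn$nodes$gene)
  expect_setequal(igraph::E(ig)$sources, unique(mn$edges$sources))
})
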