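#' Hub genes of a network
#'
#' Ranks network nodes by degree (number of connections), descending, with
#' ties broken lexicographically by gene identifier. Highly interconnected
#' genes are natural targets for transcription-factor candidate search.
#'
#' @param g A `gfn` object.
#' @param top_k Number of genes to return (default all).
#' @return A tibble with columns `gene`, `degree`, `is_tf`, `pattern`,
#'   ranked; empty for an empty network.
#' @export
hub_genes <- function(g, top_k = Inf) {
  stopifnot(inherits(g, "gfn"))
  out <- g$nodes |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene) |>
    dplyr::select("gene", "degree", "is_tf", "pattern")
  utils::head(out, top_k)
}

#' Find transcription-factor candidates for target genes
#'
#' Adaptation of the network algorithm to regulator search: for every
#' (target gene, transcription factor) pair, the per-genotype correlation of
#' time profiles is tested with exactly the gene2gene filters (FDR `f`,
#' minimum r^2, regression-outlier screen, sign policy), with q-values
#' computed per genotype over the target x TF pair universe of the query.
#' A TF becomes a candidate for a target when the pair passes in at least
#' `x` genotypes. TFs that are themselves targets are excluded from
#' candidacy.
#'
#' The outlier regression uses the target as regressor (x) and the TF as
#' response; this orientation is fixed.
#'
#' @param data A long profile tibble.
#' @param targets Target gene identifiers (e.g. the genes of one network
#'   pattern, or [hub_genes()]).
#' @param tf Transcription-factor catalog (gene identifiers).
#' @param genotypes Genotypes to analyse; default all.
#' @param thresholds A [gfn_thresholds()] object.
#' @param fdr_method,outlier_rule As [pair_stats()].
#' @return A tibble with one row per (target, candidate TF): columns
#'   `target`, `tf`, `support`, `supporting_genotypes`, `r_bar`, `q_bar`,
#'   `sign`, sorted by (target, descending support, descending r_bar).
#' @export
gene2tf <- function(data, targets, tf, genotypes = NULL,
                    thresholds = gfn_thresholds(),
                    fdr_method = c("bh", "storey"),
                    outlier_rule = c("rstudent", "loo_r2")) {
  fdr_method <- match.arg(fdr_method)
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(inherits(thresholds, "gfn_thresholds"))
  data <- validate_sep(data)
  if (is.null(genotypes)) genotypes <- sep_genotypes(data)
  genotypes <- sort(unique(as.character(genotypes)))
  targets <- sort(unique(as.character(targets)))
  pool <- setdiff(sort(unique(as.character(tf))), targets)
  pool <- intersect(pool, complete_genes(data[data$genotype %in% genotypes, ]))
  if (length(pool) == 0) {
    stop("no testable transcription factors remain after excluding targets",
         call. = FALSE)
  }
  a <- length(genotypes)
  th <- thresholds
  if (is.null(th$x)) th$x <- a
  if (th$x > a) stop("required support x exceeds the genotypes analysed",
                     call. = FALSE)
  tt <- length(sep_times(data))
  all_genes <- sort(unique(c(targets, pool)))
  pairs <- tidyr::expand_grid(target = targets, tf = pool)
  ii <- match(pairs$target, all_genes)
  jj <- match(pairs$tf, all_genes)

  stats <- purrr::map(genotypes, function(gt) {
    M <- .sep_matrix(data, all_genes, gt)
    R <- suppressWarnings(stats::cor(M))
    r <- R[cbind(ii, jj)]
    testable <- is.finite(r)
    p <- rep(NA_real_, length(r)); q <- p
    p[testable] <- cor_pvalue(r[testable], tt)
    q[testable] <- q_values(p[testable], method = fdr_method)
    tab <- tibble::tibble(genotype = gt, gene_i = pairs$target,
                          gene_j = pairs$tf, r = r, r2 = r^2, p = p, q = q,
                          max_rstudent = .max_abs_rstudent(M, ii, jj, r),
                          testable = testable)
    if (outlier_rule == "loo_r2") tab$min_loo_r2 <- .min_loo_r2(M, ii, jj)
    tab
  }) |> purrr::list_rbind()
  attr(stats, "n_times") <- tt
  attr(stats, "outlier_rule") <- outlier_rule

  passed <- .apply_thresholds(stats, th)
  ce <- .collect_edges(passed, th$x, th$sign_policy)
  ce$edges |>
    dplyr::rename(target = "gene_i", tf = "gene_j") |>
    dplyr::arrange(.data$target, dplyr::desc(.data$support),
                   dplyr::desc(.data$r_bar))
}

#' Roll candidate TFs up across targets
#'
#' Convenience summary of a [gene2tf()] result: one row per TF hitting at
#' least `min_targets` targets, with the targets listed.
#'
#' @param candidates A [gene2tf()] tibble.
#' @param min_targets Minimum number of distinct targets (default 1).
#' @return A tibble with columns `tf`, `n_targets`, `targets`, sorted by
#'   descending `n_targets`.
#' @export
tf_rollup <- function(candidates, min_targets = 1) {
  candidates |>
    dplyr::summarise(n_targets = dplyr::n(),
                     targets = paste(sort(.data$target), collapse = ","),
                     .by = "tf") |>
    dplyr::filter(.data$n_targets >= min_targets) |>
    dplyr::arrange(dplyr::desc(.data$n_targets), .data$tf)
}

#' Re-estimate a network augmented with candidate transcription factors
#'
#' Runs the network algorithm on the union of a network's genes and the
#' candidate TFs found for them, marking the TFs in the result. Because
#' q-values depend on the pair universe, a larger universe could in
#' principle drop edges the original network supported; with
#' `fixed_universe = TRUE` (default) pairs among the original input genes
#' reuse the original run's pair statistics (q-values from the original
#' universe) and only TF-involving pairs are newly tested over their own
#' universe, so augmentation never removes a previously supported edge.
#' Requires the original network to have been built with
#' `keep_stats = TRUE`; otherwise everything is recomputed over the single
#' union universe.
#'
#' @param data A long profile tibble.
#' @param g The original `gfn` object.
#' @param candidates A [gene2tf()] tibble (may be empty).
#' @param thresholds Thresholds for the new run; default those of `g`.
#' @param fixed_universe Keep the original pair universe for original-gene
#'   pairs (see above).
#' @param fdr_method,outlier_rule As [pair_stats()].
#' @return A new `gfn` over the union gene set, with TF marks.
#' @export
augment_network <- function(data, g, candidates, thresholds = NULL,
                            fixed_universe = TRUE,
                            fdr_method = "bh", outlier_rule = "rstudent") {
  stopifnot(inherits(g, "gfn"))
  th <- thresholds %||% g$thresholds
  tfs <- sort(unique(candidates$tf))
  base_genes <- sort(unique(g$nodes$gene))
  union_genes <- sort(unique(c(base_genes, tfs)))
  tf_marks <- sort(unique(c(g$tf, tfs)))
  if (length(tfs) == 0) {
    return(gene2gene(data, genes = base_genes, genotypes = g$genotypes,
                     thresholds = th, tf = tf_marks,
                     name = paste0(g$name, "+TF"),
                     fdr_method = fdr_method, outlier_rule = outlier_rule))
  }
  if (!fixed_universe || is.null(g$stats)) {
    return(gene2gene(data, genes = union_genes, genotypes = g$genotypes,
                     thresholds = th, tf = tf_marks,
                     name = paste0(g$name, "+TF"),
                     fdr_method = fdr_method, outlier_rule = outlier_rule))
  }
  # original universe for pairs among the original input genes ...
  old <- g$stats
  keep <- old$gene_i %in% union_genes & old$gene_j %in% union_genes
  old <- old[keep, , drop = FALSE]
  # ... fresh universe for pairs that involve at least one added TF
  data <- validate_sep(data)
  tt <- length(sep_times(data))
  new_tf <- setdiff(tfs, g$genes_in)
  new_pairs <- dplyr::bind_rows(
    tidyr::expand_grid(gene_i = setdiff(union_genes, new_tf), gene_j = new_tf),
    if (length(new_tf) >= 2) {
      idx <- utils::combn(sort(new_tf), 2)
      tibble::tibble(gene_i = idx[1, ], gene_j = idx[2, ])
    }
  ) |>
    dplyr::mutate(gene_i2 = pmin(.data$gene_i, .data$gene_j),
                  gene_j2 = pmax(.data$gene_i, .data$gene_j)) |>
    dplyr::distinct(gene_i = .data$gene_i2, gene_j = .data$gene_j2)
  ii <- match(new_pairs$gene_i, union_genes)
  jj <- match(new_pairs$gene_j, union_genes)
  fresh <- purrr::map(g$genotypes, function(gt) {
    M <- .sep_matrix(data, union_genes, gt)
    R <- suppressWarnings(stats::cor(M))
    r <- R[cbind(ii, jj)]
    testable <- is.finite(r)
    p <- rep(NA_real_, length(r)); q <- p
    p[testable] <- cor_pvalue(r[testable], tt)
    q[testable] <- q_values(p[testable], method = fdr_method)
    tibble::tibble(genotype = gt, gene_i = new_pairs$gene_i,
                   gene_j = new_pairs$gene_j, r = r, r2 = r^2, p = p, q = q,
                   max_rstudent = .max_abs_rstudent(M, ii, jj, r),
                   testable = testable)
  }) |> purrr::list_rbind()
  stats <- dplyr::bind_rows(old, fresh) |>
    dplyr::arrange(.data$genotype, .data$gene_i, .data$gene_j)
  attr(stats, "n_times") <- tt
  attr(stats, "outlier_rule") <- attr(g$stats, "outlier_rule") %||% "rstudent"

  th2 <- th
  if (is.null(th2$x)) th2$x <- length(g$genotypes)
  passed <- .apply_thresholds(stats, th2)
  ce <- .collect_edges(passed, th2$x, th2$sign_policy)
  new_gfn(name = paste0(g$name, "+TF"), edges = ce$edges,
          observations = ce$observations, thresholds = th2,
          genotypes = g$genotypes, genes_in = union_genes, tf = tf_marks,
          stats = stats)
}
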