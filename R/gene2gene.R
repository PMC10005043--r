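#' Threshold set of a network run
#'
#' Bundles the filter thresholds of the network algorithm. Defaults are the
#' demonstration values used throughout the package: FDR 10%, minimum
#' determination coefficient 0.7 (which under the positive-sign policy
#' implies r >= 0.837), outlier screen at 5%, and support required in all
#' genotypes analysed (`x = NULL` resolves to `a` at run time).
#'
#' @param f Maximum FDR (q-value) in (0, 1).
#' @param mr2 Minimum determination coefficient r^2 in (0, 1\].
#' @param q_out Regression-outlier elimination level in (0, 1).
#' @param x Minimum number of supporting genotypes (integer), or `NULL` for
#'   "all genotypes analysed".
#' @param sign_policy `"positive"` (only positive correlations count, the
#'   default), `"consistent"` (all supporting genotypes must agree in sign)
#'   or `"any"`.
#' @return A list of class `gfn_thresholds`.
#' @export
gfn_thresholds <- function(f = 0.1, mr2 = 0.7, q_out = 0.05, x = NULL,
                           sign_policy = c("positive", "consistent", "any")) {
  sign_policy <- match.arg(sign_policy)
  stopifnot(f > 0, f < 1, mr2 > 0, mr2 <= 1, q_out > 0, q_out < 1)
  if (!is.null(x)) stopifnot(x == round(x), x >= 1)
  structure(list(f = f, mr2 = mr2, q_out = q_out, x = x,
                 sign_policy = sign_policy),
            class = "gfn_thresholds")
}

# Adds `pass` to a pair_stats tibble: q <= f, r2 >= mr2, not outlier-driven
# at level q_out, sign admissible. Outlier flags are re-derived from the
# cached statistic so one pair_stats table serves any q_out (or any mr2
# under the loo_r2 rule).
.apply_thresholds <- function(stats, th) {
  tt <- attr(stats, "n_times")
  rule <- attr(stats, "outlier_rule") %||% "rstudent"
  if (rule == "loo_r2") {
    out <- !is.na(stats$min_loo_r2) & stats$min_loo_r2 < th$mr2
  } else if (tt >= 4) {
    crit <- outlier_critical(th$q_out, tt)
    out <- !is.na(stats$max_rstudent) & stats$max_rstudent > crit
  } else {
    out <- FALSE
  }
  sign_ok <- if (th$sign_policy == "positive") stats$r > 0 else TRUE
  stats$outlier <- stats$testable & out
  stats$pass <- stats$testable &
    !is.na(stats$q) & stats$q <= th$f &
    stats$r2 >= th$mr2 &
    !stats$outlier &
    sign_ok
  stats
}

# Aggregates passing (pair, genotype) records into supported edges under the
# sign policy. Returns list(edges, observations): observations holds one row
# per (edge, supporting genotype) with its r and q, the basis of the
# summary averages.
.collect_edges <- function(passed, x, sign_policy) {
  obs <- passed[passed$pass, c("gene_i", "gene_j", "genotype", "r", "q")]
  empty <- list(
    edges = tibble::tibble(gene_i = character(), gene_j = character(),
                           support = integer(), supporting_genotypes = character(),
                           r_bar = double(), q_bar = double(), sign = integer()),
    observations = obs[0, ]
  )
  if (nrow(obs) == 0) return(empty)
  obs$s <- ifelse(obs$r >= 0, 1L, -1L)
  by_sign <- obs |>
    dplyr::summarise(support = dplyr::n(), .by = c("gene_i", "gene_j", "s"))
  chosen <- switch(
    sign_policy,
    positive = by_sign[by_sign$s == 1L, ],
    # one sign must carry all the support; keep the majority sign
    # (ties resolved toward positive), count only its genotypes
    consistent = by_sign |>
      dplyr::arrange(dplyr::desc(.data$support), dplyr::desc(.data$s)) |>
      dplyr::distinct(.data$gene_i, .data$gene_j, .keep_all = TRUE),
    any = by_sign |>
      dplyr::summarise(support = sum(.data$support), s = NA_integer_,
                       .by = c("gene_i", "gene_j"))
  )
  chosen <- chosen[chosen$support >= x, , drop = FALSE]
  if (nrow(chosen) == 0) return(empty)
  if (sign_policy %in% c("positive", "consistent")) {
    obs <- dplyr::semi_join(obs, chosen, by = c("gene_i", "gene_j", "s"))
  } else {
    obs <- dplyr::semi_join(obs, chosen, by = c("gene_i", "gene_j"))
  }
  obs <- dplyr::arrange(obs, .data$gene_i, .data$gene_j, .data$genotype)
  edges <- obs |>
    dplyr::summarise(
      support = dplyr::n(),
      supporting_genotypes = paste(.data$genotype, collapse = ","),
      r_bar = mean(.data$r),
      q_bar = mean(.data$q),
      sign = ifelse(mean(.data$r) >= 0, 1L, -1L),
      .by = c("gene_i", "gene_j")
    ) |>
    dplyr::arrange(.data$gene_i, .data$gene_j)
  list(edges = edges, observations = obs[, c("gene_i", "gene_j", "genotype", "r", "q")])
}

#' Estimate a gene functional network
#'
#' The two-step network algorithm. Step one estimates and tests all
#' g(g-1)/2 Pearson correlations between the g input genes in each of the a
#' genotypes ([pair_stats()]). Step two keeps, per genotype, the pairs with
#' q-value <= `f`, determination coefficient r^2 >= `mr2`, no regression
#' outlier at level `q_out`, and an admissible sign; a pair becomes a
#' network edge only when it passes in at least `x` of the `a` genotypes —
#' the replication filter that makes the network robust (see
#' [pred_error_g2g()] for the implied chance rate). Network nodes are
#' exactly the genes incident to at least one edge; the result may be empty.
#'
#' Support is counted against all genotypes analysed: a genotype where the
#' pair is not testable counts as non-support, keeping the replication
#' denominator fixed at `a` for every pair.
#'
#' @param data A long profile tibble; standardized internally if needed.
#' @param genes Input gene set (all must have complete profiles in every
#'   genotype analysed); default every complete gene.
#' @param genotypes Genotypes to analyse; default all.
#' @param thresholds A [gfn_thresholds()] object.
#' @param tf Character vector of transcription-factor gene identifiers used
#'   to mark nodes (may be `NULL`).
#' @param name Optional network name (e.g. the biological-process label).
#' @param fdr_method,outlier_rule Passed to [pair_stats()].
#' @param stats Optional precomputed [pair_stats()] table over exactly
#'   (`genes`, `genotypes`) — used to avoid recomputing correlations when
#'   exploring thresholds.
#' @param keep_stats Keep the pair table inside the returned object
#'   (needed by [augment_network()]'s fixed-universe mode).
#' @return An object of class `gfn`: a list with tibbles `nodes` (gene,
#'   is_tf, degree, pattern), `edges` (gene_i, gene_j, support,
#'   supporting_genotypes, r_bar, q_bar, sign) and `observations` (one row
#'   per edge x supporting genotype), plus the thresholds, genotypes and
#'   input-gene bookkeeping.
#' @export
gene2gene <- function(data, genes = NULL, genotypes = NULL,
                      thresholds = gfn_thresholds(), tf = NULL, name = NULL,
                      fdr_method = c("bh", "storey"),
                      outlier_rule = c("rstudent", "loo_r2"),
                      stats = NULL, keep_stats = TRUE) {
  fdr_method <- match.arg(fdr_method)
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(inherits(thresholds, "gfn_thresholds"))
  if (is.null(stats)) {
    data <- validate_sep(data)
    if (is.null(genotypes)) genotypes <- sep_genotypes(data)
    genotypes <- sort(unique(as.character(genotypes)))
    if (is.null(genes)) {
      genes <- complete_genes(data[data$genotype %in% genotypes, , drop = FALSE])
    }
    if (length(genes) == 0) stop("empty input gene list", call. = FALSE)
    genes <- sort(unique(as.character(genes)))
    stats <- pair_stats(data, genes = genes, genotypes = genotypes,
                        q_out = thresholds$q_out, fdr_method = fdr_method,
                        outlier_rule = outlier_rule, mr2_loo = thresholds$mr2)
  } else {
    genotypes <- sort(unique(stats$genotype))
    genes <- sort(unique(c(stats$gene_i, stats$gene_j)))
  }
  a <- length(genotypes)
  th <- thresholds
  if (is.null(th$x)) th$x <- a
  if (th$x > a) stop("required support x = ", th$x, " exceeds the ", a,
                     " genotypes analysed", call. = FALSE)

  passed <- .apply_thresholds(stats, th)
  ce <- .collect_edges(passed, th$x, th$sign_policy)
  new_gfn(name = name, edges = ce$edges, observations = ce$observations,
          thresholds = th, genotypes = genotypes, genes_in = genes,
          tf = tf, stats = if (keep_stats) stats else NULL)
}

# Constructor shared by gene2gene() and augment_network(): derives nodes,
# degrees and pattern labels from the edge list.
new_gfn <- function(name, edges, observations, thresholds, genotypes,
                    genes_in, tf, stats) {
  node_ids <- sort(unique(c(edges$gene_i, edges$gene_j)))
  nodes <- tibble::tibble(
    gene = node_ids,
    is_tf = node_ids %in% (tf %||% character()),
    degree = vapply(node_ids, function(g) {
      sum(edges$gene_i == g) + sum(edges$gene_j == g)
    }, integer(1), USE.NAMES = FALSE)
  )
  g <- structure(
    list(name = name %||% "GFN", nodes = nodes, edges = edges,
         observations = observations, thresholds = thresholds,
         genotypes = genotypes, a = length(genotypes),
         genes_in = genes_in, n_in = length(genes_in),
         tf = sort(unique(tf %||% character())), stats = stats),
    class = "gfn"
  )
  g$nodes$pattern <- connected_patterns(g$edges, g$nodes$gene)
  g
}

#' Connected-component pattern labels of an edge list
#'
#' Partitions the nodes of an undirected edge list into connected
#' components ("patterns"). Labels P = 1..k are assigned by decreasing
#' component size, ties broken by the lexicographically smallest member
#' gene, so labelling is deterministic.
#'
#' @param edges A tibble with columns `gene_i`, `gene_j`.
#' @param nodes Character vector of node identifiers (isolated nodes allowed).
#' @return Integer vector of pattern labels parallel to `nodes`.
#' @export
connected_patterns <- function(edges, nodes) {
  if (length(nodes) == 0) return(integer())
  ig <- igraph::graph_from_data_frame(edges[, c("gene_i", "gene_j")],
                                      directed = FALSE,
                                      vertices = data.frame(name = nodes))
  comp <- igraph::components(ig)
  member <- comp$membership[nodes]
  info <- tibble::tibble(comp = unname(member), gene = nodes) |>
    dplyr::summarise(size = dplyr::n(), first = min(.data$gene), .by = "comp") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first)
  relabel <- stats::setNames(seq_len(nrow(info)), info$comp)
  unname(relabel[as.character(member)])
}

#' Summarize a gene functional network
#'
#' One-row summary in the conventional reporting order: genes in, genes
#' out, percent retained, number of connections, and the averages of the
#' per-genotype correlation r and q-value over all (edge x supporting
#' genotype) observations. An empty network reports `NA` averages.
#'
#' @param x A `gfn` object.
#' @param ... Ignored.
#' @return A one-row tibble with columns `name`, `n_in`, `n_out`,
#'   `pct_out`, `n_con`, `r_bar`, `q_bar`.
#' @method glance gfn
#' @export
glance.gfn <- function(x, ...) {
  obs <- x$observations
  tibble::tibble(
    name = x$name,
    n_in = x$n_in,
    n_out = nrow(x$nodes),
    pct_out = as.integer(round(100 * nrow(x$nodes) / max(1, x$n_in))),
    n_con = nrow(x$edges),
    r_bar = if (nrow(obs) > 0) mean(obs$r) else NA_real_,
    q_bar = if (nrow(obs) > 0) mean(obs$q) else NA_real_
  )
}

#' @describeIn glance.gfn Edge list as a tibble (one row per connection).
#' @method tidy gfn
#' @export
tidy.gfn <- function(x, ...) x$edges

#' @export
print.gfn <- function(x, ...) {
  s <- glance(x)
  cat(sprintf("<gfn> %s: %d/%d genes (%d%%), %d connections, %d pattern(s)\n",
              s$name, s$n_out, s$n_in, s$pct_out, s$n_con,
              if (nrow(x$nodes)) max(x$nodes$pattern) else 0L))
  cat(sprintf("  thresholds: f=%g mr2=%g q_out=%g x=%d sign=%s over a=%d genotypes\n",
              x$thresholds$f, x$thresholds$mr2, x$thresholds$q_out,
              x$thresholds$x, x$thresholds$sign_policy, x$a))
  if (!is.na(s$r_bar)) {
    cat(sprintf("  r_bar=%.4f q_bar=%.3g; chance rate %.3g (about one in %.0f)\n",
                s$r_bar, s$q_bar,
                pred_error_g2g(x$a, x$thresholds$f, x$thresholds$x),
                1 / pred_error_g2g(x$a, x$thresholds$f, x$thresholds$x)))
  } else {
    cat("  null output: no gene pair passed all filters\n")
  }
  invisible(x)
}

#' Plot a gene functional network
#'
#' Draws nodes (circles; squares for transcription factors) at a
#' deterministic force-directed layout, coloured by connected-component
#' pattern, with edges as segments.
#'
#' @param object A `gfn` object.
#' @param label Draw gene labels.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gfn
#' @export
autoplot.gfn <- function(object, label = nrow(object$nodes) <= 40, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::ggtitle(paste0(object$name, " (empty)")))
  }
  ig <- igraph::graph_from_data_frame(object$edges[, c("gene_i", "gene_j")],
                                      directed = FALSE,
                                      vertices = data.frame(name = object$nodes$gene))
  xy <- .with_local_seed(1L, igraph::layout_with_fr(ig))
  lay <- tibble::tibble(gene = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2]) |>
    dplyr::left_join(object$nodes, by = "gene")
  seg <- object$edges |>
    dplyr::left_join(lay[, c("gene", "x", "y")], by = c(gene_i = "gene")) |>
    dplyr::left_join(lay[, c("gene", "x", "y")], by = c(gene_j = "gene"),
                     suffix = c("", "end"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = factor(.data$pattern),
                                     shape = .data$is_tf), size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 15),
                                labels = c(`FALSE` = "gene", `TRUE` = "TF")) +
    ggplot2::labs(title = object$name, colour = "pattern", shape = NULL) +
    ggplot2::theme_void()
  if (label) {
    p <- p + ggplot2::geom_text(data = lay,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             label = .data$gene),
                                vjust = -1, size = 2.7)
  }
  p
}

#' Sensitivity of the network to its thresholds
#'
#' Runs [gene2gene()] over the full factorial grid of FDR, minimum r^2 and
#' outlier-level thresholds at a fixed support requirement `x`. Pair
#' correlations are computed once and cached; only the (pure) filtering is
#' re-applied per cell. The attribute `cor_genes_edges` holds the Pearson
#' correlation between the retained gene and edge counts across cells
#' (`NA` when either count is constant over the grid).
#'
#' @param data,genes,genotypes,tf,fdr_method,outlier_rule As [gene2gene()].
#' @param f_values,mr2_values,q_out_values Non-empty threshold grids.
#' @param x Fixed support requirement; `NULL` = all genotypes.
#' @param sign_policy Sign policy applied in every cell.
#' @return A tibble with columns `f`, `mr2`, `q_out`, `n_genes`, `n_edges`,
#'   with attribute `cor_genes_edges`.
#' @export
sensitivity_grid <- function(data, genes = NULL, genotypes = NULL,
                             f_values, mr2_values, q_out_values, x = NULL,
                             sign_policy = "positive", tf = NULL,
                             fdr_method = "bh", outlier_rule = "rstudent") {
  if (!length(f_values) || !length(mr2_values) || !length(q_out_values)) {
    stop("threshold grids must be non-empty", call. = FALSE)
  }
  data <- validate_sep(data)
  if (is.null(genotypes)) genotypes <- sep_genotypes(data)
  if (is.null(genes)) {
    genes <- complete_genes(data[data$genotype %in% genotypes, , drop = FALSE])
  }
  stats <- pair_stats(data, genes = genes, genotypes = genotypes,
                      fdr_method = fdr_method, outlier_rule = outlier_rule)
  grid <- tidyr::expand_grid(f = f_values, mr2 = mr2_values, q_out = q_out_values)
  res <- purrr::pmap(grid, function(f, mr2, q_out) {
    g <- gene2gene(stats = stats,
                   thresholds = gfn_thresholds(f = f, mr2 = mr2, q_out = q_out,
                                               x = x, sign_policy = sign_policy),
                   tf = tf, keep_stats = FALSE)
    tibble::tibble(n_genes = nrow(g$nodes), n_edges = nrow(g$edges))
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(grid, res)
  cge <- if (isTRUE(stats::sd(out$n_genes) > 0) &&
               isTRUE(stats::sd(out$n_edges) > 0)) {
    stats::cor(out$n_genes, out$n_edges)
  } else NA_real_
  attr(out, "cor_genes_edges") <- cge
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
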