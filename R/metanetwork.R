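#' Join gene functional networks into a meta-network
#'
#' Several networks estimated over the same gene namespace (e.g. one per
#' biological process) can be linked through the genes they share. The
#' meta-network is the union graph: nodes carry the set of member networks
#' containing them (a node is "shared" when it belongs to two or more),
#' edges carry their source network(s) (an edge present in two networks
#' appears once with both sources recorded), and the union graph is
#' partitioned into connected-component patterns labelled P = 1..k, each
#' corresponding to one characteristic time-expression profile.
#'
#' @param gfns A list of `gfn` objects with distinct names (a named list
#'   overrides the objects' own names).
#' @return An object of class `meta_network`: tibbles `nodes` (gene, gfns,
#'   n_gfns, shared, is_tf, pattern), `edges` (gene_i, gene_j, sources,
#'   support, r_bar, q_bar, sign) and `shared_counts` (gfn_a, gfn_b,
#'   n_shared), plus the member names.
#' @export
build_metanetwork <- function(gfns) {
  stopifnot(is.list(gfns), length(gfns) >= 2)
  stopifnot(all(vapply(gfns, inherits, logical(1), "gfn")))
  nm <- names(gfns) %||% vapply(gfns, function(g) g$name, character(1))
  if (is.null(names(gfns))) names(gfns) <- nm
  nm[!nzchar(nm)] <- vapply(gfns[!nzchar(nm)], function(g) g$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate network names: ",
                              paste(nm[duplicated(nm)], collapse = ", "),
                              call. = FALSE)
  names(gfns) <- nm

  membership <- purrr::imap(gfns, function(g, n) {
    tibble::tibble(gene = g$nodes$gene, gfn = n, is_tf = g$nodes$is_tf)
  }) |> purrr::list_rbind()
  nodes <- membership |>
    dplyr::summarise(gfns = paste(sort(unique(.data$gfn)), collapse = ","),
                     n_gfns = dplyr::n_distinct(.data$gfn),
                     is_tf = any(.data$is_tf), .by = "gene") |>
    dplyr::mutate(shared = .data$n_gfns >= 2) |>
    dplyr::arrange(.data$gene)

  all_edges <- purrr::imap(gfns, function(g, n) {
    dplyr::mutate(g$edges, gfn = n)
  }) |> purrr::list_rbind()
  edges <- all_edges |>
    dplyr::summarise(
      sources = paste(sort(unique(.data$gfn)), collapse = ","),
      support = max(.data$support),
      r_bar = mean(.data$r_bar), q_bar = mean(.data$q_bar),
      sign = .data$sign[1],
      .by = c("gene_i", "gene_j")
    ) |>
    dplyr::arrange(.data$gene_i, .data$gene_j)

  pairs <- utils::combn(sort(nm), 2)
  shared_counts <- tibble::tibble(gfn_a = pairs[1, ], gfn_b = pairs[2, ]) |>
    dplyr::mutate(n_shared = purrr::map2_int(.data$gfn_a, .data$gfn_b,
      function(x, y) length(intersect(gfns[[x]]$nodes$gene, gfns[[y]]$nodes$gene))))

  nodes$pattern <- connected_patterns(edges, nodes$gene)
  structure(list(members = sort(nm), nodes = nodes, edges = edges,
                 shared_counts = shared_counts),
            class = "meta_network")
}

#' @export
print.meta_network <- function(x, ...) {
  cat(sprintf("<meta_network> %d member networks (%s): %d genes (%d shared), %d edges, %d pattern(s)\n",
              length(x$members), paste(x$members, collapse = ", "),
              nrow(x$nodes), sum(x$nodes$shared), nrow(x$edges),
              if (nrow(x$nodes)) max(x$nodes$pattern) else 0L))
  invisible(x)
}

#' Summarize a meta-network
#'
#' @param x A `meta_network` object.
#' @param ... Ignored.
#' @return One-row tibble: member count, node/shared-node/edge/pattern
#'   counts.
#' @method glance meta_network
#' @export
glance.meta_network <- function(x, ...) {
  tibble::tibble(n_gfns = length(x$members), n_nodes = nrow(x$nodes),
                 n_shared = sum(x$nodes$shared), n_edges = nrow(x$edges),
                 n_patterns = if (nrow(x$nodes)) max(x$nodes$pattern) else 0L)
}

#' @describeIn glance.meta_network Node table with membership and pattern.
#' @method tidy meta_network
#' @export
tidy.meta_network <- function(x, ...) x$nodes

#' Average standardized expression profile of each pattern
#'
#' For every connected-component pattern of a meta-network (or single
#' network) and every genotype group, computes at each time point the mean
#' standardized expression over all (gene in pattern) x (genotype in group)
#' observations, with a t-based 95% confidence interval for that mean:
#' mean +/- t(0.975, n - 1) * sd / sqrt(n). The `"all"` group (every
#' genotype) is always included; further groups (e.g. domesticated / wild)
#' come from `groups`. Groups with a single observation get `NA` interval
#' bounds.
#'
#' @param data A long profile tibble holding *standardized* profiles for at
#'   least the pattern genes (standardized internally otherwise).
#' @param mn A `meta_network` or `gfn` object.
#' @param groups Named character vector or two-column data frame
#'   (`genotype`, `group`) mapping genotypes to group labels; `NULL` for
#'   the "all" group only. Defaults to `attr(data, "group_labels")`.
#' @param conf_level Confidence level of the interval.
#' @return A tibble of class `pattern_profiles` with columns `pattern`,
#'   `group`, `time`, `n`, `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
pattern_profiles <- function(data, mn, groups = attr(data, "group_labels"),
                             conf_level = 0.95) {
  stopifnot(inherits(mn, c("meta_network", "gfn")))
  nodes <- if (inherits(mn, "gfn")) mn$nodes else mn$nodes
  data <- validate_sep(data)
  if (!is_standardized(data[data$gene %in% nodes$gene, , drop = FALSE])) {
    data <- standardize_sep(data)
  }
  if (!is.null(groups) && is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$genotype)
  }
  gts <- sep_genotypes(data)
  group_sets <- c(list(all = gts),
                  if (!is.null(groups)) split(names(groups), groups))
  alpha <- 1 - conf_level

  out <- purrr::imap(group_sets, function(members, label) {
    d <- data[data$genotype %in% members & data$gene %in% nodes$gene, ,
              drop = FALSE]
    d <- dplyr::left_join(d, nodes[, c("gene", "pattern")], by = "gene")
    d |>
      dplyr::summarise(
        group = label, n = dplyr::n(), mean = mean(.data$expression),
        sd = stats::sd(.data$expression), .by = c("pattern", "time")
      )
  }) |> purrr::list_rbind()
  out <- out |>
    dplyr::mutate(
      half = ifelse(.data$n >= 2,
                    stats::qt(1 - alpha / 2, pmax(.data$n - 1, 1)) *
                      .data$sd / sqrt(.data$n),
                    NA_real_),
      ci_low = .data$mean - .data$half,
      ci_high = .data$mean + .data$half
    ) |>
    dplyr::select("pattern", "group", "time", "n", "mean", "sd",
                  "ci_low", "ci_high") |>
    dplyr::arrange(.data$pattern, .data$group, .data$time)
  class(out) <- c("pattern_profiles", class(out))
  out
}

#' Plot pattern-wise average expression profiles
#'
#' One panel per pattern; lines are group means over time with vertical
#' segments marking the confidence interval of the mean at each time point.
#'
#' @param object A [pattern_profiles()] tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot pattern_profiles
#' @export
autoplot.pattern_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$mean,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0, na.rm = TRUE) +
    ggplot2::facet_wrap(~ .data$pattern,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time", y = "mean standardized expression",
                  colour = "group")
}
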