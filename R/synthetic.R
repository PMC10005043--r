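#' Simulation design for multi-genotype time-course profiles
#'
#' Describes a synthetic dataset emulating the multi-genotype
#' fruit-development study design the package targets: by default 12
#' genotypes — six domesticated (D1–D6), four wild (W1–W4) and two F1
#' hybrids (H1–H2) — each sampled at seven development times (0–60 days
#' after anthesis). The dataset contains independent-noise ("null") genes,
#' planted co-expression modules, and optional outlier-driven pairs:
#'
#' * a module draws one fresh latent profile per supporting genotype (the
#'   same gene pair shows *different* profile shapes in different
#'   genotypes, yet is internally correlated within each — exactly the
#'   phenomenon the replication filter exploits); member genes observe
#'   latent + Normal(0, noise_sd) noise. Outside its supporting genotypes a
#'   module's genes revert to independent noise, so modules supported in
#'   few genotypes act as decoys for the replication filter.
#' * an outlier pair is collinear except for one gross off-line time point
#'   in the second gene (shifted by `offset` latent-scale units), the
#'   signature the regression-outlier screen is designed to catch.
#'
#' @param a Number of genotypes.
#' @param times Sampling time grid (length T).
#' @param n_null Number of independent standard-normal noise genes.
#' @param modules List of module specs, each a list with elements `size`
#'   (genes, >= 2), `support` (genotype identifiers sharing the module
#'   profile; default all) and `noise_sd` (latent-scale observation noise,
#'   default 0.05).
#' @param n_outlier_pairs Number of planted outlier-driven pairs.
#' @param outlier_offset Latent-scale shift of the aberrant point.
#' @param genotypes Genotype identifiers (length `a`).
#' @param group_labels Named character vector genotype -> group.
#' @param seed Integer RNG seed; generation is fully reproducible.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(a = 12, times = seq(0, 60, by = 10), n_null = 0,
                     modules = list(), n_outlier_pairs = 0,
                     outlier_offset = 3,
                     genotypes = NULL, group_labels = NULL, seed = 1L) {
  if (is.null(genotypes)) {
    genotypes <- if (a == 12) {
      c(paste0("D", 1:6), paste0("W", 1:4), paste0("H", 1:2))
    } else sprintf("G%02d", seq_len(a))
  }
  stopifnot(length(genotypes) == a, length(times) >= 2, !is.unsorted(times))
  if (is.null(group_labels) && a == 12) {
    group_labels <- stats::setNames(
      rep(c("domesticated", "wild", "F1"), c(6, 4, 2)), genotypes)
  }
  modules <- purrr::map(modules, function(m) {
    m$size <- as.integer(m$size)
    stopifnot(m$size >= 2)
    m$support <- as.character(m$support %||% genotypes)
    stopifnot(all(m$support %in% genotypes))
    m$noise_sd <- m$noise_sd %||% 0.05
    stopifnot(m$noise_sd >= 0)
    m
  })
  structure(list(a = a, genotypes = sort(genotypes), times = times,
                 n_null = n_null, modules = modules,
                 n_outlier_pairs = n_outlier_pairs,
                 outlier_offset = outlier_offset,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a synthetic standardized-profile dataset
#'
#' Draws the dataset described by a [sim_spec()] and standardizes every
#' profile (see [standardize_sep()]). Gene naming: null genes `Nxxxx`,
#' module m genes `M<m>_xx`, outlier-pair genes `O<p>a`/`O<p>b`. The result
#' carries the genotype -> group map as attribute `group_labels`.
#'
#' @param spec A [sim_spec()].
#' @return A standardized long profile tibble.
#' @export
generate_sep <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  tt <- length(spec$times)
  .with_local_seed(spec$seed, {
    blocks <- list()
    if (spec$n_null > 0) {
      null_genes <- sprintf("N%04d", seq_len(spec$n_null))
      blocks$null <- tidyr::expand_grid(genotype = spec$genotypes,
                                        gene = null_genes,
                                        time = spec$times) |>
        dplyr::mutate(expression = stats::rnorm(dplyr::n()))
    }
    for (m in seq_along(spec$modules)) {
      mod <- spec$modules[[m]]
      genes <- sprintf("M%d_%02d", m, seq_len(mod$size))
      rows <- purrr::map(spec$genotypes, function(gt) {
        if (gt %in% mod$support) {
          latent <- stats::rnorm(tt)
          vals <- purrr::map(genes, function(g) {
            latent + stats::rnorm(tt, sd = mod$noise_sd)
          })
        } else {
          vals <- purrr::map(genes, function(g) stats::rnorm(tt))
        }
        tibble::tibble(genotype = gt,
                       gene = rep(genes, each = tt),
                       time = rep(spec$times, length(genes)),
                       expression = unlist(vals))
      }) |> purrr::list_rbind()
      blocks[[paste0("mod", m)]] <- rows
    }
    if (spec$n_outlier_pairs > 0) {
      rows <- purrr::map(seq_len(spec$n_outlier_pairs), function(p) {
        ga <- sprintf("O%da", p); gb <- sprintf("O%db", p)
        purrr::map(spec$genotypes, function(gt) {
          latent <- stats::rnorm(tt)
          b <- latent + stats::rnorm(tt, sd = 0.02)
          k <- sample.int(tt, 1)
          b[k] <- b[k] + spec$outlier_offset
          tibble::tibble(genotype = gt, gene = rep(c(ga, gb), each = tt),
                         time = rep(spec$times, 2),
                         expression = c(latent, b))
        }) |> purrr::list_rbind()
      }) |> purrr::list_rbind()
      blocks$outliers <- rows
    }
    if (length(blocks) == 0) stop("empty simulation design", call. = FALSE)
    out <- purrr::list_rbind(blocks) |>
      dplyr::arrange(.data$genotype, .data$gene, .data$time)
    out <- suppressMessages(standardize_sep(out))
    attr(out, "group_labels") <- spec$group_labels
    out
  })
}

#' Generate a fully null dataset
#'
#' Shorthand for [generate_sep()] with `g` independent standard-normal
#' noise genes and no planted structure.
#'
#' @param a Genotypes.
#' @param n_times Time points (grid `0, 10, ..., 10 * (n_times - 1)`).
#' @param g Genes.
#' @param seed RNG seed.
#' @return A standardized long profile tibble.
#' @export
null_sep <- function(a = 12, n_times = 7, g = 50, seed = 1L) {
  generate_sep(sim_spec(a = a, times = seq(0, by = 10, length.out = n_times),
                        n_null = g, seed = seed))
}

#' Write annotation and TF-catalog fixtures for a synthetic dataset
#'
#' Writes a gene -> term annotation TSV (every planted module becomes one
#' term `BP<m>`, null genes get term `BPnull`) and a TF catalog listing the
#' requested genes, in the dialects read by [read_annotation()] and
#' [read_tf_catalog()].
#'
#' @param spec A [sim_spec()].
#' @param annotation_path,tf_path Output paths (`NULL` to skip either).
#' @param tf_genes Genes to list as transcription factors.
#' @return Invisibly, a list of the paths written.
#' @export
write_sim_fixtures <- function(spec, annotation_path = NULL, tf_path = NULL,
                               tf_genes = character()) {
  stopifnot(inherits(spec, "sim_spec"))
  written <- list()
  if (!is.null(annotation_path)) {
    ann <- dplyr::bind_rows(
      if (spec$n_null > 0) {
        tibble::tibble(gene = sprintf("N%04d", seq_len(spec$n_null)),
                       term = "BPnull", label = "independent noise")
      },
      purrr::imap(spec$modules, function(m, i) {
        tibble::tibble(gene = sprintf("M%d_%02d", i, seq_len(m$size)),
                       term = paste0("BP", i),
                       label = paste("planted module", i))
      }) |> purrr::list_rbind()
    )
    readr::write_tsv(ann, annotation_path)
    written$annotation <- annotation_path
  }
  if (!is.null(tf_path)) {
    writeLines(sort(unique(tf_genes)), tf_path)
    written$tf <- tf_path
  }
  invisible(written)
}
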