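#' Provenance comment header for output files
#'
#' Every file the package writes begins with comment lines recording the
#' package version, the run configuration, and (when supplied) checksums of
#' the input files, so a result can always be traced back to its inputs.
#'
#' @param config Named list echoed as `# key: value` lines.
#' @param input_files Character vector of paths to checksum (md5 of the
#'   file bytes via [tools::md5sum()]).
#' @return Character vector of `#`-prefixed lines.
#' @export
gfnet_header <- function(config = list(), input_files = character()) {
  lines <- c(
    paste0("# gfnet ", as.character(utils::packageVersion("gfnet"))),
    purrr::imap_chr(config, function(v, k) {
      paste0("# ", k, ": ", paste(format(unlist(v)), collapse = " "))
    })
  )
  for (f in input_files) {
    lines <- c(lines, paste0("# input ", basename(f), " md5=",
                             unname(tools::md5sum(f))))
  }
  lines
}

.write_tsv_commented <- function(df, path, config = list(),
                                 input_files = character()) {
  writeLines(gfnet_header(config, input_files), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Writes a `gfn` or `meta_network` as GraphML with node attributes
#' (`is_tf`, `pattern`, and for meta-networks the member networks) and edge
#' attributes (`support`, `r_bar`, `q_bar`, `sign`, and for meta-networks
#' `sources`). Element ordering is deterministic (nodes and edges sorted
#' lexicographically), so two exports of the same object are
#' byte-identical. A provenance XML comment is placed after the XML
#' declaration.
#'
#' @param g A `gfn` or `meta_network` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path) {
  if (inherits(g, "gfn")) {
    vattrs <- data.frame(name = g$nodes$gene, is_tf = g$nodes$is_tf,
                         pattern = g$nodes$pattern)
    eattrs <- as.data.frame(g$edges[, c("gene_i", "gene_j", "support",
                                        "r_bar", "q_bar", "sign")])
    eattrs$supporting_genotypes <- g$edges$supporting_genotypes
    cfg <- c(unclass(g$thresholds)[c("f", "mr2", "q_out", "x", "sign_policy")],
             list(name = g$name, a = g$a))
  } else if (inherits(g, "meta_network")) {
    vattrs <- data.frame(name = g$nodes$gene, is_tf = g$nodes$is_tf,
                         pattern = g$nodes$pattern, gfns = g$nodes$gfns,
                         shared = g$nodes$shared)
    eattrs <- as.data.frame(g$edges[, c("gene_i", "gene_j", "support",
                                        "r_bar", "q_bar", "sign", "sources")])
    cfg <- list(members = paste(g$members, collapse = ","))
  } else {
    stop("`g` must be a gfn or meta_network", call. = FALSE)
  }
  ig <- igraph::graph_from_data_frame(eattrs, directed = FALSE,
                                      vertices = vattrs)
  tmp <- tempfile(fileext = ".graphml")
  igraph::write_graph(ig, tmp, format = "graphml")
  lines <- readLines(tmp)
  unlink(tmp)
  comment <- paste0("<!-- ", paste(sub("^# ?", "", gfnet_header(cfg)),
                                   collapse = " | "), " -->")
  writeLines(append(lines, comment, after = 1), path)
  invisible(path)
}

#' Import a GraphML file written by [export_graphml()]
#'
#' @param path Path to the GraphML file.
#' @return An igraph object with the exported node and edge attributes.
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Rebuild a network object from an exported GraphML file
#'
#' Reconstructs a `gfn` from a file written by [export_graphml()]. Only the
#' graph structure and edge/node attributes survive the round trip; the
#' per-genotype observations and cached pair statistics do not, so the
#' result supports meta-network assembly and plotting, not re-filtering.
#'
#' @param path Path to the GraphML file.
#' @param name Network name; default the file name without extension.
#' @return A `gfn` object.
#' @export
gfn_from_graphml <- function(path, name = NULL) {
  ig <- import_graphml(path)
  vd <- igraph::as_data_frame(ig, what = "vertices")
  ed <- igraph::as_data_frame(ig, what = "edges")
  edges <- tibble::tibble(
    gene_i = pmin(ed$from, ed$to), gene_j = pmax(ed$from, ed$to),
    support = as.integer(ed$support),
    supporting_genotypes = ed$supporting_genotypes %||% NA_character_,
    r_bar = ed$r_bar, q_bar = ed$q_bar, sign = as.integer(ed$sign)
  ) |> dplyr::arrange(.data$gene_i, .data$gene_j)
  tf <- vd$name[isTRUE_vec(vd$is_tf)]
  genotypes <- sort(unique(unlist(strsplit(
    edges$supporting_genotypes[!is.na(edges$supporting_genotypes)], ","))))
  new_gfn(name = name %||% sub("\\.graphml$", "", basename(path)),
          edges = edges, observations = edges[0, c("gene_i", "gene_j")],
          thresholds = gfn_thresholds(x = 1), genotypes = genotypes,
          genes_in = sort(vd$name), tf = tf, stats = NULL)
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "true" | x == 1)

#' Write the full output bundle of a network run
#'
#' Writes `prefix.edges.tsv`, `prefix.nodes.tsv`, `prefix.graphml` and
#' `prefix.summary.tsv` (the one-row [glance.gfn()] table), each with a
#' provenance header. Edge rows are sorted by (gene_i, gene_j) and node
#' rows by gene, so outputs are byte-stable.
#'
#' @param g A `gfn` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_gfn <- function(g, prefix) {
  stopifnot(inherits(g, "gfn"))
  cfg <- c(unclass(g$thresholds)[c("f", "mr2", "q_out", "x", "sign_policy")],
           list(name = g$name, a = g$a))
  paths <- c(edges = paste0(prefix, ".edges.tsv"),
             nodes = paste0(prefix, ".nodes.tsv"),
             graphml = paste0(prefix, ".graphml"),
             summary = paste0(prefix, ".summary.tsv"))
  .write_tsv_commented(g$edges, paths[["edges"]], cfg)
  .write_tsv_commented(g$nodes, paths[["nodes"]], cfg)
  export_graphml(g, paths[["graphml"]])
  .write_tsv_commented(glance(g), paths[["summary"]], cfg)
  invisible(paths)
}

#' Write the output bundle of a meta-network
#'
#' Writes `prefix.mn.graphml`, `prefix.shared.tsv` (genes shared per
#' network pair), `prefix.patterns.tsv` (node membership and pattern) and,
#' when profiles are supplied, `prefix.profiles.tsv`.
#'
#' @param mn A `meta_network` object.
#' @param prefix Output path prefix.
#' @param profiles Optional [pattern_profiles()] tibble.
#' @return Invisibly, the named vector of paths written.
#' @export
write_metanetwork <- function(mn, prefix, profiles = NULL) {
  stopifnot(inherits(mn, "meta_network"))
  cfg <- list(members = paste(mn$members, collapse = ","))
  paths <- c(graphml = paste0(prefix, ".mn.graphml"),
             shared = paste0(prefix, ".shared.tsv"),
             patterns = paste0(prefix, ".patterns.tsv"))
  export_graphml(mn, paths[["graphml"]])
  .write_tsv_commented(mn$shared_counts, paths[["shared"]], cfg)
  .write_tsv_commented(mn$nodes, paths[["patterns"]], cfg)
  if (!is.null(profiles)) {
    paths[["profiles"]] <- paste0(prefix, ".profiles.tsv")
    .write_tsv_commented(profiles, paths[["profiles"]], cfg)
  }
  invisible(paths)
}

#' Human-readable report of a network run
#'
#' Produces the standard run report: the summary row (genes in / out,
#' percent retained, connections, average r and q), the pattern census, the
#' count of input genes not retained, and the replication-filter chance
#' rate for the run's (a, f, x) with its "one in N" framing. A run with no
#' edges is reported as a null output explicitly.
#'
#' @param g A `gfn` object.
#' @return Character vector of report lines (also printed).
#' @export
gfn_report <- function(g) {
  stopifnot(inherits(g, "gfn"))
  s <- glance(g)
  th <- g$thresholds
  pe <- pred_error_g2g(g$a, th$f, th$x)
  lines <- c(
    sprintf("Network: %s", g$name),
    sprintf("Thresholds: f=%g mr2=%g q_out=%g x=%d sign=%s (a=%d genotypes)",
            th$f, th$mr2, th$q_out, th$x, th$sign_policy, g$a),
    "BP\tIn\tOut\t% Out/In\tCon.\tr_bar\tq_bar",
    sprintf("%s\t%d\t%d\t%d\t%d\t%s\t%s", s$name, s$n_in, s$n_out, s$pct_out,
            s$n_con,
            if (is.na(s$r_bar)) "NA" else sprintf("%.4f", s$r_bar),
            if (is.na(s$q_bar)) "NA" else sprintf("%.3g", s$q_bar)),
    if (s$n_con == 0) {
      "Null output: no gene pair passed all filters in >= x genotypes."
    } else {
      census <- g$nodes |>
        dplyr::summarise(n = dplyr::n(), .by = "pattern") |>
        dplyr::arrange(.data$pattern)
      c(sprintf("Patterns: %d disconnected sub-graph(s): %s",
                nrow(census),
                paste(sprintf("[P=%d] %d genes", census$pattern, census$n),
                      collapse = ", ")),
        sprintf("Genes dropped from input: %d of %d", s$n_in - s$n_out, s$n_in))
    },
    sprintf("Chance rate of a spurious relation at (a=%d, f=%g, x=%d): %.3g (about one in %.0f)",
            g$a, th$f, th$x, pe, 1 / pe)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Reproduce the published chili-pepper cell-cycle analysis
#'
#' Runs the full pipeline on a local copy of the curated *Capsicum annuum*
#' fruit-development deposit (GEO series GSE165448; curated standardized
#' profiles distributed with the Salsa 1.0 archive). The deposit is not
#' redistributed with this package; download it and lay it out as:
#'
#' * `<dir>/sep.tsv` — long table `genotype  gene  time  expression` with
#'   the standardized profiles of the 12 accessions at 7 times,
#' * `<dir>/annotation.tsv` — `gene  term  label` with the GO
#'   biological-process annotation (terms `celcy`, `rep`, `vir`),
#' * `<dir>/tf.txt` — one TF gene identifier per line.
#'
#' @param dir Directory holding the deposit files.
#' @param terms Biological-process terms to analyse.
#' @param thresholds A [gfn_thresholds()] (defaults are the demonstration
#'   values: f = 0.1, mr2 = 0.7, q_out = 0.05, x = all 12 genotypes).
#' @return A list with one `gfn` per term, the meta-network over them, and
#'   the per-term [glance.gfn()] summary table.
#' @export
reproduce_capsicum <- function(dir, terms = c("celcy", "rep", "vir"),
                               thresholds = gfn_thresholds()) {
  need <- file.path(dir, c("sep.tsv", "annotation.tsv", "tf.txt"))
  if (!all(file.exists(need))) {
    stop("deposit files not found under ", dir, "; expected ",
         paste(basename(need), collapse = ", "), call. = FALSE)
  }
  data <- read_sep(need[1])
  ann <- read_annotation(need[2])
  tf <- read_tf_catalog(need[3])
  gfns <- purrr::map(terms, function(term) {
    genes <- select_genes_by_bp(data, ann, term)
    gene2gene(data, genes = genes, thresholds = thresholds, tf = tf,
              name = term)
  })
  names(gfns) <- terms
  mn <- if (length(gfns) >= 2) build_metanetwork(gfns) else NULL
  list(gfns = gfns, metanetwork = mn,
       summary = purrr::map(gfns, glance) |> purrr::list_rbind())
}
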