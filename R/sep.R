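#' Read a long-format table of time-course expression profiles
#'
#' Reads a tab-separated file with one row per (genotype, gene, time point)
#' and validates it into the long tibble layout used throughout the package.
#' Profiles are expected on a shared time grid: every genotype must use the
#' same set of sampling times (e.g. days after anthesis). A gene may be
#' absent from a genotype (its profile is then treated as missing), but a
#' present profile must cover the full grid.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param dialect Named character vector mapping the canonical column names
#'   `genotype`, `gene`, `time`, `expression` to the names used in the file.
#'   Defaults to the identity mapping.
#' @return A tibble with columns `genotype`, `gene` (character), `time`,
#'   `expression` (double), sorted by (genotype, gene, time).
#' @seealso [write_sep()], [standardize_sep()]
#' @export
read_sep <- function(path, dialect = NULL) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  canon <- c("genotype", "gene", "time", "expression")
  map <- stats::setNames(canon, canon)
  if (!is.null(dialect)) map[names(dialect)] <- unname(dialect)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    stop("input is missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    genotype = raw[[map[["genotype"]]]],
    gene = raw[[map[["gene"]]]],
    time = .parse_numeric(raw[[map[["time"]]]], "time"),
    expression = .parse_numeric(raw[[map[["expression"]]]], "expression")
  )
  validate_sep(out)
}

.parse_numeric <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & !(toupper(x) %in% c("NA", "NAN")))
  if (length(bad) > 0) {
    stop("non-numeric ", what, " value '", x[bad[1]], "' at data row ", bad[1],
         call. = FALSE)
  }
  out
}

#' Validate a long expression-profile table
#'
#' Checks the contract assumed by every analysis function: required columns,
#' numeric time/expression, no duplicated (genotype, gene, time) key, and a
#' time grid shared by all genotypes. Fewer than five time points triggers a
#' loud warning (correlations over so few points are too flimsy to be
#' useful) but is not an error.
#'
#' @param data A data frame with columns `genotype`, `gene`, `time`,
#'   `expression`.
#' @return The validated data as a tibble, sorted by (genotype, gene, time).
#' @export
validate_sep <- function(data) {
  need <- c("genotype", "gene", "time", "expression")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!is.numeric(data$time)) stop("`time` must be numeric", call. = FALSE)
  if (!is.numeric(data$expression)) stop("`expression` must be numeric", call. = FALSE)
  data$genotype <- as.character(data$genotype)
  data$gene <- as.character(data$gene)

  key <- paste(data$genotype, data$gene, data$time, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    d <- data[dup[1], ]
    stop(sprintf("duplicated (genotype, gene, time) row: (%s, %s, %g)",
                 d$genotype, d$gene, d$time), call. = FALSE)
  }

  grid <- sep_times(data)
  if (length(grid) < 2) stop("time grid must contain at least 2 points", call. = FALSE)
  bad <- data |>
    dplyr::summarise(
      ok = length(.data$time) == length(grid) && all(sort(.data$time) == grid),
      .by = c("genotype", "gene")
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    off <- paste(utils::head(paste0(bad$genotype, "/", bad$gene), 5), collapse = ", ")
    stop("ragged time grid: ", nrow(bad), " (genotype, gene) profile(s) do not ",
         "cover the shared grid {", paste(grid, collapse = ", "), "}: ", off,
         call. = FALSE)
  }
  if (length(grid) < 5) {
    warning("only ", length(grid), " time points: correlations over fewer than ",
            "five points are too flimsy to be trusted", call. = FALSE)
  }
  dplyr::arrange(data, .data$genotype, .data$gene, .data$time)
}

#' Write a long expression-profile table
#'
#' Inverse of [read_sep()]: writes the long tab-separated dialect, preceded
#' by provenance comment lines (see [gfnet_header()]). `read_sep()` of the
#' written file reproduces the data bit-exactly.
#'
#' @param data A validated long profile tibble.
#' @param path Output file path.
#' @param header Logical; prepend the provenance comment header.
#' @return `path`, invisibly.
#' @export
write_sep <- function(data, path, header = TRUE) {
  data <- validate_sep(data)
  lines <- c(
    if (header) gfnet_header(list(rows = nrow(data))),
    paste(c("genotype", "gene", "time", "expression"), collapse = "\t"),
    sprintf("%s\t%s\t%s\t%s", data$genotype, data$gene,
            format(data$time, digits = 17, trim = TRUE, scientific = FALSE),
            vapply(data$expression, .fmt_full, character(1)))
  )
  writeLines(lines, path)
  invisible(path)
}

.fmt_full <- function(x) {
  if (is.na(x)) return("NA")
  # shortest decimal representation that survives a double round trip
  for (digits in 1:17) {
    s <- formatC(x, digits = digits, format = "g")
    if (as.numeric(s) == x) return(s)
  }
  formatC(x, digits = 17, format = "g")
}

#' Shared time grid of a profile table
#'
#' @param data A long profile tibble.
#' @return Sorted unique sampling times.
#' @export
sep_times <- function(data) sort(unique(data$time))

#' Genotypes and genes present in a profile table
#'
#' `sep_genotypes()` and `sep_genes()` return lexicographically sorted
#' identifiers; `complete_genes()` returns the genes that have a full
#' profile in *every* genotype of `data` (the only genes eligible for
#' network estimation, so that the replication denominator is the same for
#' all pairs).
#'
#' @param data A long profile tibble.
#' @return Character vector of identifiers.
#' @export
sep_genotypes <- function(data) sort(unique(as.character(data$genotype)))

#' @rdname sep_genotypes
#' @export
sep_genes <- function(data) sort(unique(as.character(data$gene)))

#' @rdname sep_genotypes
#' @export
complete_genes <- function(data) {
  a <- length(sep_genotypes(data))
  tt <- length(sep_times(data))
  counts <- data |>
    dplyr::filter(is.finite(.data$expression)) |>
    dplyr::summarise(n = dplyr::n(), .by = c("gene", "genotype")) |>
    dplyr::filter(.data$n == tt) |>
    dplyr::summarise(a_obs = dplyr::n(), .by = "gene") |>
    dplyr::filter(.data$a_obs == a)
  sort(counts$gene)
}

#' Standardize expression profiles to mean 0 and unit variance
#'
#' Converts each (genotype, gene) time profile into a standardized
#' expression profile (SEP): values are centred on the profile mean and
#' divided by the profile *sample* standard deviation (denominator T - 1).
#' Pearson correlation is invariant to this affine rescaling, so any
#' location/scale convention yields the same networks; standardization only
#' makes profile shapes comparable across genes and genotypes.
#'
#' Zero-variance (constant) profiles cannot be standardized; they are
#' removed from the output and reported with a message. The operation is
#' idempotent: standardizing a standardized table changes nothing.
#'
#' @param data A long profile tibble (raw or already standardized).
#' @return A tibble of the same layout with standardized `expression`.
#' @export
standardize_sep <- function(data) {
  data <- validate_sep(data)
  out <- data |>
    dplyr::mutate(
      expression = {
        s <- stats::sd(.data$expression)
        if (!is.finite(s) || s == 0) rep(NA_real_, length(.data$expression))
        else (.data$expression - mean(.data$expression)) / s
      },
      .by = c("genotype", "gene")
    )
  dropped <- out |>
    dplyr::filter(is.na(.data$expression)) |>
    dplyr::distinct(.data$genotype, .data$gene)
  if (nrow(dropped) > 0) {
    message("dropped ", nrow(dropped), " zero-variance or incomplete profile(s): ",
            paste(utils::head(paste0(dropped$genotype, "/", dropped$gene), 5),
                  collapse = ", "),
            if (nrow(dropped) > 5) ", ...")
    out <- dplyr::anti_join(out, dropped, by = c("genotype", "gene"))
  }
  out
}

#' Check whether a table holds standardized profiles
#'
#' @param data A long profile tibble.
#' @param tol Numeric tolerance on the profile mean and sample sd.
#' @return `TRUE` iff every profile has mean 0 and sample sd 1 within `tol`.
#' @export
is_standardized <- function(data, tol = 1e-9) {
  chk <- data |>
    dplyr::summarise(m = mean(.data$expression), s = stats::sd(.data$expression),
                     .by = c("genotype", "gene"))
  all(abs(chk$m) < tol & abs(chk$s - 1) < tol)
}

#' Read a gene-to-biological-process annotation table
#'
#' Expects a tab-separated file with columns `gene`, `term` and optionally
#' `label` (a human-readable term name). The mapping is many-to-many: a gene
#' may carry zero or many terms.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `gene`, `term`, `label`.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("gene", "term") %in% names(ann))) {
    stop("annotation file must have columns `gene` and `term`", call. = FALSE)
  }
  if (!"label" %in% names(ann)) ann$label <- NA_character_
  dplyr::distinct(ann[, c("gene", "term", "label")])
}

#' Read a transcription-factor catalog
#'
#' One gene identifier per line; `#` starts a comment.
#'
#' @param path Path to the catalog file.
#' @return Sorted character vector of TF gene identifiers.
#' @export
read_tf_catalog <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  sort(unique(x[nzchar(x)]))
}

#' Select the genes of a biological process present in every genotype
#'
#' Returns, sorted lexicographically, the genes annotated with `term` that
#' also carry a complete profile in every genotype of `data`. Annotated
#' genes dropped for missingness are reported with a warning, since they
#' silently shrink the input gene set of a network run.
#'
#' @param data A long profile tibble.
#' @param annotation Annotation tibble as returned by [read_annotation()].
#' @param term A biological-process term identifier present in `annotation`.
#' @return Character vector of gene identifiers.
#' @export
select_genes_by_bp <- function(data, annotation, term) {
  if (!term %in% annotation$term) {
    stop("unknown annotation term: ", term, call. = FALSE)
  }
  annotated <- sort(unique(annotation$gene[annotation$term == term]))
  present <- intersect(annotated, complete_genes(data))
  dropped <- setdiff(annotated, present)
  if (length(dropped) > 0) {
    warning("dropped ", length(dropped), " annotated gene(s) lacking complete ",
            "profiles in every genotype: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ...", call. = FALSE)
  }
  present
}
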