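#' Two-sided p-value of a Pearson correlation
#'
#' Refers t = r * sqrt(n - 2) / sqrt(1 - r^2) to a Student t distribution
#' with n - 2 degrees of freedom, where n is the number of time points.
#' |r| = 1 returns exactly 0.
#'
#' @param r Pearson correlation coefficient(s) in \[-1, 1\].
#' @param n Number of paired observations (time points); must be >= 3.
#' @return Two-sided p-value(s) in \[0, 1\].
#' @export
cor_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need at least 3 observations (n - 2 df)", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                            lower.tail = FALSE))
  pmin(p, 1)
}

#' FDR q-values for a set of p-values
#'
#' Converts p-values to q-values with the monotone step-up adjustment
#' (`method = "bh"`, the default): the q-value of the i-th order statistic
#' is min over j >= i of p_(j) * m / j, capped at 1. `method = "storey"`
#' additionally multiplies by an estimate of the null proportion pi0
#' (Storey's estimator at lambda = 0.5), which is less conservative when
#' many tests are non-null.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA`s propagate.
#' @param method `"bh"` or `"storey"`.
#' @return q-values in the original input order.
#' @export
q_values <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    lambda <- 0.5
    pi0 <- min(1, mean(p > lambda, na.rm = TRUE) / (1 - lambda))
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
    q <- pmin(1, q * pi0)
  }
  q
}

# Maximum |externally studentized residual| of the simple regression of y on
# x, computed closed-form for *standardized* columns (mean 0, sample sd 1),
# where the fitted line is yhat = r * x and the leverages are
# h_t = 1/T + x_t^2 / (T - 1). Vectorised over pairs: M is the T x g
# standardized profile matrix, ii/jj column indices (x = ii regressor),
# r the pairwise correlations. Returns NA where T < 4 or a profile is NA;
# exact fits (all residuals ~ 0) return 0.
.max_abs_rstudent <- function(M, ii, jj, r) {
  tt <- nrow(M)
  n_pair <- length(ii)
  if (tt < 4) return(rep(NA_real_, n_pair))
  X <- M[, ii, drop = FALSE]
  Y <- M[, jj, drop = FALSE]
  E <- Y - sweep(X, 2, r, `*`)
  sse <- colSums(E^2)
  s2 <- sse / (tt - 2)
  H <- 1 / tt + X^2 / (tt - 1)
  denom <- sweep(1 - H, 2, s2, `*`)
  tint2 <- E^2 / denom
  # internal -> external: t_ext^2 = t_int^2 (T-3) / (T-2-t_int^2)
  text2 <- tint2 * (tt - 3) / pmax(tt - 2 - tint2, .Machine$double.xmin)
  out <- sqrt(apply(text2, 2, max))
  out[sse < 1e-20] <- 0
  out[!is.finite(sse)] <- NA_real_
  out
}

#' Critical value of the regression-outlier screen
#'
#' The screen flags a pair when the maximum absolute externally studentized
#' residual of the y-on-x regression over the T time points exceeds the
#' two-sided Student t critical value at level `q_out / T` (Bonferroni
#' across the T points) with T - 3 degrees of freedom.
#'
#' @param q_out Outlier-elimination level in (0, 1).
#' @param n_times Number of time points T (>= 4).
#' @return The critical value.
#' @export
outlier_critical <- function(q_out, n_times) {
  stats::qt(1 - q_out / (2 * n_times), df = n_times - 3)
}

#' Flag a gene pair whose correlation is driven by a single aberrant point
#'
#' Fits the least-squares line of `y` on `x` over the shared time points and
#' flags the pair when any externally studentized residual exceeds the
#' Bonferroni-corrected critical value (see [outlier_critical()]). The
#' regression orientation is fixed (x = regressor); pair tables always use
#' the lexicographically smaller gene as x.
#'
#' @param x,y Numeric vectors of equal length T.
#' @param q_out Outlier-elimination level in (0, 1).
#' @return `TRUE` if the pair is outlier-driven. T < 4 (no residual degrees
#'   of freedom) forces `FALSE` with a warning.
#' @export
outlier_flag <- function(x, y, q_out = 0.05) {
  tt <- length(x)
  if (length(y) != tt) stop("x and y must have equal length", call. = FALSE)
  if (tt < 4) {
    warning("fewer than 4 time points: outlier screen skipped (flag = FALSE)",
            call. = FALSE)
    return(FALSE)
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(FALSE)
  M <- cbind((x - mean(x)) / sx, (y - mean(y)) / sy)
  r <- stats::cor(x, y)
  m <- .max_abs_rstudent(M, 1L, 2L, r)
  isTRUE(m > outlier_critical(q_out, tt))
}

# Minimum leave-one-out r^2 over the T points (alternative outlier rule:
# a pair is outlier-driven when removing one time point can push r^2 below
# the mr2 threshold).
.min_loo_r2 <- function(M, ii, jj) {
  tt <- nrow(M)
  n_pair <- length(ii)
  out <- rep(NA_real_, n_pair)
  if (tt < 4) return(out)
  for (k in seq_len(n_pair)) {
    x <- M[, ii[k]]; y <- M[, jj[k]]
    r2s <- vapply(seq_len(tt), function(t) {
      r <- suppressWarnings(stats::cor(x[-t], y[-t]))
      if (is.na(r)) 1 else r^2
    }, numeric(1))
    out[k] <- min(r2s)
  }
  out
}

# Standardized T x g profile matrix for one genotype; columns are genes in
# lexicographic order, rows the sorted time grid. Genes with zero-variance
# or incomplete profiles become all-NA columns (non-testable downstream).
.sep_matrix <- function(data, genes, genotype) {
  genes <- sort(genes)
  grid <- sep_times(data)
  d <- data[data$genotype == genotype & data$gene %in% genes, , drop = FALSE]
  M <- matrix(NA_real_, nrow = length(grid), ncol = length(genes),
              dimnames = list(NULL, genes))
  if (nrow(d) > 0) {
    ri <- match(d$time, grid)
    ci <- match(d$gene, genes)
    M[cbind(ri, ci)] <- d$expression
  }
  s <- apply(M, 2, stats::sd)
  m <- colMeans(M)
  bad <- !is.finite(s) | s == 0
  M <- sweep(sweep(M, 2, m, `-`), 2, s, `/`)
  M[, bad] <- NA_real_
  M
}

#' Per-genotype correlation statistics for all gene pairs
#'
#' For each genotype, estimates the Pearson correlation of every unordered
#' pair of the g input genes over the T shared time points (g(g-1)/2 pairs),
#' its two-sided p-value, FDR q-values computed over exactly the testable
#' pairs of that genotype, and the regression-outlier statistic. Pairs
#' involving a zero-variance or incomplete profile are kept as non-testable
#' records (`testable = FALSE`) and excluded from the FDR conversion.
#'
#' @param data A long profile tibble (standardized internally if needed —
#'   Pearson correlation is scale-invariant).
#' @param genes Genes to test; default all genes complete in every genotype.
#' @param genotypes Genotypes to analyse; default all present.
#' @param q_out Level of the outlier screen used for the `outlier` column.
#' @param fdr_method Passed to [q_values()].
#' @param outlier_rule `"rstudent"` (default: Bonferroni-corrected
#'   externally studentized residual screen) or `"loo_r2"` (flag pairs whose
#'   minimum leave-one-out r^2 drops below `mr2_loo`).
#' @param mr2_loo Determination-coefficient floor used by the `"loo_r2"`
#'   rule.
#' @return A tibble with one row per (genotype, pair): columns `genotype`,
#'   `gene_i`, `gene_j` (gene_i < gene_j), `r`, `r2`, `p`, `q`,
#'   `max_rstudent`, `min_loo_r2` (only under the loo rule), `outlier`,
#'   `testable`, and attribute `m` (testable tests per genotype).
#' @export
pair_stats <- function(data, genes = NULL, genotypes = NULL, q_out = 0.05,
                       fdr_method = c("bh", "storey"),
                       outlier_rule = c("rstudent", "loo_r2"), mr2_loo = 0.7) {
  fdr_method <- match.arg(fdr_method)
  outlier_rule <- match.arg(outlier_rule)
  data <- validate_sep(data)
  if (is.null(genes)) genes <- complete_genes(data)
  genes <- sort(unique(as.character(genes)))
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  if (is.null(genotypes)) genotypes <- sep_genotypes(data)
  genotypes <- sort(unique(as.character(genotypes)))
  tt <- length(sep_times(data))
  if (tt < 4 && outlier_rule == "rstudent") {
    warning("fewer than 4 time points: outlier screen skipped for all pairs",
            call. = FALSE)
  }

  idx <- which(upper.tri(diag(length(genes))), arr.ind = TRUE)
  ii <- idx[, 1]; jj <- idx[, 2]  # ii < jj, so gene_i < gene_j lexicographically
  ord <- order(ii, jj)
  ii <- ii[ord]; jj <- jj[ord]

  res <- purrr::map(genotypes, function(gt) {
    M <- .sep_matrix(data, genes, gt)
    R <- suppressWarnings(stats::cor(M))
    r <- R[cbind(ii, jj)]
    testable <- is.finite(r)
    p <- rep(NA_real_, length(r))
    p[testable] <- cor_pvalue(r[testable], tt)
    q <- rep(NA_real_, length(r))
    q[testable] <- q_values(p[testable], method = fdr_method)
    tab <- tibble::tibble(
      genotype = gt,
      gene_i = genes[ii], gene_j = genes[jj],
      r = r, r2 = r^2, p = p, q = q,
      max_rstudent = .max_abs_rstudent(M, ii, jj, r),
      testable = testable
    )
    if (outlier_rule == "loo_r2") {
      tab$min_loo_r2 <- .min_loo_r2(M, ii, jj)
      tab$outlier <- testable & !is.na(tab$min_loo_r2) & tab$min_loo_r2 < mr2_loo
    } else {
      crit <- if (tt >= 4) outlier_critical(q_out, tt) else Inf
      tab$outlier <- testable & !is.na(tab$max_rstudent) & tab$max_rstudent > crit
    }
    tab
  }) |> purrr::list_rbind()

  m <- res |>
    dplyr::filter(.data$testable) |>
    dplyr::summarise(m = dplyr::n(), .by = "genotype")
  attr(res, "m") <- m
  attr(res, "n_times") <- tt
  attr(res, "outlier_rule") <- outlier_rule
  res
}

#' Export a pair-statistics table as TSV
#'
#' @param stats A tibble from [pair_stats()] (optionally with a `pass`
#'   column added by thresholding).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_stats <- function(stats, path) {
  .write_tsv_commented(stats, path, list(kind = "pair_stats"))
}
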