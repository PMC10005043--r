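#' Chance rate of a gene relation surviving the replication filter
#'
#' Under the null, a fortuitous gene relation passes the per-genotype filter
#' with probability `f` (the FDR threshold) independently in each of the `a`
#' genotypes, so the number of supporting genotypes X is Binomial(a, f).
#' The probability that a chance relation is nevertheless reported at the
#' required support `x` is the upper tail P(X >= x), computed by direct
#' summation of C(a, k) f^k (1 - f)^(a - k) for k = x..a in log space (so
#' very small tails, e.g. f^a for x = a, do not underflow prematurely).
#'
#' With a = 12 genotypes and f = 0.05, requiring x = 5 gives ~1.84e-4
#' (about one chance relation in 5436), and requiring support in all 12
#' genotypes gives 0.05^12 ~ 2.4e-16.
#'
#' @param a Total number of independent genotypes (positive integer).
#' @param f Per-genotype false-relation rate in (0, 1), conventionally the
#'   FDR threshold of the network run.
#' @param x Required support, integer in 0..a. Vectorised.
#' @return P(X >= x) in \[0, 1\].
#' @export
pred_error_g2g <- function(a, f, x) {
  if (a < 1 || a != round(a)) stop("`a` must be a positive integer", call. = FALSE)
  if (f <= 0 || f >= 1) stop("`f` must lie in (0, 1)", call. = FALSE)
  if (any(x != round(x))) stop("`x` must be integer", call. = FALSE)
  if (any(x > a)) stop("`x` cannot exceed `a`", call. = FALSE)
  vapply(x, function(xi) {
    if (xi <= 0) return(1)
    if (xi == a) return(f^a)  # single-term tail, kept exact
    k <- xi:a
    lterms <- lchoose(a, k) + k * log(f) + (a - k) * log1p(-f)
    mx <- max(lterms)
    min(1, exp(mx) * sum(exp(lterms - mx)))
  }, numeric(1))
}

#' Factorial grid of replication-filter chance rates
#'
#' Evaluates [pred_error_g2g()] over the full factorial of the supplied
#' genotype counts, false-relation rates and support requirements.
#' Combinations with x > a are invalid and are skipped with a message.
#'
#' @param a_values,f_values,x_values Numeric vectors (non-empty).
#' @return A tibble with columns `a`, `f`, `x`, `p_chance` and the
#'   reciprocal `one_in` (= 1 / p_chance).
#' @export
error_grid <- function(a_values, f_values, x_values) {
  if (length(a_values) == 0 || length(f_values) == 0 || length(x_values) == 0) {
    stop("grids must be non-empty", call. = FALSE)
  }
  grid <- tidyr::expand_grid(a = a_values, f = f_values, x = x_values)
  bad <- grid$x > grid$a
  if (any(bad)) {
    message("skipping ", sum(bad), " grid cell(s) with x > a")
    grid <- grid[!bad, , drop = FALSE]
  }
  grid |>
    dplyr::mutate(
      p_chance = purrr::pmap_dbl(list(.data$a, .data$f, .data$x),
                                 function(a, f, x) pred_error_g2g(a, f, x)),
      one_in = 1 / .data$p_chance
    )
}

#' @describeIn error_grid Line plot of the chance rate against required
#'   support, one line per (a, f) combination, log-scaled y axis.
#' @param object An `error_grid()` tibble.
#' @param ... Ignored.
#' @export
plot_error_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$p_chance,
                                       colour = factor(.data$f),
                                       linetype = factor(.data$a))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "required supporting genotypes (x)",
                  y = "chance rate P(X ≥ x)",
                  colour = "per-genotype rate f",
                  linetype = "genotypes a")
}
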