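#' Exact binomial triangle difference test
#'
#' In a triangle test each panelist picks the odd sample among three, so the
#' probability of a correct pick under the no-difference hypothesis is 1/3.
#' The one-sided p-value is the exact binomial upper tail,
#' `P(X >= n_correct)` with `X ~ Binomial(n_total, 1/3)`, accumulated in
#' log-space (no normal approximation).
#'
#' @param n_correct Number of correct identifications (integer).
#' @param n_total Number of panelists (integer >= 1).
#' @param alpha Significance level used for the `significant` flag.
#' @return An object of classes `triangle_test` and `htest` with the exact
#'   `p.value`, the observed proportion, and `significant` at `alpha`.
#' @examples
#' triangle_test(24, 38)
#' @export
triangle_test <- function(n_correct, n_total, alpha = 0.05) {
  .check_count(n_correct, "n_correct")
  .check_count(n_total, "n_total")
  if (n_total < 1L) stop("n_total must be >= 1", call. = FALSE)
  if (n_correct < 0L || n_correct > n_total)
    stop("n_correct must be between 0 and n_total", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]", call. = FALSE)

  p_value <- .binom_upper_tail(n_correct, n_total, 1 / 3)
  structure(list(
    statistic = c("correct" = n_correct),
    parameter = c("panelists" = n_total),
    p.value = p_value,
    estimate = c("proportion correct" = n_correct / n_total),
    null.value = c("probability of correct pick" = 1 / 3),
    alternative = "greater",
    method = "Exact binomial triangle test (guessing probability 1/3)",
    data.name = sprintf("%d correct of %d panelists", n_correct, n_total),
    alpha = alpha,
    significant = p_value <= alpha
  ), class = c("triangle_test", "htest"))
}

.check_count <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x))
    stop(what, " must be a single integer", call. = FALSE)
  invisible(x)
}

# exact upper tail P(X >= x), X ~ Binomial(n, p), summed in log-space from
# the smallest terms up to limit cancellation
.binom_upper_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  k <- x:n
  log_terms <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  m <- max(log_terms)
  min(1, exp(m) * sum(exp(sort(log_terms - m))))
}

#' @export
print.triangle_test <- function(x, ...) {
  # standard htest layout plus the decision at alpha
  class(x) <- "htest"
  print(x, ...)
  cat(sprintf("decision: %s at alpha = %g\n",
              if (x$significant) "difference perceived (reject guessing)"
              else "no significant difference", x$alpha))
  invisible(x)
}

#' Minimum correct answers for a significant triangle test
#'
#' Smallest number of correct identifications whose exact upper-tail
#' p-value is at or below `alpha`, for a panel of `n_total`.
#'
#' @param n_total Number of panelists (integer >= 1).
#' @param alpha Significance level in (0, 1).
#' @return Integer threshold `m` with
#'   `triangle_test(m, n_total)$p.value <= alpha` and the tail above `alpha`
#'   at `m - 1` (0 if even zero correct is "significant", i.e. `alpha = 1`).
#' @examples
#' triangle_threshold(38, 0.05)
#' @export
triangle_threshold <- function(n_total, alpha) {
  .check_count(n_total, "n_total")
  if (n_total < 1L) stop("n_total must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]", call. = FALSE)
  for (m in 0:n_total) {
    if (.binom_upper_tail(m, n_total, 1 / 3) <= alpha) return(m)
  }
  n_total + 1L  # unreachable significance (alpha below (1/3)^n)
}
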