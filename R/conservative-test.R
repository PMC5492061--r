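#' Conservative p-value for the multinomial matching test
#'
#' Exact conservative test of a putative condition value (age or succession
#' interval) from a categorical response.  The training data at the candidate
#' condition are \code{n} specimens classified into one of \code{c} response
#' categories; the test statistic is \code{m}, the number of training
#' specimens falling in the same category as the mystery specimen.  The
#' p-value is the least upper bound, over all multinomial probability vectors
#' \eqn{p = (p_1, \dots, p_c)} on the \code{c} categories, of the null
#' probability of observing \code{m} or fewer matches:
#' \deqn{\sup_p \sum_j p_j \, F_B(m;\, n, p_j),}
#' where \eqn{F_B} is the binomial distribution function.  Maximizing over
#' the whole simplex makes the test valid whatever the true category
#' probabilities are (the least favorable configuration), so non-rejected
#' condition values form a confidence set with at least the nominal coverage.
#'
#' The supremum is attained within the structured family of probability
#' vectors having \code{r} coordinates equal to some \eqn{q}, one coordinate
#' equal to \eqn{1 - rq}, and the rest zero (\code{r} in \code{1..c-1},
#' \eqn{q \in [0, 1/r]}): the objective is symmetric and separable in the
#' coordinates, so its maximum lies on such a ridge.  Each \code{r} gives a
#' one-dimensional maximization solved numerically to tolerance 1e-9; the
#' unit tests check this against a brute-force search over the simplex.
#'
#' @param n number of training specimens at the candidate condition
#'   (integer, at least 1).  Vectorized.
#' @param c number of response categories in the declared scheme (integer,
#'   at least 2).  For presence/absence of \code{s} species, \code{c = 2^s}.
#' @param m observed match count, between 0 and \code{n}.  Vectorized.
#' @return the conservative p-value, in (0, 1].
#' @seealso [rejection_threshold()], [min_sample_size()],
#'   [categorical_confidence_set()]
#' @examples
#' conservative_p_value(7, 2, 0)   # ~0.0491: just below 5%
#' conservative_p_value(6, 2, 0)   # > 0.05: six specimens can never reject
#' @export
conservative_p_value <- function(n, c, m) {
  if (length(c) != 1L || is.na(c) || c < 2 || c != round(c))
    stop("'c' must be a single integer >= 2: with one category the test is degenerate",
         call. = FALSE)
  if (any(is.na(n)) || any(n < 1) || any(n != round(n)))
    stop("'n' must be integer >= 1", call. = FALSE)
  if (length(m) == 1L && length(n) > 1L) m <- rep(m, length(n))
  if (length(n) == 1L && length(m) > 1L) n <- rep(n, length(m))
  if (any(is.na(m)) || any(m < 0) || any(m > n) || any(m != round(m)))
    stop("'m' must be an integer in 0..n", call. = FALSE)
  vapply(seq_along(n), function(i) .sup_match_prob(n[i], c, m[i]), numeric(1))
}

# sup over the structured candidate family, one 1-D maximization per r
.sup_match_prob <- function(n, c, m) {
  if (m >= n) return(1)
  f <- function(q, r) r * q * pbinom(m, n, q) + (1 - r * q) * pbinom(m, n, 1 - r * q)
  best <- 0
  for (r in seq_len(c - 1L)) {
    opt <- optimize(f, c(0, 1 / r), r = r, maximum = TRUE, tol = 1e-9)
    best <- max(best, opt$objective, f(0, r), f(1 / r, r))
  }
  best
}

#' Largest rejectable match count at a given training sample size
#'
#' Returns the largest match count \code{k} for which the conservative
#' matching test still rejects at level \code{alpha}: a candidate condition
#' is rejected whenever at most \code{k} of its \code{n} training specimens
#' match the mystery specimen's category.  With too few training specimens
#' no rejection is possible at all and \code{NA} is returned.
#'
#' @inheritParams conservative_p_value
#' @param alpha significance level, in (0, 1).  Default 0.05.
#' @return integer threshold \code{k >= 0}, or \code{NA_integer_} when even
#'   zero matches cannot be rejected.
#' @examples
#' rejection_threshold(20, 2)  # 1: reject on zero or one match
#' rejection_threshold(6, 2)   # NA: below the minimum sample size
#' @export
rejection_threshold <- function(n, c, alpha = 0.05) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  if (conservative_p_value(n, c, 0L) > alpha) return(NA_integer_)
  k <- 0L
  while (k + 1L <= n && conservative_p_value(n, c, k + 1L) <= alpha)
    k <- k + 1L
  k
}

#' Minimum training sample size for a categorical response
#'
#' Smallest per-condition training sample size \code{n} at which the
#' conservative matching test can reject a condition value at level
#' \code{alpha} when at most \code{k} training specimens match the mystery
#' specimen.  Below this size the training data cannot support any rejection,
#' i.e. every confidence set is the full set of candidate conditions.  The
#' conservative p-value is non-increasing in \code{n}, so an increasing
#' search terminates at the exact boundary.
#'
#' @inheritParams rejection_threshold
#' @param k match-count rejection rule: reject when at most \code{k}
#'   training specimens match (integer, at least 0).
#' @return smallest integer \code{n} with
#'   \code{conservative_p_value(n, c, k) <= alpha}.
#' @examples
#' min_sample_size(2, 0)  # 7 carcasses for one species present/absent
#' min_sample_size(6, 0)  # 37 insects per age for six life stages
#' @export
min_sample_size <- function(c, k = 0L, alpha = 0.05) {
  stopifnot(length(k) == 1L, k >= 0, k == round(k),
            length(alpha) == 1L, alpha > 0, alpha < 1)
  n <- as.integer(k) + 1L
  while (conservative_p_value(n, c, k) > alpha)
    n <- n + 1L
  n
}
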