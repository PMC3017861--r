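#' Karlin-Altschul calibration of a match/mismatch scheme
#'
#' Solves for the positive parameter lambda of the ungapped Karlin-Altschul
#' statistics, i.e. the unique positive root of
#' \deqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}
#' for a simple match/mismatch nucleotide scoring with background letter
#' probabilities `background`.
#'
#' @param match positive integer match reward.
#' @param mismatch negative integer mismatch penalty.
#' @param background per-letter probabilities (A, C, G, T), summing to 1.
#' @param tol relative tolerance of the root.
#' @return the positive real lambda.
#' @examples
#' solve_lambda(1, -1)            # log(3) for a uniform background
#' @export
solve_lambda <- function(match, mismatch, background = rep(0.25, 4),
                         tol = 1e-12) {
  stopifnot(match > 0, mismatch < 0)
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0))
    stop("background probabilities must be nonnegative and sum to 1")
  p_id <- sum(background^2)
  escore <- p_id * match + (1 - p_id) * mismatch
  if (escore >= 0)
    stop("calibration error: expected per-letter score is non-negative, ",
         "no positive lambda exists")
  f <- function(l) p_id * exp(l * match) + (1 - p_id) * exp(l * mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1e-12, hi), tol = tol)$root
}

#' Nucleotide scoring scheme with Karlin-Altschul statistics
#'
#' Bundles the local-alignment scores with the ungapped Karlin-Altschul
#' parameters used to convert scores into E-values.  Defaults are BLASTN-like
#' (+1/-3 with affine gaps); `lambda` is calibrated from the match/mismatch
#' scores and background unless supplied.  E-values computed from gapped
#' scores with these ungapped parameters are an approximation, which is all
#' the coarse cutoffs used downstream require; both `lambda` and `k_const`
#' can be overridden.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores; a gap of length
#'   L costs `gap_open + L * gap_extend`.
#' @param background per-letter background probabilities (A, C, G, T).
#' @param k_const Karlin-Altschul K.
#' @param lambda Karlin-Altschul lambda; calibrated if `NULL`.
#' @return an object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' sc$lambda
#' @export
scoring_scheme <- function(match = 1L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, background = rep(0.25, 4),
                           k_const = 0.71, lambda = NULL) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            k_const > 0)
  if (is.null(lambda))
    lambda <- solve_lambda(match, mismatch, background)
  stopifnot(lambda > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 background = background, k_const = k_const, lambda = lambda),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: match %+d mismatch %+d gap %d/%d  lambda %.4f K %.3f\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend, x$lambda,
              x$k_const))
  invisible(x)
}

#' Effective search space
#'
#' @param m effective query length (letters, >= 1).
#' @param n effective database length (letters, >= 1).
#' @return an object of class `search_space`.
#' @export
search_space <- function(m, n) {
  stopifnot(m >= 1, n >= 1)
  structure(list(m = as.numeric(m), n = as.numeric(n)),
            class = "search_space")
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' \eqn{E = K m n e^{-\lambda S}}: the expected number of chance local
#' alignments scoring at least S in a search space of m-by-n letters.
#'
#' @param score alignment score (vectorised).
#' @param space a [search_space()].
#' @param scheme a calibrated [scoring_scheme()].
#' @return nonnegative E-value(s), monotone decreasing in `score`.
#' @export
evalue_of <- function(score, space, scheme) {
  if (is.null(scheme$lambda) || is.null(scheme$k_const) ||
      !is.finite(scheme$lambda) || !is.finite(scheme$k_const))
    stop("calibration error: scheme has no lambda/K")
  stopifnot(inherits(space, "search_space"))
  scheme$k_const * space$m * space$n * exp(-scheme$lambda * score)
}
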