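# Exhaustive reference fitter used to validate the EM implementation on
# tiny instances.

#' Exhaustive grid-search reference fit (tiny instances)
#'
#' Brute-force maximum likelihood for a 2-component Bernoulli mixture over a
#' 2-genome presence/absence matrix: both components' per-genome
#' probabilities are swept over a regular \code{step} grid (clamped to
#' \eqn{[10^{-4}, 1-10^{-4}]}, matching [fitBernoulliMixture()]'s clamp) and
#' the mixing weight is profiled at every grid point (the log-likelihood is
#' concave in the weight for fixed profiles).  This is a slow, independent
#' reference for validating EM fits, not a fitter — the grid has
#' \eqn{O(step^{-4})} points.
#'
#' @param pa a [PresenceAbsenceMatrix-class] with exactly 2 genomes.
#' @param step grid resolution (default 0.01).
#' @param pi_iter fixed-point iterations for the mixing-weight profile.
#' @return A list with \code{logLik}, \code{pi}, \code{theta1},
#'   \code{theta2}.
#' @seealso [fitBernoulliMixture()]
#' @export
bmmGridSearch <- function(pa, step = 0.01, pi_iter = 25L) {
  stopifnot(is(pa, "PresenceAbsenceMatrix"))
  X <- paMatrix(pa)
  if (ncol(X) != 2L)
    stop("the grid reference supports exactly 2 genomes", call. = FALSE)
  pat <- X[, 1] * 2L + X[, 2]           # 0..3 = (0,0),(0,1),(1,0),(1,1)
  counts <- tabulate(pat + 1L, nbins = 4L)
  bmm_grid_search_2x2(as.numeric(counts), step, THETA_EPS,
                      as.integer(pi_iter))
}

#' @useDynLib essMiner, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
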