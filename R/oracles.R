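#' Closed-form expectations used to validate the stochastic engine
#'
#' Pure functions with no dependence on the simulation code paths. The test
#' suite checks that engine means match these expectations to within a few
#' standard errors; if either side drifts, the tests fail.
#'
#' `neutral_copy_growth()` gives the expected mean diploid copy number after
#' `g` generations of unchecked transposition (no selection, no clusters):
#' every copy produces `u` new copies per generation in expectation, so the
#' mean grows geometrically by `(1 + u)` per generation.
#'
#' `prob_escapes_trap()` gives the probability that none of `k` uniformly
#' placed insertions lands inside piRNA clusters covering a fraction `c` of
#' the genome: `(1 - c)^k`.
#'
#' `expected_initial_mean_fitness()` gives the exact mean fitness of a
#' freshly seeded population under the linear model: the mean diploid copy
#' number is `seeds/N`, so mean fitness is `1 - x * seeds/N` (exact as long
#' as no individual is pushed to the clamping region).
#'
#' @param n0 Initial mean diploid copy number.
#' @param u Transposition rate per copy per generation.
#' @param g Number of generations.
#' @param k Number of uniformly placed insertions.
#' @param c Fraction of the genome inside clusters, in `[0, 1]`.
#' @param seeds Number of seed insertions.
#' @param N Population size.
#' @param x Linear selection coefficient.
#' @return A single expected value (mean copies, probability, or fitness).
#' @examples
#' neutral_copy_growth(1, 0.1, 10)          # 1.1^10
#' prob_escapes_trap(10, 0.03)              # 0.97^10
#' expected_initial_mean_fitness(1000, 20, 0.01) # 0.5
#' @export
neutral_copy_growth <- function(n0, u, g) {
  stopifnot(u >= 0, g >= 0)
  n0 * (1 + u)^g
}

#' @rdname neutral_copy_growth
#' @export
prob_escapes_trap <- function(k, c) {
  stopifnot(c >= 0, c <= 1, k >= 0)
  (1 - c)^k
}

#' @rdname neutral_copy_growth
#' @export
expected_initial_mean_fitness <- function(seeds, N, x) {
  stopifnot(seeds >= 0, N > 0, x >= 0)
  w <- 1 - x * seeds / N
  if (w < 0) {
    warning("mean load is in the clamping region; value is approximate",
            call. = FALSE)
  }
  max(0, w)
}
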