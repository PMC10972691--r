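#' Unit conversions between scaled and absolute demographic parameters
#'
#' The coalescent machinery works in scaled units; published estimates are in
#' absolute units.  The conversions are `t = T * 2 * Ne_ref * g` (split time
#' in generations/years from coalescent units of `2 * Ne_ref` generations),
#' `Ne = theta / (4 * mu)` and `M = 2 * Ne_recipient * m` (scaled migration
#' rate from the per-lineage per-generation migration probability).  All
#' functions are vectorized and round-trip exactly.
#'
#' @param T Split time in coalescent units of `2 * Ne_ref` generations.
#' @param t Absolute split time in generations.
#' @param ne_ref Reference diploid effective size used for time scaling.
#' @param g Generation time in years (default 1).
#' @param theta Population-scaled mutation rate `4 * Ne * mu`.
#' @param mu Mutation rate per site per generation.
#' @param m Per-lineage per-generation migration probability.
#' @param M Scaled migration rate `2 * Ne_recipient * m`.
#' @param ne_recipient Diploid effective size of the population receiving
#'   migrants (forwards in time).
#' @return A numeric vector.
#' @examples
#' t_from_T(3.3501, 377000)            # about 2.526 Mya at g = 1
#' M_from_m(1.29e-8, 377000)           # about 0.0097
#' migrant_fraction(3.3501, 0.0097)    # about 3.2%
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
t_from_T <- function(T, ne_ref, g = 1) T * 2 * ne_ref * g

#' @rdname unit-conversions
#' @export
T_from_t <- function(t, ne_ref, g = 1) t / (2 * ne_ref * g)

#' @rdname unit-conversions
#' @export
ne_from_theta <- function(theta, mu) theta / (4 * mu)

#' @rdname unit-conversions
#' @export
theta_from_ne <- function(ne_ref, mu) 4 * ne_ref * mu

#' @rdname unit-conversions
#' @export
M_from_m <- function(m, ne_recipient) 2 * ne_recipient * m

#' @rdname unit-conversions
#' @export
m_from_M <- function(M, ne_recipient) M / (2 * ne_recipient)

#' Total probability that a lineage traces back through migration
#'
#' Under a unidirectional IM history, the probability that a lineage sampled
#' in the recipient species migrates (backwards in time) before the split is
#' `1 - exp(-T * M)`, with `T` in coalescent units of `2 * Ne_recipient`
#' generations and `M = 2 * Ne_recipient * m`.
#'
#' @inheritParams unit-conversions
#' @return Probability in `[0, 1)`.
#' @export
migrant_fraction <- function(T, M) {
  stopifnot(all(T >= 0), all(M >= 0))
  1 - exp(-T * M)
}

#' Gene-conversion initiation rate from a converted-sites rate
#'
#' Converts an estimate of converted sites per base per generation into an
#' initiation rate per base per generation by dividing by the mean tract
#' length, the parameterization used by coalescent simulators.
#'
#' @param converted_sites_rate Converted sites per base per generation.
#' @param mean_tract Mean gene-conversion tract length in bp.
#' @return Initiation rate per base per generation.
#' @examples
#' gc_initiation_rate(1.4e-5, 390) # about 3.59e-8
#' @export
gc_initiation_rate <- function(converted_sites_rate, mean_tract) {
  stopifnot(all(converted_sites_rate >= 0), all(mean_tract > 0))
  converted_sites_rate / mean_tract
}
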