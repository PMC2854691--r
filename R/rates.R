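#' Exponential genome-growth rate
#'
#' If a genome grows at a per-time rate proportional to its length,
#' `dL/dt = lambda * L`, then growing from `L0` to `L` over `t` Mya implies
#' `lambda = ln(L / L0) / t` events per Mya. Units are fixed throughout:
#' lengths in bases, time in Mya.
#'
#' @param L0 initial length in bases.
#' @param L final length in bases, `L > L0`.
#' @param t elapsed time in Mya.
#' @return A `growth_rate_estimate`: list with `lambda` (per Mya), `t`,
#'   `L0`, `L`. Invariant: `lambda * t = ln(L / L0)`.
#' @examples
#' growth_rate(2e5, 3e9, 3400)$lambda  # about 2.8e-3 / Mya (human scenario)
#' @export
growth_rate <- function(L0, L, t) {
  stopifnot(L0 > 0, L > L0, t > 0)
  structure(list(lambda = log(L / L0) / t, t = t, L0 = L0, L = L),
            class = "growth_rate_estimate")
}

#' Duplication and point-mutation rate densities
#'
#' With growth purely by segmental duplication of mean segment length
#' `d_mean`, the per-base SD event rate is `rho = lambda / d_mean`. The
#' cumulative point-mutation density `r` relates to the per-site per-Mya
#' mutation rate by `mu = r * lambda / 2`: under exponential growth,
#' mutated sites are themselves copied by later duplications, so the
#' cumulative number of mutated sites is twice the naive `mu * L / lambda`.
#'
#' @param est a `growth_rate_estimate`, or a bare `lambda` (per Mya).
#' @param d_mean mean duplicated-segment length in bases.
#' @param r cumulative point-mutation density (per site).
#' @return A `rate_densities`: list with `lambda`, `rho` (SD events per
#'   base per Mya), `rho_per_mb` (per Mb per Mya), `mu` (mutations per site
#'   per Mya), `d_mean`, `r`.
#' @examples
#' rate_densities(2.7e-3, d_mean = 2000, r = 0.73)$mu  # about 0.99e-3
#' @export
rate_densities <- function(est, d_mean, r) {
  lambda <- if (inherits(est, "growth_rate_estimate")) est$lambda else est
  stopifnot(lambda > 0, d_mean > 0, r >= 0)
  rho <- lambda / d_mean
  structure(list(lambda = lambda, rho = rho, rho_per_mb = rho * 1e6,
                 mu = r * lambda / 2, d_mean = d_mean, r = r),
            class = "rate_densities")
}

#' Cumulative point mutations implied by a rate pair
#'
#' Integrating mutation accrual against exponential growth (and neglecting
#' the length added by point events themselves) gives
#' `n_mut = (mu / lambda) * L` mutations accumulated by the time the genome
#' reaches length `L`; doubling for the copying of mutated sites recovers
#' `r = 2 * n_mut / L`.
#'
#' @param mu point-mutation rate, per site per Mya.
#' @param lambda growth rate, per Mya.
#' @param L genome length in bases.
#' @return `n_mut`, the cumulative point-mutation count.
#' @export
cumulative_mutations <- function(mu, lambda, L) {
  stopifnot(lambda > 0, mu >= 0, L > 0)
  (mu / lambda) * L
}
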