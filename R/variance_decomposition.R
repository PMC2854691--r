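#' Decompose the squared coefficient of variation of a k-mer spectrum
#'
#' The squared coefficient of variation of the k-mer frequency distribution,
#' `M2 = sigma^2 / Nbar^2`, splits exactly into two parts (a parallel-axis
#' identity over the m-set strata):
#'
#' * a *non-fluctuating* part `Mnf2 = sum_m n_m (Nbar_m - Nbar)^2 / (4^k
#'   Nbar^2)`, fixed by the average frequencies of the m-sets, i.e. by base
#'   composition — a background that can dwarf the statistical signal when
#'   the AT fraction is far from 0.5;
#' * a *fluctuating* part `Mf2 = sum_m sum_{i in K_m} (N_i - Nbar_m)^2 /
#'   (4^k Nbar^2)`, the spread of individual k-mer frequencies around their
#'   own m-set mean — the statistical signal.
#'
#' `M2 = Mnf2 + Mf2` holds to machine precision for any count vector.
#'
#' @param spec a `kmer_spectrum`.
#' @param part an `mset_partition` of the same `k`.
#' @return A `variance_decomposition`: list with `k`, `W`, `Nbar`, `M2`,
#'   `Mnf2`, `Mf2` and a per-m `data.frame` of contributions.
#' @export
decompose_cv <- function(spec, part = mset_partition(spec$k)) {
  if (spec$k != part$k) stop("k mismatch")
  if (spec$W <= 0) stop("empty spectrum (W = 0)")
  counts <- spec$counts
  four_k <- 4^spec$k
  Nbar <- spec$Nbar
  summ <- mset_summaries(spec, part)
  denom <- four_k * Nbar^2
  mnf2_m <- summ$n_m * (summ$Nbar_m - Nbar)^2 / denom
  mf2_m <- summ$n_m * summ$sigma2_m / denom
  M2 <- sum((counts - Nbar)^2) / denom
  structure(
    list(k = spec$k, W = spec$W, Nbar = Nbar,
         M2 = M2, Mnf2 = sum(mnf2_m), Mf2 = sum(mf2_m),
         per_m = data.frame(m = summ$m, n_m = summ$n_m,
                            Nbar_m = summ$Nbar_m, sigma2_m = summ$sigma2_m,
                            Mnf2_m = mnf2_m, Mf2_m = mf2_m)),
    class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "<variance_decomposition> k = %d: M2 = %.4g = Mnf2 %.4g + Mf2 %.4g\n",
    x$k, x$M2, x$Mnf2, x$Mf2))
  invisible(x)
}

#' Expected m-set mean frequency in a long random sequence
#'
#' In the large-length limit, every k-mer type with `m` A/T letters occurs
#' with mean frequency `L * (p/2)^m * (q/2)^(k-m)` in a random sequence of
#' length `L` and AT fraction `p` (binomial expansion of the window
#' probability). All classes collapse to `L / 4^k` at `p = 0.5`. The row sum
#' `sum_m n_m * mean_m` equals `L` for any `p`.
#'
#' @param L sequence length in bases.
#' @param p AT fraction, in (0, 1).
#' @param k word length.
#' @param m A/T-letter count(s), `0..k`; vectorized.
#' @param integer_values report nearest integers (the convention used for
#'   printed tables) instead of the exact means.
#' @return Expected mean count(s), same length as `m`.
#' @examples
#' round(expected_mset_mean(2e6, 0.492, 5, 0:5))
#' @export
expected_mset_mean <- function(L, p, k, m, integer_values = FALSE) {
  stopifnot(L > 0, p > 0, p < 1)
  if (any(m < 0 | m > k)) stop("m out of range 0..k")
  val <- L * (p / 2)^m * ((1 - p) / 2)^(k - m)
  if (integer_values) round(val) else val
}

#' Large-length limit of the non-fluctuating variance part
#'
#' `Mnf2` of a random sequence converges, as the length grows, to
#' `sum_m (choose(k, m) / 2^k) * ((2p)^m (2q)^(k-m) - 1)^2`,
#' a composition background that vanishes at `p = 0.5`, is symmetric under
#' `p <-> 1 - p`, and grows steeply with `|p - 0.5|`.
#'
#' @param p AT fraction in (0, 1).
#' @param k word length.
#' @return The limiting `Mnf2`, a dimensionless number.
#' @export
nf_variance_limit <- function(p, k) {
  stopifnot(p > 0, p < 1, k >= 1)
  m <- 0:k
  q <- 1 - p
  sum(choose(k, m) / 2^k * ((2 * p)^m * (2 * q)^(k - m) - 1)^2)
}

#' Crossover length between fluctuating and composition background
#'
#' For a random sequence the fluctuating part is nearly Poisson,
#' `Mf2 ~= 4^k / L`, and decreases with length, while the composition
#' background `Mnf2` tends to a constant. The crossover length
#' `4^k / Mnf2_inf(p, k)` is where the background overtakes the fluctuating
#' part; beyond it, raw variances of biased-composition sequences mostly
#' reflect composition, not statistics. Reported to the nearest integer;
#' infinite at `p = 0.5`.
#'
#' @param p AT fraction in (0, 1).
#' @param k word length.
#' @return Crossover length in bases (`Inf` when `p = 0.5`).
#' @examples
#' crossover_length(0.7, 4)  # 316
#' @export
crossover_length <- function(p, k) {
  stopifnot(p > 0, p < 1)
  if (p == 0.5) return(Inf)
  round(4^k / nf_variance_limit(p, k))
}

#' Equivalent length of a sequence from its fluctuating variance
#'
#' The k-mer equivalent length is `Le = gamma * 4^k / Mf2`: the length of a
#' random sequence whose fluctuating part matches the observed one. For
#' random sequences `Le ~= L` regardless of composition; for genomes `Le`
#' is orders of magnitude below `L`, reflecting the excess fluctuation left
#' by duplication-driven growth.
#'
#' Three policies for the dimensionless factor `gamma`:
#' * `"analytic"` (default): `1 - sum_m (p/2)^m (q/2)^(k-m)`, which at
#'   `p = 0.5` reduces to `1 - (k+1)/4^k`. This is the exact centering
#'   factor for independent-letter sampling: within an m-set every type
#'   shares the occurrence probability `pi_m = (p/2)^m (q/2)^(k-m)`, and
#'   the expected within-set sum of squares about the *estimated* set mean
#'   is `(n_m - 1) * W * pi_m` (one degree of freedom is spent per m-set),
#'   so `E[Mf2] = gamma * 4^k / L` with `gamma = sum_m (n_m - 1) pi_m`.
#'   Residual window-overlap covariance (a few percent at `k = 2`,
#'   negligible by `k = 6`) is not captured;
#' * `"unity"`: `gamma = 1`, the approximation used when mapping equivalent
#'   lengths onto the universal curve;
#' * `"montecarlo"`: calibrated as the mean of `L * Mf2 / 4^k` over `n_cal`
#'   seeded exact-composition shuffles of the same `(L, p)` — the
#'   matching-random null itself, whose fixed letter counts depress `Mf2`
#'   below the independent-letter theory at small `k` — which forces
#'   `Le(random) ~= L` by construction (requires `L`).
#'
#' @param dec a `variance_decomposition`.
#' @param p AT fraction of the sequence.
#' @param gamma_policy `"analytic"`, `"unity"` or `"montecarlo"`.
#' @param L sequence length in bases (required for `"montecarlo"`).
#' @param n_cal number of calibration sequences for `"montecarlo"`.
#' @param seed optional seed for the calibration draws.
#' @return An `equivalent_length`: list with `k`, `Le` (bases), `gamma`,
#'   `gamma_policy`, `Mf2`.
#' @export
equivalent_length <- function(dec, p,
                              gamma_policy = c("analytic", "unity",
                                               "montecarlo"),
                              L = NULL, n_cal = 10L, seed = NULL) {
  gamma_policy <- match.arg(gamma_policy)
  if (dec$Mf2 <= 0)
    stop("zero fluctuating variance: equivalent length undefined ",
         "(perfectly ordered input)")
  k <- dec$k
  gamma <- switch(gamma_policy,
    analytic = gamma_analytic(p, k),
    unity = 1,
    montecarlo = {
      if (is.null(L)) stop("montecarlo gamma policy requires L")
      calibrate_gamma_mc(L, p, k, n_cal = n_cal, seed = seed)
    })
  structure(list(k = k, Le = gamma * 4^k / dec$Mf2, gamma = gamma,
                 gamma_policy = gamma_policy, Mf2 = dec$Mf2),
            class = "equivalent_length")
}

#' @export
print.equivalent_length <- function(x, ...) {
  cat(sprintf("<equivalent_length> k = %d: Le = %.4g b (gamma = %.4f, %s)\n",
              x$k, x$Le, x$gamma, x$gamma_policy))
  invisible(x)
}

gamma_analytic <- function(p, k) {
  q <- 1 - p
  1 - sum((p / 2)^(0:k) * (q / 2)^(k - 0:k))
}

#' @rdname equivalent_length
#' @export
calibrate_gamma_mc <- function(L, p, k, n_cal = 10L, seed = NULL) {
  stopifnot(n_cal >= 1)
  run <- function() {
    vapply(seq_len(n_cal), function(i) {
      x <- exact_composition_sequence(L, p)
      d <- decompose_cv(count_kmers(x, k))
      L * d$Mf2 / 4^k
    }, numeric(1))
  }
  vals <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mean(vals)
}

#' Equivalent length directly from a sequence
#'
#' Convenience pipeline: count k-mers, partition into m-sets, decompose the
#' variance, and convert the fluctuating part into an equivalent length.
#'
#' @param seq a `seq_record` or residue string.
#' @param k word length.
#' @inheritParams equivalent_length
#' @return An `equivalent_length` with the `variance_decomposition`
#'   attached as `$decomposition`.
#' @export
equivalent_length_of <- function(seq, k, gamma_policy = "analytic",
                                 n_cal = 10L, seed = NULL) {
  seq <- as_seq_record(seq)
  dec <- decompose_cv(count_kmers(seq, k))
  out <- equivalent_length(dec, p = seq$p, gamma_policy = gamma_policy,
                           L = seq$length, n_cal = n_cal, seed = seed)
  out$decomposition <- dec
  out
}

#' Segment-wise equivalent-length profile
#'
#' Measures how the equivalent length depends on the segment length it is
#' measured on: `Le` tracks the segment length for random sequences but
#' saturates for genome-like sequences. For each requested length `l` the
#' sequence is cut into all non-overlapping segments (left-anchored tiling),
#' or 20 randomly placed segments when more than 20 fit; mean and SD of the
#' per-segment `Le` are reported.
#'
#' Segment lengths well below the sequence's asymptotic equivalent length
#' carry no information about the saturation level. When the full-sequence
#' `Le` saturates (below `L / 4`), lengths under `min_length_factor * Le`
#' are refused; random-like sequences (whose `Le` grows with the segment)
#' are exempt from the check.
#'
#' @param seq a `seq_record` or residue string.
#' @param k word length.
#' @param lengths segment lengths (bases) to profile.
#' @param seed seed for random segment placement.
#' @param n_max maximum number of segments per length.
#' @param gamma_policy passed to [equivalent_length()].
#' @param min_length_factor validity multiple of the asymptotic `Le`.
#' @return A `data.frame` with columns `length`, `n_segments`, `le_mean`,
#'   `le_sd`.
#' @export
le_profile <- function(seq, k, lengths, seed = NULL, n_max = 20L,
                       gamma_policy = "analytic", min_length_factor = 4) {
  seq <- as_seq_record(seq)
  L <- seq$length
  if (any(lengths > L))
    stop("sequence (", L, " b) shorter than requested segment length ",
         max(lengths))
  le_full <- equivalent_length_of(seq, k, gamma_policy = gamma_policy)$Le
  if (le_full < L / 4) {  # saturating regime: short segments uninformative
    bad <- lengths < min_length_factor * le_full
    if (any(bad))
      stop("segment length(s) ", paste(lengths[bad], collapse = ", "),
           " below ", min_length_factor, " times the asymptotic Le (",
           round(le_full), " b)")
  }
  run <- function() {
    do.call(rbind, lapply(lengths, function(l) {
      n_fit <- L %/% l
      starts <- if (n_fit > n_max) {
        sort(sample.int(L - l + 1L, n_max)) - 1L
      } else {
        (seq_len(n_fit) - 1L) * l
      }
      les <- vapply(starts, function(s) {
        piece <- substr(seq$residues, s + 1L, s + l)
        equivalent_length_of(seq_record("segment", piece), k,
                             gamma_policy = gamma_policy)$Le
      }, numeric(1))
      data.frame(length = l, n_segments = length(starts),
                 le_mean = mean(les),
                 le_sd = if (length(les) > 1L) stats::sd(les) else NA_real_)
    }))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
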