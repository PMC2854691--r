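#' The universal equivalent-length curve
#'
#' Across genomes of all lengths and taxa, equivalent lengths cluster around
#' a single exponential-in-k curve, `Le_uc(k) = A * exp(beta * k)` at even
#' composition. The model is calibrated from two printed anchor points
#' (310 b at `k = 2` and 194 kb at `k = 9` by default); with `beta = 0.92`
#' the two anchors imply amplitudes that agree to about 0.1%, and `A` is
#' taken as their log-mean. A residual composition correction (parameter
#' `tau`) exists in principle but its functional form is not pinned down by
#' the published account, so it is exposed only as an optional hook and
#' disabled by default; all computations here use the `p = 0.5` curve.
#'
#' @param beta per-k exponential coefficient.
#' @param anchors named numeric vector of anchor equivalent lengths (bases),
#'   names giving the anchor `k` values.
#' @param tau optional residual composition-correction parameter (stored,
#'   not applied).
#' @return A `universality_model`: list with `A` (bases), `beta`, `anchors`,
#'   `tau`.
#' @examples
#' m <- universality_model()
#' universal_Le(m, 4)  # about 1.95 kb
#' @export
universality_model <- function(beta = 0.92,
                               anchors = c("2" = 310, "9" = 194000),
                               tau = NULL) {
  ks <- as.numeric(names(anchors))
  if (any(is.na(ks))) stop("anchor names must be k values")
  lnA <- log(anchors) - beta * ks
  if (length(lnA) > 1L && (max(lnA) - min(lnA)) / abs(mean(lnA)) > 0.005)
    warning("anchors are mutually inconsistent beyond 0.5% in ln A")
  structure(list(A = exp(mean(lnA)), beta = beta, anchors = anchors,
                 tau = tau),
            class = "universality_model")
}

#' @export
print.universality_model <- function(x, ...) {
  cat(sprintf("<universality_model> Le_uc(k) = %.3f * exp(%.3f k) b\n",
              x$A, x$beta))
  invisible(x)
}

#' Universal equivalent length at word length k
#'
#' @param model a `universality_model`.
#' @param k word length, 2 to 10 (the curve is not meaningful much beyond
#'   10, where `Le_uc` approaches usable sequence lengths).
#' @return `Le_uc(k)` in bases; vectorized over `k`.
#' @export
universal_Le <- function(model, k) {
  if (any(k < 2 | k > 10))
    stop("universal curve is calibrated for k in 2..10")
  model$A * exp(model$beta * k)
}

#' Universal standard deviation of the fluctuating k-mer frequency part
#'
#' Converting the universal curve through the equivalent-length definition
#' (with `gamma` approximated by unity) gives the m-set-averaged SD of the
#' fluctuating part of the k-mer frequency distribution for a
#' universality-class sequence of length `L`:
#' `sigma_f = L / sqrt(4^k * Le_uc(k))`.
#' The random-sequence reference SD is `sqrt(L / 4^k)` (Poisson), so the
#' genomic-to-random ratio is `sqrt(L / Le_uc(k))`. The formula is meant for
#' `L` several times `Le_uc(k)`; below that a warning is issued.
#'
#' @param model a `universality_model`.
#' @param k word length.
#' @param L sequence length in bases.
#' @return List with `sigma_f` (counts), `random_sd`, `ratio`, `k`, `L`.
#' @export
universal_sigma_f <- function(model, k, L) {
  le_uc <- universal_Le(model, k)
  if (L < 4 * le_uc)
    warning("L = ", L, " b is not several times Le_uc(k) = ",
            round(le_uc), " b; sigma_f outside its validity range")
  list(sigma_f = L / sqrt(4^k * le_uc),
       random_sd = sqrt(L / 4^k),
       ratio = sqrt(L / le_uc), k = k, L = L)
}

#' Mean squared log deviation from the universal curve (chi-square)
#'
#' For a set of `(k, Le)` observations the deviation statistic is the mean
#' of `(ln Le - ln Le_uc(k))^2`. It is zero iff every observation sits on
#' the curve, equals 1 when every `Le` is off by a factor of `e`, and
#' `exp(sqrt(chi2))` is the typical multiplicative deviation: 0.18
#' corresponds to agreement within a factor of about 1.6, and 0.43 within a
#' factor of about 2.
#'
#' @param le_values `data.frame` with columns `k` and `Le` (bases), or a
#'   numeric vector of `Le` with `k` supplied in `names`.
#' @param model a `universality_model`.
#' @return A `chi_square_result`: list with `chi2`, `n_terms`, `deviations`
#'   (per-entry squared log deviations) and `typical_factor =
#'   exp(sqrt(chi2))`.
#' @export
chi_square <- function(le_values, model = universality_model()) {
  if (is.numeric(le_values))
    le_values <- data.frame(k = as.numeric(names(le_values)),
                            Le = as.numeric(le_values))
  if (nrow(le_values) == 0L) stop("no (k, Le) entries")
  if (any(le_values$Le <= 0)) stop("Le values must be positive")
  dev2 <- (log(le_values$Le) - log(universal_Le(model, le_values$k)))^2
  chi2 <- mean(dev2)
  structure(list(chi2 = chi2, n_terms = length(dev2), deviations = dev2,
                 typical_factor = exp(sqrt(chi2))),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf(
    "<chi_square_result> chi2 = %.4g over %d terms (factor %.2f)\n",
    x$chi2, x$n_terms, x$typical_factor))
  invisible(x)
}

#' Fraction of k-mers deviating beyond a random-sequence threshold
#'
#' Null theory: if a genome were a random sequence, k-mer counts would
#' deviate from the mean with SD `sqrt(L / 4^k)`. For a universality-class
#' genome the actual deviation SD is `sigma_f` from
#' [universal_sigma_f()], so the expected fraction of k-mer types whose
#' frequency lies more than `n_sigma` *random-sequence* SDs from the mean
#' is the two-sided Gaussian mass
#' `2 * (1 - Phi(n_sigma * sqrt(L / 4^k) / sigma_f))`.
#'
#' @param model a `universality_model`.
#' @param k word length.
#' @param L sequence length in bases.
#' @param n_sigma threshold in random-sequence standard deviations.
#' @return Fraction in `[0, 1]`; 1 at `n_sigma = 0`.
#' @examples
#' m <- universality_model()
#' pvalue_fraction(m, 9, 8e5, 6)   # about 0.0031
#' @export
pvalue_fraction <- function(model, k, L, n_sigma) {
  stopifnot(n_sigma >= 0)
  s <- universal_sigma_f(model, k, L)
  z <- n_sigma * s$random_sd / s$sigma_f
  2 * stats::pnorm(z, lower.tail = FALSE)
}
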