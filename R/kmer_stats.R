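#' Count k-mers with an overlapping sliding window
#'
#' Counts occurrences of every one of the `4^k` k-mer types using a window of
#' width `k` and slide 1. Windows containing any `N` are skipped and do not
#' contribute to the valid-window count `W`; for a gap-free sequence
#' `W = L - k + 1`. Counting is strand-naive and deterministic.
#'
#' Counts are indexed by the 2-bit encoding `A=0, C=1, G=2, T=3`, big-endian
#' within the word, which coincides with lexicographic order. Labels are
#' attached for `k <= 8`; for larger `k` use [kmer_labels()] (building a
#' million-element name vector costs far more than the count itself).
#'
#' @param seq a `seq_record` or residue string.
#' @param k word length, 2 to 12.
#' @return A `kmer_spectrum`: list with `k`, `counts` (length `4^k`), `W`
#'   (number of valid windows) and `Nbar = W / 4^k`.
#' @examples
#' count_kmers("ACGT", 2)$counts[c("AC", "CG", "GT")]
#' @export
count_kmers <- function(seq, k) {
  seq <- as_seq_record(seq)
  k <- as.integer(k)
  if (k < 2L || k > 12L) stop("k must be between 2 and 12")
  if (seq$length < k) stop("sequence shorter than k = ", k)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq$residues), width = k,
    with.labels = (k <= 8L))
  counts <- as.numeric0(counts)
  W <- sum(counts)
  if (W == 0) stop("no valid (N-free) window of width ", k)
  structure(list(k = k, counts = counts, W = W, Nbar = W / 4^k),
            class = "kmer_spectrum")
}

# as.numeric but keeping names
as.numeric0 <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> k = %d, W = %.0f windows, Nbar = %.4g\n",
              x$k, x$W, x$Nbar))
  invisible(x)
}

#' All k-mer labels in index order
#'
#' @param k word length.
#' @return Character vector of the `4^k` words in lexicographic (2-bit
#'   index) order.
#' @export
kmer_labels <- function(k) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

#' Partition of k-mer types into m-sets by A/T-letter count
#'
#' The `4^k` k-mer types split naturally into classes `K_m`, `m = 0..k`,
#' where `K_m` holds the words containing exactly `m` letters from `{A, T}`.
#' The class sizes are `n_m = choose(k, m) * 2^k` and satisfy
#' `sum(n_m) = 4^k` (binomial sum rule). In a long random sequence every
#' word in `K_m` has the same expected frequency, so the m-sets are the
#' natural strata for separating composition effects from statistical
#' fluctuation.
#'
#' @param k word length.
#' @return An `mset_partition`: list with `k`, `m_of` (integer vector over
#'   the `4^k` types giving each type's `m`) and `sizes` (`n_m`,
#'   `m = 0..k`). Cached per `k`.
#' @examples
#' mset_partition(2)$sizes  # 4 8 4
#' @export
mset_partition <- function(k) {
  k <- as.integer(k)
  if (k < 1L || k > 12L) stop("k must be between 1 and 12")
  key <- as.character(k)
  cached <- .mset_cache[[key]]
  if (!is.null(cached)) return(cached)
  idx <- 0:(4^k - 1)
  m_of <- integer(4^k)
  for (j in 0:(k - 1L)) {
    digit <- (idx %/% 4^j) %% 4
    m_of <- m_of + (digit == 0 | digit == 3)  # A or T at this position
  }
  part <- structure(
    list(k = k, m_of = m_of, sizes = choose(k, 0:k) * 2^k),
    class = "mset_partition")
  .mset_cache[[key]] <- part
  part
}

.mset_cache <- new.env(parent = emptyenv())

#' Members of one m-set
#'
#' @param part an `mset_partition`.
#' @param m A/T-letter count.
#' @return Character vector of the k-mer types in `K_m`.
#' @export
mset_members <- function(part, m) {
  stopifnot(m >= 0, m <= part$k)
  kmer_labels(part$k)[part$m_of == m]
}

#' Per-m-set frequency summaries
#'
#' For each m-set `K_m`: the sum frequency `F_m`, the mean frequency
#' `Nbar_m = F_m / n_m`, and the within-set population variance `sigma2_m`.
#' The sums satisfy `sum(F_m) = W`.
#'
#' @param spec a `kmer_spectrum`.
#' @param part an `mset_partition` of the same `k` (defaults to it).
#' @return A `data.frame` with columns `m`, `n_m`, `F_m`, `Nbar_m`,
#'   `sigma2_m`.
#' @export
mset_summaries <- function(spec, part = mset_partition(spec$k)) {
  if (spec$k != part$k)
    stop("k mismatch between spectrum (", spec$k, ") and partition (",
         part$k, ")")
  n_m <- part$sizes
  F_m <- as.vector(rowsum(spec$counts, part$m_of))
  Nbar_m <- F_m / n_m
  ss <- as.vector(rowsum((spec$counts - Nbar_m[part$m_of + 1L])^2,
                         part$m_of))
  data.frame(m = 0:part$k, n_m = n_m, F_m = F_m, Nbar_m = Nbar_m,
             sigma2_m = ss / n_m)
}

#' Occurrence-frequency histogram (spectrum) of k-mer counts
#'
#' Tabulates, for each occurrence frequency, how many k-mer types occur at
#' that frequency, optionally smoothed with a centered boxcar average to
#' reduce fluctuation when plotting. The raw histogram mass equals `4^k`.
#'
#' @param spec a `kmer_spectrum`.
#' @param smooth_width odd boxcar width in frequency bins; 21 matches the
#'   convention used for published spectra, 1 disables smoothing.
#' @return A `data.frame` with columns `frequency`, `n_types` (raw) and
#'   `n_types_smooth` (edge-truncated boxcar mean).
#' @export
frequency_spectrum <- function(spec, smooth_width = 21L) {
  smooth_width <- as.integer(smooth_width)
  if (smooth_width < 1L || smooth_width %% 2L == 0L)
    stop("smooth_width must be odd and >= 1")
  top <- max(spec$counts)
  raw <- tabulate(as.integer(spec$counts) + 1L, nbins = top + 1L)
  if (smooth_width == 1L) {
    smooth <- raw
  } else {
    half <- smooth_width %/% 2L
    csum <- cumsum(c(0, raw))
    n <- length(raw)
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    smooth <- (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
  }
  data.frame(frequency = 0:top, n_types = raw, n_types_smooth = smooth)
}
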