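#' Sliding-window specification
#'
#' @param width window width in bases.
#' @param slide slide (step) in bases, `0 < slide <= width`.
#' @return A `window_spec` list.
#' @export
window_spec <- function(width, slide = width) {
  stopifnot(width >= 1, slide >= 1, slide <= width)
  structure(list(width = as.integer(width), slide = as.integer(slide)),
            class = "window_spec")
}

#' m-set-normalized similarity index between two spectra
#'
#' Measures how far two equal-`k` spectra differ relative to their own
#' within-m-set spread:
#' `Delta = (1 / 4^k) * sum_m sum_{i in K_m} (N_i^a - N_i^b)^2 /
#' (sigma_m^2(a) + sigma_m^2(b))`,
#' with both spectra first scaled to a common window total. The denominator
#' uses the unbiased (n_m - 1) within-m-set variance: for independent
#' random windows `E[(N_i^a - N_i^b)^2] = sigma_m^2(a) + sigma_m^2(b)`
#' exactly, and at small k the m-sets are tiny (4 to 8 types at k = 2), so
#' a population-variance denominator would inflate the index by its
#' downward bias. Calibration:
#' `Delta = 0` for identical spectra, `Delta ~= 1` for independent random
#' windows of the same composition (each squared difference averages the
#' pooled variance within an m-set), and `Delta >> 1` for
#' composition-divergent pairs. An m-set in which both spectra are constant
#' (zero pooled variance) cannot be normalized; such sets are skipped with a
#' warning and the average is taken over the contributing types.
#'
#' @param spec_a,spec_b `kmer_spectrum` objects with the same `k`.
#' @param part an `mset_partition` of the same `k`.
#' @return The similarity index `Delta` (dimensionless, `>= 0`).
#' @export
similarity_index <- function(spec_a, spec_b,
                             part = mset_partition(spec_a$k)) {
  if (spec_a$k != spec_b$k) stop("k mismatch between spectra")
  if (spec_a$k != part$k) stop("k mismatch with partition")
  W_common <- (spec_a$W + spec_b$W) / 2
  a <- spec_a$counts * (W_common / spec_a$W)
  b <- spec_b$counts * (W_common / spec_b$W)
  stats_m <- function(x) {
    mu <- as.vector(rowsum(x, part$m_of)) / part$sizes
    dev <- x - mu[part$m_of + 1L]
    list(dev = dev,
         s2 = as.vector(rowsum(dev^2, part$m_of)) / (part$sizes - 1))
  }
  sa <- stats_m(a)
  sb <- stats_m(b)
  den <- sa$s2 + sb$s2
  diff2_m <- as.vector(rowsum((a - b)^2, part$m_of))
  use <- den > 0
  if (!any(use)) {
    if (all(a == b)) return(0)
    stop("similarity undefined: zero within-m-set variance in both spectra")
  }
  if (!all(use))
    warning("skipping m-set(s) with zero pooled variance: m = ",
            paste((0:part$k)[!use], collapse = ", "))
  sum(diff2_m[use] / den[use]) / sum(part$sizes[use])
}

#' Sliding-window similarity matrix between two sequences
#'
#' Cuts each sequence into sliding windows, computes the k-mer spectrum of
#' every window, and fills the matrix of pairwise similarity indices
#' `Delta(i, j)`. Comparing a sequence against itself gives a symmetric
#' matrix with an exactly zero diagonal. One axis may equally be a
#' concatenate (e.g. gene or intergene splice) instead of a chromosome.
#'
#' @param seq_a,seq_b `seq_record`s or residue strings (use the same object
#'   twice for a self-comparison).
#' @param window a `window_spec`; published conventions are width 25 kb /
#'   slide 10 kb for chromosome-vs-concatenate plots and width 100 kb /
#'   slide 25 kb for chromosome-vs-chromosome plots.
#' @param k word length (2 is the published default for similarity plots).
#' @return A `similarity_matrix`: list with `delta` (matrix, rows = windows
#'   of `seq_a`), `starts_a`, `starts_b` (0-based window starts), `width`,
#'   `slide`, `k`, `labels`, and `self` (logical: same windows on both
#'   axes).
#' @export
similarity_matrix <- function(seq_a, seq_b = seq_a,
                              window = window_spec(25000L, 10000L),
                              k = 2L) {
  seq_a <- as_seq_record(seq_a, "a")
  seq_b <- as_seq_record(seq_b, "b")
  self <- identical(seq_a$residues, seq_b$residues)
  part <- mset_partition(k)
  win_counts <- function(s) {
    L <- s$length
    if (L < window$width)
      stop("sequence ", s$id, " shorter than the window width")
    starts <- seq.int(0L, L - window$width, by = window$slide)
    d <- Biostrings::DNAString(s$residues)
    v <- Biostrings::Views(d, start = starts + 1L,
                           width = window$width)
    counts <- Biostrings::oligonucleotideFrequency(v, width = k,
                                                   with.labels = FALSE)
    W <- rowSums(counts)
    if (any(W == 0))
      stop("degenerate (all-N) window in ", s$id)
    list(starts = starts, counts = counts, W = W)
  }
  wa <- win_counts(seq_a)
  wb <- if (self) wa else win_counts(seq_b)
  W_common <- mean(c(wa$W, wb$W))
  A <- wa$counts * (W_common / wa$W)
  B <- wb$counts * (W_common / wb$W)
  n_m <- part$sizes
  groups <- part$m_of
  na <- nrow(A); nb <- nrow(B)
  total <- matrix(0, na, nb)
  types_used <- matrix(0, na, nb)
  for (m in 0:k) {
    cols <- which(groups == m)
    Am <- A[, cols, drop = FALSE]
    Bm <- B[, cols, drop = FALSE]
    nm <- length(cols)
    s2a <- (rowMeans(Am^2) - rowMeans(Am)^2) * nm / (nm - 1)
    s2b <- (rowMeans(Bm^2) - rowMeans(Bm)^2) * nm / (nm - 1)
    # squared distance between every window pair over this m-set
    D <- outer(rowSums(Am^2), rowSums(Bm^2), "+") - 2 * tcrossprod(Am, Bm)
    D[D < 0] <- 0  # numerical noise
    den <- outer(s2a, s2b, "+")
    ok <- den > 0
    total[ok] <- total[ok] + D[ok] / den[ok]
    types_used <- types_used + ok * n_m[m + 1L]
  }
  delta <- ifelse(types_used > 0, total / types_used, NA_real_)
  if (self) {
    delta[cbind(seq_len(na), seq_len(na))] <- 0  # exact zero diagonal
    delta <- (delta + t(delta)) / 2
  }
  structure(list(delta = delta, starts_a = wa$starts, starts_b = wb$starts,
                 width = window$width, slide = window$slide, k = k,
                 labels = c(a = seq_a$id, b = seq_b$id), self = self),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<similarity_matrix> %s vs %s: %d x %d windows (w = %d, s = %d, k = %d)\n",
    x$labels["a"], x$labels["b"], nrow(x$delta), ncol(x$delta), x$width,
    x$slide, x$k))
  invisible(x)
}

#' Summarize a similarity matrix, optionally against a reference
#'
#' Mean and SD of the matrix entries (excluding the diagonal for
#' self-comparisons), and, when a reference matrix is supplied, a Welch
#' two-sample t test of equality of mean similarity — the test used to ask
#' whether an inter-chromosome plot differs from an intra-chromosome one.
#'
#' @param mat a `similarity_matrix`.
#' @param reference optional second `similarity_matrix`.
#' @return List with `mean`, `sd`, `n`, and (with a reference) `t`,
#'   `p_value`, `reference_mean`.
#' @export
summarize_similarity <- function(mat, reference = NULL) {
  vals <- similarity_values(mat)
  out <- list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
  if (!is.null(reference)) {
    ref <- similarity_values(reference)
    if (length(vals) < 2L || length(ref) < 2L)
      stop("need at least 2 values per matrix for a t test")
    if (stats::sd(vals) == 0 && stats::sd(ref) == 0) {
      out$t <- if (mean(vals) == mean(ref)) 0 else Inf
      out$p_value <- if (mean(vals) == mean(ref)) 1 else 0
    } else {
      tt <- stats::t.test(vals, ref)
      out$t <- unname(tt$statistic)
      out$p_value <- tt$p.value
    }
    out$reference_mean <- mean(ref)
  }
  out
}

similarity_values <- function(mat) {
  v <- mat$delta
  if (isTRUE(mat$self)) v <- v[row(v) != col(v)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty similarity matrix")
  as.numeric(v)
}
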