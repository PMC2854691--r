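#' Sequence records
#'
#' A `seq_record` is a lightweight container for a named DNA sequence: the
#' residue string over the alphabet `{A,C,G,T,N}`, its length `L`, and its
#' AT fraction `p` (computed over non-N residues; `q = 1 - p`). Characters
#' outside `A/C/G/T` (including IUPAC ambiguity codes and soft-masked
#' lower case after upper-casing) are mapped to `N`; `N` positions are
#' excluded from `p` and, downstream, from k-mer windows.
#'
#' @param id character label for the sequence.
#' @param residues character scalar of residues; upper-cased on input.
#' @return An object of class `seq_record` with fields `id`, `residues`,
#'   `length`, `p`, `q`. `p` is `NA` when every residue is `N`.
#' @examples
#' r <- seq_record("x", "aacgtn")
#' r$length  # 6
#' r$p       # 3 A/T among 5 non-N residues
#' @export
seq_record <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  residues <- gsub("[^ACGTN]", "N", residues)
  comp <- letter_counts(residues)
  n_valid <- sum(comp[c("A", "C", "G", "T")])
  p <- if (n_valid == 0L) NA_real_ else (comp[["A"]] + comp[["T"]]) / n_valid
  structure(
    list(id = id, residues = residues, length = nchar(residues),
         p = p, q = if (is.na(p)) NA_real_ else 1 - p),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d b, p(AT) = %s\n", x$id, x$length,
              if (is.na(x$p)) "undefined" else sprintf("%.4f", x$p)))
  invisible(x)
}

# per-letter counts of A, C, G, T, N (raw-byte scan; residues are clean)
letter_counts <- function(residues) {
  r <- charToRaw(residues)
  vapply(c(A = "A", C = "C", G = "G", T = "T", N = "N"),
         function(ch) sum(r == charToRaw(ch)), numeric(1))
}

as_seq_record <- function(x, id = "seq") {
  if (inherits(x, "seq_record")) x else seq_record(id, x)
}

#' Fractional AT and CG content
#'
#' Returns `p`, the fraction of A/T among non-N residues, and `q = 1 - p`.
#' A sequence consisting only of `N` has no defined composition and is an
#' error.
#'
#' @param seq a `seq_record` or a residue string.
#' @return Named numeric vector `c(p = , q = )`.
#' @export
base_composition <- function(seq) {
  seq <- as_seq_record(seq)
  if (is.na(seq$p))
    stop("base composition undefined: sequence contains no non-N residues")
  c(p = seq$p, q = seq$q)
}

#' Read a FASTA file
#'
#' One `seq_record` per FASTA entry. Residues are upper-cased and characters
#' outside `A/C/G/T` become `N`. An empty file yields an empty list.
#'
#' @param path path to a FASTA file.
#' @return List of [seq_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  first <- which(nzchar(trimws(lines)))[1L]
  if (!startsWith(lines[[first]], ">"))
    stop("malformed FASTA in ", path, ": line ", first,
         " is not a '>' header")
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- names(set)
  if (any(!nzchar(ids)))
    stop("malformed FASTA in ", path, ": empty header for record ",
         which(!nzchar(ids))[1L])
  mapply(function(id, s) seq_record(id, s),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records a `seq_record` or list of them.
#' @param path output path.
#' @param width line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "residues"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Matching random (shuffled) control sequence
#'
#' Returns an exact in-place permutation of the input residues: the multiset
#' of letters (including `N`) is preserved, so length and base composition
#' match the original exactly. This is the null model against which genomic
#' fluctuation statistics are compared.
#'
#' @param seq a `seq_record` or residue string.
#' @param seed integer seed; the permutation is deterministic for a fixed
#'   seed. `NULL` uses the current RNG state.
#' @return A `seq_record` with id suffixed `"_shuffled"`.
#' @export
shuffle_matching_random <- function(seq, seed = NULL) {
  seq <- as_seq_record(seq)
  r <- charToRaw(seq$residues)
  perm <- function() r[sample.int(length(r))]
  r <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())
  seq_record(paste0(seq$id, "_shuffled"), rawToChar(r))
}

#' Random sequences with a given AT fraction
#'
#' `random_sequence()` draws residues independently with
#' `P(A) = P(T) = p/2`, `P(C) = P(G) = (1-p)/2`.
#' `exact_composition_sequence()` instead builds a fixed multiset with
#' `round(p * length)` A/T letters (split as evenly as possible between A and
#' T, and between C and G) and permutes it, so the realized composition is
#' exact by construction.
#'
#' @param length sequence length in bases.
#' @param p target AT fraction in (0, 1) (degenerate 0 or 1 allowed).
#' @param seed optional integer seed.
#' @param id record label.
#' @return A `seq_record`.
#' @export
random_sequence <- function(length, p = 0.5, seed = NULL, id = "random") {
  stopifnot(length >= 1, p >= 0, p <= 1)
  draw <- function() {
    BASES_RAW[sample.int(4L, length, replace = TRUE,
                         prob = c(p / 2, (1 - p) / 2, (1 - p) / 2, p / 2))]
  }
  r <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  seq_record(id, rawToChar(r))
}

#' @rdname random_sequence
#' @export
exact_composition_sequence <- function(length, p = 0.5, seed = NULL,
                                       id = "random_exact") {
  stopifnot(length >= 1, p >= 0, p <= 1)
  n_at <- round(p * length)
  n_a <- n_at %/% 2L
  n_c <- (length - n_at) %/% 2L
  pool <- rep(BASES_RAW, times = c(n_a, n_c, length - n_at - n_c, n_at - n_a))
  perm <- function() pool[sample.int(length)]
  r <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())
  seq_record(id, rawToChar(r))
}

BASES_RAW <- charToRaw("ACGT")

INTERVAL_CATEGORIES <- c("gene", "intergene", "exon", "intron")

#' Annotation intervals
#'
#' Intervals are 0-based, half-open `[start, end)` on the forward coordinate
#' system (BED convention), with a `category` in
#' `gene/intergene/exon/intron`. The strand is carried along but splicing
#' never reverse-complements minus-strand intervals.
#'
#' @param seq_id sequence label the intervals belong to.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param category character vector (recycled) of interval categories.
#' @param strand `"+"` or `"-"` (recycled; informational only).
#' @return A `data.frame` with columns `seq_id`, `start`, `end`, `strand`,
#'   `category`.
#' @export
annotation_intervals <- function(seq_id, start, end, category,
                                 strand = "+") {
  stopifnot(all(start >= 0), all(end > start))
  category <- match.arg(category, INTERVAL_CATEGORIES, several.ok = TRUE)
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end),
             strand = rep_len(strand, length(start)),
             category = rep_len(category, length(start)),
             stringsAsFactors = FALSE)
}

#' Read intervals from a 6-column BED file
#'
#' The BED name field carries the interval category
#' (`gene/intergene/exon/intron`).
#'
#' @param path BED file path.
#' @return An interval `data.frame` as from [annotation_intervals()].
#' @export
read_bed_intervals <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED files requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  strand <- as.character(gr$strand)
  strand[strand == "*"] <- "+"
  annotation_intervals(seq_id = as.character(gr$seqnames),
                       start = gr$start - 1L, end = gr$end,
                       category = gr$name, strand = strand)
}

#' Read gene/exon intervals from a GFF3 file
#'
#' Minimal extraction: features whose type is `gene` or `exon` become
#' intervals of the same category.
#'
#' @param path GFF3 file path.
#' @param types feature types to keep.
#' @return An interval `data.frame` as from [annotation_intervals()].
#' @export
read_gff_intervals <- function(path, types = c("gene", "exon")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 files requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "GFF3"))
  gr <- gr[as.character(gr$type) %in% types, , drop = FALSE]
  if (nrow(gr) == 0L)
    stop("no features of type ", paste(types, collapse = "/"), " in ", path)
  strand <- as.character(gr$strand)
  strand[strand == "*"] <- "+"
  annotation_intervals(seq_id = as.character(gr$seqnames),
                       start = gr$start - 1L, end = gr$end,
                       category = as.character(gr$type), strand = strand)
}

#' Complement of a set of intervals
#'
#' Derives the gaps between intervals of one category over `[0, seq_length)`,
#' e.g. intergenic regions from gene intervals.
#'
#' @param intervals interval `data.frame`.
#' @param seq_length length of the underlying sequence.
#' @param category category label for the new intervals.
#' @return An interval `data.frame`.
#' @export
complement_intervals <- function(intervals, seq_length,
                                 category = "intergene") {
  ir <- IRanges::reduce(IRanges::IRanges(intervals$start + 1L,
                                         intervals$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = seq_length)
  if (length(gaps) == 0L)
    return(annotation_intervals(character(0), integer(0), integer(0),
                                category)[0, ])
  annotation_intervals(seq_id = rep(intervals$seq_id[1L], length(gaps)),
                       start = IRanges::start(gaps) - 1L,
                       end = IRanges::end(gaps), category = category)
}

#' Build a category concatenate by splicing intervals
#'
#' Splices the substrings of `seq` covered by the intervals of the requested
#' category, joined in ascending genomic order. Minus-strand intervals are
#' *not* reverse-complemented, so a genic concatenate carries negatively
#' oriented genes in forward-strand reading. Overlapping intervals of the
#' category are merged before splicing, so no base is counted twice. `N`
#' runs are retained (they are excluded later, at k-mer counting).
#'
#' @param seq a `seq_record`.
#' @param intervals interval `data.frame` (see [annotation_intervals()]).
#' @param category one of `gene`, `intergene`, `exon`, `intron`.
#' @return A `seq_record` subclassed `concatenate`, with the merged source
#'   intervals in `$source`.
#' @export
build_concatenate <- function(seq, intervals, category) {
  seq <- as_seq_record(seq)
  category <- match.arg(category, INTERVAL_CATEGORIES)
  sel <- intervals[intervals$category == category &
                     intervals$seq_id == seq$id, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no intervals of category '", category, "' for sequence ", seq$id)
  if (any(sel$start < 0L) || any(sel$end > seq$length))
    stop("interval out of range for sequence ", seq$id,
         " (length ", seq$length, ")")
  ir <- IRanges::reduce(IRanges::IRanges(sel$start + 1L, sel$end))
  parts <- substring(seq$residues,
                     IRanges::start(ir), IRanges::end(ir))
  out <- seq_record(paste0(seq$id, "_", category),
                    paste(parts, collapse = ""))
  out$category <- category
  out$source <- annotation_intervals(
    seq_id = rep(seq$id, length(ir)),
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir), category = category)
  class(out) <- c("concatenate", class(out))
  out
}
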