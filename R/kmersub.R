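#' Build a canonical k-mer catalog for one pool
#'
#' Every N-free window of length `k` in every read contributes one count to
#' its canonical k-mer (the lexicographic minimum of the window and its
#' reverse complement), so both sequencing strands count together. The
#' study's in silico subtraction used `k = 37`.
#'
#' @param x a [read_set] or character vector of sequences.
#' @param k k-mer length (1-63).
#' @param pool_label free-text label carried in the catalog.
#' @return A `kmer_catalog`: list with `k`, `kmer` (sorted canonical
#'   k-mers), `count`, `pool_label`.
#' @export
build_catalog <- function(x, k = 37L, pool_label = "") {
  seqs <- if (inherits(x, "read_set")) x$seq else as.character(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  cat <- cpp_build_catalog(seqs, k)
  structure(list(k = k, kmer = as.character(cat$kmer),
                 count = as.integer(cat$count), pool_label = pool_label),
            class = "kmer_catalog")
}

#' @export
print.kmer_catalog <- function(x, ...) {
  cat(sprintf("<kmer_catalog> k=%d, %d distinct k-mers, %s\n",
              x$k, length(x$kmer),
              if (nzchar(x$pool_label)) x$pool_label else "unlabelled"))
  invisible(x)
}

#' Pool-specific k-mers by catalog subtraction
#'
#' The core of the in silico subtraction: k-mers counted at least
#' `min_count` times in catalog `a` and entirely absent from catalog `b`.
#' The count threshold on the source pool suppresses sequencing-error
#' k-mers; absence from the other pool is strict.
#'
#' @param a,b `kmer_catalog`s with equal `k`.
#' @param min_count minimum count in `a`.
#' @return A `specific_kmer_set`: list with `k`, `kmer`, `count` (counts in
#'   `a`), `source_pool`, `min_count`.
#' @export
subtract_catalogs <- function(a, b, min_count = 2L) {
  stopifnot(inherits(a, "kmer_catalog"), inherits(b, "kmer_catalog"))
  if (a$k != b$k) stop("catalogs have different k")
  mask <- cpp_subtract_mask(a$kmer, a$count, b$kmer, a$k, as.integer(min_count))
  structure(list(k = a$k, kmer = a$kmer[mask], count = a$count[mask],
                 source_pool = a$pool_label, min_count = as.integer(min_count)),
            class = "specific_kmer_set")
}

#' @export
print.specific_kmer_set <- function(x, ...) {
  cat(sprintf("<specific_kmer_set> k=%d, %d k-mers specific to %s (min_count=%d)\n",
              x$k, length(x$kmer),
              if (nzchar(x$source_pool)) x$source_pool else "pool A", x$min_count))
  invisible(x)
}

#' Recruit reads containing pool-specific k-mers
#'
#' A read is recruited iff at least one of its canonical k-mers belongs to
#' the specific set; each read is emitted once, with its name (and so its
#' mate information) preserved.
#'
#' @param reads a [read_set].
#' @param specific a `specific_kmer_set`.
#' @return The recruited subset of `reads`, with an integer attribute
#'   `recruited_idx` giving the positions in the input.
#' @export
recruit_reads <- function(reads, specific) {
  stopifnot(inherits(specific, "specific_kmer_set"))
  hit <- cpp_recruit(reads$seq, specific$kmer, specific$k)
  out <- reads[hit]
  attr(out, "recruited_idx") <- which(hit)
  out
}

#' Canonical form of k-mers
#' @param kmers character vector.
#' @return The lexicographic minimum of each k-mer and its reverse
#'   complement.
#' @export
canonical_kmer <- function(kmers) cpp_canonical(as.character(kmers))

#' Write a specific k-mer set as TSV
#'
#' Columns `kmer`, `count_a`, `count_b` (zero by construction).
#'
#' @param specific a `specific_kmer_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_tsv <- function(specific, path) {
  out <- data.frame(kmer = specific$kmer, count_a = specific$count,
                    count_b = rep(0L, length(specific$kmer)),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
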