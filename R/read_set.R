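#' Construct a read set
#'
#' A `read_set` is the unit flowing through trimming, subtraction and
#' mapping: parallel vectors of read identifiers, sequences over
#' `{A,C,G,T,N}` and Phred quality strings (offset 33) of equal length.
#'
#' @param id character vector of read names.
#' @param seq character vector of sequences.
#' @param qual character vector of Phred+33 quality strings, same
#'   per-element length as `seq`.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, seq, qual) {
  id <- as.character(id)
  seq <- as.character(seq)
  qual <- as.character(qual)
  if (length(id) != length(seq) || length(seq) != length(qual)) {
    stop("id, seq and qual must have equal length")
  }
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality strings must have equal length per read")
  }
  structure(list(id = id, seq = seq, qual = qual), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$seq)

#' @export
`[.read_set` <- function(x, i) {
  read_set(x$id[i], x$seq[i], x$qual[i])
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads\n", length(x)))
  n <- min(3L, length(x))
  if (n > 0) {
    for (i in seq_len(n)) {
      cat(sprintf("  %s  %s...\n", x$id[i], substr(x$seq[i], 1, 40)))
    }
  }
  invisible(x)
}

#' Concatenate read sets
#' @param ... `read_set` objects.
#' @return A single `read_set`.
#' @export
concat_reads <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, function(x) length(x) > 0, logical(1))]
  if (length(xs) == 0) return(read_set(character(), character(), character()))
  read_set(
    unlist(lapply(xs, `[[`, "id"), use.names = FALSE),
    unlist(lapply(xs, `[[`, "seq"), use.names = FALSE),
    unlist(lapply(xs, `[[`, "qual"), use.names = FALSE)
  )
}

#' Reverse complement
#' @param seqs character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) cpp_revcomp(as.character(seqs))

#' Read a FASTQ file into a read set
#'
#' Phred+33 qualities; gzip input is handled transparently.
#'
#' @param path FASTQ file path.
#' @return A [read_set].
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on conversion
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  read_set(
    id = names(x),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x))
  )
}

#' Write a read set to FASTQ
#' @param reads a [read_set].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  q <- Biostrings::PhredQuality(reads$qual)
  x <- Biostrings::QualityScaledDNAStringSet(s, q)
  Biostrings::writeQualityScaledXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  # keep only the first word of each header, BLAST-style
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences to FASTA (60-column wrap)
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
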