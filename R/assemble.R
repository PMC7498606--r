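#' Assemble reads into contigs with a small de Bruijn assembler
#'
#' Desk-scale de Bruijn assembly of recruited allele-specific reads: build
#' the canonical `k_asm`-mer graph with node counts, drop nodes below the
#' coverage cutoff, iteratively clip dead-end tips shorter than
#' `tip_max_len` bases, and emit every maximal unbranched path as a contig.
#' Each contig is reported once, as the lexicographic minimum of the path
#' sequence and its reverse complement; output order (longest first, then
#' lexicographic) and path tie-breaks (nodes visited in ascending packed
#' 2-bit order) are deterministic.
#'
#' No paired-end scaffolding and no bubble popping: this reproduces the
#' role, not the scaffold tallies, of a full assembler.
#'
#' @param reads a [read_set] or character vector of sequences.
#' @param k_asm odd k-mer length, `15 <= k_asm < read length`.
#' @param cov_cutoff minimum node count (2 suppresses sequencing-error
#'   k-mers; use 1 for error-free reads).
#' @param tip_max_len clip dead-end unbranched paths shorter than this many
#'   bases.
#' @return A `contig_set`: data frame with `id`, `sequence`, `length`,
#'   `coverage` (mean node count).
#' @export
assemble_reads <- function(reads, k_asm = 31L, cov_cutoff = 2L,
                           tip_max_len = 2L * k_asm) {
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  k_asm <- as.integer(k_asm)
  if (k_asm < 15L || k_asm %% 2L == 0L) stop("k_asm must be odd and >= 15")
  df <- cpp_assemble(seqs, k_asm, as.integer(cov_cutoff), as.integer(tip_max_len))
  out <- data.frame(
    id = if (nrow(df) > 0) sprintf("contig_%d", seq_len(nrow(df))) else character(0),
    sequence = as.character(df$sequence),
    length = as.integer(df$length),
    coverage = as.numeric(df$coverage),
    stringsAsFactors = FALSE
  )
  class(out) <- c("contig_set", "data.frame")
  out
}

#' Write contigs as FASTA
#'
#' Headers follow `contig_<n> len=<L> cov=<c>`.
#'
#' @param contigs a `contig_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  seqs <- contigs$sequence
  names(seqs) <- sprintf("%s len=%d cov=%.2f", contigs$id, contigs$length,
                         contigs$coverage)
  write_fasta(seqs, path)
  invisible(path)
}

#' Read contigs from FASTA
#' @param path FASTA path (headers as written by [write_contigs_fasta()]
#'   or any FASTA; `len=`/`cov=` fields are recovered when present).
#' @return A `contig_set`.
#' @export
read_contigs_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  cov <- suppressWarnings(as.numeric(sub(".*cov=([0-9.eE+-]+).*", "\\1", hdr)))
  out <- data.frame(
    id = sub("\\s.*$", "", hdr),
    sequence = as.character(x),
    length = Biostrings::width(x),
    coverage = ifelse(is.na(cov), NA_real_, cov),
    stringsAsFactors = FALSE
  )
  class(out) <- c("contig_set", "data.frame")
  out
}
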