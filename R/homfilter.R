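#' Alignment scoring scheme
#'
#' The classic nucleotide scheme: match +2, mismatch -3, gap open -5, gap
#' extend -2, where a gap of length L scores `gap_open + L * gap_extend`.
#' Under this scheme an exact 100-base match scores 200, the raw-score
#' interpretation of the "score > 200" scaffold-retention threshold.
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores (penalties
#'   negative).
#' @return An `align_scoring` list.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -5, gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

#' Optimal local alignment with affine gaps
#'
#' Full-DP Smith-Waterman (Gotoh) between one query and one subject; both
#' query strands are evaluated and the better reported (ties prefer the
#' plus strand). Spans are reported 1-based inclusive on the original
#' sequences; for a minus-strand hit the subject span is reported with
#' `sstart > send`, BLAST-style.
#'
#' @param query,subject DNA sequences (single strings).
#' @param scoring an [align_scoring].
#' @return An `alignment_hit`: list with `score`, `strand`, `qstart`,
#'   `qend`, `sstart`, `send`, `identity_pct`, `aln_len`.
#' @export
local_align <- function(query, subject, scoring = align_scoring()) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  fwd <- cpp_sw_align(query, subject, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  rev <- cpp_sw_align(revcomp(query), subject, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  L <- nchar(query)
  if (rev$score > fwd$score) {
    r <- rev
    hit <- list(
      score = r$score, strand = "-",
      # map the revcomp-query span back to original query coordinates
      qstart = L - r$qend + 1L, qend = L - r$qstart,
      sstart = r$send, send = r$sstart + 1L
    )
    aln <- r
  } else {
    r <- fwd
    hit <- list(
      score = r$score, strand = "+",
      qstart = r$qstart + 1L, qend = r$qend,
      sstart = r$sstart + 1L, send = r$send
    )
    aln <- r
  }
  if (aln$score <= 0) {
    hit$qstart <- hit$qend <- hit$sstart <- hit$send <- 0L
  }
  hit$identity_pct <- if (aln$aln_len > 0) 100 * aln$matches / aln$aln_len else NA_real_
  hit$aln_len <- aln$aln_len
  structure(hit, class = "alignment_hit")
}

best_db_scores <- function(seqs, db, scoring) {
  cpp_best_db_scores(as.character(seqs), as.character(db), scoring$match,
                     scoring$mismatch, scoring$gap_open, scoring$gap_extend)
}

#' Retain scaffolds homologous to a predicted-gene set
#'
#' A contig is kept iff its best local-alignment score against any gene
#' sequence is strictly greater than `min_score` (the study's
#' "score > 200" retention rule).
#'
#' @param contigs a `contig_set`.
#' @param genes named character vector (or FASTA path) of gene sequences.
#' @param min_score retention threshold (strict inequality).
#' @param scoring an [align_scoring].
#' @return The retained `contig_set`; attribute `best_score` holds the per-
#'   input-contig best scores.
#' @export
filter_scaffolds <- function(contigs, genes, min_score = 200,
                             scoring = align_scoring()) {
  if (is.character(genes) && length(genes) == 1 && file.exists(genes)) {
    genes <- read_fasta(genes)
  }
  if (length(genes) == 0) stop("gene_db must be non-empty")
  if (nrow(contigs) == 0) {
    attr(contigs, "best_score") <- numeric(0)
    return(contigs)
  }
  sc <- best_db_scores(contigs$sequence, genes, scoring)
  out <- contigs[sc > min_score, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contig_set", "data.frame")
  attr(out, "best_score") <- sc
  out
}

#' Discard scaffolds similar to transposable elements
#'
#' A contig is dropped iff its best score against any TE sequence exceeds
#' `min_score`; an empty TE library is a no-op.
#'
#' @param contigs a `contig_set`.
#' @param te_db named character vector (or FASTA path) of TE sequences; may
#'   be empty or `NULL`.
#' @param min_score removal threshold (strict inequality).
#' @param scoring an [align_scoring].
#' @return The surviving `contig_set`.
#' @export
remove_te_like <- function(contigs, te_db, min_score = 200,
                           scoring = align_scoring()) {
  if (is.character(te_db) && length(te_db) == 1 && file.exists(te_db)) {
    te_db <- read_fasta(te_db)
  }
  if (is.null(te_db) || length(te_db) == 0 || nrow(contigs) == 0) return(contigs)
  sc <- best_db_scores(contigs$sequence, te_db, scoring)
  out <- contigs[sc <= min_score, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contig_set", "data.frame")
  out
}

#' All pairwise alignment hits above a threshold
#'
#' One [local_align()] per query/subject pair; used for the hits TSV.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param scoring an [align_scoring].
#' @param min_score report hits with score strictly above this (default
#'   reports everything positive).
#' @return Data frame: `query`, `subject`, `score`, `identity_pct`,
#'   `qstart`, `qend`, `sstart`, `send`, `strand` (1-based inclusive,
#'   minus-strand hits carry `sstart > send`).
#' @export
alignment_hits <- function(queries, subjects, scoring = align_scoring(),
                           min_score = 0) {
  if (is.null(names(queries))) names(queries) <- sprintf("query_%d", seq_along(queries))
  if (is.null(names(subjects))) names(subjects) <- sprintf("subject_%d", seq_along(subjects))
  rows <- list()
  for (qn in names(queries)) {
    for (sn in names(subjects)) {
      h <- local_align(queries[[qn]], subjects[[sn]], scoring)
      if (h$score > min_score) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = qn, subject = sn, score = h$score,
          identity_pct = h$identity_pct, qstart = h$qstart, qend = h$qend,
          sstart = h$sstart, send = h$send, strand = h$strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), identity_pct = numeric(),
                      qstart = integer(), qend = integer(), sstart = integer(),
                      send = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
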