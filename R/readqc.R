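#' Read-trimming operators
#'
#' Vectorized quality/adapter trimming of a [read_set], mirroring the
#' classic trimming-tool operator vocabulary. Every operator returns reads
#' whose sequence and quality are equal-length substrings of the input.
#'
#' * `headcrop(n)` removes the first `min(n, length)` bases.
#' * `leading(q)` removes 5' bases while their quality is `< q`.
#' * `trailing(q)` removes 3' bases while their quality is `< q`.
#' * `sliding_window(w, q)` scans complete `w`-base windows from the 5'
#'   end and keeps only the bases before the first window whose mean
#'   quality drops below `q`; reads shorter than `w` pass unchanged. Only
#'   full windows are scanned, which makes the operator idempotent.
#' * `adapter_clip(adapters, min_overlap)` clips the read suffix when a
#'   prefix of an adapter of length `>= min_overlap` matches it exactly
#'   (longest match wins; `N` never matches).
#'
#' @param reads a [read_set].
#' @param n,q,w,min_overlap operator parameters.
#' @param adapters character vector of adapter sequences.
#' @return A trimmed [read_set].
#' @name trim_operators
NULL

#' @rdname trim_operators
#' @export
headcrop <- function(reads, n) {
  out <- cpp_headcrop(reads$seq, reads$qual, as.integer(n))
  read_set(reads$id, out$seq, out$qual)
}

#' @rdname trim_operators
#' @export
leading <- function(reads, q) {
  stopifnot(q >= 0)
  out <- cpp_leading(reads$seq, reads$qual, as.integer(q))
  read_set(reads$id, out$seq, out$qual)
}

#' @rdname trim_operators
#' @export
trailing <- function(reads, q) {
  stopifnot(q >= 0)
  out <- cpp_trailing(reads$seq, reads$qual, as.integer(q))
  read_set(reads$id, out$seq, out$qual)
}

#' @rdname trim_operators
#' @export
sliding_window <- function(reads, w, q) {
  out <- cpp_sliding_window(reads$seq, reads$qual, as.integer(w), as.numeric(q))
  read_set(reads$id, out$seq, out$qual)
}

#' @rdname trim_operators
#' @export
adapter_clip <- function(reads, adapters, min_overlap = 8L) {
  out <- cpp_adapter_clip(reads$seq, reads$qual, as.character(adapters),
                          as.integer(min_overlap))
  read_set(reads$id, out$seq, out$qual)
}

#' The study's library adapters
#' @return Character vector of the two adapter sequences.
#' @export
default_adapters <- function() {
  c("CACGACGCTCTTCCGATCT", "ACCGCTCTTCCGATCTGTAA")
}

#' Minimum-length filter over read pairs
#'
#' A pair is kept only if both mates survive with length `>= n`; a lone
#' survivor is demoted to the singleton stream.
#'
#' @param r1,r2 mate [read_set]s (parallel), or `r2 = NULL` for single-end
#'   reads (survivors stay in `r1`).
#' @param n minimum surviving length.
#' @return `list(r1, r2, singletons)` of [read_set]s.
#' @export
minlen_filter <- function(r1, r2 = NULL, n) {
  stopifnot(n >= 0)
  if (is.null(r2)) {
    keep <- nchar(r1$seq) >= n
    return(list(r1 = r1[keep], r2 = NULL,
                singletons = read_set(character(), character(), character())))
  }
  stopifnot(length(r1) == length(r2))
  ok1 <- nchar(r1$seq) >= n
  ok2 <- nchar(r2$seq) >= n
  both <- ok1 & ok2
  list(
    r1 = r1[both],
    r2 = r2[both],
    singletons = concat_reads(r1[ok1 & !ok2], r2[ok2 & !ok1])
  )
}

#' Quality-fraction read filter
#'
#' Discard a read iff more than `max_frac` of its bases have quality below
#' `q_min` (the pre-filter applied before SNP-index calling: reads with
#' >10\% of bases under Q30 are excluded). Empty reads are discarded.
#'
#' @param reads a [read_set].
#' @param q_min Phred threshold.
#' @param max_frac maximum tolerated fraction of sub-threshold bases.
#' @return Logical keep vector, one per read.
#' @export
quality_fraction_filter <- function(reads, q_min = 30L, max_frac = 0.10) {
  cpp_quality_fraction_keep(reads$qual, as.integer(q_min), as.numeric(max_frac))
}

#' Parse a trimming-operator string
#'
#' The grammar matches the command strings of the classic trimming tool,
#' e.g. `"HEADCROP:1 SLIDINGWINDOW:4:20 LEADING:20 TRAILING:20 MINLEN:40"`.
#' Adapter clipping is written `ADAPTERCLIP:<seq>+<seq>:<min_overlap>`.
#' Operators are applied strictly in the listed order.
#'
#' @param text operator string.
#' @return A `trim_spec`: ordered list of operator descriptors.
#' @export
trim_spec <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  ops <- lapply(toks, function(tok) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    op <- toupper(parts[1])
    switch(op,
      HEADCROP = {
        stopifnot(length(parts) == 2)
        list(op = "HEADCROP", n = as.integer(parts[2]))
      },
      SLIDINGWINDOW = {
        stopifnot(length(parts) == 3)
        list(op = "SLIDINGWINDOW", w = as.integer(parts[2]), q = as.numeric(parts[3]))
      },
      LEADING = {
        stopifnot(length(parts) == 2)
        list(op = "LEADING", q = as.integer(parts[2]))
      },
      TRAILING = {
        stopifnot(length(parts) == 2)
        list(op = "TRAILING", q = as.integer(parts[2]))
      },
      MINLEN = {
        stopifnot(length(parts) == 2)
        list(op = "MINLEN", n = as.integer(parts[2]))
      },
      ADAPTERCLIP = {
        stopifnot(length(parts) >= 2)
        adapters <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
        mo <- if (length(parts) >= 3) as.integer(parts[3]) else 8L
        list(op = "ADAPTERCLIP", adapters = adapters, min_overlap = mo)
      },
      stop("unknown trimming operator: ", op)
    )
  })
  structure(ops, class = "trim_spec", text = text)
}

#' Apply a trimming specification to (paired) reads
#'
#' Per-read operators act on both mates; `MINLEN` acts pairwise at its
#' position in the operator list, demoting lone survivors to the singleton
#' stream.
#'
#' @param r1,r2 mate [read_set]s (`r2 = NULL` for single-end input).
#' @param spec a [trim_spec] or its string form.
#' @return `list(r1, r2, singletons)`.
#' @export
apply_trim <- function(r1, r2 = NULL, spec) {
  if (is.character(spec)) spec <- trim_spec(spec)
  stopifnot(inherits(spec, "trim_spec"))
  singles <- read_set(character(), character(), character())
  apply_one <- function(reads, o) {
    switch(o$op,
      HEADCROP = headcrop(reads, o$n),
      SLIDINGWINDOW = sliding_window(reads, o$w, o$q),
      LEADING = leading(reads, o$q),
      TRAILING = trailing(reads, o$q),
      ADAPTERCLIP = adapter_clip(reads, o$adapters, o$min_overlap),
      stop("unhandled operator")
    )
  }
  for (o in spec) {
    if (o$op == "MINLEN") {
      res <- minlen_filter(r1, r2, o$n)
      r1 <- res$r1
      r2 <- res$r2
      if (length(singles) > 0) {
        keep <- nchar(singles$seq) >= o$n
        singles <- singles[keep]
      }
      singles <- concat_reads(singles, res$singletons)
    } else {
      r1 <- apply_one(r1, o)
      if (!is.null(r2)) r2 <- apply_one(r2, o)
      if (length(singles) > 0) singles <- apply_one(singles, o)
    }
  }
  list(r1 = r1, r2 = r2, singletons = singles)
}

#' Trim FASTQ files
#'
#' File-level wrapper over [apply_trim()].
#'
#' @param in1,in2 input mate FASTQs (`in2 = NULL` for single-end).
#' @param out1,out2 output mate FASTQs.
#' @param singletons output FASTQ for demoted lone survivors (optional).
#' @param spec operator string or [trim_spec].
#' @return Named tally vector (reads in / surviving pairs / singletons),
#'   invisibly.
#' @export
trim_fastq <- function(in1, in2 = NULL, out1, out2 = NULL, singletons = NULL, spec) {
  r1 <- read_fastq(in1)
  r2 <- if (!is.null(in2)) read_fastq(in2) else NULL
  res <- apply_trim(r1, r2, spec)
  write_fastq(res$r1, out1)
  if (!is.null(r2) && !is.null(out2)) write_fastq(res$r2, out2)
  if (!is.null(singletons)) write_fastq(res$singletons, singletons)
  invisible(c(reads_in = length(r1) + ifelse(is.null(r2), 0L, length(r2)),
              pairs_out = length(res$r1),
              singletons = length(res$singletons)))
}
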