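#' Read a gene-level counts table
#'
#' TSV with columns `gene_id`, `length`, and four sample count columns
#' `wt1`, `rebc1`, `wt2`, `rebc2` (a WT/mutant pair per mutant allele).
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_counts_table <- function(path) {
  tbl <- read.delim(path, stringsAsFactors = FALSE)
  validate_counts_table(tbl)
  tbl
}

count_cols <- c("wt1", "rebc1", "wt2", "rebc2")

validate_counts_table <- function(tbl) {
  need <- c("gene_id", "length", count_cols)
  if (!all(need %in% names(tbl))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tbl$length <= 0)) stop("gene lengths must be > 0")
  cts <- as.matrix(tbl[count_cols])
  if (any(cts < 0) || any(cts != round(cts))) stop("counts must be non-negative integers")
  invisible(tbl)
}

#' Discard weakly covered genes
#'
#' A gene survives iff the sum of its four sample counts strictly exceeds
#' `max_total` (genes with a total of <= `max_total` reads across the four
#' samples are discarded).
#'
#' @param tbl counts table (see [read_counts_table()]).
#' @param max_total discard threshold (default 40).
#' @return The filtered table.
#' @export
filter_low_counts <- function(tbl, max_total = 40) {
  validate_counts_table(tbl)
  keep <- rowSums(tbl[count_cols]) > max_total
  out <- tbl[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcripts per kilobase million
#'
#' `rate_i = count_i / length_i`; `tpm_i = rate_i / sum(rate) * 1e6`. A
#' non-degenerate column sums to 1e6; an all-zero column stays all zero.
#'
#' @param counts numeric count vector for one sample.
#' @param lengths gene lengths in bases, parallel to `counts`.
#' @return TPM vector.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0))
  rate <- counts / lengths
  s <- sum(rate)
  if (s == 0) return(rep(0, length(counts)))
  rate / s * 1e6
}

#' Concordant two-fold expression selection
#'
#' Per mutant/WT pair, the fold change is computed on library-size
#' normalized counts (counts per million; `normalize = "raw"` uses raw
#' counts) with an optional pseudocount. A gene is `down` iff both fold
#' changes are `< low` and `up` iff both are `> high` (strict, concordant
#' across the two mutants); a zero WT count with `pseudo = 0` yields an
#' infinite ratio, which counts as exceeding `high`.
#'
#' @param tbl counts table, already low-count filtered.
#' @param low,high fold-change thresholds (default 0.5 / 2.0).
#' @param pseudo pseudocount added to both numerator and denominator.
#' @param normalize `"cpm"` (default) or `"raw"`.
#' @return A `screen_result` data frame: `gene_id`, `fc1`, `fc2`,
#'   `direction` (`up`/`down`/`none`), and per-sample `tpm_*` columns.
#' @export
fold_change_select <- function(tbl, low = 0.5, high = 2.0, pseudo = 0,
                               normalize = c("cpm", "raw")) {
  normalize <- match.arg(normalize)
  validate_counts_table(tbl)
  cts <- as.matrix(tbl[count_cols])
  norm <- if (normalize == "cpm") {
    libs <- colSums(cts)
    libs[libs == 0] <- 1
    sweep(cts, 2, libs, "/") * 1e6
  } else {
    cts
  }
  fc1 <- (norm[, "rebc1"] + pseudo) / (norm[, "wt1"] + pseudo)
  fc2 <- (norm[, "rebc2"] + pseudo) / (norm[, "wt2"] + pseudo)
  direction <- rep("none", nrow(tbl))
  direction[!is.nan(fc1) & !is.nan(fc2) & fc1 < low & fc2 < low] <- "down"
  direction[!is.nan(fc1) & !is.nan(fc2) & fc1 > high & fc2 > high] <- "up"
  out <- data.frame(
    gene_id = tbl$gene_id, fc1 = unname(fc1), fc2 = unname(fc2),
    direction = direction, stringsAsFactors = FALSE
  )
  for (cc in count_cols) out[[paste0("tpm_", cc)]] <- tpm(tbl[[cc]], tbl$length)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Intersect screen results with external EBC expression
#'
#' Flags each selected gene as expressed in epidermal bladder cells when
#' its TPM in the external EBC table reaches `min_tpm`; genes absent from
#' the EBC table are flagged unknown (`NA`), not unexpressed.
#'
#' @param results a `screen_result` (see [fold_change_select()]).
#' @param ebc_tpm data frame with columns `gene_id` and `tpm` (or a TSV
#'   path).
#' @param min_tpm expression threshold (inclusive).
#' @return `results` with columns `ebc_tpm` and `expressed_in_ebc`.
#' @export
ebc_intersect <- function(results, ebc_tpm, min_tpm = 1.0) {
  if (is.character(ebc_tpm) && length(ebc_tpm) == 1) {
    ebc_tpm <- read.delim(ebc_tpm, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "tpm") %in% names(ebc_tpm)))
  m <- match(results$gene_id, ebc_tpm$gene_id)
  results$ebc_tpm <- ebc_tpm$tpm[m]
  results$expressed_in_ebc <- ifelse(is.na(m), NA, results$ebc_tpm >= min_tpm)
  results
}

#' Full RNA-seq screening arithmetic
#'
#' Low-count filter, concordant two-fold selection, TPM conversion, and
#' EBC-expression intersection, in that order.
#'
#' @param counts counts table or TSV path.
#' @param ebc_tpm EBC TPM table or TSV path (optional).
#' @param max_total,low,high,pseudo,normalize,min_tpm stage parameters.
#' @return List: `results` (selected genes only), `all` (every surviving
#'   gene), `tallies`.
#' @export
expression_screen <- function(counts, ebc_tpm = NULL, max_total = 40,
                              low = 0.5, high = 2.0, pseudo = 0,
                              normalize = "cpm", min_tpm = 1.0) {
  if (is.character(counts) && length(counts) == 1) counts <- read_counts_table(counts)
  n_in <- nrow(counts)
  kept <- filter_low_counts(counts, max_total)
  res <- fold_change_select(kept, low, high, pseudo, normalize)
  if (!is.null(ebc_tpm)) res <- ebc_intersect(res, ebc_tpm, min_tpm)
  sel <- res[res$direction != "none", , drop = FALSE]
  rownames(sel) <- NULL
  list(
    results = sel,
    all = res,
    tallies = c(
      genes_in = n_in,
      genes_after_count_filter = nrow(kept),
      genes_down = sum(res$direction == "down"),
      genes_up = sum(res$direction == "up"),
      genes_down_in_ebc = if (!is.null(ebc_tpm)) {
        sum(res$direction == "down" & res$expressed_in_ebc %in% TRUE)
      } else NA_integer_,
      genes_up_in_ebc = if (!is.null(ebc_tpm)) {
        sum(res$direction == "up" & res$expressed_in_ebc %in% TRUE)
      } else NA_integer_
    )
  )
}

#' Write screen results as TSV
#' @param results a `screen_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
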