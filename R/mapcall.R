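#' Map reads to contigs, ungapped, with a mismatch budget
#'
#' Each read is placed at its best ungapped locus over both strands with at
#' most `max_mismatches` mismatches (the re-implementation of a
#' one-mismatch short-read aligner run). The best placement must be unique:
#' a mismatch-count tie between distinct loci makes the read `ambiguous`
#' and it is excluded from pileups. Placement search is exact (pigeonhole
#' seeding, full-scan fallback for short reads).
#'
#' @param reads a [read_set] or character vector.
#' @param contigs a `contig_set`, named character vector, or FASTA path.
#' @param max_mismatches mismatch budget (default 1).
#' @return Data frame: `id`, `contig`, `start0` (0-based), `strand`
#'   (+1/-1), `mismatches`, `status` in `mapped`/`unmapped`/`ambiguous`;
#'   attribute `contig_names`.
#' @export
map_reads <- function(reads, contigs, max_mismatches = 1L) {
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  ids <- if (inherits(reads, "read_set")) reads$id else as.character(seq_along(seqs))
  ct <- contig_seqs(contigs)
  df <- cpp_map_reads(seqs, ct, as.integer(max_mismatches))
  out <- data.frame(
    id = ids,
    contig = names(ct)[df$contig],
    start0 = df$start0,
    strand = df$strand,
    mismatches = df$mismatches,
    status = df$status,
    stringsAsFactors = FALSE
  )
  attr(out, "contig_idx") <- df$contig
  attr(out, "contig_names") <- names(ct)
  out
}

contig_seqs <- function(contigs) {
  if (inherits(contigs, "contig_set")) {
    out <- contigs$sequence
    names(out) <- contigs$id
  } else if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs)) {
    out <- read_fasta(contigs)
  } else {
    out <- structure(as.character(contigs), names = names(contigs))
    if (is.null(names(out))) names(out) <- sprintf("contig_%d", seq_along(out))
  }
  out
}

#' Per-position base counts from mapped reads
#'
#' Minus-strand reads are complemented back to the forward strand; every
#' mapped base increments its column's count for its base. `N` bases are
#' skipped.
#'
#' @param mapped output of [map_reads()].
#' @param reads the same reads passed to [map_reads()].
#' @param contigs the same contigs passed to [map_reads()].
#' @return Named list (per contig) of 4 x length integer matrices with rows
#'   `A`, `C`, `G`, `T`.
#' @export
pileup_counts <- function(mapped, reads, contigs) {
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  ct <- contig_seqs(contigs)
  idx <- attr(mapped, "contig_idx")
  if (is.null(idx)) idx <- match(mapped$contig, names(ct))
  strands <- mapped$strand
  strands[is.na(strands)] <- 1L
  mats <- cpp_pileup(seqs, idx, ifelse(is.na(mapped$start0), 0L, mapped$start0),
                     strands, nchar(ct))
  names(mats) <- names(ct)
  mats
}

#' SNP index of a site
#'
#' Fraction of aligned reads carrying the alternate allele,
#' `alt / (ref + alt)`; `NA` at zero depth (the site is skipped).
#'
#' @param ref_count,alt_count read counts for the reference and alternate
#'   alleles.
#' @return Numeric in `[0, 1]`, or `NA` when `ref + alt == 0`.
#' @export
snp_index <- function(ref_count, alt_count) {
  d <- ref_count + alt_count
  ifelse(d > 0, alt_count / d, NA_real_)
}

#' Classify one site from per-pool base counts
#'
#' `candidate` iff total depth reaches `min_depth` in both pools, the
#' wild-type pool's alternate-allele frequency lies in `het_band`
#' (heterozygous bulk) and the mutant pool's is at least `hom_min`
#' (homozygous bulk); `low_depth` when either pool is under `min_depth`.
#' The alternate allele is the most frequent non-reference base in the
#' mutant pool.
#'
#' @param wt_counts,mut_counts named counts (`A`,`C`,`G`,`T`) per pool.
#' @param ref_base the scaffold (wild-type) base.
#' @param min_depth minimum per-pool depth.
#' @param het_band inclusive alternate-frequency band for the WT pool.
#' @param hom_min minimum mutant-pool alternate frequency.
#' @return List: `classification`, `alt`, `wt_alt_freq`, `mut_alt_freq`.
#' @export
classify_site <- function(wt_counts, mut_counts, ref_base, min_depth = 10L,
                          het_band = c(0.10, 0.80), hom_min = 0.90) {
  bases <- c("A", "C", "G", "T")
  wt_counts <- wt_counts[bases]
  mut_counts <- mut_counts[bases]
  stopifnot(all(wt_counts >= 0), all(mut_counts >= 0))
  nonref <- setdiff(bases, ref_base)
  alt <- nonref[which.max(mut_counts[nonref])]
  wt_f <- snp_index(wt_counts[[ref_base]], wt_counts[[alt]])
  mut_f <- snp_index(mut_counts[[ref_base]], mut_counts[[alt]])
  cls <- if (sum(wt_counts) < min_depth || sum(mut_counts) < min_depth) {
    "low_depth"
  } else if (!is.na(wt_f) && !is.na(mut_f) &&
             wt_f >= het_band[1] && wt_f <= het_band[2] && mut_f >= hom_min) {
    "candidate"
  } else {
    "not_candidate"
  }
  list(classification = cls, alt = alt, wt_alt_freq = unname(wt_f),
       mut_alt_freq = unname(mut_f))
}

ems_transition <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Call candidate sites on contigs from both pools
#'
#' Maps both pools to the contigs (ungapped, `max_mismatches` budget,
#' unique best), builds per-pool pileups and classifies every position
#' where the mutant pool shows a non-scaffold base. `snp_index_wt` is the
#' fraction of WT-pool reads carrying the mutant allele.
#'
#' @param contigs a `contig_set`, named character vector or FASTA path.
#' @param wt_reads,mut_reads [read_set]s for the two pools.
#' @param min_depth,het_band,hom_min see [classify_site()].
#' @param max_mismatches see [map_reads()].
#' @return A `site_call` data frame: `contig`, `pos_1based`, `ref`, `alt`,
#'   `wt_ref`, `wt_alt`, `mut_ref`, `mut_alt`, `wt_alt_freq`,
#'   `mut_alt_freq`, `snp_index_wt`, `classification`, `ems_consistent`.
#' @export
call_sites <- function(contigs, wt_reads, mut_reads, min_depth = 10L,
                       het_band = c(0.10, 0.80), hom_min = 0.90,
                       max_mismatches = 1L) {
  ct <- contig_seqs(contigs)
  wt_map <- map_reads(wt_reads, ct, max_mismatches)
  mut_map <- map_reads(mut_reads, ct, max_mismatches)
  wt_pile <- pileup_counts(wt_map, wt_reads, ct)
  mut_pile <- pileup_counts(mut_map, mut_reads, ct)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (cn in names(ct)) {
    refchars <- strsplit(ct[[cn]], "")[[1]]
    wp <- wt_pile[[cn]]
    mp <- mut_pile[[cn]]
    ref_idx <- match(refchars, bases)
    # positions where the mutant pool shows any non-scaffold base
    mut_tot <- colSums(mp)
    nonref_ct <- mut_tot - ifelse(is.na(ref_idx), 0L, mp[cbind(ref_idx, seq_along(refchars))])
    for (p in which(nonref_ct > 0 & !is.na(ref_idx))) {
      wt_counts <- stats::setNames(wp[, p], bases)
      mut_counts <- stats::setNames(mp[, p], bases)
      cl <- classify_site(wt_counts, mut_counts, refchars[p], min_depth,
                          het_band, hom_min)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cn, pos_1based = p, ref = refchars[p], alt = cl$alt,
        wt_ref = wt_counts[[refchars[p]]], wt_alt = wt_counts[[cl$alt]],
        mut_ref = mut_counts[[refchars[p]]], mut_alt = mut_counts[[cl$alt]],
        wt_alt_freq = cl$wt_alt_freq, mut_alt_freq = cl$mut_alt_freq,
        snp_index_wt = cl$wt_alt_freq,
        classification = cl$classification,
        ems_consistent = ems_transition(refchars[p], cl$alt),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    contig = character(), pos_1based = integer(), ref = character(),
    alt = character(), wt_ref = integer(), wt_alt = integer(),
    mut_ref = integer(), mut_alt = integer(), wt_alt_freq = numeric(),
    mut_alt_freq = numeric(), snp_index_wt = numeric(),
    classification = character(), ems_consistent = logical(),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("site_call", "data.frame")
  out
}

#' Build the mutant-pool consensus reference
#'
#' Maps the mutant pool to the reference and replaces every base whose
#' total depth reaches `min_depth` and whose SNP index (alternate /
#' (reference + alternate)) strictly exceeds `idx_min` (the "SNP index >
#' 0.9" consensus rule) by the alternate base; all other positions are
#' unchanged.
#'
#' @param reference named character vector (or FASTA path).
#' @param mut_reads mutant-pool [read_set].
#' @param idx_min strict SNP-index threshold for replacement.
#' @param min_depth minimum total depth for replacement.
#' @param max_mismatches see [map_reads()].
#' @return A `mutant_consensus`: list with `consensus` (named character)
#'   and `replaced` (data frame `seqname`, `pos_1based`, `ref`, `alt`,
#'   `snp_index`, `depth`).
#' @export
build_mutant_consensus <- function(reference, mut_reads, idx_min = 0.9,
                                   min_depth = 10L, max_mismatches = 1L) {
  ref <- contig_seqs(reference)
  mp_map <- map_reads(mut_reads, ref, max_mismatches)
  piles <- pileup_counts(mp_map, mut_reads, ref)
  bases <- c("A", "C", "G", "T")
  consensus <- ref
  rows <- list()
  for (sn in names(ref)) {
    refchars <- strsplit(ref[[sn]], "")[[1]]
    m <- piles[[sn]]
    ref_idx <- match(refchars, bases)
    tot <- colSums(m)
    npos <- length(refchars)
    # top non-reference base per column, vectorized
    safe_ref <- ifelse(is.na(ref_idx), 1L, ref_idx)
    masked <- m
    masked[cbind(safe_ref, seq_len(npos))] <- -1L
    alt_i <- max.col(t(masked), ties.method = "first")
    alt_ct <- masked[cbind(alt_i, seq_len(npos))]
    ref_ct <- m[cbind(safe_ref, seq_len(npos))]
    idx <- ifelse(ref_ct + alt_ct > 0, alt_ct / (ref_ct + alt_ct), NA_real_)
    hit <- which(tot >= min_depth & !is.na(ref_idx) & alt_ct > 0 &
                   !is.na(idx) & idx > idx_min)
    if (length(hit) > 0) {
      newchars <- refchars
      newchars[hit] <- bases[alt_i[hit]]
      consensus[[sn]] <- paste(newchars, collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = sn, pos_1based = hit, ref = refchars[hit],
        alt = bases[alt_i[hit]], snp_index = idx[hit], depth = tot[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  replaced <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    seqname = character(), pos_1based = integer(), ref = character(),
    alt = character(), snp_index = numeric(), depth = integer(),
    stringsAsFactors = FALSE
  )
  structure(list(consensus = consensus, replaced = replaced),
            class = "mutant_consensus")
}

#' WT-pool SNP indexes at chosen sites of the mutant consensus
#'
#' Maps the WT pool to the mutant consensus and reports, per site, the
#' fraction of WT-pool reads carrying the mutant allele. Sites default to
#' the consensus's replaced positions; any site table with columns
#' `seqname`, `pos_1based`, `ref`, `alt` may be supplied (e.g. truth-table
#' background sites). Zero-depth sites are flagged, not dropped.
#'
#' @param consensus a `mutant_consensus` (or named character vector when
#'   `sites` is given explicitly).
#' @param wt_reads WT-pool [read_set].
#' @param sites site table, or `NULL` for the replaced sites.
#' @param max_mismatches see [map_reads()].
#' @return Data frame: `seqname`, `pos_1based`, `ref`, `alt`, `ref_count`,
#'   `alt_count`, `depth`, `snp_index`, `covered`.
#' @export
wt_pool_snp_indexes <- function(consensus, wt_reads, sites = NULL,
                                max_mismatches = 1L) {
  if (inherits(consensus, "mutant_consensus")) {
    seqs <- consensus$consensus
    if (is.null(sites)) sites <- consensus$replaced
  } else {
    seqs <- contig_seqs(consensus)
    if (is.null(sites)) stop("sites must be given when consensus is a plain sequence set")
  }
  wt_map <- map_reads(wt_reads, seqs, max_mismatches)
  piles <- pileup_counts(wt_map, wt_reads, seqs)
  bases <- c("A", "C", "G", "T")
  n <- nrow(sites)
  ref_count <- alt_count <- depth <- integer(n)
  for (i in seq_len(n)) {
    m <- piles[[sites$seqname[i]]]
    p <- sites$pos_1based[i]
    ref_count[i] <- m[match(sites$ref[i], bases), p]
    alt_count[i] <- m[match(sites$alt[i], bases), p]
    depth[i] <- sum(m[, p])
  }
  out <- data.frame(
    seqname = sites$seqname, pos_1based = sites$pos_1based,
    ref = sites$ref, alt = sites$alt,
    ref_count = ref_count, alt_count = alt_count, depth = depth,
    snp_index = snp_index(ref_count, alt_count),
    covered = depth > 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a site-call table as TSV
#' @param sites a `site_call` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
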