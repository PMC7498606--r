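# Independent brute-force oracles, kept deliberately naive and separate from
# the package's C++ paths: character-vector scans, full-matrix DP, quadratic
# counters. Tests compare package output against these.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_reads <- function(n, len_range = c(20L, 150L), q_range = c(0L, 41L),
                         with_n = FALSE) {
  alphabet <- if (with_n) c(BASES, "N") else BASES
  lens <- len_range[1] + sample.int(len_range[2] - len_range[1] + 1L, n,
                                    replace = TRUE) - 1L
  seqs <- vapply(lens, random_dna, character(1), alphabet = alphabet)
  quals <- vapply(lens, function(L) {
    q <- q_range[1] + sample.int(q_range[2] - q_range[1] + 1L, L,
                                 replace = TRUE) - 1L
    intToUtf8(33L + q)
  }, character(1))
  read_set(sprintf("r%04d", seq_len(n)), seqs, quals)
}

oracle_revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", vapply(strsplit(s, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}

qvals <- function(qual) utf8ToInt(qual) - 33L

substr_read <- function(seq, qual, from, to) {
  if (to < from) list(seq = "", qual = "")
  else list(seq = substr(seq, from, to), qual = substr(qual, from, to))
}

# --- trimming oracles (one read at a time) ---

oracle_headcrop <- function(seq, qual, n) {
  substr_read(seq, qual, n + 1L, nchar(seq))
}

oracle_leading <- function(seq, qual, q) {
  qs <- qvals(qual)
  i <- 1L
  while (i <= length(qs) && qs[i] < q) i <- i + 1L
  substr_read(seq, qual, i, nchar(seq))
}

oracle_trailing <- function(seq, qual, q) {
  qs <- qvals(qual)
  j <- length(qs)
  while (j >= 1L && qs[j] < q) j <- j - 1L
  substr_read(seq, qual, 1L, j)
}

oracle_sliding_window <- function(seq, qual, w, q) {
  qs <- qvals(qual)
  L <- length(qs)
  cut <- L
  if (L >= w) {
    for (s in seq_len(L - w + 1L)) {   # full windows only
      if (mean(qs[s:(s + w - 1L)]) < q) { cut <- s - 1L; break }
    }
  }
  substr_read(seq, qual, 1L, cut)
}

oracle_adapter_clip <- function(seq, qual, adapters, min_overlap) {
  L <- nchar(seq)
  best <- 0L
  for (ad in adapters) {
    for (o in seq.int(min(L, nchar(ad)), 1L)) {
      if (o < min_overlap || o <= best) next
      sfx <- substr(seq, L - o + 1L, L)
      pfx <- substr(ad, 1L, o)
      if (grepl("N", sfx, fixed = TRUE) || grepl("N", pfx, fixed = TRUE)) next
      if (sfx == pfx) { best <- o; break }
    }
  }
  substr_read(seq, qual, 1L, L - best)
}

oracle_quality_fraction_keep <- function(qual, q_min, max_frac) {
  qs <- qvals(qual)
  if (length(qs) == 0) return(FALSE)
  (sum(qs < q_min) / length(qs)) <= max_frac
}

# --- k-mer oracles ---

oracle_canonical <- function(km) {
  rc <- oracle_revcomp(km)
  ifelse(km <= rc, km, rc)
}

oracle_catalog <- function(seqs, k) {
  all_kmers <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    w <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    w[!grepl("N", w, fixed = TRUE)]
  }))
  if (length(all_kmers) == 0) {
    return(data.frame(kmer = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(oracle_canonical(all_kmers))
  data.frame(kmer = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

oracle_recruit <- function(seqs, specific, k) {
  vapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(FALSE)
    w <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    w <- w[!grepl("N", w, fixed = TRUE)]
    any(oracle_canonical(w) %in% specific)
  }, logical(1), USE.NAMES = FALSE)
}

# --- full-DP affine local alignment oracle (score only) ---

oracle_sw_score_one_strand <- function(q, s, match = 2, mismatch = -3,
                                       gap_open = -5, gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  open <- gap_open + gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + open, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + open, F[i - 1, j] + gap_extend)
      sub <- if (qc[i - 1] %in% BASES && qc[i - 1] == sc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

oracle_sw_score <- function(q, s, ...) {
  max(oracle_sw_score_one_strand(q, s, ...),
      oracle_sw_score_one_strand(oracle_revcomp(q), s, ...))
}

# --- exhaustive ungapped mapping oracle ---

oracle_map_read <- function(read, contigs, max_mm) {
  hits <- list()
  for (ci in seq_along(contigs)) {
    ctg <- strsplit(contigs[ci], "")[[1]]
    for (strand in c(1L, -1L)) {
      oriented <- if (strand == 1L) read else oracle_revcomp(read)
      rc <- strsplit(oriented, "")[[1]]
      L <- length(rc)
      if (L > length(ctg)) next
      for (start in 0:(length(ctg) - L)) {
        seg <- ctg[(start + 1):(start + L)]
        mm <- sum(rc != seg | !(rc %in% BASES) | !(seg %in% BASES))
        if (mm <= max_mm) {
          hits[[length(hits) + 1L]] <- list(contig = ci, start = start,
                                            strand = strand, mm = mm)
        }
      }
    }
  }
  if (length(hits) == 0) return(list(status = "unmapped"))
  mms <- vapply(hits, `[[`, numeric(1), "mm")
  best <- min(mms)
  if (sum(mms == best) > 1) return(list(status = "ambiguous"))
  c(hits[[which.min(mms)]], status = "mapped")
}

# --- pileup oracle ---

oracle_pileup <- function(read_seqs, contig_idx, start0, strand, contig_lens) {
  mats <- lapply(contig_lens, function(L) {
    m <- matrix(0L, 4, L, dimnames = list(BASES, NULL))
    m
  })
  for (i in seq_along(read_seqs)) {
    if (is.na(contig_idx[i])) next
    s <- read_seqs[i]
    if (strand[i] < 0) s <- oracle_revcomp(s)
    ch <- strsplit(s, "")[[1]]
    for (j in seq_along(ch)) {
      if (ch[j] %in% BASES) {
        m <- mats[[contig_idx[i]]]
        m[ch[j], start0[i] + j] <- m[ch[j], start0[i] + j] + 1L
        mats[[contig_idx[i]]] <- m
      }
    }
  }
  mats
}

# --- expression-screen oracle (one pass, explicit loops) ---

oracle_screen <- function(tbl, max_total = 40, low = 0.5, high = 2.0) {
  keep <- logical(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    keep[i] <- (tbl$wt1[i] + tbl$rebc1[i] + tbl$wt2[i] + tbl$rebc2[i]) > max_total
  }
  kept <- tbl[keep, , drop = FALSE]
  libs <- c(sum(kept$wt1), sum(kept$rebc1), sum(kept$wt2), sum(kept$rebc2))
  libs[libs == 0] <- 1
  dirs <- character(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    n1 <- kept$wt1[i] / libs[1] * 1e6
    m1 <- kept$rebc1[i] / libs[2] * 1e6
    n2 <- kept$wt2[i] / libs[3] * 1e6
    m2 <- kept$rebc2[i] / libs[4] * 1e6
    f1 <- m1 / n1
    f2 <- m2 / n2
    dirs[i] <- if (!is.nan(f1) && !is.nan(f2) && f1 < low && f2 < low) "down"
    else if (!is.nan(f1) && !is.nan(f2) && f1 > high && f2 > high) "up"
    else "none"
  }
  list(kept = kept, direction = dirs)
}

oracle_tpm <- function(counts, lengths) {
  r <- counts / lengths
  if (sum(r) == 0) return(rep(0, length(counts)))
  r / sum(r) * 1e6
}

# random counts table fixture
random_counts_table <- function(n_genes = 100L) {
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    length = sample(200:5000, n_genes, replace = TRUE),
    wt1 = rpois(n_genes, 30), rebc1 = rpois(n_genes, 30),
    wt2 = rpois(n_genes, 30), rebc2 = rpois(n_genes, 30),
    stringsAsFactors = FALSE
  )
}

# tiled error-free reads covering a source sequence end to end at ~20x
tiled_reads <- function(src, read_len = 150L, step = 7L) {
  L <- nchar(src)
  starts <- unique(c(seq(1L, L - read_len + 1L, by = step), L - read_len + 1L))
  fwd <- substring(src, starts, starts + read_len - 1L)
  # alternate strands so both orientations are exercised
  flip <- seq_along(fwd) %% 2L == 0L
  fwd[flip] <- oracle_revcomp(fwd[flip])
  fwd
}
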