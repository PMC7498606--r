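# Ungapped mapping, pileups, zygosity classification, SNP indexes

test_that("exact substrings map uniquely with zero mismatches", {
  set.seed(61)
  ctg <- c(one = random_dna(500))
  r <- substr(ctg, 101, 200)
  m <- map_reads(r, ctg, 1)
  expect_equal(m$status, "mapped")
  expect_equal(m$start0, 100L)
  expect_equal(m$mismatches, 0L)
  expect_equal(m$strand, 1L)
  # its reverse complement maps to the same locus on the minus strand
  m2 <- map_reads(revcomp(r), ctg, 1)
  expect_equal(m2$start0, 100L)
  expect_equal(m2$strand, -1L)
})

test_that("one mismatch maps within budget, two do not", {
  set.seed(62)
  ctg <- c(one = random_dna(500))
  r <- substr(ctg, 201, 300)
  substr(r, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(r, 50, 50))[1]
  m <- map_reads(r, ctg, 1)
  expect_equal(m$status, "mapped")
  expect_equal(m$mismatches, 1L)
  substr(r, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(r, 10, 10))[1]
  expect_equal(map_reads(r, ctg, 1)$status, "unmapped")
})

test_that("ties between distinct loci are ambiguous", {
  set.seed(63)
  block <- random_dna(80)
  ctg <- c(one = paste0(block, random_dna(100), block))
  m <- map_reads(block, ctg, 1)
  expect_equal(m$status, "ambiguous")
  expect_true(is.na(m$start0))
})

test_that("mapping agrees with the exhaustive all-offset oracle", {
  set.seed(64)
  contigs <- c(a = random_dna(300), b = random_dna(250))
  reads <- character(40)
  for (i in 1:40) {
    kind <- i %% 4
    if (kind == 0) {
      reads[i] <- random_dna(sample(30:60, 1))       # random, likely unmapped
    } else {
      src <- sample(1:2, 1)
      L <- sample(40:80, 1)
      st <- sample(nchar(contigs[src]) - L + 1, 1)
      r <- substr(contigs[src], st, st + L - 1)
      nmut <- sample(0:2, 1)
      for (j in seq_len(nmut)) {
        p <- sample(L, 1)
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (kind == 2) r <- revcomp(r)
      reads[i] <- r
    }
  }
  for (mm in 0:2) {
    got <- map_reads(reads, contigs, mm)
    for (i in seq_along(reads)) {
      ora <- oracle_map_read(reads[i], unname(contigs), mm)
      expect_equal(got$status[i], ora$status,
                   label = sprintf("read %d mm %d status", i, mm))
      if (ora$status == "mapped") {
        expect_equal(unname(c(match(got$contig[i], names(contigs)),
                              got$start0[i], got$strand[i], got$mismatches[i])),
                     unname(c(ora$contig, ora$start, ora$strand, ora$mm)))
      }
    }
  }
})

test_that("short reads fall back to a full scan and still map", {
  set.seed(65)
  ctg <- c(one = random_dna(200))
  r <- substr(ctg, 50, 69)   # 20 bases, below seeded minimum for mm=1
  m <- map_reads(r, ctg, 1)
  expect_equal(m$status, "mapped")
  expect_equal(m$start0, 49L)
})

test_that("pileups equal a brute-force per-column tally", {
  set.seed(66)
  contigs <- c(a = random_dna(200), b = random_dna(150))
  reads <- character(30)
  for (i in 1:30) {
    src <- sample(1:2, 1)
    L <- sample(40:70, 1)
    st <- sample(nchar(contigs[src]) - L + 1, 1)
    r <- substr(contigs[src], st, st + L - 1)
    if (i %% 2 == 0) r <- revcomp(r)
    reads[i] <- r
  }
  m <- map_reads(reads, contigs, 1)
  got <- pileup_counts(m, reads, contigs)
  idx <- match(m$contig, names(contigs))
  ora <- oracle_pileup(reads, idx, m$start0, ifelse(is.na(m$strand), 1L, m$strand),
                       nchar(contigs))
  expect_equal(unname(got[["a"]]), unname(ora[[1]]))
  expect_equal(unname(got[["b"]]), unname(ora[[2]]))
  # column sums never exceed the number of overlapping reads
  expect_true(all(colSums(got[["a"]]) <= length(reads)))
  # total tallied bases equal total mapped bases
  mapped_bases <- sum(nchar(reads[m$status == "mapped"]))
  expect_equal(sum(got[["a"]]) + sum(got[["b"]]), mapped_bases)
})

test_that("two agreeing overlapping reads double their overlap counts", {
  ctg <- c(one = random_dna(120))
  r1 <- substr(ctg, 1, 80)
  r2 <- substr(ctg, 41, 120)
  m <- map_reads(c(r1, r2), ctg, 0)
  p <- pileup_counts(m, c(r1, r2), ctg)[["one"]]
  expect_true(all(colSums(p)[41:80] == 2L))
  expect_true(all(colSums(p)[1:40] == 1L))
  # counts agree with the contig base everywhere (no disagreement)
  chars <- strsplit(unname(ctg), "")[[1]]
  hit <- p[cbind(match(chars, c("A", "C", "G", "T")), 1:120)]
  expect_equal(sum(hit), sum(p))
})

test_that("snp_index is alt/(ref+alt) with NA at zero depth", {
  expect_equal(snp_index(5, 5), 0.5)
  expect_equal(snp_index(1, 19), 0.95)
  expect_gt(snp_index(1, 19), 0.9)
  expect_equal(snp_index(20, 0), 0)
  expect_true(is.na(snp_index(0, 0)))
})

test_that("classify_site applies depth, het-band and hom-min rules", {
  ct <- function(A = 0, C = 0, G = 0, T = 0) c(A = A, C = C, G = G, T = T)
  # WT 12 ref / 6 alt (0.333), mutant 1 ref / 19 alt (0.95): candidate
  r <- classify_site(ct(G = 12, A = 6), ct(G = 1, A = 19), "G")
  expect_equal(r$classification, "candidate")
  expect_equal(r$alt, "A")
  expect_equal(r$wt_alt_freq, 1 / 3, tolerance = 1e-9)
  expect_equal(r$mut_alt_freq, 0.95)
  # WT homozygous ref: 0 not in [0.2, 0.8]
  r2 <- classify_site(ct(G = 20), ct(A = 20), "G")
  expect_equal(r2$classification, "not_candidate")
  # WT depth below 10
  r3 <- classify_site(ct(G = 3, A = 2), ct(A = 20), "G")
  expect_equal(r3$classification, "low_depth")
  # mutant pool not homozygous enough
  r4 <- classify_site(ct(G = 10, A = 10), ct(G = 10, A = 10), "G")
  expect_equal(r4$classification, "not_candidate")
})

test_that("call_sites finds a planted het/hom site and flags EMS type", {
  set.seed(67)
  ctg <- c(ctg1 = random_dna(300))
  pos <- 150L
  substr(ctg, pos, pos) <- "G"
  alt_version <- ctg
  substr(alt_version, pos, pos) <- "A"
  mk_reads <- function(src, n, seed_off) {
    starts <- sample(1:(300 - 100 + 1), n, replace = TRUE)
    substring(src, starts, starts + 99)
  }
  wt <- read_set(sprintf("w%d", 1:60),
                 c(mk_reads(ctg, 40), mk_reads(alt_version, 20)),
                 rep(strrep("F", 100), 60))
  mut <- read_set(sprintf("m%d", 1:40), mk_reads(alt_version, 40),
                  rep(strrep("F", 100), 40))
  sites <- call_sites(ctg, wt, mut)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos_1based, pos)
  expect_equal(sites$ref, "G")
  expect_equal(sites$alt, "A")
  expect_equal(sites$classification, "candidate")
  expect_true(sites$ems_consistent)
  expect_equal(sites$snp_index_wt, sites$wt_alt_freq)
})

test_that("consensus replacement follows the strict SNP index > 0.9 rule", {
  set.seed(68)
  ref <- c(chr = random_dna(200))
  pos <- 100L
  alt_base <- setdiff(c("A", "C", "G", "T"), substr(ref, pos, pos))[1]
  mk <- function(n_alt, n_ref) {
    alt_src <- ref
    substr(alt_src, pos, pos) <- alt_base
    starts <- rep(seq(41L, 100L, by = 3L), length.out = n_alt + n_ref)
    src <- c(rep(alt_src, n_alt), rep(unname(ref), n_ref))
    read_set(sprintf("r%d", seq_along(src)),
             substring(src, starts, starts + 99L),
             rep(strrep("F", 100), length(src)))
  }
  # 19 alt / 1 ref: index 0.95 > 0.9 -> replaced
  cons <- build_mutant_consensus(ref, mk(19L, 1L))
  expect_equal(nrow(cons$replaced), 1L)
  expect_equal(cons$replaced$pos_1based, pos)
  expect_equal(unname(substr(cons$consensus, pos, pos)), alt_base)
  expect_equal(cons$replaced$snp_index, 0.95)
  # 18 alt / 2 ref: index exactly 0.9, NOT replaced
  cons2 <- build_mutant_consensus(ref, mk(18L, 2L))
  expect_equal(nrow(cons2$replaced), 0L)
  expect_identical(unname(cons2$consensus), unname(ref))
  # no site above threshold: consensus equals reference
  cons3 <- build_mutant_consensus(ref, mk(0L, 20L))
  expect_identical(unname(cons3$consensus), unname(ref))
})

test_that("WT pool identical to the mutant pool gives SNP indexes near 1", {
  set.seed(69)
  ref <- c(chr = random_dna(300))
  pos <- 150L
  alt_src <- ref
  alt_base <- setdiff(c("A", "C", "G", "T"), substr(ref, pos, pos))[1]
  substr(alt_src, pos, pos) <- alt_base
  starts <- seq(60L, 150L, by = 4L)
  reads <- read_set(sprintf("r%d", seq_along(starts)),
                    substring(alt_src, starts, starts + 99L),
                    rep(strrep("F", 100), length(starts)))
  cons <- build_mutant_consensus(ref, reads)
  expect_equal(cons$replaced$pos_1based, pos)
  idx <- wt_pool_snp_indexes(cons, reads)
  expect_equal(idx$snp_index, 1)
  expect_true(idx$covered)
})

test_that("uncovered sites are flagged rather than dropped", {
  ref <- c(chr = random_dna(200))
  reads <- read_set("r1", substr(ref, 1, 100), strrep("F", 100))
  sites <- data.frame(seqname = "chr", pos_1based = 180L,
                      ref = substr(ref, 180, 180), alt = "A",
                      stringsAsFactors = FALSE)
  idx <- wt_pool_snp_indexes(unname(c(chr = ref)), reads, sites = NULL) |>
    try(silent = TRUE)
  expect_s3_class(idx, "try-error")   # plain sequences require explicit sites
  idx2 <- wt_pool_snp_indexes(ref, reads, sites = sites)
  expect_false(idx2$covered)
  expect_true(is.na(idx2$snp_index))
})
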