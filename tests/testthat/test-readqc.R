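# Trimming and filtering operators

q2c <- function(q) intToUtf8(33L + q)  # Phred values -> quality string
one_read <- function(seq, q) read_set("r1", seq, q2c(q))

test_that("headcrop removes the requested prefix and saturates", {
  r150 <- read_set("x", random_dna(150), strrep("F", 150))
  expect_identical(headcrop(r150, 0)$seq, r150$seq)
  h1 <- headcrop(r150, 1)
  expect_equal(nchar(h1$seq), 149L)
  expect_identical(h1$seq, substr(r150$seq, 2, 150))
  expect_identical(headcrop(r150, 200)$seq, "")
})

test_that("leading and trailing scan from the correct ends", {
  r <- one_read("ACGTA", c(5L, 5L, 30L, 30L, 5L))
  led <- leading(r, 15)
  expect_identical(led$seq, "GTA")         # last 3 kept
  tra <- trailing(led, 15)
  expect_identical(tra$seq, "GT")          # first 2 of those kept
  hi <- one_read("ACGT", rep(30L, 4))
  expect_identical(leading(hi, 15)$seq, "ACGT")
  expect_identical(trailing(hi, 15)$seq, "ACGT")
  lo <- one_read("ACGT", rep(5L, 4))
  expect_identical(leading(lo, 15)$seq, "")
  expect_identical(trailing(lo, 15)$seq, "")
})

test_that("sliding_window cuts at the first failing window", {
  r <- one_read(random_dna(30), c(rep(30L, 20), rep(2L, 10)))
  got <- sliding_window(r, 4, 20)
  ora <- oracle_sliding_window(r$seq[1], r$qual[1], 4L, 20)
  expect_identical(got$seq[1], ora$seq)
  expect_identical(got$qual[1], ora$qual)

  hi <- one_read(random_dna(50), rep(30L, 50))
  expect_identical(sliding_window(hi, 4, 20)$seq, hi$seq)
  lo <- one_read(random_dna(50), rep(2L, 50))
  expect_identical(sliding_window(lo, 4, 20)$seq, "")
})

test_that("adapter_clip clips suffix-prefix overlaps above min_overlap", {
  ad <- default_adapters()
  core <- random_dna(60)
  r <- read_set("x", paste0(core, substr(ad[1], 1, 10)), strrep("F", 70))
  got <- adapter_clip(r, ad, 8)
  expect_identical(got$seq, core)
  expect_equal(nchar(got$qual), 60L)
  # 7-base overlap: below min_overlap, unclipped
  r7 <- read_set("x", paste0(core, substr(ad[1], 1, 7)), strrep("F", 67))
  expect_identical(adapter_clip(r7, ad, 8)$seq, r7$seq)
  # no adapter at all
  expect_identical(adapter_clip(r, "GGGGGGGGGGGG", 8)$seq, r$seq)
})

test_that("minlen_filter keeps pairs, demotes singletons, drops failures", {
  r1 <- read_set(c("a/1", "b/1", "c/1"),
                 c(random_dna(150), random_dna(39), random_dna(10)),
                 c(strrep("F", 150), strrep("F", 39), strrep("F", 10)))
  r2 <- read_set(c("a/2", "b/2", "c/2"),
                 c(random_dna(150), random_dna(150), random_dna(20)),
                 c(strrep("F", 150), strrep("F", 150), strrep("F", 20)))
  res <- minlen_filter(r1, r2, 40)
  expect_equal(res$r1$id, "a/1")           # both mates >= 40
  expect_equal(res$r2$id, "a/2")
  expect_equal(res$singletons$id, "b/2")   # 39 < 40 boundary demotes pair b
  # pair c dropped entirely
  expect_false(any(grepl("^c", c(res$r1$id, res$r2$id, res$singletons$id))))
})

test_that("quality_fraction_filter enforces the >10% below-Q30 rule", {
  mk <- function(n_low, n = 100L) {
    one_read(random_dna(n), c(rep(29L, n_low), rep(40L, n - n_low)))
  }
  expect_true(quality_fraction_filter(mk(10L)))    # 0.10 is not > 0.10
  expect_false(quality_fraction_filter(mk(11L)))   # 0.11 > 0.10
  expect_true(quality_fraction_filter(mk(0L)))
  empty <- read_set("e", "", "")
  expect_false(quality_fraction_filter(empty))
})

test_that("quality and adapter operators are idempotent and yield substrings", {
  set.seed(101)
  reads <- random_reads(300, with_n = TRUE)
  # headcrop removes a fixed count per application, so it is only
  # idempotent once saturated; the scan-based operators are idempotent
  # outright
  sat <- headcrop(reads, 200)
  expect_identical(headcrop(sat, 200), sat)
  ops <- list(
    function(r) leading(r, 20),
    function(r) trailing(r, 20),
    function(r) sliding_window(r, 5, 22),
    function(r) adapter_clip(r, default_adapters(), 8)
  )
  for (f in ops) {
    once <- f(reads)
    twice <- f(once)
    expect_identical(once$seq, twice$seq)
    expect_identical(once$qual, twice$qual)
    expect_identical(nchar(once$seq), nchar(once$qual))
    # outputs are substrings of inputs
    ok <- mapply(function(a, b) a == "" || grepl(a, b, fixed = TRUE),
                 once$seq, reads$seq)
    expect_true(all(ok))
  }
})

test_that("operators agree byte-for-byte with naive re-implementations", {
  set.seed(202)
  reads <- random_reads(1000, with_n = TRUE)
  check <- function(fast, slow) {
    got <- fast(reads)
    for (i in seq_along(reads$seq)) {
      o <- slow(reads$seq[i], reads$qual[i])
      expect_identical(got$seq[i], o$seq)
      expect_identical(got$qual[i], o$qual)
    }
  }
  check(function(r) headcrop(r, 5),
        function(s, q) oracle_headcrop(s, q, 5L))
  check(function(r) leading(r, 18),
        function(s, q) oracle_leading(s, q, 18))
  check(function(r) trailing(r, 18),
        function(s, q) oracle_trailing(s, q, 18))
  check(function(r) sliding_window(r, 4, 20),
        function(s, q) oracle_sliding_window(s, q, 4L, 20))
  check(function(r) adapter_clip(r, default_adapters(), 8),
        function(s, q) oracle_adapter_clip(s, q, default_adapters(), 8L))
  keep <- quality_fraction_filter(reads)
  ora <- vapply(reads$qual, oracle_quality_fraction_keep, logical(1),
                q_min = 30L, max_frac = 0.10, USE.NAMES = FALSE)
  expect_identical(keep, ora)
})

test_that("trim_spec parses the study's operator strings in order", {
  sp <- trim_spec("HEADCROP:1 SLIDINGWINDOW:4:20 LEADING:20 TRAILING:20 MINLEN:40")
  expect_equal(vapply(sp, `[[`, character(1), "op"),
               c("HEADCROP", "SLIDINGWINDOW", "LEADING", "TRAILING", "MINLEN"))
  expect_equal(sp[[2]]$w, 4L)
  expect_equal(sp[[2]]$q, 20)
  sp2 <- trim_spec("SLIDINGWINDOW:10:20 LEADING:15 TRAILING:10 MINLEN:40")
  expect_equal(sp2[[1]]$w, 10L)
  ad <- trim_spec("ADAPTERCLIP:CACGACGCTCTTCCGATCT+ACCGCTCTTCCGATCTGTAA:8")
  expect_equal(ad[[1]]$adapters, default_adapters())
  expect_error(trim_spec("BOGUS:1"), "unknown")
})

test_that("apply_trim runs operators in order with pairwise MINLEN", {
  r1 <- read_set("a/1", random_dna(150),
                 q2c(c(rep(35L, 60), rep(2L, 90))))
  r2 <- read_set("a/2", random_dna(150), strrep("F", 150))
  res <- apply_trim(r1, r2, "SLIDINGWINDOW:10:20 MINLEN:40")
  # first failing 10-window starts at base 56 (5 x Q35 + 5 x Q2 -> 18.5)
  expect_equal(nchar(res$r1$seq), 55L)
  expect_equal(length(res$singletons), 0L)
  # shrink mate 1 below MINLEN: pair demotes to a singleton mate 2
  r1b <- read_set("a/1", random_dna(150),
                  q2c(c(rep(35L, 20), rep(2L, 130))))
  res2 <- apply_trim(r1b, r2, "SLIDINGWINDOW:10:20 MINLEN:40")
  expect_equal(length(res2$r1), 0L)
  expect_equal(res2$singletons$id, "a/2")
})

test_that("trim_fastq round-trips through files", {
  dir <- withr::local_tempdir()
  set.seed(7)
  r1 <- random_reads(50, len_range = c(150L, 150L), q_range = c(30L, 40L))
  r2 <- random_reads(50, len_range = c(150L, 150L), q_range = c(30L, 40L))
  write_fastq(r1, file.path(dir, "in1.fastq"))
  write_fastq(r2, file.path(dir, "in2.fastq"))
  trim_fastq(file.path(dir, "in1.fastq"), file.path(dir, "in2.fastq"),
             file.path(dir, "out1.fastq"), file.path(dir, "out2.fastq"),
             file.path(dir, "single.fastq"),
             "HEADCROP:1 SLIDINGWINDOW:4:20 LEADING:20 TRAILING:20 MINLEN:40")
  out1 <- read_fastq(file.path(dir, "out1.fastq"))
  expect_equal(length(out1), 50L)
  expect_true(all(nchar(out1$seq) == 149L))
})
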