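# Synthetic allotetraploid EMS bulk generator

test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(divergence = 0.5), "divergence")
  expect_error(sim_config(error_rate = 1), "error_rate")
  expect_error(sim_config(subgenome_length = 100, read_length = 150), "read_length")
  expect_error(sim_config(causal_position = c(3, 10)), "causal_position")
  expect_error(sim_config(insert_mean = 100, read_length = 150), "insert_mean")
})

test_that("zero divergence yields identical subgenomes", {
  cfg <- sim_config(seed = 3, subgenome_length = 2000, divergence = 0)
  ref <- make_reference(cfg)
  expect_length(ref, 2)
  expect_identical(ref[[1]], ref[[2]])
})

test_that("observed divergence matches the substitution probability", {
  cfg <- sim_config(seed = 5, subgenome_length = 1e5, divergence = 0.02)
  ref <- make_reference(cfg)
  a <- strsplit(ref[[1]], "")[[1]]
  b <- strsplit(ref[[2]], "")[[1]]
  d_hat <- mean(a != b)
  se <- sqrt(0.02 * 0.98 / 1e5)
  expect_lt(abs(d_hat - 0.02), 3 * se)
})

test_that("the reference generator is deterministic", {
  cfg <- sim_config(seed = 42, subgenome_length = 5000)
  expect_identical(make_reference(cfg), make_reference(cfg))
})

test_that("subgenome 37-mer identity follows (1 - divergence)^37", {
  d <- 0.02
  k <- 37L
  cfg <- sim_config(seed = 8, subgenome_length = 1e5, divergence = d)
  ref <- make_reference(cfg)
  a <- strsplit(ref[[1]], "")[[1]]
  b <- strsplit(ref[[2]], "")[[1]]
  # non-overlapping windows are i.i.d. Bernoulli((1-d)^k)
  starts <- seq(1L, length(a) - k + 1L, by = k)
  same <- vapply(starts, function(s) all(a[s:(s + k - 1L)] == b[s:(s + k - 1L)]),
                 logical(1))
  p <- (1 - d)^k
  se <- sqrt(p * (1 - p) / length(starts))
  expect_lt(abs(mean(same) - p), 3 * se)
})

test_that("truth tables carry exactly one causal EMS record", {
  cfg <- sim_config(seed = 2, subgenome_length = 20000, n_background_mutations = 0L)
  ref <- make_reference(cfg)
  truth <- plant_mutations(ref, cfg)
  expect_equal(nrow(truth$records), 1L)
  expect_true(truth$records$is_causal)

  cfg2 <- sim_config(seed = 2, subgenome_length = 20000, n_background_mutations = 12L)
  truth2 <- plant_mutations(ref, cfg2)
  expect_equal(nrow(truth2$records), 13L)
  expect_equal(sum(truth2$records$is_causal), 1L)
  # default spectrum: everything is a G>A / C>T transition
  expect_true(all(truth2$records$ems_consistent))
  expect_true(all(truth2$records$ref_base != truth2$records$alt_base))
  # distinct positions
  key <- paste(truth2$records$subgenome, truth2$records$position)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("pool genotypes follow the 1 AA : 2 Aa / homozygous-alt design", {
  cfg <- sim_config(seed = 6, subgenome_length = 20000,
                    n_plants_per_pool = 400L, n_background_mutations = 5L)
  ref <- make_reference(cfg)
  truth <- plant_mutations(ref, cfg)
  ci <- which(truth$records$is_causal)
  # mutant pool: all homozygous alternate
  expect_true(all(truth$mut_geno[ci, ] == 2L))
  # WT pool: AA or Aa, never aa
  expect_true(all(truth$wt_geno[ci, ] %in% c(0L, 1L)))
  # expected mutant-allele frequency 1/3 across plant chromosomes
  freq <- sum(truth$wt_geno[ci, ]) / (2 * 400)
  p_aa <- 2 / 3  # per plant, dosage 1 w.p. 2/3 -> allele freq 1/3
  se <- sqrt(p_aa * (1 - p_aa) / 400) / 2
  expect_lt(abs(freq - 1 / 3), 3 * se)
  # background sites: allele frequency 0.5 in both pools
  for (i in setdiff(seq_len(nrow(truth$records)), ci)) {
    for (g in list(truth$wt_geno[i, ], truth$mut_geno[i, ])) {
      f <- sum(g) / (2 * 400)
      expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / (2 * 400)))
    }
  }
})

test_that("a causal position on a non-EMS base moves to the nearest eligible one", {
  cfg <- sim_config(seed = 9, subgenome_length = 5000)
  ref <- make_reference(cfg)
  chars <- strsplit(ref[[1]], "")[[1]]
  bad <- which(chars %in% c("A", "T"))[50]
  cfg2 <- sim_config(seed = 9, subgenome_length = 5000,
                     causal_position = c(1L, bad - 1L))
  truth <- plant_mutations(ref, cfg2)
  rec <- truth$records[truth$records$is_causal, ]
  expect_true(rec$position_adjusted)
  expect_true(rec$ref_base %in% c("G", "C"))
  expect_true(rec$ems_consistent)
})

test_that("error-free mutant reads always carry the alternate causal allele", {
  cfg <- sim_config(seed = 4, subgenome_length = 20000, depth = 60,
                    error_rate = 0, n_background_mutations = 0L)
  ref <- make_reference(cfg)
  truth <- plant_mutations(ref, cfg)
  rec <- truth$records[truth$records$is_causal, ]
  pos1 <- rec$position + 1L
  ctx_ref <- substr(ref[[rec$subgenome]], pos1 - 18L, pos1 + 18L)
  ctx_alt <- ctx_ref
  substr(ctx_alt, 19L, 19L) <- rec$alt_base
  pool <- sequence_pool(ref, truth, "mutant", cfg)
  reads <- concat_reads(pool$r1, pool$r2)
  # the homoeologous subgenome can carry the reference-allele context in
  # locally undiverged windows; the claim concerns the causal subgenome
  reads <- reads[grepl(sprintf("_s%d_", rec$subgenome), reads$id)]
  has <- function(p) grepl(p, reads$seq, fixed = TRUE) |
    grepl(revcomp(p), reads$seq, fixed = TRUE)
  expect_equal(sum(has(ctx_ref)), 0L)
  expect_gt(sum(has(ctx_alt)), 0L)
})

test_that("WT-pool causal-allele read fraction is near 1/3 at deep coverage", {
  cfg <- sim_config(seed = 10, subgenome_length = 20000, depth = 100,
                    error_rate = 0, n_background_mutations = 0L)
  ref <- make_reference(cfg)
  truth <- plant_mutations(ref, cfg)
  rec <- truth$records[truth$records$is_causal, ]
  pos1 <- rec$position + 1L
  ctx_ref <- substr(ref[[rec$subgenome]], pos1 - 18L, pos1 + 18L)
  ctx_alt <- ctx_ref
  substr(ctx_alt, 19L, 19L) <- rec$alt_base
  pool <- sequence_pool(ref, truth, "wt", cfg)
  reads <- concat_reads(pool$r1, pool$r2)
  reads <- reads[grepl(sprintf("_s%d_", rec$subgenome), reads$id)]
  has <- function(p) sum(grepl(p, reads$seq, fixed = TRUE) |
                           grepl(revcomp(p), reads$seq, fixed = TRUE))
  n_ref <- has(ctx_ref)
  n_alt <- has(ctx_alt)
  # realized pool allele frequency, then binomial read sampling around it
  p_real <- sum(truth$wt_geno[truth$records$is_causal, ]) /
    (2 * cfg$n_plants_per_pool)
  n <- n_ref + n_alt
  expect_gt(n, 20)
  expect_lt(abs(n_alt / n - p_real), 3 * sqrt(p_real * (1 - p_real) / n))
  # and the realized frequency itself is consistent with 1/3
  expect_lt(abs(p_real - 1 / 3), 3 * sqrt((2 / 9) / cfg$n_plants_per_pool) / 2)
})

test_that("read generation is deterministic and validates depth", {
  cfg <- sim_config(seed = 12, subgenome_length = 5000, depth = 5)
  ref <- make_reference(cfg)
  truth <- plant_mutations(ref, cfg)
  a <- sequence_pool(ref, truth, "wt", cfg)
  b <- sequence_pool(ref, truth, "wt", cfg)
  expect_identical(a, b)
  cfg_bad <- cfg
  cfg_bad$depth <- 0
  expect_error(sequence_pool(ref, truth, "wt", cfg_bad), "depth")
})

test_that("simulated experiments round-trip through FASTA/FASTQ files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 13, subgenome_length = 5000, depth = 4,
                    n_background_mutations = 3L)
  sim <- simulate_experiment(cfg, dir)
  expect_true(all(file.exists(unlist(sim$paths))))
  ref_back <- read_fasta(sim$paths$reference)
  expect_identical(unname(ref_back), unname(sim$reference))
  r1 <- read_fastq(sim$paths$wt_1)
  expect_gt(length(r1), 0)
  expect_true(all(nchar(r1$seq) == cfg$read_length))
  truth_tsv <- read.delim(sim$paths$truth)
  expect_equal(nrow(truth_tsv), nrow(sim$truth$records))
  expect_equal(sum(truth_tsv$is_causal), 1L)
  expect_equal(truth_tsv$wt_pool_alt_freq_expected[truth_tsv$is_causal],
               1 / 3, tolerance = 1e-12)
  # the synthetic causal gene model covers the causal site
  genes <- read_fasta(sim$paths$genes)
  rec <- sim$truth$records[sim$truth$records$is_causal, ]
  ctx <- substr(sim$reference[[rec$subgenome]], rec$position - 10L, rec$position + 12L)
  expect_true(grepl(ctx, genes[[1]], fixed = TRUE))
})

test_that("FASTQ bytes are reproducible for an identical config", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 21, subgenome_length = 4000, depth = 3)
  s1 <- simulate_experiment(cfg, d1)
  s2 <- simulate_experiment(cfg, d2)
  expect_identical(readLines(s1$paths$wt_1), readLines(s2$paths$wt_1))
  expect_identical(readLines(s1$paths$mut_2), readLines(s2$paths$mut_2))
})
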