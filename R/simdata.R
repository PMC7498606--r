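#' Configuration for a synthetic allotetraploid EMS bulked-segregant experiment
#'
#' The generator emulates the experimental design the pipeline assumes: an
#' allopolyploid genome of `n_subgenomes` homoeologous subgenomes derived
#' from a common ancestor by i.i.d. per-base substitution, an EMS mutant
#' carrying one recessive causal point mutation plus unlinked background
#' mutations, and two phenotype bulks re-sequenced with 150-bp paired-end
#' reads: a mutant pool homozygous for the causal allele and a
#' phenotypically wild-type pool that is a 1 AA : 2 Aa genotype mixture
#' (expected causal-allele read fraction 1/3), as implied by a 1:3
#' recessive segregation ratio.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param subgenome_length bases per subgenome.
#' @param n_subgenomes number of homoeologous subgenomes (2 = allotetraploid).
#' @param divergence per-base substitution probability between subgenomes,
#'   in `[0, 0.2]`.
#' @param n_background_mutations unlinked EMS background sites segregating
#'   at allele frequency 0.5 in both pools.
#' @param causal_position `c(subgenome, position0)` (0-based position) or
#'   `NULL` to let the generator choose (see `require_mappable`).
#' @param require_mappable when choosing the causal position, require at
#'   least one homoeolog-diverged site within `k - 1` bases so that
#'   pool-specific k-mers spanning the causal site exist. This emulates the
#'   locus the study mapped; loci without nearby homoeolog divergence are
#'   invisible to k-mer subtraction (a limitation of the method, not of the
#'   simulator).
#' @param k k-mer length used for the mappability window (default 37).
#' @param n_plants_per_pool plants pooled per phenotype bulk.
#' @param read_length bases per read.
#' @param insert_mean,insert_sd fragment-length distribution (bases).
#' @param depth mean sequencing coverage per pool.
#' @param error_rate per-base substitution error probability.
#' @param base_quality constant Phred base quality written to FASTQ.
#' @param ems_spectrum `"ems"` restricts mutations to G>A / C>T
#'   transitions (classic EMS chemistry); `"uniform"` allows any base at any
#'   position.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       subgenome_length = 1e5,
                       n_subgenomes = 2L,
                       divergence = 0.02,
                       n_background_mutations = 30L,
                       causal_position = NULL,
                       require_mappable = TRUE,
                       k = 37L,
                       n_plants_per_pool = 25L,
                       read_length = 150L,
                       insert_mean = 350L,
                       insert_sd = 50L,
                       depth = 40,
                       error_rate = 0.001,
                       base_quality = 37L,
                       ems_spectrum = c("ems", "uniform")) {
  ems_spectrum <- match.arg(ems_spectrum)
  cfg <- list(
    seed = as.integer(seed),
    subgenome_length = as.integer(subgenome_length),
    n_subgenomes = as.integer(n_subgenomes),
    divergence = divergence,
    n_background_mutations = as.integer(n_background_mutations),
    causal_position = causal_position,
    require_mappable = isTRUE(require_mappable),
    k = as.integer(k),
    n_plants_per_pool = as.integer(n_plants_per_pool),
    read_length = as.integer(read_length),
    insert_mean = as.integer(insert_mean),
    insert_sd = as.numeric(insert_sd),
    depth = as.numeric(depth),
    error_rate = as.numeric(error_rate),
    base_quality = as.integer(base_quality),
    ems_spectrum = ems_spectrum
  )
  if (is.na(cfg$seed) || cfg$seed < 0L || cfg$seed > 2^31 - 100) {
    stop("seed must be an integer in [0, 2^31 - 100]")
  }
  if (cfg$subgenome_length < cfg$read_length) {
    stop("read_length must not exceed subgenome_length")
  }
  if (cfg$n_subgenomes < 1L) stop("n_subgenomes must be >= 1")
  if (cfg$divergence < 0 || cfg$divergence > 0.2) {
    stop("divergence must be in [0, 0.2]")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) {
    stop("error_rate must be in [0, 1)")
  }
  if (cfg$n_background_mutations < 0L) {
    stop("n_background_mutations must be >= 0")
  }
  if (!is.null(cfg$causal_position)) {
    cp <- as.integer(cfg$causal_position)
    if (length(cp) != 2L || cp[1] < 1L || cp[1] > cfg$n_subgenomes ||
        cp[2] < 0L || cp[2] >= cfg$subgenome_length) {
      stop("causal_position must be c(subgenome, position0) within bounds")
    }
    cfg$causal_position <- cp
  }
  if (cfg$n_plants_per_pool < 1L) stop("n_plants_per_pool must be >= 1")
  if (cfg$insert_mean < cfg$read_length) {
    stop("insert_mean must be >= read_length (read length exceeds fragment)")
  }
  structure(cfg, class = "sim_config")
}

#' Generate homoeologous subgenome sequences
#'
#' Subgenome 1 is drawn uniformly over `{A,C,G,T}`; every further subgenome
#' is derived from it by independent per-base substitution (to a different
#' base) with probability `divergence`. Deterministic given `config$seed`.
#'
#' @param config a [sim_config].
#' @return Named character vector `subgenome_1 ... subgenome_n`.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bases <- c("A", "C", "G", "T")
  with_seed(config$seed, {
    L <- config$subgenome_length
    anc <- sample(bases, L, replace = TRUE)
    out <- character(config$n_subgenomes)
    out[1] <- paste(anc, collapse = "")
    if (config$n_subgenomes > 1L) {
      for (s in 2:config$n_subgenomes) {
        v <- anc
        hit <- which(runif(L) < config$divergence)
        if (length(hit) > 0) {
          shift <- sample(1:3, length(hit), replace = TRUE)
          v[hit] <- bases[((match(v[hit], bases) - 1L + shift) %% 4L) + 1L]
        }
        out[s] <- paste(v, collapse = "")
      }
    }
    names(out) <- paste0("subgenome_", seq_len(config$n_subgenomes))
    out
  })
}

# 0-based positions where subgenome `s` differs from subgenome 1
homoeolog_diff_positions <- function(reference, s) {
  a <- strsplit(reference[[1]], "")[[1]]
  b <- strsplit(reference[[s]], "")[[1]]
  which(a != b) - 1L
}

#' Plant the causal and background mutations and draw pool genotypes
#'
#' All mutations are EMS-type transitions by default (G>A or C>T). The
#' causal site is homozygous alternate in every mutant-pool plant; each
#' wild-type-pool plant is AA with probability 1/3 and Aa with probability
#' 2/3 (the genotype mixture implied by 1:3 recessive segregation).
#' Background sites segregate independently at allele frequency 0.5 in both
#' pools, with no linkage. Deterministic given `config$seed`.
#'
#' @param reference output of [make_reference()].
#' @param config a [sim_config].
#' @return A `truth_table`: list with `records` (one row per mutation:
#'   `subgenome`, `position` (0-based), `ref_base`, `alt_base`, `is_causal`,
#'   `ems_consistent`, `position_adjusted`), and per-plant alternate-allele
#'   dosage matrices `wt_geno` and `mut_geno` (sites x plants).
#' @export
plant_mutations <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    L <- config$subgenome_length
    nsg <- config$n_subgenomes
    refchars <- lapply(reference, function(x) strsplit(x, "")[[1]])

    ems_ok <- function(base) base %in% c("G", "C")
    ems_alt <- function(base) ifelse(base == "G", "A", ifelse(base == "C", "T", NA))

    # --- causal site ---
    margin <- min(2L * config$read_length, floor(L / 4))
    adjusted <- FALSE
    if (!is.null(config$causal_position)) {
      causal_sg <- config$causal_position[1]
      causal_pos <- config$causal_position[2]
      if (config$ems_spectrum == "ems" &&
          !ems_ok(refchars[[causal_sg]][causal_pos + 1L])) {
        # nearest EMS-eligible base, flagged
        cand <- which(refchars[[causal_sg]] %in% c("G", "C")) - 1L
        causal_pos <- cand[which.min(abs(cand - causal_pos))]
        adjusted <- TRUE
      }
    } else {
      causal_sg <- 1L
      eligible <- (margin:(L - margin - 1L))
      if (config$ems_spectrum == "ems") {
        eligible <- eligible[refchars[[causal_sg]][eligible + 1L] %in% c("G", "C")]
      }
      if (config$require_mappable && nsg > 1L) {
        win <- config$k - 1L
        ok <- rep(TRUE, length(eligible))
        for (s in 2:nsg) {
          diffs <- homoeolog_diff_positions(reference, s)
          if (length(diffs) == 0) { ok[] <- FALSE; break }
          is_diff <- logical(L)
          is_diff[diffs + 1L] <- TRUE
          cs <- cumsum(is_diff)
          hi <- pmin(eligible + win, L - 1L) + 1L
          lo <- pmax(eligible - win, 0L)  # count over [lo, hi] 0-based
          near <- (cs[hi] - ifelse(lo > 0L, cs[lo], 0L)) > 0L
          ok <- ok & near
        }
        if (!any(ok)) {
          stop("no mappable EMS-eligible causal position available; ",
               "lower k, raise divergence, or set require_mappable = FALSE")
        }
        eligible <- eligible[ok]
      }
      if (length(eligible) == 0) stop("no eligible causal position")
      causal_pos <- eligible[sample.int(length(eligible), 1L)]
    }
    causal_ref <- refchars[[causal_sg]][causal_pos + 1L]
    if (config$ems_spectrum == "ems") {
      causal_alt <- ems_alt(causal_ref)
      if (is.na(causal_alt)) stop("causal position not mutable to an EMS transition")
    } else {
      bases <- c("A", "C", "G", "T")
      causal_alt <- sample(setdiff(bases, causal_ref), 1L)
    }

    # --- background sites, distinct positions ---
    nbg <- config$n_background_mutations
    if (nbg > 0) {
      pool_pos <- do.call(rbind, lapply(seq_len(nsg), function(s) {
        p <- seq.int(0L, L - 1L)
        if (config$ems_spectrum == "ems") p <- p[refchars[[s]][p + 1L] %in% c("G", "C")]
        cbind(s, p)
      }))
      keep <- !(pool_pos[, 1] == causal_sg & pool_pos[, 2] == causal_pos)
      pool_pos <- pool_pos[keep, , drop = FALSE]
      if (nrow(pool_pos) < nbg) stop("not enough positions for background mutations")
      sel <- pool_pos[sample.int(nrow(pool_pos), nbg), , drop = FALSE]
      bg_sg <- sel[, 1]
      bg_pos <- sel[, 2]
      bg_ref <- vapply(seq_len(nbg), function(i) refchars[[bg_sg[i]]][bg_pos[i] + 1L], character(1))
      if (config$ems_spectrum == "ems") {
        bg_alt <- ems_alt(bg_ref)
      } else {
        bases <- c("A", "C", "G", "T")
        bg_alt <- vapply(bg_ref, function(r) sample(setdiff(bases, r), 1L), character(1))
      }
    } else {
      bg_sg <- integer(0); bg_pos <- integer(0)
      bg_ref <- character(0); bg_alt <- character(0)
    }

    records <- data.frame(
      subgenome = c(causal_sg, bg_sg),
      position = c(causal_pos, bg_pos),
      ref_base = c(causal_ref, bg_ref),
      alt_base = c(causal_alt, bg_alt),
      is_causal = c(TRUE, rep(FALSE, nbg)),
      stringsAsFactors = FALSE
    )
    records$ems_consistent <- (records$ref_base == "G" & records$alt_base == "A") |
      (records$ref_base == "C" & records$alt_base == "T")
    records$position_adjusted <- c(adjusted, rep(FALSE, nbg))
    ord <- order(records$subgenome, records$position)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL

    # --- genotypes: alternate-allele dosage (0/1/2) per plant ---
    np <- config$n_plants_per_pool
    nsite <- nrow(records)
    wt_geno <- matrix(0L, nsite, np)
    mut_geno <- matrix(0L, nsite, np)
    for (i in seq_len(nsite)) {
      if (records$is_causal[i]) {
        mut_geno[i, ] <- 2L
        wt_geno[i, ] <- ifelse(runif(np) < 1 / 3, 0L, 1L)
      } else {
        wt_geno[i, ] <- rbinom(np, 2L, 0.5)
        mut_geno[i, ] <- rbinom(np, 2L, 0.5)
      }
    }
    structure(list(records = records, wt_geno = wt_geno, mut_geno = mut_geno,
                   n_plants_per_pool = np),
              class = "truth_table")
  })
}

# haplotype strings for one pool: vector indexed by (plant, copy, subgenome)
build_haplotypes <- function(reference, truth, pool) {
  geno <- if (pool == "wt") truth$wt_geno else truth$mut_geno
  np <- truth$n_plants_per_pool
  nsg <- length(reference)
  rec <- truth$records
  haps <- vector("character", np * 2L * nsg)
  dim(haps) <- c(nsg, 2L, np)
  for (p in seq_len(np)) {
    for (cp in 1:2) {
      for (s in seq_len(nsg)) {
        h <- reference[[s]]
        # dosage 1 puts the alternate allele on copy 1 (copies exchangeable)
        sites <- which(rec$subgenome == s & geno[, p] >= cp)
        for (i in sites) {
          substr(h, rec$position[i] + 1L, rec$position[i] + 1L) <- rec$alt_base[i]
        }
        haps[s, cp, p] <- h
      }
    }
  }
  haps
}

#' Draw paired-end reads for one phenotype pool
#'
#' Fragments are drawn uniformly: plant, haplotype copy and strand uniform,
#' subgenome proportional to length, fragment start uniform; fragment
#' lengths are normal (`insert_mean`, `insert_sd`) truncated to
#' `[read_length, subgenome_length]`. Each mate is `read_length` bases; per
#' base, sequencing errors substitute a uniformly chosen different base
#' with probability `error_rate`; qualities are constant `base_quality`.
#' Total bases approximate `depth` x total reference length. Deterministic
#' given `config$seed` (distinct streams per pool).
#'
#' @param reference output of [make_reference()].
#' @param truth output of [plant_mutations()].
#' @param pool `"wt"` or `"mutant"`.
#' @param config a [sim_config].
#' @return `list(r1 = read_set, r2 = read_set)`. Read names encode pool,
#'   plant, haplotype copy, subgenome and 1-based fragment coordinates, e.g.
#'   `wt_p07_c1_s2_12345_12694/1`.
#' @export
sequence_pool <- function(reference, truth, pool = c("wt", "mutant"), config) {
  pool <- match.arg(pool)
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  if (config$depth <= 0) stop("depth must be > 0")
  if (config$insert_mean < config$read_length) {
    stop("read length exceeds fragment length")
  }
  seed_off <- if (pool == "wt") 2L else 3L
  with_seed(config$seed + seed_off, {
    haps <- build_haplotypes(reference, truth, pool)
    nsg <- length(reference)
    np <- truth$n_plants_per_pool
    L <- config$subgenome_length
    rl <- config$read_length
    total_len <- nsg * L
    n_pairs <- max(1L, round(config$depth * total_len / (2 * rl)))

    sg <- sample.int(nsg, n_pairs, replace = TRUE)
    plant <- sample.int(np, n_pairs, replace = TRUE)
    copy <- sample.int(2L, n_pairs, replace = TRUE)
    frag_len <- round(rnorm(n_pairs, config$insert_mean, config$insert_sd))
    frag_len <- pmin(pmax(frag_len, rl), L)
    start <- floor(runif(n_pairs, min = 1, max = L - frag_len + 1 + 1))
    start <- pmin(start, L - frag_len + 1)
    end <- start + frag_len - 1L
    minus <- runif(n_pairs) < 0.5

    hap_idx <- (plant - 1L) * 2L * nsg + (copy - 1L) * nsg + sg
    frags <- substring(haps[hap_idx], start, end)
    head_seq <- substring(frags, 1L, rl)
    tail_seq <- cpp_revcomp(substring(frags, frag_len - rl + 1L, frag_len))
    r1 <- ifelse(minus, tail_seq, head_seq)
    r2 <- ifelse(minus, head_seq, tail_seq)
    r1 <- cpp_inject_errors(r1, config$error_rate)
    r2 <- cpp_inject_errors(r2, config$error_rate)

    qual <- strrep(rawToChar(as.raw(33L + config$base_quality)), rl)
    ids <- sprintf("%s_p%02d_c%d_s%d_%d_%d", pool, plant, copy, sg, start, end)
    list(
      r1 = read_set(paste0(ids, "/1"), r1, rep(qual, n_pairs)),
      r2 = read_set(paste0(ids, "/2"), r2, rep(qual, n_pairs))
    )
  })
}

#' Synthetic predicted-gene set covering the causal locus
#'
#' Emulates the predicted-gene database used to retain scaffolds: windows
#' sampled from the reference, one of which is guaranteed to contain the
#' causal site (the causal gene), so that a correctly assembled causal
#' scaffold survives the homology filter.
#'
#' @param reference output of [make_reference()].
#' @param truth output of [plant_mutations()].
#' @param config a [sim_config].
#' @param n_genes number of gene models.
#' @param gene_length bases per gene model.
#' @return Named character vector of gene sequences.
#' @export
simulate_gene_models <- function(reference, truth, config, n_genes = 20L,
                                 gene_length = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 4L, {
    L <- config$subgenome_length
    gene_length <- min(gene_length, L)
    rec <- truth$records
    causal <- rec[rec$is_causal, ]
    cstart <- causal$position + 1L - floor(gene_length / 2)
    cstart <- min(max(cstart, 1L), L - gene_length + 1L)
    genes <- character(n_genes)
    genes[1] <- substring(reference[[causal$subgenome]], cstart, cstart + gene_length - 1L)
    if (n_genes > 1L) {
      for (i in 2:n_genes) {
        s <- sample.int(length(reference), 1L)
        st <- sample.int(L - gene_length + 1L, 1L)
        genes[i] <- substring(reference[[s]], st, st + gene_length - 1L)
      }
    }
    names(genes) <- sprintf("gene_%03d", seq_len(n_genes))
    genes
  })
}

#' Synthetic transposable-element library
#'
#' Random sequences unrelated to the reference; in the synthetic experiment
#' the TE-removal stage is exercised as a (near) no-op, while unit tests
#' plant real TE segments into contigs.
#'
#' @param config a [sim_config].
#' @param n_te number of elements.
#' @param te_length bases per element.
#' @return Named character vector.
#' @export
simulate_te_library <- function(config, n_te = 5L, te_length = 500L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 5L, {
    out <- vapply(seq_len(n_te), function(i) {
      paste(sample(c("A", "C", "G", "T"), te_length, replace = TRUE), collapse = "")
    }, character(1))
    names(out) <- sprintf("TE_%02d", seq_len(n_te))
    out
  })
}

#' Write the truth table as TSV
#'
#' Columns: `subgenome`, `pos_1based`, `ref`, `alt`, `is_causal`,
#' `ems_consistent`, `wt_pool_alt_freq_expected`,
#' `mut_pool_alt_freq_expected`.
#'
#' @param truth a `truth_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  rec <- truth$records
  out <- data.frame(
    subgenome = rec$subgenome,
    pos_1based = rec$position + 1L,
    ref = rec$ref_base,
    alt = rec$alt_base,
    is_causal = rec$is_causal,
    ems_consistent = rec$ems_consistent,
    wt_pool_alt_freq_expected = ifelse(rec$is_causal, 1 / 3, 0.5),
    mut_pool_alt_freq_expected = ifelse(rec$is_causal, 1.0, 0.5),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a full bulked-segregant experiment to disk
#'
#' Writes the reference FASTA, paired FASTQ for both pools, the truth TSV,
#' per-plant genotype dosages, a synthetic predicted-gene FASTA and a
#' synthetic TE library.
#'
#' @param config a [sim_config].
#' @param outdir output directory (created if absent).
#' @return List with the in-memory objects (`reference`, `truth`) and all
#'   file `paths`.
#' @export
simulate_experiment <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  reference <- make_reference(config)
  truth <- plant_mutations(reference, config)
  wt <- sequence_pool(reference, truth, "wt", config)
  mut <- sequence_pool(reference, truth, "mutant", config)
  genes <- simulate_gene_models(reference, truth, config)
  te <- simulate_te_library(config)

  paths <- list(
    reference = file.path(outdir, "reference.fa"),
    wt_1 = file.path(outdir, "wt_1.fastq"),
    wt_2 = file.path(outdir, "wt_2.fastq"),
    mut_1 = file.path(outdir, "mut_1.fastq"),
    mut_2 = file.path(outdir, "mut_2.fastq"),
    truth = file.path(outdir, "truth.tsv"),
    genotypes = file.path(outdir, "genotypes.tsv"),
    genes = file.path(outdir, "genes.fa"),
    te = file.path(outdir, "te.fa")
  )
  write_fasta(reference, paths$reference)
  write_fastq(wt$r1, paths$wt_1)
  write_fastq(wt$r2, paths$wt_2)
  write_fastq(mut$r1, paths$mut_1)
  write_fastq(mut$r2, paths$mut_2)
  write_truth_tsv(truth, paths$truth)
  geno <- data.frame(
    subgenome = truth$records$subgenome,
    pos_1based = truth$records$position + 1L,
    pool = rep(c("wt", "mutant"), each = nrow(truth$records)),
    rbind(truth$wt_geno, truth$mut_geno),
    stringsAsFactors = FALSE
  )
  names(geno)[-(1:3)] <- sprintf("plant_%02d", seq_len(truth$n_plants_per_pool))
  write.table(geno, paths$genotypes, sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(genes, paths$genes)
  write_fasta(te, paths$te)

  list(config = config, reference = reference, truth = truth, paths = paths)
}
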