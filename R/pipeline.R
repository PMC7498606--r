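#' Configuration for the subtraction pipeline
#'
#' Aggregates every stage parameter of the mapping-by-sequencing workflow:
#' trimming (the study's two operator strings are the defaults), k-mer
#' subtraction (k = 37), assembly, homology/TE filtering (score > 200) and
#' mapping/zygosity thresholds.
#'
#' @param wt_fastq,mut_fastq character vectors of pool FASTQ paths (1 or 2
#'   files per pool; two files are treated as mates).
#' @param genes_fasta predicted-gene FASTA used to retain scaffolds.
#' @param te_fasta optional transposable-element FASTA.
#' @param reference_fasta optional reference FASTA (enables the SNP-index
#'   comparison stages).
#' @param outdir output directory for all stage intermediates.
#' @param trim_spec_wt,trim_spec_mut trimming operator strings per pool.
#' @param k subtraction k-mer length.
#' @param min_count minimum k-mer count in the WT pool.
#' @param k_asm,cov_cutoff,tip_max_len assembler parameters.
#' @param min_score scaffold retention/removal score threshold.
#' @param max_mismatches ungapped mapping mismatch budget.
#' @param min_depth,het_band,hom_min zygosity-classification thresholds.
#' @param seed integer seed recorded in the report.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(wt_fastq, mut_fastq, genes_fasta, te_fasta = NULL,
                            reference_fasta = NULL, outdir,
                            trim_spec_wt = "HEADCROP:1 SLIDINGWINDOW:4:20 LEADING:20 TRAILING:20 MINLEN:40",
                            trim_spec_mut = "SLIDINGWINDOW:10:20 LEADING:15 TRAILING:10 MINLEN:40",
                            k = 37L, min_count = 2L, k_asm = 31L,
                            cov_cutoff = 2L, tip_max_len = 2L * k_asm,
                            min_score = 200, max_mismatches = 1L,
                            min_depth = 10L, het_band = c(0.10, 0.80),
                            hom_min = 0.90, seed = 1L) {
  cfg <- list(
    wt_fastq = as.character(wt_fastq), mut_fastq = as.character(mut_fastq),
    genes_fasta = genes_fasta, te_fasta = te_fasta,
    reference_fasta = reference_fasta, outdir = outdir,
    trim_spec_wt = trim_spec_wt, trim_spec_mut = trim_spec_mut,
    k = as.integer(k), min_count = as.integer(min_count),
    k_asm = as.integer(k_asm), cov_cutoff = as.integer(cov_cutoff),
    tip_max_len = as.integer(tip_max_len), min_score = min_score,
    max_mismatches = as.integer(max_mismatches),
    min_depth = as.integer(min_depth), het_band = as.numeric(het_band),
    hom_min = hom_min, seed = as.integer(seed)
  )
  for (f in c(cfg$wt_fastq, cfg$mut_fastq, cfg$genes_fasta, cfg$te_fasta,
              cfg$reference_fasta)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  if (length(cfg$wt_fastq) < 1 || length(cfg$mut_fastq) < 1) {
    stop("each pool needs at least one FASTQ")
  }
  trim_spec(cfg$trim_spec_wt)
  trim_spec(cfg$trim_spec_mut)
  structure(cfg, class = "pipeline_config")
}

read_pool <- function(paths) {
  r1 <- read_fastq(paths[1])
  r2 <- if (length(paths) >= 2) read_fastq(paths[2]) else NULL
  list(r1 = r1, r2 = r2)
}

stage <- function(name, expr) {
  message(sprintf("[ksubmap] stage %s", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full subtraction workflow
#'
#' Executes trim -> k-mer subtraction -> read recruitment -> assembly ->
#' gene-homology filter -> TE removal -> ungapped mapping and zygosity
#' classification, writing every stage intermediate into
#' `config$outdir` and returning a mapping report. Candidate sites are
#' ranked by mutant-pool alternate frequency (descending), then by
#' closeness of the WT-pool frequency to 1/3 (the expectation under 1 AA :
#' 2 Aa segregation). An empty candidate list is a valid outcome, not an
#' error. Fully deterministic given the config.
#'
#' @param config a [pipeline_config].
#' @return A `mapping_report`: list with `config`, per-stage `tallies`,
#'   `contigs` (retained), `sites` (all tested), `candidates` (ranked) and
#'   an EMS-consistency summary.
#' @export
run_subtraction_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  od <- function(...) file.path(config$outdir, ...)

  wt <- stage("read_input", read_pool(config$wt_fastq))
  mut <- stage("read_input", read_pool(config$mut_fastq))
  n_wt_in <- length(wt$r1) + ifelse(is.null(wt$r2), 0L, length(wt$r2))
  n_mut_in <- length(mut$r1) + ifelse(is.null(mut$r2), 0L, length(mut$r2))

  wt_trim <- stage("trim_wt", apply_trim(wt$r1, wt$r2, config$trim_spec_wt))
  mut_trim <- stage("trim_mut", apply_trim(mut$r1, mut$r2, config$trim_spec_mut))
  wt_reads <- concat_reads(wt_trim$r1, if (!is.null(wt_trim$r2)) wt_trim$r2,
                           wt_trim$singletons)
  mut_reads <- concat_reads(mut_trim$r1, if (!is.null(mut_trim$r2)) mut_trim$r2,
                            mut_trim$singletons)
  write_fastq(wt_reads, od("wt_trimmed.fastq"))
  write_fastq(mut_reads, od("mut_trimmed.fastq"))

  wt_cat <- stage("catalog_wt", build_catalog(wt_reads, config$k, "wt"))
  mut_cat <- stage("catalog_mut", build_catalog(mut_reads, config$k, "mutant"))
  specific <- stage("subtract",
                    subtract_catalogs(wt_cat, mut_cat, config$min_count))
  write_kmer_tsv(specific, od("wt_specific_kmers.tsv"))

  recruited <- stage("recruit", recruit_reads(wt_reads, specific))
  write_fastq(recruited, od("recruited.fastq"))

  contigs <- stage("assemble",
                   assemble_reads(recruited, config$k_asm, config$cov_cutoff,
                                  config$tip_max_len))
  write_contigs_fasta(contigs, od("contigs_raw.fa"))

  kept <- stage("filter_genes",
                filter_scaffolds(contigs, config$genes_fasta, config$min_score))
  kept <- stage("remove_te",
                if (!is.null(config$te_fasta)) {
                  remove_te_like(kept, config$te_fasta, config$min_score)
                } else kept)
  write_contigs_fasta(kept, od("contigs_retained.fa"))

  sites <- stage("callsites", {
    if (nrow(kept) > 0) {
      call_sites(kept, wt_reads, mut_reads, config$min_depth, config$het_band,
                 config$hom_min, config$max_mismatches)
    } else {
      call_sites(character(0), wt_reads[integer(0)], mut_reads[integer(0)])
    }
  })
  write_sites_tsv(sites, od("sites.tsv"))

  cand <- sites[sites$classification == "candidate", , drop = FALSE]
  if (nrow(cand) > 0) {
    cand <- cand[order(-cand$mut_alt_freq, abs(cand$wt_alt_freq - 1 / 3)), ,
                 drop = FALSE]
    rownames(cand) <- NULL
  }

  tallies <- c(
    reads_in_wt = n_wt_in, reads_in_mut = n_mut_in,
    reads_trimmed_wt = length(wt_reads), reads_trimmed_mut = length(mut_reads),
    kmers_wt = length(wt_cat$kmer), kmers_mut = length(mut_cat$kmer),
    kmers_specific = length(specific$kmer),
    reads_recruited = length(recruited),
    contigs_assembled = nrow(contigs),
    contigs_retained = nrow(kept),
    sites_tested = nrow(sites),
    candidates = nrow(cand)
  )
  report <- structure(list(
    config = unclass(config),
    tallies = tallies,
    contigs = kept,
    sites = sites,
    candidates = cand,
    ems_summary = c(
      candidates_ems_consistent = if (nrow(cand) > 0) sum(cand$ems_consistent) else 0L,
      candidates_total = nrow(cand)
    )
  ), class = "mapping_report")
  write_report_json(report, od("report.json"))
  report
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("<mapping_report>\n")
  for (n in names(x$tallies)) cat(sprintf("  %-22s %s\n", n, x$tallies[[n]]))
  if (nrow(x$candidates) > 0) {
    cat("  top candidate:", x$candidates$contig[1], "pos",
        x$candidates$pos_1based[1], x$candidates$ref[1], ">",
        x$candidates$alt[1], "\n")
  } else {
    cat("  no candidate sites\n")
  }
  invisible(x)
}

#' Serialize a mapping report to JSON
#'
#' Byte-identical for identical configs: no timestamps or environment
#' state.
#'
#' @param report a `mapping_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- list(
    config = report$config[!vapply(report$config, is.null, logical(1))],
    tallies = as.list(report$tallies),
    candidates = report$candidates,
    ems_summary = as.list(report$ems_summary)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Locate candidate sites on the simulated reference and truth table
#'
#' Maps each candidate-bearing contig back to the reference (ungapped,
#' small mismatch budget) to convert contig coordinates into genome
#' coordinates, then marks which candidates coincide with the planted
#' causal site.
#'
#' @param report a `mapping_report`.
#' @param reference named character vector of subgenome sequences.
#' @param truth a `truth_table`.
#' @param max_mismatches placement budget for contigs (default 4 tolerates
#'   residual assembly errors).
#' @return `report` with `candidates` gaining `subgenome`, `genome_pos_1based`
#'   and `is_causal` columns.
#' @export
annotate_candidates <- function(report, reference, truth, max_mismatches = 4L) {
  cand <- report$candidates
  if (nrow(cand) == 0) {
    cand$subgenome <- integer(0)
    cand$genome_pos_1based <- integer(0)
    cand$is_causal <- logical(0)
    report$candidates <- cand
    return(report)
  }
  ctg <- report$contigs
  placements <- map_reads(ctg$sequence, reference, max_mismatches)
  sg_idx <- match(placements$contig, names(reference))
  cand$subgenome <- NA_integer_
  cand$genome_pos_1based <- NA_integer_
  for (i in seq_len(nrow(cand))) {
    j <- match(cand$contig[i], ctg$id)
    if (is.na(j) || placements$status[j] != "mapped") next
    cand$subgenome[i] <- sg_idx[j]
    if (placements$strand[j] > 0) {
      cand$genome_pos_1based[i] <- placements$start0[j] + cand$pos_1based[i]
    } else {
      cand$genome_pos_1based[i] <- placements$start0[j] + ctg$length[j] -
        cand$pos_1based[i] + 1L
    }
  }
  rec <- truth$records
  causal <- rec[rec$is_causal, ]
  cand$is_causal <- !is.na(cand$subgenome) &
    cand$subgenome == causal$subgenome &
    cand$genome_pos_1based == causal$position + 1L
  report$candidates <- cand
  report
}

#' Simulate an experiment and run the pipeline on it
#'
#' Convenience wrapper used for validation: generates a synthetic
#' bulked-segregant experiment, runs the subtraction pipeline on its
#' FASTQs with the synthetic gene/TE databases, and annotates candidates
#' against the truth table.
#'
#' @param config a [sim_config].
#' @param outdir working directory for simulated inputs and pipeline
#'   outputs.
#' @param ... overrides passed to [pipeline_config()].
#' @return The annotated `mapping_report`, with the simulation attached as
#'   attribute `simulation`.
#' @export
run_synthetic_pipeline <- function(config, outdir, ...) {
  sim <- simulate_experiment(config, file.path(outdir, "sim"))
  pcfg <- pipeline_config(
    wt_fastq = c(sim$paths$wt_1, sim$paths$wt_2),
    mut_fastq = c(sim$paths$mut_1, sim$paths$mut_2),
    genes_fasta = sim$paths$genes,
    te_fasta = sim$paths$te,
    reference_fasta = sim$paths$reference,
    outdir = file.path(outdir, "pipeline"),
    seed = config$seed,
    ...
  )
  report <- run_subtraction_pipeline(pcfg)
  report <- annotate_candidates(report, sim$reference, sim$truth)
  attr(report, "simulation") <- sim
  report
}

#' Segregation chi-squared test
#'
#' Goodness of fit of observed mutant/wild-type plant counts to an expected
#' segregation ratio (default 1 mutant : 3 wild type, the recessive
#' single-gene expectation).
#'
#' @param n_mutant,n_wt observed plant counts.
#' @param ratio expected `c(mutant, wt)` ratio weights.
#' @return List: `chi2`, `df` (= 1), `p`.
#' @export
segregation_chi2 <- function(n_mutant, n_wt, ratio = c(1, 3)) {
  if (n_mutant + n_wt <= 0) stop("total count must be > 0")
  stopifnot(length(ratio) == 2, all(ratio > 0))
  ht <- suppressWarnings(
    chisq.test(c(n_mutant, n_wt), p = ratio / sum(ratio))
  )
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
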