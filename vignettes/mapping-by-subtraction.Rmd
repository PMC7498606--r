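---
title: "Mapping an EMS mutation by pool-specific k-mer subtraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping an EMS mutation by pool-specific k-mer subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulked segregant analysis maps a recessive mutation by sequencing two
pools of segregating plants — one with the mutant phenotype, one without —
and looking for the locus where the pools' allele frequencies differ in a
characteristic way. For a recessive single-gene mutation segregating 1:3,
every mutant-pool plant is homozygous for the mutant allele, while the
phenotypically wild-type pool is a 1 AA : 2 Aa genotype mixture, so the
expected mutant-allele read fraction is 1 at the causal site in the mutant
pool and 1/3 in the WT pool. Background EMS mutations, unlinked to the
phenotype, sit near frequency 0.5 in both pools and carry no contrast.

In an allotetraploid with a draft-quality reference, the standard
alignment-first approach (MutMap-style SNP-index scanning) can fail:
homoeologous subgenomes cross-map, and mis-assemblies break the
frequency signal. `ksubmap` implements the alignment-free alternative:

1. quality-trim both pools (`SLIDINGWINDOW` / `LEADING` / `TRAILING` /
   `MINLEN` / `HEADCROP` / adapter clipping operators);
2. count canonical 37-mers per pool and keep those present at least
   `min_count` times in the WT pool and **absent** from the mutant pool —
   at the causal site the mutant pool has lost the wild-type allele, so
   WT-allele k-mers spanning it are pool-specific;
3. recruit the reads containing those k-mers and assemble them with a
   small de Bruijn assembler into candidate scaffolds;
4. retain scaffolds homologous to a predicted-gene set (affine local
   alignment, raw score strictly greater than 200) and discard
   transposable-element-like scaffolds;
5. map both pools back to the retained scaffolds (ungapped, at most one
   mismatch, unique best placement) and call sites where the WT pool is
   heterozygous and the mutant pool homozygous for the alternate allele.

A MutMap-style route is also provided for when a reference is usable:
build a mutant-pool consensus by replacing reference bases whose SNP index
exceeds 0.9, then compute the WT pool's SNP index at each replaced site;
the causal site is the one near 1/3. Finally, an RNA-seq screening step
(low-count filter at 40 total reads, concordant two-fold selection across
two mutant alleles, TPM conversion, intersection with an external
bladder-cell expression table) reproduces the downstream expression
arithmetic, and `segregation_chi2()` is the 1:3 segregation test.

## Why k = 37 works, and when it cannot

A WT-allele k-mer spanning the causal site is pool-specific only if it is
absent from the mutant pool, whose genomes still contain the intact
homoeologous subgenome. With i.i.d. per-base divergence $d$ between
subgenomes, a given 37-mer window is identical across homoeologs with
probability $(1-d)^{37}$ (at $d = 0.02$, about 0.47), and *no* specific
window spanning the causal site exists unless at least one diverged site
lies within $k - 1 = 36$ bases of it. Under uniform placement that failure
has probability $(1-d)^{2(k-1)} \approx 0.23$: roughly a quarter of
allotetraploid loci are blind to 37-mer subtraction at 2% divergence. This
is a property of the method, not of any implementation. The synthetic
generator therefore defaults to `require_mappable = TRUE`: the causal site
is placed (seed-deterministically) at an EMS-eligible position with at
least one homoeolog-diverged site within 36 bp, emulating a locus the
method can map — as the study's locus necessarily was. Setting
`require_mappable = FALSE` restores uniform placement for studying the
blind fraction itself.

## What the generator emulates — and what it does not

`sim_config()` defaults describe the experiment the pipeline assumes:
2 homoeologous subgenomes of 100 kb derived by 2% i.i.d. substitution,
one causal EMS transition (G>A or C>T) plus 30 background EMS sites,
pools of 25 plants each, 150-bp paired-end reads at 40x per pool, normal
fragment lengths (350 +/- 50 bp), 0.1% uniform per-base substitution
errors, constant Q37 base qualities. Genotypes: mutant pool homozygous
alternate at the causal site; WT pool AA with probability 1/3 and Aa with
2/3; background sites drawn independently per plant at allele frequency
0.5 with no linkage.

Deliberately not modelled: recombination and linkage (the mapping logic
needs only the causal-site contrast), indels and structural variants,
position- or context-dependent error and quality profiles, adapter
read-through, contamination, and non-uniform subgenome divergence. Passing
tests on this generator therefore demonstrate the pipeline's logic and its
statistical behaviour under the stated design, not robustness to the full
error structure of real instruments, nor performance at genome scale. For
the same reason the study's own funnel counts (6555 recruited reads, 983
scaffolds, 14 retained, one 196-bp scaffold) are not reproduction targets:
they depend on genome-scale data and external tool versions.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `k` (subtraction) | 37 | the study's k; long enough to be near-unique in a diploid-sized genome, short enough that divergence windows exist |
| `min_count` | 2 | a k-mer seen once in the WT pool is as likely a sequencing error as a variant; absence from the mutant pool stays strict (0) |
| `k_asm` | 31 | odd (no reverse-palindromic nodes), below read length, standard short-read choice |
| `cov_cutoff` | 2 | removes error k-mers from the graph; use 1 for error-free reads, where the cutoff would only truncate coverage-1 contig ends |
| `tip_max_len` | `2 * k_asm` | dead-end paths shorter than two node-lengths are clipped as spurs |
| scoring | +2 / -3, gap 5 + 2L | classic nucleotide scheme; an exact match scores 2/base, so "score > 200" means "more than 100 identical bases' worth of alignment" |
| `max_mismatches` | 1 | the study's one-mismatch alignment setting |
| `min_depth` | 10 | below ~10 reads a pool frequency is too noisy to classify |
| `het_band` | [0.10, 0.80] | see below |
| `hom_min` | 0.90 | homozygous mutant pool, allowing ~10% error/dilution |
| SNP-index consensus | index > 0.9, strict | the consensus-replacement rule |

**The het band's lower edge.** The WT pool's expected mutant-allele
fraction at the causal site is 1/3, but mapping with a one-mismatch budget
against the WT-allele scaffold is reference-biased: a mutant-allele read
spends its whole budget on the allele itself, so any sequencing error
unmaps it, while a reference-allele read tolerates one error. At 0.1%
error over 150 bp the retention ratio is $P(0\ \mathrm{err})/P(\le 1\
\mathrm{err}) \approx 0.87$, deflating the expected observed fraction to
about 0.29; read sampling at 40x plus 25-plant genotype sampling give it a
standard deviation near 0.08. The band floor is set to 0.10 — roughly
three of those standard deviations below the deflated expectation — so a
true heterozygous bulk is essentially never rejected. The floor does not
create false positives: unlinked background sites sit near 0.5 in *both*
pools and are rejected by the mutant pool's homozygosity requirement, not
by the band.

## Numerical and design choices

- **Canonical k-mers** (lexicographic minimum of a window and its reverse
  complement) are used throughout, since reads come from both strands.
  N-containing windows are skipped entirely.
- **Sliding-window trimming** scans only complete windows: the read keeps
  the prefix before the first full `w`-base window whose mean quality
  falls below the threshold, and reads shorter than `w` pass unchanged.
  Scanning truncated windows at the read end would make the operator
  non-idempotent (a shortened tail re-forms shorter, lower-mean windows),
  and idempotence is asserted by the test suite.
- **Pair handling**: a pair survives `MINLEN` only if both mates do; a
  lone survivor moves to a singleton stream, which the k-mer stages accept.
- **Assembler determinism**: nodes are visited in ascending 2-bit packed
  order, each unitig is emitted once as the lexicographic minimum of the
  path and its reverse complement, and contigs are reported longest-first.
  Tips are clipped iteratively (a unitig with exactly one dead end and
  fewer than `tip_max_len` bases); isolated short contigs are not tips and
  are kept. No bubble popping and no paired-end scaffolding.
- **Gap convention**: a gap of length $L$ costs $5 + 2L$ (open 5, extend
  2), i.e. the first gapped base costs 7. Both query strands are
  evaluated; ties prefer the plus strand.
- **Mapping** is exact, not heuristic: pigeonhole seeding (one exact
  16-mer seed per mismatch-budget segment) finds every placement within
  the budget, with a full scan fallback for reads shorter than
  16 x (budget + 1). A tie in mismatch count between distinct loci makes
  the read ambiguous, and ambiguous reads are discarded rather than placed
  randomly — determinism over sensitivity. Alignments must lie fully
  within a contig; near contig ends this costs depth, and the `min_depth`
  guard can report `low_depth` for causal sites on short scaffolds
  (observed on a minority of simulated seeds) rather than risk a call from
  a handful of reads.
- **Coordinates** are 0-based half-open internally; every report is
  1-based inclusive. Minus-strand subject spans are reported with
  `sstart > send`, BLAST-style.
- **Candidate ranking** (mutant alternate frequency descending, then
  closeness of the WT frequency to 1/3) is this package's choice; the
  study inspected a single surviving scaffold manually.
- **Fold changes** are computed on counts-per-million by default (raw
  mode available); a zero WT count yields an infinite ratio, which counts
  as exceeding the two-fold threshold, and 0/0 is non-evaluable. "Expressed
  in bladder cells" means external TPM >= 1; genes absent from the external
  table are flagged unknown rather than unexpressed.
- **Problem sizes.** The validation suite runs the full default experiment
  (2 x 100 kb, 40x pools) across 10 seeds, the assembler reconstruction
  study on 50 sources of 1-5 kb, and oracle-equivalence checks on
  100-1000 random instances per operator; these sizes give the binomial
  checks 3-sigma resolution while keeping a complete run on a single CPU
  in minutes.

## Known limitations

- The k-mer subtraction is blind to causal sites without nearby homoeolog
  divergence (about a quarter of loci at 2% divergence; see above) and to
  any mutation type other than substitutions.
- Ungapped one-mismatch mapping cannot place reads over indels and is
  reference-biased, as quantified above.
- The assembler reproduces the role of the study's assembler, not its
  scaffold counts; repeat structures and heterozygous bubbles are out of
  scope.
- The expression screen deliberately performs thresholding, not
  statistical testing: it has no replicate-variance model, mirroring the
  original selection procedure.
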