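---
title: "Genetic-code-aware gene calling for phage genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-code-aware gene calling for phage genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecode)
```

## The problem

Some bacteriophage lineages repurpose a stop codon to encode an amino
acid: TAG (*amber*) read as glutamine corresponds to NCBI translation
table 15, TGA (*opal*) read as tryptophan to table 4.  A gene caller
that assumes the standard prokaryotic code (table 11) truncates every
gene of such a genome at the first in-frame reassigned codon.  The
symptom is an annotation with an unusually low coding density (around
70% of nucleotides in genes, against roughly 90% for phages annotated
with their true code), many short genes, and a high fraction of
products that cannot be assigned a function.  phagecode detects this
situation *before* annotation: it evaluates candidate genetic codes on
the genome, selects the one the evidence supports, and quantifies how
much the code-aware annotation improves on the standard one.

All coordinates in memory are 0-based half-open; all coordinates in
files (GFF3, TSV reports) are 1-based inclusive.  That rule is stated
once here and tested at the IO boundary.

## Candidate genetic codes

`genetic_code()` serves tables 11, 4 and 15 plus a generic
`"tag-unknown"` variant (TAG read as `X`) for lineages where the
reassigned amino acid is not known; the generic variant is not in the
default candidate set.  Start codons are ATG, GTG and TTG for every
code.  Codons containing IUPAC ambiguity codes translate to `X` and are
never treated as stops, so assembly ambiguity cannot truncate a gene.

## ORF engine

`find_orfs()` scans all six frames and reports one maximal ORF per
stop-to-stop interval: from the first in-frame start codon to and
including the terminal stop.  Stop-free runs touching the contig edge
are reported as partials — the 5' run is anchored at the edge (the gene
may continue off the fragment), while the 3' run still requires a start
codon, since a gene there must have started inside the contig.
Relaxing the stop set (table 11 → 15 or 4) can only merge or extend
stop-to-stop intervals, never split them, so every table-11 ORF lies
inside exactly one same-frame ORF of the relaxed code.  This
containment law is enforced by property tests.

## Self-trained coding model and gene selection

The coding-potential model is a hexamer (dicodon) log-odds table in the
Prodigal tradition, trained on the genome being annotated:

* coding counts from the in-frame hexamer walk (step 3) of all ORFs of
  at least `seed_min_len_nt` (default 300 nt);
* background counts from every overlapping hexamer of the contig and
  its reverse complement;
* add-one pseudocounts on both sides; scores in log base 2, so gene
  scores are in bits.

A gene's score is its hexamer sum minus a flat per-gene penalty
(default 6 bits).  The penalty is the filtering knob: it is calibrated
so that random 90-nt ORFs score negative under a trained model, and
raising it emulates a stricter ORF filter.  Contigs shorter than 2 kb
fall back to a uniform model (all log-odds zero) with a warning — under
that model every candidate scores exactly minus the penalty and no
genes are called, which we prefer to confident nonsense on fragments.

Selection is weighted interval scheduling: among positive-scoring
candidates, the subset maximizing total score subject to a pairwise
overlap of at most `max_overlap_nt` (default 30 nt, enough for common
stop/start overlaps) is found by dynamic programming; score ties
resolve toward more genes, then earlier coordinates.  Two training
passes are run by default; the second re-estimates the model from the
first pass's selected genes.

One design decision was revised during development.  A first version
gave the DP exactly one candidate per stop-to-stop interval (the
first-start ORF).  Under a relaxed code the interval often reaches deep
into the upstream gene, and that single candidate then overlaps its
neighbour by hundreds of nucleotides: the DP had to drop whole true
genes, and called coding capacity on reassigned genomes saturated
around 77% against a 91% truth.  `call_genes()` therefore expands each
ORF into one candidate per plausible in-frame start codon, all sharing
the ORF's stop and scored by suffix sums of the same hexamer walk.
Variants of one interval overlap each other by at least `min_len_nt`,
so the DP can select at most one of them — the interval structure is
preserved, but the selection may now shorten a gene instead of dropping
it.  With this change called capacity tracks truth within a few points
under the correct code.

## Predicting the genetic code

`select_code()` evaluates each candidate with `evaluate_code()` (a full
gene-calling run plus summary) and applies a conservative three-part
rule for choosing an alternative code `c` over table 11:

1. coding-density gain `density(c) − density(11) ≥ δ` points
   (default `δ = 5`);
2. median gene-length ratio `median_len(c) / median_len(11) ≥ ρ`
   (default `ρ = 1.2`);
3. at least `f` of the genes called under `c` contain the reassigned
   codon in frame (default `f = 0.33`).

The defaults sit well inside the ~70% vs ~90% diagnostic gap that
motivates the method: a genuine reassignment shows density gains of 15
points or more on synthetic genomes, while a table-11 genome evaluated
under a relaxed code gains at most a few points (read-through past true
TAG/TGA stops into short intergenic gaps).  All ties and sub-threshold
gains resolve to table 11 — the safe error mode, since mis-predicting
an alternative code harms annotation far more than missing one.
Predictions of table 4 carry a host-context note rather than a
computation: *Mycoplasma* and *Spiroplasma* hosts natively use table 4,
so a table-4 phage may simply share its host's code; host inference is
out of scope.

## Suppressor tRNA detection

Reassignment is often accompanied by a suppressor tRNA whose anticodon
pairs with the repurposed stop (Sup-CTA reading amber TAG, Sup-TCA
reading opal TGA).  `find_trnas()` is a geometric cloverleaf heuristic,
not a covariance model: windows of 60–100 nt on both strands must show

* an acceptor stem of 7 pairs between the window ends (≥ 5 of 7 paired,
  Watson–Crick or GU);
* a D-arm stem (≥ 3 of 4 pairs) and an anticodon-arm stem (≥ 4 of 5
  pairs flanking a 7-nt loop), the anticodon arm searched 22–38 nt from
  the window 5' end and the other arms at canonical offsets from it;
* a T-arm stem (≥ 4 of 5 pairs) whose loop opens with the canonical TTC
  (TΨC) motif.

The structure score is the total number of paired positions over the
four stems (maximum 21); hits require a score of at least 16 (default)
and are deduplicated by coordinate overlap, keeping the higher score.
Stem complementarity alone arises constantly by chance in a 30-kb
genome — the TTC motif requirement is what keeps the false-positive
rate at the level the tests enforce (no hits in shuffled 80-mers at the
default threshold, a handful of sense-anticodon hits per 30-kb genome).
Geometry note: all four arms only fit in windows of 68 nt and larger,
so the lower end of the window range never fires.  The anticodon is
reported in the DNA alphabet (CTA, not CUA), and
`classify_suppressor()` maps it to amber/opal/ochre via its reverse
complement.  `verify_trna_hit()` re-checks any reported hit against
these rules independently of the scanner, and the test suite runs it on
every hit.

## Annotation metrics and paired comparison

`genome_metrics()` computes the per-genome quantities used to judge an
annotation: gene count, median gene length, coding capacity (percentage
of nucleotides covered by the *union* of gene intervals — overlaps
counted once, so 100% is a hard ceiling), genes per kb, and optionally
the percentage of genes labelled hypothetical.  Dataset-level gene
length is summarized as the median of per-genome medians.
`compare_strategies()` pairs the same genomes under two annotation
strategies, runs a two-sided paired t test per metric (differences
taken as B − A), and adjusts across the family of metric tests with the
Benjamini–Hochberg step-up procedure.  Degenerate metrics (identical
values under both strategies) are reported with NA test columns rather
than an error.  Percentages are reported at one decimal, rounded half
away from zero — base R's round-half-even would turn 72.95…% into 72.9
rather than 73.0, which does not match how such improvements are
conventionally printed.

## The synthetic genome generator

`generate_genome()` is the test bed for everything else, so its
defaults are the study conditions, chosen once: 45 genes of lognormal
length (median 550 nt, sigma 0.45, minimum 120 nt), geometric
intergenic gaps of mean 60 nt — together about 30 kb at about 91% true
coding density, matching cultured-phage statistics; GC 45%; 30% of
genes on the minus strand; reassigned-codon rate `q = 0.3` (each
glutamine position of a table-15 gene, or tryptophan position of a
table-4 gene, independently uses the reassigned stop codon with
probability 0.3).

Codons are sampled from a usage table built as a base-composition prior
times a fixed per-codon bias (the bias is what gives the hexamer model
its signal), with glutamine and tryptophan codons boosted so that
reassignment-eligible positions are plentiful, then exponentially
tilted so the expected GC of coding sequence hits the target exactly.
Every gene starts with ATG/GTG/TTG (0.8/0.15/0.05) and ends with a stop
codon of the true code.  The generator is a deterministic function of
its config, including the seed.

What the generator does *not* emulate: real codon usage of any taxon,
ribosome-binding sites, promoters and terminators, gene synteny,
overlapping genes, mosaic genomes mixing codes, and sequencing error.
Passing tests therefore demonstrate that the method recovers
reassignment from coding statistics under controlled conditions — not
that it reproduces any published prevalence on real catalogues, which
depend on external databases and detectors out of scope here.

`embed_trna()` inserts a 76-nt canonical cloverleaf cassette (built to
satisfy the detector's stem rules perfectly, score 21) into an
intergenic gap, preferring a gap of at least 96 nt, falling back to the
widest gap, and appending past the last gene on the rare genome without
any wide gap.

## Problem sizes and numerical choices

The test suite validates code recovery on three cohorts of 100 synthetic
genomes (~30 kb, `q = 0.3`, seeds 1–100; true codes 11, 4 and 15,
requiring at least 95 correct predictions each), the paired
improvement statistics on the table-15 cohort (median length ratio,
capacity gain, BH-adjusted paired-t p values), oracle equivalence of
the DP against exhaustive subset search on 200 small instances, of the
ORF engine against a naive scanner, of coding capacity against per-base
masks and of BH against the step-up definition, plus the tRNA fixture
and false-positive checks.  `scripts/acceptance.R` recomputes the same
quantities on 25-genome cohorts per code, a size chosen to keep the
script around a minute of CPU.

Tie-breaks and degenerate inputs are pinned down deterministically
throughout: ORF output order is by start, end, strand; DP ties prefer
more genes, then earlier coordinates; tRNA deduplication prefers higher
score, then leftmost; empty annotations report zero metrics with a
warning rather than NA; `paired_t_test()` raises a degenerate-input
error for n < 2 or constant differences, which `compare_strategies()`
converts to NA rows.

## Limitations

The coding model is an order-0 hexamer model without start-context or
RBS scoring, so predicted start codons are approximate even when stops
are exact; gene-level comparisons in this package key on stop
coordinates.  The code selector assumes one code per genome (no
MgCod-style mosaics).  The tRNA detector is a geometric heuristic and
is validated against generator-built cassettes, not against tRNA
databases; its counts on real genomes should not be compared with
covariance-model annotators.  Genomes are treated as linear; ORFs
spanning the origin of a circular genome are not joined.
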