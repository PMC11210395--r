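# phagecode

Genetic-code-aware gene calling and stop-codon reassignment detection
for bacteriophage genomes.

## The problem

Some phage lineages repurpose a stop codon to encode an amino acid:
TAG (*amber*) read as glutamine is NCBI translation table 15, TGA
(*opal*) read as tryptophan is table 4.  Annotating such a genome with
the standard prokaryotic code (table 11) truncates every gene at its
first in-frame reassigned codon.  The signature is an annotation with
coding density around 70% instead of the ~90% typical of phages, short
median gene lengths, and a large fraction of "hypothetical" products.

phagecode is for people annotating phage genomes and virome contigs who
want to catch this *before* annotation.  It provides:

* `genetic_code()` — translation tables 11, 4, 15 and a generic
  TAG-reassigned variant;
* `find_orfs()` — six-frame maximal ORFs under any of these codes;
* `call_genes()` — a self-training hexamer gene caller: log2-odds
  dicodon scores `s(g) = Σ log2 f_cod(h) / f_bg(h) − λ` over the
  in-frame hexamer walk (penalty λ = 6 bits), with a
  weighted-interval-scheduling DP choosing a maximum-score gene set
  with pairwise overlap ≤ 30 nt, one candidate per in-frame start;
* `select_code()` — the code predictor: choose code *c* ≠ 11 iff
  density(*c*) − density(11) ≥ δ (5 points) **and**
  median_len(*c*)/median_len(11) ≥ ρ (1.2) **and** the reassigned codon
  appears in-frame in ≥ f (33%) of the genes called under *c*;
* `find_trnas()` / `classify_suppressor()` — a cloverleaf heuristic for
  amber/opal/ochre suppressor tRNAs (Sup-CTA, Sup-TCA anticodons);
* `genome_metrics()` / `compare_strategies()` — coding capacity
  (union-based, % of genome), median gene length, genes/kb,
  hypothetical fraction, with paired t tests and Benjamini–Hochberg
  adjustment across metrics;
* `generate_genome()` — a synthetic phage-genome generator with known
  genes, known code, tunable reassigned-codon usage and an optional
  embedded suppressor-tRNA cassette, used as ground truth throughout
  the test suite;
* a command-line interface (`inst/exec/phagecode`) with subcommands
  `simulate | call | select-code | trna-scan | metrics | compare`.

## Worked example

Simulate a 30-kb table-15 phage genome and ask phagecode which genetic
code it uses:

```r
library(phagecode)

ts <- generate_genome(generator_config(seed = 42, code_id = 15))
ts
#> <truth_set synth_seed42: 30455 nt, 45 genes, code 15>

select_code(ts$seq)
#> <code_prediction: table 15>
#>  code_id n_genes coding_density_pct median_gene_len_nt genes_per_kb
#>       11      31              22.45              159.0        1.018
#>        4      42              43.47              321.0        1.379
#>       15      46              92.17              529.5        1.510
#>  total_score_bits reassigned_usage_fraction
#>              1114                    0.0000
#>              1692                    0.6190
#>              7475                    0.9565
#> rationale: table 15 chosen: coding density 92.2% vs 22.4% under table 11
#> (gain 69.7 points), median gene length ratio 3.33, reassigned codon used
#> in 96% of genes
```

Under table 11 the caller recovers only short truncated fragments
(median 159 nt, 22% coding density); under the true code it recovers
essentially the whole gene complement (median 529 nt, 92% density) and
nearly every called gene contains an in-frame TAG read as glutamine —
the three signals the decision rule requires.

A genome carrying an amber-suppressor tRNA:

```r
ts2 <- generate_genome(generator_config(seed = 42, n_genes = 12,
                                        embed_trna = "CTA"))
hits <- find_trnas(ts2$seq)
hits[hits$suppressor_class != "none", ]
#>   contig_id start end strand anticodon decoded_codon suppressor_class
#> 1    contig    10  82      +       CTA           TAG            amber
#>   structure_score
#> 1              21
```

The Sup-CTA anticodon base-pairs with the amber stop TAG; its presence
corroborates a table-15 prediction.

The same pipeline from the shell:

```sh
phagecode simulate --seed 42 --code 15 --out-prefix genome
phagecode select-code genome.fasta --out prediction
phagecode trna-scan genome.fasta --out trnas.tsv
```

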