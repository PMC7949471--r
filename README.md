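# hlaumi

UMI-based quantification of HLA gene- and allele-specific mRNA expression
from 5'-end RNA-seq reads.

## The problem

The classical HLA genes (class I: *HLA-A, -B, -C*; class II: *HLA-DRA,
-DRB1, -DPA1, -DPB1, -DQA1, -DQB1*) are the most polymorphic loci in the
human genome. Measuring how strongly each *allele* of a heterozygous
individual is expressed matters for transplantation matching and
autoimmune-disease genetics, but short RNA-seq reads multi-map across the
thousands of near-identical catalogued alleles, and PCR amplification
distorts read counts away from true molecule counts.

`hlaumi` addresses both problems the way 5'-tagged (STRT-style) protocols
do:

* **Personalized reference.** Reads are aligned only against the 1–2
  allele sequences per gene that the individual actually carries (known
  from prior HLA typing at 2-field resolution, e.g. `C*06:02`), instead of
  the full IMGT/HLA catalog.
* **UMI deduplication.** Every cDNA molecule carries a random 10-bp unique
  molecular identifier (4^10 = 1,048,576 barcodes). Reads whose UMIs are
  equal or differ by at most one base are collapsed into one candidate
  molecule, so each original transcript is counted once regardless of PCR
  duplication.
* **Bayesian allele assignment.** For each gene, the per-sample multiple
  alignment of its alleles is scanned for *key polymorphic sites* —
  columns whose base composition has Shannon entropy H > 0.5 (natural
  log). A UMI whose reads hit only one allele is counted to it directly;
  otherwise the likelihood of the molecule under each candidate allele i
  is

      P(U | A_i) = (1/n) * sum_k p(b_k | A_ik)

      p(b_k | A_ik) = 1 - e   if b_k = A_ik      (e = 10^(-q/10))
                      e / 3   otherwise

  the mean over the n key sites covered by the molecule's reads, with b_k
  the observed base, q its phred score and A_ik the allele's base at site
  k. The molecule is assigned to the argmax allele (exact ties are
  reported as ambiguous by default).
* **Normalization.** Deduplicated counts from cDNA libraries are
  CPM-normalized against the sample's whole-transcriptome unique-UMI
  total; targeted amplicon libraries are converted to within-sample allele
  proportions and rescaled to the sample's cDNA CPM total so the two
  routes are comparable. Derived summaries include per-heterozygote log2
  allele ratios, the lesser-allele proportion (allelic imbalance, binned
  0.01–0.20 / 0.21–0.40 / 0.41–0.50) and allelic-lineage group medians
  with log2 fold changes.

A seeded simulator (`sim_config()`, `simulate_reads()`) generates
synthetic alleles, UMI-tagged molecules, branching-process PCR duplicates
and error-bearing paired FASTQ with a ground-truth table, so the whole
pipeline is testable without controlled-access data.

## Worked example

Simulate a 2:1 heterozygote (600 vs 300 molecules of the two alleles of
one gene, 5 discriminating substitutions, phred 30, PCR error 1e-4), then
quantify it:

```r
library(hlaumi)

cfg <- sim_config(seed = 7, genes = 1, seq_len = 300, divergence = 5,
                  molecules = c(600, 300), q = 30)
sim   <- simulate_reads(cfg)
reads <- extract_umis(sim$seqrun$fastq1, sim$seqrun$fastq2)
res   <- quantify_sample(reads, sim$alleles$catalog,
                         sim$alleles$genotypes, "SIM1")
res$counts
#>    sample    allele count
#> 1:   SIM1 SG1*01:01   593
#> 2:   SIM1 SG1*02:01   298

imb <- allelic_imbalance(res$counts, "SIM1", "SG1")
sprintf("lesser-allele proportion: %.3f (bin %s)", imb$p, imb$bin)
#> "lesser-allele proportion: 0.334 (bin 0.21-0.40)"
allele_log_ratio(res$counts, "SIM1", "SG1")
#> 0.993

cpm_normalize(res$counts, c(SIM1 = 5e5))
#>    sample    allele value library_size
#> 1:   SIM1 SG1*01:01  1186        5e+05
#> 2:   SIM1 SG1*02:01   596        5e+05
```

The 4,040 reads (PCR duplicates included) collapse to 891 UMI groups —
the 900 true molecules minus a handful of barcode-collision merges — and
the recovered lesser-allele proportion 0.334 and log2 ratio 0.993 match
the simulated 1/3 and 1.0 within binomial sampling error. `res$report`
carries the run tallies (routes, ambiguous/unassigned, parameters);
`evaluate_against_truth()` scores assignments against the simulator's
truth table.

Real data enter through `read_allele_fasta()` (IMGT/HLA-style headers),
`read_genotype_table()`, `extract_umis()` on FASTQ (or `read_maf()` for
LAST alignments), and `run_pipeline()` drives everything from a YAML
config and writes TSV/JSON outputs. A thin command-line front end with
`run`, `find-sites` and `simulate` subcommands is installed at
`system.file("cli", "hlaumi.R", package = "hlaumi")`; the remaining
pipeline stages are the exported functions themselves.

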