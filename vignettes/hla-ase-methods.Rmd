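---
title: "Methods: UMI-based HLA allele-specific expression quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UMI-based HLA allele-specific expression quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`hlaumi` estimates HLA gene- and allele-specific mRNA expression by
counting unique molecules (UMIs) assigned to the allele sequences of a
*personalized* reference — the 1–2 alleles per gene an individual is known
to carry from prior HLA typing. This vignette documents the model, its
assumptions, the tunable parameters, the numerical conventions, and what
the bundled simulator does and does not emulate. HLA genotyping itself,
whole-transcriptome alignment/counting (the library-size input), and
hypothesis testing on cohort summaries are out of scope: genotypes, library
sizes and group labels are inputs.

# The quantification model

## Personalized reference and key polymorphic sites

For each sample, the catalog sequences of its typed alleles (2-field
resolution, e.g. `DQB1*06:02`) are collected per gene and multiply aligned.
With at most two alleles per gene this is a single global pairwise
alignment; the center-star construction is kept general. Each alignment
column is scored by the Shannon entropy of its base composition across the
sample's alleles,

$$H_k = -\sum_s f_s \ln f_s,$$

and columns with $H_k > \theta$ (default $\theta = 0.5$) become *key
polymorphic sites* — the only positions the assignment likelihood looks at.

Two conventions here are genuinely open and are therefore configurable:

* **Entropy log base.** Natural log is the default: a 50/50 biallelic
  column scores $\ln 2 \approx 0.693 > 0.5$, so every substitution between
  a heterozygote's two alleles is a key site, which is the evident intent
  of the 0.5 threshold. Under base-2 the same column scores 1; `log_base`
  rescales the statistic, and the threshold should be chosen together with
  it.
* **Gap columns.** The per-site likelihood below is a substitution model,
  so columns where any allele carries a gap are excluded by default.
  `include_indel_sites = TRUE` keeps them, treating the gap as a fifth
  symbol; the gapped allele then has no coordinate at that site and indel
  evidence still never enters the likelihood. Single-allele (homozygous)
  genes have no key sites at all — their molecules are counted through the
  unique route.

## Read alignment

Candidate hits are found by *overlap* (free-end-gap) alignment of every
read against every allele sequence of the personalized reference, in both
orientations, keeping hits with percent identity ≥ 90 over the aligned
region and ≥ 50 aligned base pairs (both configurable; the length floor
mirrors a long-seed first-pass alignment contract). Because a personalized
reference holds at most ~18 short sequences, exhaustive alignment is
tractable and removes any external aligner from the test path; alignments
produced by LAST can still be imported from MAF (`read_maf()`), including
separate R1 / R2 / paired-end files whose hits are unioned per read.

The aligner is compiled (Rcpp) dynamic programming with match = 1,
mismatch = −1, gap open = −2, gap extend = −1, where a gap of length $L$
costs $2 + L$ (the Biostrings affine convention; the printed scheme does
not fix this, so it is stated here and used consistently by the package
and its test oracles). The traceback is deterministic — on ties the
diagonal move is preferred, then consuming a read base, then an allele
base — so identical inputs always give identical aligned coordinates. The
multiple alignment of allele pairs uses the same engine with a linear gap
of −2. Alignment scores are verified in the test suite against both an
independent plain-R dynamic-programming oracle and
`Biostrings::pairwiseAlignment`. The compiled implementation exists
because pipeline-scale projection needs per-read aligned coordinates,
which it returns directly and cheaply.

Per read and gene, the best-scoring hit is projected through the allele's
coordinate map onto the key-site columns, yielding observations
$(b_k, q_k)$ — the read base and its phred score at each covered site.
Read insertions contribute no observation; deletions skip the site;
non-ACGT bases are dropped.

## UMI grouping

Reads are grouped per sample by their UMI, merging barcodes at Hamming
distance ≤ 1 by single-linkage connected components — the plain reading of
"same UMI or differing by at most one nucleotide". Single linkage merges
chains (A–B–C with d(A,C) = 2); this is noted rather than guessed away,
and the count-gradient `directional` method familiar from the UMI-tools
family is available behind a flag. Canonical barcodes are the most
frequent variant (ties lexicographic), and group ids are assigned in
sorted canonical order, so clustering is order-invariant. Reads whose UMI
contains `N` are dropped and counted.

## Assignment and counting

A UMI group whose member reads hit exactly one allele is counted to that
allele (the *unique* route; homozygous genes always land here). Otherwise,
the group's observations are first reduced to one per site — highest
quality wins, quality ties go to the majority base, remaining ties to the
lexicographically smallest base — and each candidate allele $i$ is scored
with

$$P(U \mid A_i) = \frac{1}{n} \sum_{k=1}^{n} p(b_k \mid A_{ik}), \qquad
p(b_k \mid A_{ik}) = \begin{cases} 1 - e_k & b_k = A_{ik} \\ e_k/3 &
b_k \ne A_{ik} \end{cases}, \qquad e_k = 10^{-q_k/10}.$$

This is the printed form of the model: an arithmetic *mean* of per-site
probabilities, not a product. A product (log-sum) model is a plausible
alternative with different tail behavior, but the mean is what the method
defines, and it has the useful property of living in $(0, 1]$ on a scale
independent of $n$ — which is also why candidates from *different genes*
(rare cross-gene mappings) can be compared directly. The group goes to the
strict argmax. Exact ties are reported as `ambiguous` and excluded from
counts by default (a conservative undercount); `random` (seeded) and
`fractional` (1/t shares) policies exist. A multi-candidate group covering
zero key sites is `unassigned`, as is any group whose best likelihood
falls below the optional `min_likelihood` floor (default 0, disabled).
Counting conserves groups exactly: allele counts + ambiguous + unassigned
= number of UMI groups.

## Normalization and summaries

* **cDNA route:** CPM, `count * 1e6 / library_size`, the library size
  being the sample's whole-transcriptome unique-UMI total in which the
  generic HLA gene rows have been replaced by the allele rows
  (`library_sizes_from_counts()`).
* **Amplicon route:** within-sample allele proportions of amplicon UMIs,
  multiplied by the sample's total CPM-normalized cDNA HLA UMIs; the
  per-sample cDNA HLA total is conserved exactly.
* **Derived statistics:** per-heterozygote log2 allele ratio (numerator
  fixed to the lexicographically smaller allele name, so ratios are
  comparable across routes); lesser-allele proportion
  $p = \min(c_1, c_2)/(c_1 + c_2) \le 0.5$, rounded to two decimals and
  binned 0.01–0.20 / 0.21–0.40 / 0.41–0.50, with $p < 0.01$ folded into
  the first bin (a zero-count lesser allele is otherwise unrepresentable);
  group medians (midpoint convention) and log2 fold changes between
  groups, with a built-in `lineage` labeller that pools alleles on their
  first name field (`DPB1*02:01` → `DPB1*02`). Zero counts make a log
  ratio undefined; the package errors and reports the exclusion rather
  than inventing a pseudocount.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.5 | entropy gate for key sites (units set by `log_base`) |
| `log_base` | e | entropy units; ln 2 ≈ 0.693 per 50/50 biallelic column |
| `min_identity` | 90 (%) | candidate-hit identity floor over aligned columns |
| `min_aln_len` | 50 (bp) | minimum aligned base pairs per hit |
| `umi_len` | 10 (bp) | UMI prefix length; 4^10 ≈ 1.05M barcodes |
| UMI mismatch | 1 (fixed) | barcode merge radius (single linkage) |
| `tie_policy` | ambiguous | exact likelihood ties: drop, randomize or split |
| `min_likelihood` | 0 | optional floor routing weak argmax to unassigned |

# The simulator

`sim_config()` defines a seeded synthetic study: per gene a uniform random
sequence (default 1,100 bp, the scale of a class-I transcript) and a
second allele differing at exactly `divergence` planted substitutions;
`molecules[a]` transcripts per allele, each tagged with an independent
uniform UMI (collisions are possible and recorded in the truth table);
branching-process PCR (each copy duplicates with probability ε per cycle —
defaults 2 cycles at ε = 0.5, giving dispersed duplicate counts at
test-friendly depth) with per-copy substitutions at `pcr_error` (default
1e-4, UMI included, so barcode-error merging is exercised); and sequencing
with per-base substitution errors at the quality-implied rate
$10^{-q/10}$ (default q = 30) written as phred+33.

Reads are 5'-anchored: R1 is the UMI plus the template start (default
100 bp total). The default is *paired*, adding per sequenced copy an R2
read (default 200 bp) reverse-complemented from a uniformly random
template offset — the tagmentation analogue of the 100 + 200 bp library
design this emulates. This matters: 5'-anchored R1 alone can never reach
interior polymorphic sites of a transcript-length gene, so the paired
default is what makes interior key sites observable, exactly as in the
real protocol.

What the simulator does **not** emulate: real IMGT/HLA sequences and their
paralog homology, indel sequencing errors, fragment-length and GC bias,
primer-efficiency differences between alleles in amplicon enrichment, and
cell-composition effects. Passing tests therefore demonstrate the
correctness of the bookkeeping and of the statistical machinery under the
stated error model — not robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

* Coordinates are 1-based closed throughout the R API, the convention of
  R's sequence ecosystem; reports are likewise 1-based.
* Integer-valued alignment scores computed in integer arithmetic; exact
  score ties in strand choice keep the plus strand, equal-scoring hits of
  one read to the same gene resolve to the first allele in sorted order
  (identical MSA columns either way).
* Likelihood ties are detected by exact floating-point equality on values
  computed by one code path; symmetric evidence produces exact ties by
  construction.
* Degenerate cases with defined behavior: empty FASTA, empty sequences,
  colliding truncated allele names (error naming the collision); a
  genotype allele missing from the catalog (error naming sample, gene,
  allele); reads shorter than the UMI (error naming the record); mixed UMI
  lengths in one scope (error); `divergence = 0` (identical alleles, empty
  key-site table, all molecules ambiguous between the two identical
  sequences); ε = 0 PCR (one copy per molecule); empty hit tables and
  zero-group samples (empty, conserving outputs).
* Problem sizes in the test-suite studies are scaled for quick iteration
  (genes of 200–300 bp with the molecule counts, divergence and error
  rates of the recovery conditions; 50-sample concordance studies at 150+
  molecules per allele); the statistical checks use binomial sampling
  bounds, so the conclusions do not depend on the scaled length.

# Known limitations

* The likelihood is substitution-only; indel polymorphism between alleles
  contributes no assignment evidence (such columns are excluded by
  default).
* Barcode-space collisions merge distinct molecules (≈ C(M,2)·3L/4^L
  expected Hamming-≤1 merges among M molecules at UMI length L); with
  M in the low thousands at L = 10 this is a ~1–5% deflation of totals
  and is visible in the simulator's truth table, not corrected
  statistically.
* Ambiguous-tie exclusion undercounts when two alleles are genuinely
  indistinguishable over the covered sites.
* Cross-gene candidate arbitration compares normalized likelihood means
  across genes; with very unequal site coverage between genes this is a
  heuristic, documented rather than hidden.
* No posterior with allele priors, no EM reassignment of multi-mapped
  molecules, no spliced alignment.
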