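---
title: "Quantifying wobble-inosine editing and its consequences: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wobble-inosine editing and its consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wobbleseq)
```

## The biological model

Eukaryotic tRNAs whose anticodon begins with adenosine (the eight ANN
families) are deaminated at the wobble position 34 by the ADAT2/ADAT3
complex, converting A34 to inosine (I34). Inosine pairs with U, C and A,
so editing widens each family's decoding box; crucially, because G34
anticodons are absent from eukaryotic genomes for these families, the
C-ending codon of each box can only be read by the edited anticodon.
When deaminase activity drops — as in cells carrying hypomorphic *ADAT3*
variants — three measurable consequences follow, and this package
quantifies all three from tRNA-seq data:

1. **I34 stoichiometry falls.** Reverse transcriptase reads inosine as G,
   so the fraction of G among G+A calls at the wobble index of an ANN
   isodecoder estimates the edited fraction directly.
2. **Hypomodified isodecoders are destabilized.** Abundance loss correlates
   with editing loss across isodecoders; we measure this coupling on the
   log2 scale with a rank correlation.
3. **Translation of ADAT-dependent codons becomes limiting.** Gene sets
   (for instance genes acting in neuronal migration) can be tested for
   enrichment of dependent-codon usage against a background genome.

## Wobble-pairing rules and dependent codons

`enumerate_dependent_codons()` needs a decoding rule for every wobble
base. We use: G34 reads C- and U-ending codons; C34 reads G-ending codons;
U34 reads A-, G- and U-ending codons; unedited A34 reads U-ending codons;
I34 reads U-, C- and A-ending codons. The U34 rule deserves comment: a
strict Watson-Crick-plus-G:U rule would let U34 read only purine-ending
codons, which would make both the U- and C-ending codons of every ANN box
dependent on I34. In practice eukaryotic U34 is heavily modified and reads
U-ending codons of its own box (superwobble), which is why the field's
standard statement — and the output of this package — is that exactly one
codon per ANN family, always C-ending, is ADAT-dependent. The derivation
is checked against a 64-codon brute-force enumeration in the test suite,
and is invariant to the order of the anticodon table.

The packaged anticodon repertoire (`inst/extdata/anticodon_table.tsv`)
is the standard eukaryotic cytoplasmic set (45 anticodons, including
Arg-TCG, whose presence keeps CGU off the dependent list). Users can
supply their own table; mitochondrial records are loaded but excluded
from ADAT-target classification and from all I34 statistics.

## The synthetic-data generator

The simulator exists so that every estimator in the package can be tested
against a recorded ground truth. It emulates:

* **Abundance**: per-isodecoder counts are negative-binomial with mean
  `mu_i * fold_change_i * size_factor_j` and dispersion `alpha_i`
  (`alpha = 0` is Poisson). Size factors are log-normal (sd 0.15);
  relative abundances default to log-normal (sd 0.5) around an even split
  of the library. Default library depth is 1e6 reads in the shipped
  configuration scale; tests and the demo use 1e4-1e5 so the whole suite
  runs in minutes on one CPU.
* **The inosine signature**: each read covering the wobble index of an ANN
  isodecoder carries G with probability theta (the condition's planted
  stoichiometry) and A otherwise. Controls default to theta = 1 — ANN
  tRNAs are essentially fully edited in healthy cells.
* **Other modification signatures**: annotated non-I34 sites (defaults at
  the canonical positions of m1G9, m2,2G26, m1I37, m1A58) misincorporate
  with probability 0.08 and stop reverse transcription with probability
  0.05 per site; a truncated read starts just 3' of the stopping site.
  Reads are full-length-biased: they run from the 3' CCA toward the 5'
  end, so "full length" means reaching position 0.
* **Sequencing error**: substitution-only, 0.001 per base. Indels are not
  simulated; the aligner nevertheless tolerates one indel as a robustness
  measure for real data.
* **Coupling**: planted fold changes for coupled isodecoders are
  `slope * log2(theta_case/theta_control)` plus Gaussian noise, so editing
  loss and abundance loss are monotonically linked by construction. The
  standalone `simulate_coupled_deltas()` draws (delta-I34,
  delta-abundance) pairs from a Gaussian copula whose Pearson parameter
  `2*sin(pi*rho/6)` yields a target Spearman correlation of `rho`.
* **Codon enrichment**: background genes draw codons uniformly within each
  synonymous family from amino acids at human-like frequencies; target
  genes multiply the odds of each dependent codon within its family by a
  configurable factor and renormalize. Multiplier 1 makes the two groups
  exchangeable, which is the basis of the calibration test.

Every stochastic output is a pure function of (configuration, seed).

What the simulator does *not* model — and hence what passing tests do not
establish about real data: adapters and UMIs, indel errors, charging
state, base-quality variation, cross-contamination between near-identical
isodecoders beyond what `member_divergence` (default 6 substitutions from
a family consensus) induces, and the possibility that real references
contain isodecoders identical over long 3' stretches. On real libraries
the unique-assignment fraction is typically far below the near-1 values
seen on simulated data.

## Read assignment

Reads are aligned 3'-anchored (semi-global with a free 5' end on the read
side), because tRNA-seq chemistry anchors reads at the 3' terminus and RT
stops truncate the 5' side. Mismatches at annotated modification sites —
including the wobble index of ANN families — cost nothing when
`mod_site_free` is on, so modification signatures never pull a read away
from its true source. The best-scoring isodecoder wins; equal scores
within one anticodon family split the read fractionally (weights summing
to 1); equal scores across families drop the read as cross-family
ambiguous rather than rescuing it by expectation-maximization, which is
out of scope. More than `max_mismatch = 3` non-exempt mismatches leaves a
read unassigned; three is a deliberately tight budget for ~76-nt
molecules whose modification positions are already exempt. Reads that
fail the ungapped pass are retried allowing exactly one indel (gap cost
1); rescued reads enter the counts but not the pileups, since their
per-position registration is ambiguous by one base. The whole procedure
is validated read-for-read against an exhaustive brute-force aligner.

## Stoichiometry calling

`call_i34()` estimates theta as G/(G+A) at the wobble index. C and T
calls at the site are sequencing errors under the A-or-G biology and are
excluded from the denominator rather than diluting the estimate. Wilson
95% intervals are used instead of Wald because theta sits near 0 or 1 in
healthy and severely affected samples respectively, exactly where Wald
intervals degenerate; at the boundaries the interval endpoints are set
exactly to 0 or 1 to avoid floating-point residue. Units with fewer than
`min_coverage = 20` informative reads are reported `low_coverage` with no
estimate. Anticodon pools use the coverage-weighted mean of member
estimates, which is algebraically identical to calling on the summed
counts — the identity is asserted in the tests. Condition deltas are
reported in percentage points for profile-style displays and as log2
ratios for the coupling analysis. Truncation at the wobble position is
not treated as an inosine signal.

## Differential abundance

Normalization is median-of-ratios (each library's factor is the median
ratio of its counts to per-unit geometric means). Dispersion is estimated
by method of moments within conditions, `max(0, (s^2 - m*c0)/m^2)` with
`c0 = mean(1/sf)` absorbing the Poisson part, then shrunk halfway toward
a fitted `a0 + a1/mean` trend. The Wald statistic divides the log2 fold
change by a delta-method standard error built from the NB mean-variance
relation. Because the shrunk dispersion borrows strength across units,
the statistic is referred to a t distribution with
`(n1 + n2 - 2)/(1 - shrink)` degrees of freedom — a moderated-t argument:
shrinkage by weight w scales the variance of the variance estimate down
by roughly (1-w), inflating the effective degrees of freedom by 1/(1-w).
With the default shrink of 0.5 and 3-vs-3 designs this gives 8 df; the
empirical type-I error at nominal 0.05 is ~0.03-0.05 in the calibration
suite. Fractional counts from tied assignments stay exact for
normalization and are rounded for testing (the NB model wants integers);
the 0.5 pseudocount touches only units with a zero-count condition.
Significance is called at BH-adjusted p < 0.05. This module is a
self-contained NB Wald test whose calibration is verified by simulation;
it is deliberately simple — no shrinkage of fold changes, no outlier
refitting, single-factor designs only.

In power simulations we plant a 2-fold loss on all eight ANN families
over a 45-family (90-isodecoder) reference at 1e5 reads per library,
3 vs 3, with isodecoder dispersion 0.05 — a value typical of
high-quality, reproducible tRNA-seq replicates. Six to eight of the
eight families are recovered at padj < 0.05 in the large majority of
runs; the remainder are near-misses at the BH boundary, which is the
expected behaviour at this depth and replication, not an estimator
defect.

## Coupling and enrichment inference

`spearman_coupling()` uses average ranks (Pearson on ranks equals
Spearman with ties) and permutes unit labels; the two-sided p-value uses
the add-one rule, so it is never zero and never anticonservative at small
B. The sign convention puts both deltas case-minus-control on the log2
scale, so a *positive* correlation reads "more editing loss, more
abundance loss".

`enrichment_test()` compares the mean dependent-codon usage share of a
gene set with B random same-size sets from the background (optionally
matched on CDS-length decile). Usage shares restrict the denominator to
the family's own codon box (e.g. AUU/AUC/AUA for Ile, excluding AUG),
and terminal stop codons are excluded. The one-sided alternative follows
the directional biological claim; a two-sided variant is available.
Genes are deduplicated by id, making the test invariant to duplicated
background rows and to gene order.

## Numerical and design choices

* Coordinates are 0-based half-open throughout; "position 34" is the
  annotated anticodon start, not a structure-derived index.
* Internal alphabet is DNA; codons are rendered as RNA in outputs.
* Quality strings are constant and ignored; qualities carry no
  information in this analysis.
* Permutation counts default to B = 10000 in user-facing settings; tests
  use B = 999-2000 where only coarse p-resolution is needed.
* The pipeline's summary JSON is byte-identical across reruns of the same
  configuration and seed; logs carry wall-clock times and are excluded
  from that guarantee.
* Problem sizes in the shipped tests (1e4-1e5 reads, 20-225 units,
  50-500 repetitions) were chosen so the full suite completes in a few
  minutes on one CPU while leaving every statistical check adequately
  powered.

## Known limitations

* The aligner handles at most one indel and never scores internal gaps
  against modification-dense regions differently; highly degraded real
  libraries may need a dedicated mapper upstream.
* Cross-family ambiguous reads are dropped, slightly biasing counts
  against families with close non-family paralogs.
* The NB test does not model isodecoder-level composition shifts beyond
  median-of-ratios normalization; if a majority of the library changes,
  fold changes are measured relative to the stable median unit.
* Deamination assays enter as base counts; chromatogram parsing is out of
  scope.
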