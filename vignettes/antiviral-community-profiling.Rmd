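---
title: "Profiling antiviral systems and phage–host interactions in water metagenomes"
author: "aquaphage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling antiviral systems and phage-host interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaphage)
```

## The scientific problem

Drinking-water distribution systems host sparse, stressed microbial
communities in which phages and prokaryotes interact intensely. Residual
disinfectant (chlorine) is hypothesized to shift three coupled community
properties: the abundance and composition of prokaryotic antiviral defense
systems, the lysogenic fraction of the phage community, and the breadth of
phage host ranges. Measuring these from assembled metagenomes requires a
chain of quantitative steps — abundance estimation, sequence dereplication,
viral taxonomy, CRISPR array analysis, multi-channel host prediction and
comparative statistics — each with conventions that materially affect the
numbers. This package fixes those conventions explicitly, implements each
step as a tested function, and validates the full chain on synthetic
communities with planted ground truth.

## Abundance model

Reads are mapped upstream (alignment is out of scope here; alignment
records are inputs) and filtered on aligned block length. The filter
keeps records with **aligned length ≥ 30 bp**: the mapping-length rule is
stated as "more than 30 bp" in the sources this workflow follows, while the
corresponding aligner seed setting (`-k 30`) admits exactly 30; we adopt
the inclusive reading, pin it in tests, and expose the threshold as a
parameter. Whether the filter should act on query coverage rather than the
aligned block is not derivable from those sources; aligned block length is
used.

TPM for contig $i$ with $c_i$ surviving records and length $L_i$ bp is

$$\mathrm{TPM}_i = \frac{c_i / L_i}{\sum_j c_j / L_j} \times 10^6,$$

so every sample column with at least one surviving read sums to $10^6$
(asserted to $10^{-9}$ relative tolerance). Each alignment record counts
once: no fractional multi-mapping weights, the simplest auditable rule.

## Dereplication

`dereplicate()` reproduces the greedy longest-first strategy of
incremental clustering tools: contigs are visited in decreasing length
(ties broken lexicographically by id) and join the first representative
with alignment identity ≥ 0.95 and coverage of the shorter sequence ≥ 0.8.
Identity is matches over aligned columns *including gap columns* of the
best local alignment (match +1, mismatch −1, gap −2); the denominators
used by specific external tools differ subtly and are not replicated
bit-for-bit. The shared-k-mer prefilter (word size 16) skips an alignment
only when the thresholds mathematically guarantee that any qualifying pair
shares an exact 16-mer (a pigeonhole bound minimized over admissible
alignment lengths); short sequences are always aligned, which keeps the
prefilter path exactly equivalent to unconditional all-pairs alignment —
a property the test suite checks directly.

## Viral taxonomy vote

Per-gene database hits are reduced to the lowest-E-value hit per gene
(E ≤ 10⁻⁵), because the rule counts genes, not hits. A contig is
*eligible* when ≥ 20% of its genes have hits, or, for contigs with fewer
than ten genes, when at least two genes have hits. An eligible contig is
assigned at the **deepest rank at which one taxon is shared by ≥ 60% of
hit genes**; both boundaries are inclusive. Two deliberate readings are
worth noting: the 60% denominator is "genes with any hit" (not genes
attributable at that rank), and "most specific taxon" is realized as a
deepest-qualifying-rank walk; if no rank reaches consensus the contig
stays unassigned rather than falling back to a domain-level label. Two
taxa cannot both reach 60% at one rank, so ties cannot arise. The
implementation is checked against a brute-force enumeration of the rule
over all hit tables with up to 6 genes, 3 taxa and 2 ranks.

## CRISPR arrays and the spacer burden

`detect_crispr_arrays()` is a deliberate stand-in for machine-learning
array detectors: it finds maximal chains of ≥ 3 *exact* copies of a repeat
(23–55 bp) separated by spacer-length gaps (20–60 bp), greedily accepting
longer repeats first, leftmost first, without overlap. Exact matching
(`max_repeat_mismatches = 0`) is the default because the synthetic truth
plants exact repeats; tolerance is left as a parameter rather than an
implementation. The detector is verified against exhaustive chain
enumeration on small contigs.

The spacer burden normalizes spacer counts by contig length and weighs by
abundance:

$$M = \sum_{\text{CRISPR contigs}} \frac{N}{L} \, A,$$

with $N$ the contig's spacer count summed over all of its arrays (the
formula's "number of spacers in contig" read literally), $L$ the contig
length in bp, and $A$ the contig's TPM. Whether $M$ is a per-sample or a
pooled quantity is not specified by its source; we compute it per sample
from that sample's TPM column and report group means, exposing the
aggregation to the caller.

## Host linkage

Three in-situ channels produce `(phage, host contig, channel)` links:

* **CRISPR spacers**: a link when a spacer (≥ 18 bp) occurs in a viral
  contig on either strand with ≤ `max_mismatch` mismatches (default 0, no
  indels). Matching is at the nucleotide level — the standard protospacer
  convention and self-contained — although some published pipelines
  compare at the protein level; the choice is documented and the matcher
  is pluggable. `N` bases never match.
* **tRNAs**: a link requires a full-length, 100%-identity match between a
  viral and a prokaryotic tRNA gene (either strand). "Perfect match" could
  also be read as full-identity-over-HSP after a permissive BLAST; we
  require full length, the stricter and simpler criterion.
* **Prophages**: the prokaryotic contig carrying an integrated prophage is
  its host; intervals are 0-based half-open internally and validated
  against contig bounds.

Ex-situ prediction against reference databases is the same pair of
matching operations applied to a user-supplied reference table; no
database is bundled. Links deduplicate on (phage, host, channel) — a pair
supported by two channels keeps both rows, and such phages are counted as
multi-channel evidence. Genus is the linkage resolution: links whose host
contig lacks a genus are retained in the table but excluded from
genus-level summaries. A phage linked to ≥ 2 distinct genera is
*polyvalent*; the count-basis fraction divides by genus-linked phages and
is invariant to duplicated link rows, and the abundance basis weighs
phages by TPM.

## Defense profiles

Figure-style quantities follow contig-level semantics: "abundance of
contigs with system X" is the summed TPM of distinct carrying contigs — a
contig with three RM systems contributes its TPM once to RM, while a
contig carrying RM and BREX contributes to both families. Whether repeated
systems should be double-counted is genuinely open; the convention here is
fixed and documented. Condition-level profiles are means over per-sample
profiles (not pooled reads), so group comparisons run through the same
per-sample t tests as every other quantity. Restricted profiles reuse the
identical computation under a predicate (lysogenized prokaryotes = hosts
of a prophage interval; phage-carried systems split by lifestyle), and a
restriction that excludes nothing reproduces the full profile exactly.

## Statistics

All test statistics are implemented directly (and cross-checked against
`vegan`/`stats` reference implementations in the test suite):

* Shannon $H = -\sum p_i \ln p_i$ in natural log — the magnitudes this
  workflow deals in (5–8 nats) correspond to communities of thousands of
  taxa under ln.
* Bray–Curtis $d = 1 - 2\sum\min(x_i,y_i)/(\sum x + \sum y)$, bounded in
  [0, 1]; no triangle inequality is asserted.
* PCoA by classical scaling: double-center $-D^2/2$, eigendecompose, build
  coordinates from positive eigenvalues only. Negative eigenvalues are
  reported, never clamped or corrected (Cailliez/Lingoes corrections are
  deliberately off); variance explained is over the positive spectrum, and
  each axis's sign is fixed by making its first non-negligible loading
  positive.
* Mantel: Spearman correlation of upper-triangle vectors by default (the
  reported statistic is a rho), one-sided greater alternative — the Mantel
  convention — with $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 +
  n_\text{perm})$, so $p \ge 1/(n_\text{perm}+1)$ always. For $n \le 8$ an
  exhaustive mode enumerates all label permutations. The permutation count
  (default 999) and correlation flavor are this package's documented
  defaults, not inferred settings of any external study.
* Pearson r with the $t = r\sqrt{(n-2)/(1-r^2)}$ reference; Student's
  pooled-variance t (df $= n_a+n_b-2$) by default with Welch available.
  Where many correlations are screened, Benjamini–Hochberg FDR is reported
  alongside raw p-values as this package's own choice.

## The synthetic community generator

`generate_community()` emulates the *data layout* of a two-arm
drinking-water study — disinfected and non-disinfected sample groups —
with planted ground truth for every downstream stage:

* Genus-structured prokaryotic contigs (default 8 genera × 5 contigs,
  3–8 kb) with lognormal genus abundances (sdlog 1) and per-contig
  scatter: the simplest model reproducing rank-abundance skew.
* Viral contigs drawn i.i.d. uniform over {A,C,G,T} at ≥ 1.5 kb, so a
  32-mer spacer collides with an unrelated contig with probability
  < 10⁻¹⁰ and truth evaluation stays clean.
* Prophages as verbatim copies of free viral contigs inserted into host
  contigs at recorded intervals (insertions never overlap one another).
* Exact-repeat CRISPR arrays (28 bp repeat, 32 bp spacers) whose spacers
  are copied from viral contigs (either strand) at a configurable rate.
  Consecutive spacers are constrained to differ in their first and last
  characters so that no sub-chain of repeat copies admits a longer-repeat
  reading — without this, roughly one array in sixteen would legitimately
  be reported shifted by the greedy longest-repeat-first detector, and
  planted-truth recovery could not be exact. Spacer-link truth is defined
  as *all* viral-category contigs containing the spacer, computed by
  exhaustive scan at planting time (a prophage copy duplicates its source
  sequence and must count as a true target).
* Shared tRNAs (72 bp) and defense annotations as feature tables in the
  same schemas the readers consume.
* Condition effects are realized on **abundance**: defense-carrier status
  and lifestyle labels are per-contig properties drawn once (at the
  non-disinfected rates), and the disinfected arm scales carrier and
  lysogenic contig weights so their expected TPM shares match the
  configured per-condition rates (defaults: carrier share 0.25 vs 0.10,
  lysogenic share 0.3 vs 0.1, viral share 1.4% vs 0.3%). This is the
  natural reading of per-condition rates for properties that cannot differ
  between samples of the same contig, and it makes the planted effects
  detectable by the per-sample t tests.

Read simulation draws multinomial counts proportional to abundance ×
length (so TPM recovers relative abundance) and gives a configurable
fraction of reads sub-30-bp aligned lengths to exercise the filter.
Master seed → fixed per-stage child seeds; everything is byte-reproducible.

What the generator does **not** emulate: sequencing error, real genome
composition (GC, repeats, mobile elements), degenerate CRISPR repeats,
partial prophage deletions, homology between related genera, or database
noise in gene hits. Passing the planted-truth suites therefore
demonstrates the correctness of the bookkeeping and matching logic under
clean signals, not detector robustness on real, noisy assemblies — on real
data the array detector in particular should be replaced by a
mismatch-tolerant tool, which is why annotations and coordinates arrive
as input tables throughout.

## Numerical choices and degenerate inputs

Samples with no surviving reads yield an all-zero (flagged) TPM column
rather than an error. Zero-variance t-tests return t = 0, p = 1 when the
means agree and raise otherwise. Mantel p-values are bounded below by
1/(n_perm+1) by construction. PCoA on an all-zero distance matrix returns
the origin. Dereplication ties in length break lexicographically, making
cluster maps deterministic. Degenerate configurations (empty ranges,
probabilities outside [0, 1], all-zero family weights) are rejected before
any generation.

## Problem sizes

The shipped study uses 80 contigs and 12 samples at 20,000 reads per
sample; the test suite validates statistical calibration with 200
replicate null and effect simulations at 15–20 samples per group, and the
oracle-equivalence suites run on contigs up to ~1 kb, link tables up to a
few thousand rows, and 20-sequence dereplication sets. These sizes were
chosen so the complete validation runs comfortably on a laptop while every
law being checked (conservation, equivalence, calibration, recovery) is
exercised at non-trivial scale.

## A compact end-to-end run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1L)
com <- generate_community(cfg)
rep <- run_pipeline(com)
link_accuracy(rep$links, com$truth$true_host_links)
rep$tests
```

## Known limitations

Exact-repeat CRISPR detection underestimates arrays with degenerate
repeats; spacer matching defaults to 0 mismatches while real protospacers
tolerate a few; the tRNA channel treats any perfect 60–120 bp match as
evidence, without anticodon awareness; host genus assignment depends
entirely on the supplied taxonomy table; and the Mantel/PCoA layer does
not implement PERMANOVA or partial Mantel. The dereplication identity is
an explicit convention, not a bit-level reproduction of any external
clustering tool.
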