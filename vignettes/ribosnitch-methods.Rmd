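---
title: "Detecting structure-disrupting variants and structure-selected elements"
author: "ribosnitch package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structure-disrupting variants and structure-selected elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosnitch)
```

## The problem

A single-nucleotide variant can reshape the local secondary structure of the
transcript that carries it. Such variants — riboSNitches — are candidate
functional mutations in untranslated regions and noncoding RNAs, where
structure mediates miRNA and RNA-binding-protein interactions, stability and
translation. This package implements a complete scan for them in a mutation
cohort:

1. score every exonic SNV by how much it perturbs the base-pair-probability
   profile of its mature transcript (MeanDiff and EucDiff);
2. call riboSNitches as the intersection of the top tails of both statistics,
   and non-riboSNitches as the intersection of the bottom tails;
3. estimate, per transcript element (5'UTR, 3'UTR, lncRNA), the riboSNitch
   count expected under neutral mutation, by simulating mutations from an
   intronic trinucleotide substitution profile recalibrated to the element's
   own composition;
4. test observed against expected counts with one-sided Fisher's exact tests,
   Benjamini–Hochberg corrected within element class, in both directions —
   elements enriched for riboSNitches are candidates for positive selection
   on RNA shape (putative drivers), depleted elements for structural
   constraint (putative essential elements);
5. optionally compare somatic and germline cohorts to flag cancer-specific
   elements at p < 10⁻³ (strict).

## Scoring model

For a mutation at mature-transcript position $k$, with per-position pairing
probabilities $BPP_{ref,i}$ and $BPP_{alt,i}$ of the reference and mutated
sequence,

$$\mathrm{MeanDiff}_k = \sum_{i=k-w}^{k+w}
  \frac{|BPP_{ref,i} - BPP_{alt,i}|}{2w+1},
\qquad
\mathrm{EucDiff}_k = \sqrt{\sum_{i=k-w}^{k+w}
  (BPP_{ref,i} - BPP_{alt,i})^2}.$$

At sequence ends the window is clipped and MeanDiff is normalized by the
number of positions actually covered, so it remains an average (the
alternative — dividing by the literal $2w+1$ — penalizes end positions;
which convention the original formulation intends for ends is not stated,
and `effective_positions` is recorded with every score so either can be
recovered). MeanDiff rewards broad rearrangement, EucDiff large local
change; the dual-tail intersection call requires both.

Pairedness comes from a pluggable backend:

* **internal** (default): a McCaskill-style inside–outside partition
  function over all pseudoknot-free structures with canonical pairs
  (A-T, G-C, G-T), minimal hairpin loop of 3 nt and a maximal pair span
  `max_span_L`. It is deliberately *not* the Turner nearest-neighbour
  energy model: every pair contributes a constant Boltzmann weight
  (`pair_weight`, default 2), optionally multiplied by a stacking bonus
  when the enclosed neighbour is also paired (`pair_weight_model =
  "stack"`). Because the state space is exactly the combinatorial set of
  structures, the whole engine is verifiable against exhaustive
  enumeration (`enumerate_structures()`, `enumeration_bpp()`), and the
  test suite holds it to that oracle at $10^{-9}$.
* **rnaplfold**: an adapter that either parses RNAplfold `_lunp`
  unpaired-probability output (`read_plfold_lunp()`; pairedness is
  $1 - P_\mathrm{unpaired}$ at $u = 1$) or shells out to an `RNAplfold`
  executable. Use this backend when thermodynamic numbers are wanted.

Sequences longer than the folding window `window_W` (default 200 nt) are
folded in every sliding window of that length and per-position values are
averaged over covering windows; edge positions are averaged over the windows
that exist. `score_mutation()` exploits the algebra of this average: windows
not containing the mutated base cancel exactly in the profile difference, so
only windows covering the site are folded.

### Why stacking matters in a pair-weight model

With a uniform weight per pair the ensemble is dominated by entropy: a
designed helix competes against the multitude of diffuse single pairs its
bases could form elsewhere, and breaking one pair of a stable stem is
absorbed with little change in pairedness. The stacking bonus restores helix
cooperativity: splitting a stack of $n$ pairs costs a factor $s$ per lost
stacking interaction, so a contiguous helix outweighs diffuse alternatives
whenever $s^2$ exceeds the number of competing partners in reach. The
package's study configuration uses `pair_weight = 2`, `stack_bonus = 8`,
`max_span_L = 50`; under it a designed 7-bp hairpin in A-rich flanks holds
interior stem pairedness near 0.9 and loses it on a single interior stem
substitution. Ensemble coupling beyond the pair span decays roughly
exponentially but is not exactly zero; the tests assert a two-orders-of-
magnitude drop beyond three spans rather than strict locality.

## Calling riboSNitches

Tail thresholds are empirical quantiles (type 7, linear interpolation of
order statistics; the quantile convention is a package choice) of the
cohort's MeanDiff and EucDiff distributions. The default fractions are 2.5%
per tail; 5%, 10% and 20% relaxations are plain parameters. Ties at a
threshold are included in the tail, so tail sizes can slightly exceed the
nominal fraction. Cutoffs serialize to a small key-value file and can be
transferred between cohorts (e.g. calling a clinical variant set with
germline-derived cutoffs); each cutoff object carries its cohort label and
size. When the score distribution is degenerate and a mutation would satisfy
both tail rules at once, it is labelled `intermediate`.

## Neutral expectation

Intronic mutations are taken as approximately selection-free. Their
strand-collapsed trinucleotide classes (6 pyrimidine-centred substitution
types × 16 flank combinations = 96) form the background profile; each
element's own 3-mer composition (2 centres × 16 flanks = 32 classes)
reweights it:

$$P(\text{class } c \mid \text{element}) \propto
  \mathrm{rate}_c \cdot \mathrm{composition}_{\mathrm{context}(c)}.$$

Simulated mutations draw a class, then a uniform site among the element's
positions matching that class's context, then apply the class's alternative
allele (complemented back at purine-centred sites). Each element receives
`n_sims` simulated mutations (1000 by default, matching the reference
protocol of 1000 random mutations per transcript; the bundled studies use
200 for speed — the expectation is a proportion, so the cost of a smaller
`n_sims` is only resolution of that proportion). Simulated cohorts are
scored identically to observed ones and calibrated *against their own
pooled distribution* — not against the observed cutoffs — mirroring the
protocol's symmetric treatment of observed and simulated tails; expected
counts are pooled over all randomizations, with the simulation size
recorded.

Both one-sided Fisher tests compare the observed element table
$[\mathrm{obs}_{ribo}, \mathrm{obs}_{rest}]$ against
$[\mathrm{exp}_{ribo}, \mathrm{exp}_{rest}]$. BH correction is applied
within element class and direction separately (the stratification mirrors
reporting UTRs and lncRNAs separately; pooling them into one family is the
obvious alternative and a one-line change). Odds ratios use the Haldane 0.5
correction when a cell is empty. Recurrent mutations — the same site in
different samples — are counted independently throughout.

## The synthetic study system

All tests run on synthetic data generated by the package itself
(`fixture_spec()`, `make_genome_and_annotation()`,
`make_mutation_cohort()`); nothing external is downloaded. The generator
emulates:

* a one-chromosome genome with 14 protein-coding and 6 lncRNA genes on both
  strands, two-exon transcripts, GENCODE-style attributes (APPRIS, CCDS,
  level) including decoy isoforms with strictly worse priority keys, so
  principal-transcript selection (APPRIS rank, then CCDS, then level, then
  length) is exercised on realistic metadata;
* 80-nt UTR elements and 130-nt lncRNAs; mature transcripts short enough
  (≤ 200 nt) that the folding window covers them globally;
* a single-signature neutral process: all substitution mass on the 16 C>A
  classes, uniform over flanks — a stylized version of cohorts dominated by
  one trinucleotide signature. The biological point being emulated is that
  neutral structural impact is composition-dependent: in a mostly-A/C
  element a C>A event is structurally silent, in a G/C helix it is a break;
* element roles defined purely by how their structure intersects that
  process: *null* elements are near-inert A/C sequence with a sparse G/T
  background (so neutral scores form a continuum rather than a point mass
  at zero); *depleted* elements carry three G/C hairpins whose stems the
  neutral process keeps hitting (high expected riboSNitch fraction, while
  their observed mutations are drawn from the low-scoring end); *enriched*
  elements carry two A/T hairpins the C>A process cannot touch (expected
  fraction ≈ 0) plus planted observed mutations taken from the top of a
  stem-breaking candidate pool scored by the pipeline's own scorer.
  Planting with the pipeline's scorer is circular **by design**: the
  fixtures test recovery of a planted signal, not biology.
* hairpin stems use fixed aperiodic arms. This is a lesson from the model,
  not a convenience: homopolymer or periodic arms admit shifted pairing
  registers that absorb a break, and G/C-only stems inside C-rich flanks
  lose individual positions to alternative partners.

The benchmark generator (`make_hairpin_benchmark()`) produces the standard
geometry — an SNV centered in 101 nt with 50-nt flanks — with positives
breaking an interior stem pair of a G/C hairpin in A-dominant flanks and
negatives substituting a loop A by C, which can pair with nothing in the
stem. Under the study configuration both statistics separate these classes
essentially perfectly; the benchmark validates the scoring chain, and says
nothing about performance on experimentally ascertained riboSNitches.

What passing these studies does *not* show: recovery under realistic
mutational signatures (96-class mixtures), long transcripts with windowed
folding, thermodynamically realistic ensembles, overlapping genes, or the
absolute AUC levels reported for experimental benchmark sets.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_W` | 200 nt | local folding window; also the span of profile averaging |
| `max_span_L` | `window_W` (50 in the study config) | maximal base-pair span $j-i+1$ |
| `min_hairpin` | 3 nt | minimal loop closed by a pair |
| `pair_weight` | 2 | Boltzmann weight per pair (internal backend) |
| `stack_bonus` | 8 (study config) | helix-continuation bonus, `"stack"` model |
| `w` | 200 genome-scale, 15 in the fixture studies | half-window of MeanDiff/EucDiff |
| `top/bottom_fraction` | 0.025 | dual-tail call fractions |
| `n_sims` | 1000 (200 in bundled studies) | simulated mutations per element |
| cancer-specific threshold | p < 1e-3, strict | somatic-vs-germline Fisher |

Whether the genome-scale difference window means a half-window of 200 or a
total span of 200 is ambiguous in the source protocol; it is exposed as the
half-window parameter `w` and recorded in every output.

## Numerical choices and degenerate inputs

Quantiles use type 7 interpolation; ties at thresholds are included in the
tail. Degenerate Fisher tables (empty margins) return p = 1. Mutations with
N in their trinucleotide context or within 1 nt of a transcript end are
excluded from classification (classes `NA`) but still scored. Multi-allelic
VCF records are split; indels and non-variants are dropped on input.
Mutations overlapping several genes' principal transcripts are assigned to
all of them. The partition function guards against overflow and asks for a
smaller window or weight rather than returning nonsense; at the default
weights overflow needs windows far beyond 200 nt.

## A small worked run

```{r, eval = FALSE}
fix <- make_genome_and_annotation(fixture_spec(seed = 1))
cfg <- fold_config(max_span_L = 50, pair_weight_model = "stack",
                   stack_bonus = 8)
coh <- make_mutation_cohort(fix, cfg, w = 15)
scan <- element_scan(fix$genome, fix$transcripts, coh$somatic,
                     germline = coh$germline, config = cfg, w = 15,
                     n_sims = 200, seed = 1)
print(scan)
subset(scan$results, q_enriched < 0.05 | q_depleted < 0.05)
```

## Known limitations

* The internal ensemble is a two-parameter caricature of RNA
  thermodynamics; absolute pairedness values are not comparable to
  ViennaRNA's, only the pipeline logic is. The RNAplfold backend exists for
  real applications.
* Windowed folding recomputes overlapping windows; scoring long transcripts
  at single-nucleotide window steps is expensive and is the main cost of
  genome-scale use.
* The neutral model inherits every bias of intronic mutation calls and
  carries no covariates (replication timing, expression, chromatin).
* Power for cancer-specificity at p < 10⁻³ requires more mutations per
  element than enrichment itself; at fixture scale only strong contrasts
  clear it.
* Element-level BH stratification (by class and direction) is one of
  several defensible families; results at the boundary can move between
  strata conventions.
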