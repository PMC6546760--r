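# ribosnitch

Detection of RNA-structure-disrupting variants (riboSNitches) and of
transcript elements under selection on RNA shape, from somatic or germline
SNV cohorts.

RNA secondary structure in UTRs and noncoding RNAs mediates miRNA and
RNA-binding-protein interactions, stability and translation. A variant that
reshapes local structure can therefore be functional even when sequence
conservation says nothing. This package is for computational biologists who
want to (a) score individual SNVs for structural disruption, (b) call
riboSNitches cohort-wide, and (c) find UTRs/lncRNAs where riboSNitches are
significantly enriched (candidate positively selected, driver-like
elements) or depleted (candidate structurally constrained, essential
elements) relative to a neutral mutation model.

## The method

For a mutation at mature-transcript position *k*, fold the reference and
mutated mature sequence, take per-position pairing probabilities BPP, and
compute over a window of half-width *w*:

    MeanDiff_k = Σ_{i=k-w..k+w} |BPP_ref,i − BPP_alt,i| / (2w+1)
    EucDiff_k  = sqrt( Σ_{i=k-w..k+w} (BPP_ref,i − BPP_alt,i)² )

Mutations in the top 2.5% of **both** statistics are riboSNitches; bottom
2.5% of both are non-riboSNitches. Per element, the expected riboSNitch
count under neutrality comes from simulating mutations drawn from the
cohort's intronic 96-class trinucleotide profile, recalibrated to the
element's 32-class composition, scored identically and calibrated on the
pooled simulated distribution. Observed vs expected contingencies are
tested with one-sided Fisher's exact tests (both directions),
BH-corrected within element class; somatic-vs-germline contrasts at
p < 1e-3 flag cancer-specific elements.

Folding backends: an internal McCaskill-style pair-weight partition
function (exactly verifiable against exhaustive structure enumeration —
this is what the tests pin down to 1e-9) and an RNAplfold adapter
(`read_plfold_lunp()`, or shelling out to `RNAplfold`) for thermodynamic
ensembles.

## Worked example

Everything below runs on synthetic data generated by the package itself.

```r
library(ribosnitch)

fix  <- make_genome_and_annotation(fixture_spec(seed = 3))
cfg  <- fold_config(max_span_L = 50, pair_weight_model = "stack",
                    stack_bonus = 8)
coh  <- make_mutation_cohort(fix, cfg, w = 15)
scan <- element_scan(fix$genome, fix$transcripts, coh$somatic,
                     germline = coh$germline, config = cfg, w = 15,
                     n_sims = 60, seed = 3)
print(scan)
```

```
element_scan: 34 elements, 1170 somatic scores, n_sims=60
  enriched (q<0.05): 2, depleted (q<0.05): 2
  cancer-specific (p<1e-3): 4
```

The scan mapped 1170 somatic SNVs onto 34 UTR/lncRNA elements of the
20-gene toy genome, called riboSNitches by the dual 2.5% tail rule, and —
comparing observed counts with 60 neutral simulations per element — found
exactly the four planted elements: two riboSNitch-enriched (the planted
10× selection signal) and two depleted, all four absent from the matched
germline cohort and hence cancer-specific. `scan$results` holds the full
per-element table (counts, odds ratio, p/q in both directions, calls at
q ∈ {0.05, 0.1, 0.2}, cancer-specificity).

The same pipeline is scriptable from a shell:

```sh
exec/ribosnitch fixtures  --seed 3 --out fx
exec/ribosnitch score     --genome fx/genome.fa --gtf fx/annotation.gtf \
                          --mutations fx/somatic.tsv --out sc
exec/ribosnitch call      --scores sc/scores.tsv --out calls
exec/ribosnitch elements  --genome fx/genome.fa --gtf fx/annotation.gtf \
                          --somatic fx/somatic.tsv --germline fx/germline.tsv \
                          --sims 60 --seed 3 --out el
exec/ribosnitch benchmark --n-pairs 500 --out bm
```

Scoring discrimination on the built-in hairpin benchmark (SNVs centered in
101-nt inputs; stem-breakers vs loop substitutions):

```
   w auc_meandiff auc_eucdiff auc_intersection
1  5            1           1                1
2 25            1           1                1
```

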