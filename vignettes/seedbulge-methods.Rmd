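---
title: "Methods: CG-seed miRNAs and their bulge targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CG-seed miRNAs and their bulge targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedbulge)
```

## The problem

Canonical miRNA target prediction rests on the seed rule: a 3'UTR is a
target when it carries the perfect Watson-Crick complement of the miRNA
seed (mature positions 2-7, or 2-8 in the 7-mer convention used here).
Seeds that contain a CG dinucleotide are special: in mammalian genomes the
cytosine of a CpG is methylation-prone and deaminates to thymine at an
elevated rate, so the CpG inside a *target* site decays quickly over
evolutionary time, while the miRNA gene itself — under stronger selection —
keeps its CG. Such miRNAs end up with strikingly few conserved canonical
targets. The hypothesis this package operationalises is that they instead
retain a compensating class of *bulge targets*: sites carrying one extra
nucleotide between the two target bases that pair the seed's C and G, so
the duplex forms with a single-nucleotide bulge while all seed bases remain
paired.

The pipeline has six analysis stages, each exercised end to end on
synthetic data with planted ground truth:

1. **Target discovery** — seed extraction, CG-dimer classification,
   canonical site search, CG-bulge pattern enumeration, random-bulge
   controls.
2. **Conservation** — projecting each site through a multi-species
   alignment and counting the species in which it is intact.
3. **Mutation rates** — MAF-binned, neutrally normalised CpG vs non-CpG
   mutation profiles in miRNA loci and binding sites.
4. **Expression correlation** — Spearman correlation of targets with their
   miRNA across samples, against a resampled random-gene null.
5. **Duplex energy** — simplified nearest-neighbor minimum free energy of
   the site duplexes.
6. **CLASH chimeras** — splitting chimeric reads into miRNA and target
   parts, classifying the interaction, and measuring CG-bulge enrichment
   against shuffle and scramble nulls.

## Site classes and the definition of a bulge control

For a seed `s` (RNA), the canonical site pattern is the DNA reverse
complement of `s`, searched on the UTR sense strand only (miRNA targeting
is strand-specific). Overlapping occurrences are all reported; `N` bases
never match. CG-bulge patterns insert each of the four bases between the
target-side C and G of every CG dimer in the match pattern (the target-side
reading of the bulge follows the duplex geometry: the extra base sits
between the two bases that pair the seed's C and G).

Random-bulge controls insert a random base at a random insertion point of
the match pattern. Two refinements define the control class precisely:

* **Interior points only.** A base prepended or appended to the match
  pattern does not interrupt any base pair — the site still contains a
  perfect canonical match and *is* a canonical site. End insertions are
  therefore not bulges and are excluded.
* **No canonical containment.** Inserting a copy of a neighbouring base
  (e.g. a `T` next to an existing `T`) can likewise leave the intact 7-mer
  present in the 8-mer. Any (point, base) combination whose pattern still
  contains the canonical match is excluded, from the control sampler, from
  the pattern-mode conservation accept set, and from the CG-bulge planting
  step of the synthetic generator.

Without these exclusions the site classes are not disjoint: every
canonical occurrence doubles as an "end-insertion control" occurrence and
class comparisons are contaminated in both directions. The insertion point
is drawn uniformly over the legal points, then the base uniformly over
that point's legal bases, so the insertion-point distribution is uniform
over legal points by construction.

## Conservation scoring

Sites are mapped to genome coordinates (0-based half-open everywhere
internally; 1-based only at VCF ingestion) and projected through the MAF
alignment blocks covering them: for each species, the gap-stripped
subsequence under the reference columns spanning the site, with internal
insertion columns included and projections stitched across blocks whose
reference coordinates are contiguous. Sites crossing a break between
blocks are excluded from the denominator (not scored 0) and counted.

Intactness has two modes. `exact` requires the species' subsequence to
equal the site pattern and is the default for canonical sites. `pattern`
accepts any pattern of the same class for the same seed — a bulge site
conserved with a different bulge base is biologically the same class — and
is the default for CG-bulge and control sites. The conservation rate is
the number of intact species (the reference always counts, so rates live
in `1..n_species`). The species set is whatever the alignment provides; 23
is the configured default, not a constant. Class comparisons use two-sided
Wilcoxon rank-sum tests with group medians and directions.

## Mutation-rate profiles

Variants are read from VCF (biallelic SNVs only; alternate-allele
frequencies folded onto the minor allele, idempotently), assigned to
regions by interval overlap, and classified by dinucleotide context:
CG-class iff the reference base participates in a CpG on either strand,
with a C-to-T flag for deamination changes (C>T, or G>A on the
complementary strand). Counts are binned by MAF into left-open
right-closed bins with default edges 0.001, 0.005, 0.01, 0.05, 0.1, 0.5 —
only the first edge is dictated by the rare-variant range; the rest are
configuration — and normalised as

```
normalized = raw * 1000 / (n_synonymous * gene_length)
```

The normalisers (synonymous-variant count and length of the nearby gene,
with the mean length for pooled profiles) make the values rate-like
relative to neutral expectation; the product-denominator form and the
factor 1000 are the package's modelling choice, stated prominently because
only the ingredients, not their algebraic combination, are standard.

Two comparisons are provided. A two-sample KS test compares distribution
shape, either on the per-variant MAF samples (default — that is what a KS
test is for) or on the per-bin normalised values. Because a pure *rate*
difference with a shared MAF law is invisible to a shape test, the
directional claim — binding-site CpG mutates more than miRNA CpG — is
tested by an exact conditional binomial rate-ratio test of the two counts
against their CpG-position exposures.

## Expression and transfection tests

Per-gene Spearman correlations with the miRNA vector use pairwise-complete
samples (no imputation) and need at least 3 shared samples. The null is
built by drawing the same number of genes at random (default 1000 draws,
without replacement within a draw) from the expressed genes *excluding*
the miRNA's own predicted targets — the exclusion avoids null
contamination and is toggleable. Group comparisons are two-sided Wilcoxon
tests with medians. Transfection tests are one-sided Mann-Whitney tests
(the direction — down after over-expression, up after knock-down — *is*
the hypothesis); genes in both target and control sets are dropped from
the control with a warning.

## Duplex energies

`duplex_mfe()` is an intermolecular-only dynamic program: Watson-Crick and
(by default) G:U pairs, nearest-neighbor stack energies for consecutive
pairs, affine penalties for single-strand bulges and internal loops, no
intramolecular structure, empty pairing = 0 so the MFE is never positive.
The shipped parameter table carries the ten canonical Watson-Crick RNA
stack free energies at 37 °C from the standard nearest-neighbor set,
expanded by rotational symmetry; stacks involving a wobble pair use a
single simplified value (-1.0 kcal/mol), and loop penalties are affine
(bulge 3.8 + 0.5/nt, internal loop 4.0 + 0.5/nt). The table is a plain TSV
and swappable. Loop spans are capped at 10 unpaired bases per side, which
is never binding for the seed-region duplexes scored here (site pattern
plus 3 flanking bases against the mature 5' region through the seed plus 3
bases). Equal-energy structures resolve deterministically by a fixed scan
order. This is a deliberate simplification of full hybridisation tools:
parity with them is a non-goal, and the class comparison it feeds is
reported but not used as a recovery criterion — with one bulge on each
side, the energy difference between a CG-gap bulge and a random interior
bulge is a sequence-context effect the simplified model is not guaranteed
to reproduce.

## CLASH classification

Chimeric reads are split by matching catalog mature sequences against the
read prefix (or suffix, configurable) with at least 16 matched bases and
at most one mismatch (chimeras carry ligation and sequencing errors);
ambiguous multi-miRNA matches stay unassigned. Interaction classes are
assigned with a fixed precedence — canonical seed, CG-bulge, G:U wobble
(≥1 wobble, no defect), one-nucleotide mismatch, other bulge,
unclassified — because a read can satisfy several patterns and the
literature does not define an order; the precedence puts the more specific
interpretation first. The shuffle null permutes target parts across
assigned reads (identity permutations allowed); the scramble null permutes
the nucleotides within each target part, preserving length and
composition exactly, and is re-searched for patterns directly. Direct
re-search replaces genome remapping of scrambled reads: remapping needs an
aligner and a genome, and the combinatorial background it estimates is the
same quantity direct search measures. This is the pipeline's one
intentional procedural substitution. Enrichment uses two-proportion
z-tests without continuity correction (calibrated at the read counts used
here) plus per-class fold enrichments and the aggregate
non-canonical : canonical ratio.

## The synthetic generators and what they do (not) show

Every input format the pipeline reads can be generated with planted truth:
miRNA catalogs with and without seed CGs; UTR cohorts with planted
seed/bulge/control sites and an ungapped alignment in which each
non-reference species retains each site independently with its class's
retention probability (a broken site gets one substitution at a non-bulge
position, redrawn until it actually leaves its class's accept set — a
single substitution can otherwise convert one legal bulge pattern into
another); population variants with a rare-dominated MAF mixture (90%
uniform on (1e-5, 0.001], else uniform on (0.001, 0.5]) and a CpG rate
multiplier in binding sites only; expression matrices with
Spearman-targeted coupling through a Gaussian copula (Pearson parameter
`2 sin(pi rho / 6)`); transfection fold changes with planted shifts; and
chimera mixtures built constructively with the classifier as oracle.

The default study conditions are: 200 planted sites per class, 23 species,
retention 0.7 (seed, bulge) vs 0.3 (control), divergence 0.1; CpG
multiplier 10 at base rate 0.05 against a 400-locus miRNA complement
(giving on the order of a thousand variants); correlations -0.6 / -0.35
over 12 samples with 100 genes per group against 1000 background genes;
transfection shifts of 0.4 log-units on 150 targets; and a 30/50/20
canonical/CG-bulge/other chimera mixture over 300 reads. UTRs default to
500 nt and uniform base composition (a CpG-depleted mode approximating
mammalian UTR composition is available, because the background rate of
CG-containing patterns drives bulge-search specificity).

What passing recovery tests shows: the statistics detect their planted
effects at these sizes and are calibrated under the null (each test's
rejection rate at 5% sits inside the exact binomial 99% interval over
1000 null replicates). What it does not show: performance on real data.
Species retention is i.i.d., not phylogenetic; alignments are ungapped;
background composition is at best first-order; expression noise is
Gaussian; chimeras carry no adapter or processing artefacts. The printed
vertebrate-miRNA count table ships as a fixture and its group statistics
(8 CG seeds of 60; integer-truncated group means 28 vs 282; per-row
ratios rounded to 4 decimals, matching the printed display conventions)
are recomputed from it, but genome-scale target counts, real 1000-Genomes
profiles and real CLASH counts require the external resources and are out
of scope at desk scale.

## Numerical and display conventions

* Per-row conservative/total ratios are *rounded* to 4 decimals — checked
  against the printed table, rounding reproduces all 60 rows while
  truncation fails on 24 — whereas the printed group means are
  *integer-truncated* (28.625 prints as 28). Both exact and display values
  are returned.
* MAF bins are right-closed; a MAF equal to an edge falls in the lower
  bin. MAF folding is idempotent.
* Wilcoxon tests use the normal approximation (`exact = FALSE`) for
  stable behaviour with ties. Discrete test statistics use the mid-p
  convention (half weight on the observed outcome): the conditional
  binomial rate test and the exact two-sample KS test are otherwise
  conservative at the per-class counts arising here (the exact KS level
  measures ~0.044 at 400-per-group samples; mid-p restores ~0.05). With
  materially tied samples the KS falls back to the asymptotic p-value.
* All generators are pure functions of their parameters and an integer
  seed; the end-to-end report is byte-identical across reruns with the
  same seed.

## Known limitations

* The MAF reader requires reference rows on the + strand for projection;
  minus-strand UTRs are handled by reverse-complementing projections.
* The consequence annotation behind the synonymous-count normaliser is not
  computed from real annotation; synthetic truth supplies it directly, and
  real use expects a precomputed normaliser table.
* G:U-containing stacks share one energy value; absolute MFE values are
  therefore indicative, and only within-pipeline comparisons are
  meaningful.
* The CLASH miRNA assignment is prefix/suffix matching, not alignment;
  reads with internal indels in the miRNA part stay unassigned.
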