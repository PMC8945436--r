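# seedbulge

Analysis pipeline for microRNAs that carry a **CG dinucleotide in their
seed region** and the non-canonical **bulge target sites** they can
recognise.

## The scientific problem

Canonical miRNA targeting follows the seed rule: a 3'UTR is a target when
it contains the perfect Watson-Crick complement of the seed (mature
positions 2–8 in the 7-mer convention used here). CpG cytosines are
methylation-prone and hypermutable in mammalian genomes, so for a miRNA
whose seed contains a CG dimer, the CpG inside each *target* site decays
quickly while the miRNA gene itself stays conserved — leaving these
miRNAs with strikingly few conserved canonical targets. The compensating
hypothesis is a class of **bulge targets**: sites with one extra
nucleotide inserted between the two target bases that pair the seed's C
and G, so the duplex

```
 5' ...N N N N C x G N N... 3'   mRNA  (x = bulged nucleotide)
        | | | |   | | |
 3'  ...N'N'N'N' G C N'...  5'   miRNA seed
```

forms with a single-nucleotide bulge and every seed base still paired.

The package provides, for whoever needs to search for and validate such
sites (regulatory genomicists, miRNA target-prediction developers):

* seed extraction, CG-dimer classification, canonical seed-site search,
  CG-bulge pattern enumeration and random-bulge controls
  (`extract_seed`, `find_cg_dimers`, `find_seed_targets`,
  `enumerate_bulge_patterns`, `generate_random_bulge_controls`);
* conservation-rate scoring of sites through multi-species alignments
  (`read_maf`, `project_site`, `score_conservation`,
  `compare_site_classes`);
* MAF-binned, neutrally normalised CpG vs non-CpG mutation profiles from
  population variants, with `normalized = raw × 1000 / (n_syn × L)`
  (`read_vcf_snvs`, `classify_variants`, `mutation_profile`,
  `compare_profiles`, `rate_ratio_test`);
* miRNA–target Spearman correlation against resampled random-gene nulls
  and one-sided transfection shift tests (`spearman_profile`,
  `random_gene_null`, `compare_rho_groups`, `transfection_shift_test`);
* simplified nearest-neighbor duplex minimum-free-energy scoring
  (`duplex_mfe`, `compare_mfe_classes`);
* CLASH chimeric-read splitting and interaction classification with
  shuffle/scramble nulls (`split_chimera`, `classify_interaction`,
  `enrichment_report`);
* synthetic-data generators with planted ground truth for every input
  format, and an end-to-end reproduction with recovery checks
  (`gen_*`, `reproduce_synthetic`, `calibrate_null_rejection`).

The methods vignette (`vignettes/seedbulge-methods.Rmd`) documents the
models, parameter choices and limitations.

## Worked example

Classify a printed vertebrate-conserved miRNA count table by seed CG
content (the 60-row table ships with the package):

```r
library(seedbulge)
tbl <- read_tsv_table(system.file("extdata",
        "vert_mirna_targetscan_counts.tsv", package = "seedbulge"))
st <- conserved_target_stats(tbl)
c(n_cg = st$n_cg, mean_cg = st$mean_cg_trunc, mean_noncg = st$mean_noncg_trunc)
#>      n_cg    mean_cg mean_noncg
#>         8         28        282
st$per_row$ratio[st$per_row$mirna_id == "hsa-mir-126"]
#> [1] 0.1328
```

Of the 60 vertebrate-conserved miRNAs, the 8 whose seed carries a CG
dimer average 28 conserved targets; the other 52 average 282 — a
ten-fold deficit that motivates the bulge-target search.

Run the full synthetic study (generates every input with planted truth,
round-trips it through FASTA/BED/MAF/VCF/TSV, and checks that each
analysis stage recovers its planted ordering):

```r
rep <- reproduce_synthetic(rng_seed = 1)
rep
#> Synthetic-study reproduction (seed 1)
#>
#>                          check   value   p_value pass
#>   conservation_seed_gt_control  6.0000  2.65e-30 TRUE
#>  conservation_bulge_gt_control  6.0000  1.28e-20 TRUE
#>         cpg_rate_site_gt_mirna 11.7700 2.35e-117 TRUE
#>            expression_ordering -0.4720  2.81e-39 TRUE
#>        transfection_directions -0.4661  1.31e-21 TRUE
#>      clash_cg_bulge_enrichment  7.8950  1.34e-32 TRUE
#>
#> Overall: all planted orderings recovered
```

Reading the rows: seed and CG-bulge sites sit a median 6 species above
the random-bulge control in conservation; binding-site CpGs mutate at
~12× the per-site rate of miRNA-locus CpGs; bulge-target correlations sit
0.47 below the random-gene null median; bulge targets drop a median 0.47
log-units after simulated over-expression; and the CG-bulge chimera class
is ~8-fold enriched over the shuffle null.

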