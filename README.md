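# baxsplice

Quantification of BAX exon 2 skipping from bulk RNA-seq junction reads.

## The problem

Alternative splicing that removes exon 2 from the BAX transcript produces
the Bax∆2 isoform. Without the exon-2-encoded helix, Bax∆2 cannot target
mitochondria; the frameshifted protein aggregates in the cytosol and is of
interest in Alzheimer's disease, where skipping is markedly more prevalent
in patients than in unimpaired controls. Measuring the event in a cohort
requires counting, per sample, the RNA-seq reads that span the diagnostic
splice junction of each isoform:

* **ALPHA** — reads crossing the exon-1/exon-2 junction (canonical Baxα),
* **DELTA2** — reads crossing the exon-1/exon-3 skip junction (Bax∆2),

and forming the per-sample percent-skipped statistic

```
pct_skipped = 100 · n_delta2 / (n_alpha + n_delta2)
```

the skipped-isoform share of junction evidence (the two-isoform analogue of
PSI). A sample *contains* skipping when at least one skip-junction read
survives all filters; per-group **prevalence** is the percentage of such
samples.

`baxsplice` implements the full pipeline for users who want to run or audit
this analysis: reference modelling (canonical transcript + exon model →
derived skipped isoform → diagnostic window, default bases 30–40),
competitive junction-read classification (deterministic affine-gap local
alignment, or ingestion of primary SAM/BAM records — `samtools view -F 256`
semantics), per-sample quantification, de-identified cohort tables (sample
ids replaced by unlinked numbers, sequences masked with `N` runs), and the
case-control statistics: prevalence, Mann–Whitney rank-sum on
`pct_skipped`, sex-stratified contrasts and one-way ANOVA across APOE
genotypes. Because the original cohorts are controlled-access, a seeded
simulator (reads plus whole mock cohorts with a zero-inflated-Beta skipping
distribution) makes every stage testable against known truth.

## Worked example

Simulate a 60 + 60 mock cohort under the study-like design (expected
skipping prevalence 85% in AD, 48% in NCI), run the pipeline, and read the
statistics panel:

```r
library(baxsplice)

pair <- synthetic_bax_pair()            # synthetic stand-in reference pair
design <- cohort_design(n_per_group = c(AD = 60L, NCI = 60L),
                        n_reads = 600L)
sim <- simulate_cohort(pair, design, "cohort_fastq", seed = 11)
manifest <- data.frame(sample_id = sim$metadata$sample_id,
                       reads_path = unname(sim$fastq_paths))
res <- run_pipeline(manifest, pair, metadata = sim$metadata_path,
                    out_dir = "results_demo", seed = 11)
res$stats
```

```
Cohort group comparisons
        contrast       statistic n_a n_b value   p_value p_bonferroni    note
   prevalence|AD      prevalence  60  NA 81.67        NA           NA percent
  prevalence|NCI      prevalence  60  NA 46.67        NA           NA percent
       AD_vs_NCI prevalence_diff  60  60    35 0.0001404    0.0007019    <NA>
       AD_vs_NCI  mann_whitney_U  60  60  2754 3.037e-07    1.519e-06    <NA>
 AD_vs_NCI|sex=F  mann_whitney_U  49  44  1668 3.072e-06    1.536e-05    <NA>
 AD_vs_NCI|sex=M  mann_whitney_U  11  16 135.5   0.01879      0.09397    <NA>
     across_apoe         anova_F 120  NA 1.445    0.2237          1.0    <NA>
```

Reading the output: the measured prevalences (81.7% AD, 46.7% NCI) recover
the generating expectations (85% / 48%) within binomial noise at n = 60;
the rank-sum test detects the group difference in `pct_skipped`
(p ≈ 3·10⁻⁷); the contrast is carried by both sex strata in this replicate;
and `pct_skipped` shows no association with APOE genotype (p = 0.22), as
none was simulated. `res$table` is the de-identified per-sample table that
`write_summary()` renders as the tab-delimited release file:

```
 sample_id group sex apoe n_alpha n_delta2 pct_skipped has_splicing
         1   NCI   F   33     104        0     0.00000        FALSE
         2   NCI   M   33      89        0     0.00000        FALSE
         3    AD   M   34      91       23    20.17544         TRUE
         4   NCI   F   33      96        0     0.00000        FALSE
```

Real data enter the same way: `load_reference()` on a FASTA plus an exon
TSV, `build_skipped_isoform()`, `set_junction_window()` (default 30–40),
and a manifest pointing at FASTQ or SAM/BAM files. A thin command-line
wrapper with `simulate`, `classify`, `quantify`, `stats` and `run`
subcommands ships in `inst/scripts/baxsplice.R`.

## Method notes

The methods vignette (`vignettes/bax-exon2-skipping.Rmd`) documents the
junction rule and its default thresholds, what the simulator does and does
not emulate, the estimator's target under the read-level mixture, the
statistical conventions (tie handling, sidedness, degenerate ANOVA cases,
NA policy), de-identification, and known limitations.
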