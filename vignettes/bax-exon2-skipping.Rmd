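---
title: "Quantifying BAX exon 2 skipping from junction-spanning reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying BAX exon 2 skipping from junction-spanning reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baxsplice)
```

## The event and the statistic

The BAX gene encodes six exons. Alternative splicing that removes exon 2
produces the Bax-delta2 isoform: the exon-2-encoded helix needed for
mitochondrial targeting is lost, the reading frame shifts at the start of
exon 3, and the protein aggregates in the cytosol instead of acting at the
mitochondrial membrane. At the transcript level the two isoforms differ
only in the presence of the exon-2 block, so bulk RNA-seq can measure the
event through reads that span the diagnostic splice junction:

* canonical isoform (Bax-alpha): reads crossing the exon-1/exon-2 boundary;
* skipped isoform (Bax-delta2): reads crossing the exon-1/exon-3 boundary.

Because the two references are identical upstream of the junction, both
junctions sit at the same transcript coordinate (the last base of exon 1),
and a short window around it -- bases 30 to 40 on both references by
default -- is diagnostic: a read whose primary alignment covers the window
can be attributed to exactly one isoform.

For a sample with `n_alpha` canonical-junction reads and `n_delta2`
skip-junction reads, the per-sample statistic is the skipped share of
junction evidence,

$$\text{pct\_skipped} = 100 \cdot \frac{n_{\Delta 2}}{n_\alpha + n_{\Delta 2}},$$

the percent-spliced-out analogue of PSI restricted to this two-isoform
event. A sample *contains* skipped transcripts when at least
`min_skip_reads` (default 1) skip-junction reads survive all filters; group
prevalence is the percentage of such samples per diagnosis group. No length
normalization enters the ratio: both junction windows have the same width
by construction, so the junction-read share needs no correction for
reference length.

## Competitive junction-read classification

Each read is aligned locally (affine-gap Smith-Waterman-Gotoh, both
orientations) against both references, and each reference is tested
against the *junction rule*. A reference satisfies the rule when the read's
best local alignment to it

1. covers the whole diagnostic window (`full_window` mode; an
   `any_overlap` mode is available for sensitivity experiments),
2. is gapless inside the window,
3. has at least `min_anchor` aligned bases on each side of the junction
   position, and
4. has at most `max_mismatch_in_window` mismatches inside the window.

The satisfying reference with the strictly higher alignment score wins
(`ALPHA` or `DELTA2`). If both satisfy the rule with equal scores the read
is `AMBIGUOUS` -- ties are never broken arbitrarily, because an arbitrary
rule would bias the ratio. Reads satisfying neither reference, including
the majority that align entirely within shared exons, are `NON_JUNCTION`
and are excluded from the ratio denominator. The four class counts always
sum to the number of reads processed.

Rationale for the defaults:

* `min_anchor = 5`, `max_mismatch_in_window = 1`: the two junction k-mers
  (5 bases either side of the boundary) differ at `min_anchor` positions
  right of the junction, so a single sequencing error can reduce a read's
  evidence but can never convert it into valid evidence for the *other*
  isoform -- that would require `min_anchor - 1` or more coordinated
  substitutions.
* `full_window` coverage: a rule accepting any overlap with the window
  would admit reads that touch base 30 without crossing the junction;
  requiring full coverage makes every counted read genuinely
  junction-spanning.
* Scoring (`match 2, mismatch -3, gap open -5, gap extend -2`): standard
  short-read local-alignment weights; `N` never scores as a match in
  either sequence. Traceback tie-breaks are fixed (diagonal, then gap in
  read, then gap in reference; earliest reference coordinate wins), so the
  classifier is fully deterministic.

Pre-computed alignments are ingested from SAM/BAM as an alternative input
path: only mapped primary records are used (FLAG bits 0x4 and 0x100 unset,
the `samtools view -F 256` filter), mismatch positions are taken from the
MD tag or recomputed against the reference, and records whose in-window
mismatch count cannot be established are classed `AMBIGUOUS` rather than
guessed. Paired-end mates are classified independently and merged to one
call per fragment; conflicting informative mates become `AMBIGUOUS`.

## What the simulator emulates

The controlled-access frontal-lobe cohorts behind the original analysis
cannot be redistributed, so the package ships a generative stand-in with
two layers.

**Reads.** `simulate_sample_reads()` draws each read's source isoform as
Bernoulli(`fraction_skipped`), a uniform start position among all positions
where the read fits, and independent per-base substitutions (default rate
0.5%). There is no fragment-length model, no positional bias and no
quality model (constant `"I"`); the statistic only needs junction coverage,
and the simple model keeps every property provable against closed-form
oracles. Read ids carry no information about the truth, which lives only
in a separate truth table.

**Cohorts.** `cohort_design()` describes a case-control cohort in the
image of the published one: 324 AD / 327 NCI samples by default, sex
frequencies per group and APOE genotype frequencies matching the published
panel counts, and ages from a truncated normal (mean 85, sd 6, range
70-104, the study population being elderly). The per-sample true skipping
fraction follows a zero-inflated Beta: a point mass at zero (a sample with
no skipping at all) plus a Beta tail. The defaults are
$\pi_{AD} = 0.15$ with Beta(2, 8) and $\pi_{NCI} = 0.52$ with
Beta(1.5, 12), chosen so the *expected prevalences* are 85% and 48% -- the
two published prevalence figures -- while the Beta tails give the AD group
the heavier skipping distribution. The per-sample distribution of skipping
ratios is not published; the zero-inflated Beta family reflects the
published pattern of many zero-ratio samples plus a long positive tail,
and every parameter is configurable.

A counts-level mode (`simulate_counts_cohort()`) draws the junction-read
depth as Poisson and the skip-junction count as Binomial directly -- the
distribution an unbiased classifier samples from -- and is used for
statistical replicate studies where base-level reads add nothing.

**What passing tests do and do not show.** The simulator validates the
pipeline's *inferential machinery*: that the classifier recovers known
mixtures, that prevalence and rank-sum statistics recover generating
parameters, and that the null calibration holds. It does not emulate
Illumina error profiles, indels, coverage bias, degradation, or expression
of the rest of the transcriptome, so passing tests certify correctness of
the method, not performance on any particular real library.

## What the estimator targets

Under the read-level mixture above, the skipped isoform is the shorter
transcript, so a uniformly placed read covers the junction window with
slightly higher probability on the skipped reference. The junction-read
share therefore estimates the *skipped fraction of junction-spanning
reads*, which is what recovery tests compare against (they compute it from
the truth table). In real RNA-seq, where read counts scale with transcript
length, the two isoforms expose identical numbers of junction-covering
start positions, so the junction-read share estimates the molecule
fraction directly. At 500 or more junction reads and the default error
rate, estimates sit within three binomial standard deviations of the truth
in at least 99% of seeded runs, and a sample simulated with fraction zero
yields exactly 0% -- the single-error tolerance cannot manufacture
skip-junction evidence.

## Statistics

The cohort layer reproduces the published analysis panel:

* per-group prevalence of skipping, with a two-proportion test on the
  difference;
* Mann-Whitney rank-sum comparison of `pct_skipped` between diagnosis
  groups (midrank ties; exact enumeration for pooled samples up to 12
  without ties, otherwise the normal approximation with tie-corrected
  variance and continuity correction -- the only practical choice at
  cohort scale);
* the same contrast within each sex stratum (strata under 3 samples per
  arm are reported as skipped);
* one-way ANOVA of `pct_skipped` across APOE genotypes.

All tests are two-sided; the original figures annotate symmetric
significance stars and state no sidedness. Samples with no junction reads
(`NA` percentage) are excluded from rank-sum and ANOVA comparisons but
remain in prevalence denominators, and the choice is recorded in the
report. Panels are reported without multiple-testing correction, matching
per-panel reporting in the source analyses; a Bonferroni column is emitted
alongside for transparency. Degenerate ANOVA inputs follow explicit
conventions: zero within-group variance with separated means gives
`F = Inf`, `p = 0`; no variance at all gives `p = NA`.

## De-identification

Before a cohort table leaves the pipeline, sample identifiers are replaced
by sequential numbers assigned in a seeded random order, and any
nucleotide-sequence column is replaced by an `N` run of equal length; SAM
exports can likewise be masked. The original-to-new mapping is written
only to a separate, optional file that is never part of the released
outputs. An audit test greps every released file for original identifiers
and for unmasked bases.

## Numerical and design choices

* **Coordinates.** All coordinates, internal and user-facing, are 1-based
  inclusive -- the convention of the R/Bioconductor ecosystem the package
  lives in, and of the "bases 30 to 40" window specification. Junction
  positions are stored as the last base before the splice boundary, and
  the window must span the boundary on both references or it is rejected
  as non-diagnostic.
* **Derived skipped reference.** The skipped isoform is always derived
  from the canonical transcript plus its exon model, guaranteeing the pair
  differs exactly by the skipped exon; an independently obtained skipped
  sequence can be supplied and is then validated against the derivation.
* **Synthetic reference pair.** `synthetic_bax_pair()` is a fixed,
  engineered 240-nt six-exon transcript -- not the BAX sequence -- with
  the exon-1 boundary after base 35 so the default window spans the
  junction, junction k-mers that are unique and maximally distinct, and a
  length short enough that simulation studies run in seconds. Real
  references are loaded with `load_reference()` from FASTA plus an exon
  TSV.
* **Problem sizes.** Validation studies use desk-scale versions of the
  cohort design: 60 + 60 samples at 600 reads each for the end-to-end
  recovery study, 100 cohort replicates for power and 2000 for null
  calibration at the counts level, and 10,000 reads for the
  classifier-vs-oracle comparison. These sizes give the binomial bounds
  quoted above while keeping the whole suite fast enough to run routinely.
* **Determinism.** Every stochastic step flows from an explicit seed;
  reruns with identical seeds produce byte-identical FASTQ, tables and
  reports (files are written bytewise with Unix newlines).

## Known limitations

* Only single-exon-skipping events with two isoforms are modelled; the
  event definition is transcript-coordinate based, not genomic (no
  GTF/GFF).
* The internal aligner is a full Smith-Waterman over short references --
  appropriate for a two-reference competitive assay, not a general
  spliced aligner.
* Base qualities are ignored in scoring; the mismatch tolerance plays
  that role.
* The exact normalization used by the original extraction script is not
  published; the junction-read share documented above is this package's
  stated interpretation.

## A worked example

```{r example, eval = FALSE}
pair <- synthetic_bax_pair()
design <- cohort_design(n_per_group = c(AD = 60L, NCI = 60L),
                        n_reads = 600L)
sim <- simulate_cohort(pair, design, "cohort_fastq", seed = 11)
manifest <- data.frame(sample_id = sim$metadata$sample_id,
                       reads_path = unname(sim$fastq_paths))
res <- run_pipeline(manifest, pair, metadata = sim$metadata_path,
                    out_dir = "results", seed = 11)
res$stats
```
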