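---
title: "Assessing PDX genomic fidelity from germline-tumor-xenograft trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing PDX genomic fidelity from germline-tumor-xenograft trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxfidelity)
```

## The problem

Patient-derived xenografts (PDXs) are human tumors propagated in
immunodeficient mice and are widely used for preclinical work. A basic
quality question for any PDX cohort is *genomic fidelity*: does the
xenograft still carry the somatic mutations and copy-number profile of the
primary tumor it came from? `pdxfidelity` answers this from whole-exome
variant calls of matched **trios** — the patient's germline DNA, the primary
tumor, and the derived PDX — by filtering candidate variants to a
comparison-eligible somatic set, then labelling each variant

* **shared** — detected in both primary and PDX,
* **newly detected (N/D)** — meeting detection criteria in the PDX only
  (typically de novo mutations acquired during expansion in the mouse, which
  are expected to be enriched for nucleotide transitions),
* **newly undetected (N/U)** — detected in the primary tumor but lost in the
  PDX (typically low-frequency subclones eliminated at the engraftment
  bottleneck).

## Filtering model

A trio record enters the comparison only if it survives three filters,
applied in a fixed order with *all* failing reasons recorded so that every
downstream count can be audited:

1. **Consequence** — only nonsynonymous coding changes are compared. The
   default vocabulary is missense, stop gained/lost, start lost, frameshift,
   inframe insertion/deletion and splice acceptor/donor terms; it is a
   configurable set because annotation pipelines differ.
2. **Coverage and quality** — every observation present in the trio
   (germline included, when reported) needs depth ≥ 10 reads (inclusive) and
   mapping and base quality strictly > 20. Qualities that the caller did not
   annotate are treated as passing, with a warning at read time, since the
   package does not re-derive alignment statistics.
3. **Germline polymorphism** — a variant present in the patient's germline
   DNA at allele fraction strictly > 0.05 is excluded as constitutional.
   Only the matched germline is consulted; population databases are out of
   scope.

The boundary conventions (≥ 10 inclusive, > 20 and > 0.05 strict) follow the
usual phrasing of these thresholds and are all configurable through
`filter_config()` or a YAML file.

## Classification model

With detection threshold $t = 0.1$ (allele fraction, inclusive) and read
support $m = 3$ alternate reads:

* a variant is **shared** if it has ≥ $m$ alt reads in *both* samples and AF
  ≥ $t$ in at least one;
* failing that, detection on one side only (AF ≥ $t$) gives **N/D** (PDX
  side) or **N/U** (primary side);
* when *both* sides reach $t$ but one lacks the $m$-read support, the
  undersupported sample decides the label (lacking support in the primary →
  N/D; in the PDX → N/U). This tie-break is the package's own choice: it is
  the unique completion of the rules that keeps the label set symmetric
  under swapping the compared samples, which we treat as a defining
  invariant. If neither side has the support, the record is
  **not comparable** — retained and reported, never silently dropped.

"Present in $m$ reads" is read as *alt-supporting* reads rather than total
depth (total depth is already governed by the coverage filter); this is
configurable. N/D variants additionally carry a
`below_threshold_in_primary` flag separating true zeros (AF = 0 in the
primary) from sub-threshold detections (0 < AF < $t$), which distinguishes
de novo mutation from threshold effects.

Summaries follow the reporting conventions of trio concordance studies:
per-model counts of the three labels (stacked-bar ready); pooled median
allele fractions per subtype group — N/D measured in the PDX, N/U in the
primary, shared in both — with the even-$n$ median taken as the midpoint of
the central values and empty cells reported as `NA`, never 0. Group medians
pool variants across a group's models (per-model medians are also emitted);
subtype groups collapse transformed DLBCL into DLBCL and pool the T-cell
entities (AITL, PTCL-NOS, ALCL) into T-NHL. Gene-list annotation marks
variants in per-subtype lists of recurrently mutated genes and reports
per-model N/D and N/U hit sets. The substitution spectrum assigns each SNV
to one of the six pyrimidine-anchored classes and reports the transition
fraction (transitions are A↔G and C↔T); indels are counted separately.

## Copy-number comparison

Segmentation is consumed, not produced: the package reads CNVkit-style
`.cns` tables (0-based half-open, with `cn` and/or `log2`). Log2-only
segments are bridged to integer copy number as `round(2 * 2^log2)`, floored
at 0, with exact .5 ties rounded *away* from the neutral copy number 2 so
borderline segments stay on the aberrant side; the map inverts
`log2(c/2)` exactly for integer `c`. Per-gene categories follow the
ideogram legend convention — "0" biallelic deletion, "1" monoallelic
deletion, "2" neutral, "3" single-allele gain, ">3" higher amplification.
When a gene spans several segments the call comes from the segment covering
the largest fraction of the gene; ties prefer the more extreme category
(larger |cn − 2|), then the deletion side — a deterministic, conservative
rule documented here because segment callers do not dictate one. Genes with
no overlapping segment are neutral with `covered = FALSE` provenance.
Primary-vs-PDX concordance is the fraction of genes with exactly matching
categories.

## What the simulator emulates

`simulate_cohort()` generates a trio with known truth, modelling the two
mechanisms that dominate primary/PDX divergence:

* **Engraftment bottleneck** — the tumor is a truncal background plus
  private subclones (default prevalences 0.6 and 0.4). Each subclone
  survives engraftment independently (default probability 0.9); the PDX
  regrows from truncal cells (which always engraft) plus survivors,
  renormalized. Lost subclones turn their private variants into N/U truth.
* **De novo PDX mutation** — a Poisson number (default mean 30) of PDX-only
  variants, each a transition with probability 0.8, at cellular prevalence
  0.5 in the xenograft.

True allele fractions are `0.5 × purity × (carrier prevalence)`; purity
defaults to 0.8 in the primary biopsy and 1.0 in the PDX, reflecting the
loss of human non-malignant cells in xenografts. Germline polymorphisms sit
at AF 0.5 or 1.0 in all three samples. Read counts are
Binomial(depth, VAF) at negative-binomial depths (default mean 200,
dispersion 0.05); qualities are passing unless a contamination rate is set.
Truth labels are the classifier's own thresholds applied to the noise-free
VAFs — this defines *recoverable* truth, and is stated explicitly because a
simulator cannot adjudicate labels finer than the rules it feeds. The
default prevalences keep every true VAF at least 0.05 away from the 0.1
threshold, so with depth 200 the binomial tails make near-perfect recovery
the correct expectation (and the test suite demands ≥ 99% per-label
accuracy there).

What the simulator does **not** model: sequencing error and mapping
artifacts (no base-level noise), copy-number effects on VAF (diploid
assumption, with segment input available separately), spatial or multi-stage
clonal structure, and mutational context beyond the transition bias.
Passing tests therefore demonstrate the *procedure's* correctness —
thresholds, joins, labels, summaries — not robustness to caller-specific
artifact modes, which the quality filters only partially proxy.

## Numerical and design choices

* Variant keys are minimal and left-anchored (shared suffix then prefix
  trimmed, one anchor base kept for indels); chromosome names are compared
  without the `chr` prefix. Normalization is idempotent.
* AF source precedence: caller's per-sample AF field, else AD-derived
  (`alt/depth`), with provenance recorded. Depth-0 loci are present
  observations with AF 0 — distinct from loci a sample never reported.
* Trio joins are outer joins on the normalized key; duplicate keys within
  one sample are an upstream normalization bug and error out.
* The package is organised in the classic modelling idiom: `pdx_fidelity()`
  is the single fitting-style entry point returning a classed object with
  `print`/`summary`/`plot` methods. `coef`/`predict`/`residuals` methods are
  deliberately absent — the procedure is a deterministic classification, not
  an estimator with parameters to extract.
* Problem sizes in the shipped tests and acceptance script — 12 simulated
  models of ~500 somatic variants at depth 200, 20 replicate seeds for the
  N/D rate check, 1000 de novo draws for the transition fraction — were
  chosen as the smallest sizes at which the binomial/Poisson error bands
  quoted in the tests are decisive.

## Known limitations

Only the matched germline filters polymorphisms (no panel of normals); the
manual IGV-style review step of curated analyses is replaced by, not
reproduced in, the machine-readable exclusion reasons; sex-chromosome
ploidy is not modelled in the CNV categories beyond treating X like an
autosome; and the deposited variant list of any particular published cohort
must be supplied by the user as the harmonized TSV — the package ships only
simulated and fixture data.

## A worked example

```{r example}
sim <- simulate_trio_cohort(3, sim_config(seed = 11))
lists <- read_gene_list(system.file("extdata", "gene_lists.tsv",
                                    package = "pdxfidelity"))
fit <- pdx_fidelity(sim$trios, gene_lists = lists)
fit
summary(fit)$medians
evaluate_recovery(sim$truth, fit$classified)$per_label_accuracy
```
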