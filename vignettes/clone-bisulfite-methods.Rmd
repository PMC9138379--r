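---
title: "Clone-based bisulfite methylation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-based bisulfite methylation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneMeth)
```

## The assay this package models

Clone-based (Sanger) bisulfite sequencing resolves single-molecule
methylation patterns in a targeted region. Genomic DNA is treated with
sodium bisulfite, which deaminates unmethylated cytosine to uracil (read as
T after PCR) while 5-methylcytosine is protected and still reads C. The
region of interest is amplified with primers designed against the
*converted* template, the product is cloned into *E. coli*, and ~10
individual colonies per sample are Sanger-sequenced. Comparing each cloned
read with the unconverted reference reveals, molecule by molecule, which
cytosines carried 5mC.

Plants methylate cytosine in three sequence contexts — CpG, CpHpG and CpHpH
(H = A, C or T) — and the CpHpH marks are "non-canonical". A typical study
of a promoter therefore asks three questions this package answers in code:

1. Where are CpG islands predicted, and do observed marks coincide with
   them?
2. How many of the potential CpG / CpHpG / CpHpH sites are methylated, in
   how many clones (the colony-table summary, cells like "7/50 in 10")?
3. Which cis-regulatory motifs overlap methylated cytosines, per tissue?

## CpG island prediction

`find_cpg_islands()` implements the classical sliding-window criterion:
a window of `window` bp (default 100) slides by `step` (default 1); a
window passes when its G+C fraction is at least `min_gc` (default 0.50)
**and** its CpG observed/expected ratio is at least `min_obs_exp` (default
0.60), where

$$\mathrm{ObsExp} = \frac{N_{CpG} \times L}{N_C \times N_G}.$$

Passing windows whose spans overlap or touch are merged; merged regions
shorter than `min_length` (default 100 bp) are dropped; GC and ObsExp are
then *recomputed on the merged region itself* rather than averaged over
windows, so the reported statistics describe the interval the user sees.
Note the merge is by window span: two passing windows less than one window
apart merge even if a window between them fails. Islands are numbered
"Island 1", "Island 2", ... by start coordinate. `N` bases are excluded
from the GC numerator and denominator, and an all-N window is unclassifiable.
CpG is its own reverse complement, so islands are computed on the top strand
only.

These defaults are the published defaults of the widely used bisulfite
primer-design tools; all are overridable through `island_params()`.

## In-silico PCR and the callable region

Bisulfite primers are written against the fully converted top strand (every
C read as T), with R/Y degeneracies where a primer straddles a cytosine of
unknown state. `in_silico_pcr()` converts the reference under the
all-unmethylated assumption, matches the forward primer on that strand and
the reverse primer on its reverse complement (degenerate codes expand;
reference `N` never matches a concrete primer base), and demands exactly one
orientation-consistent site pair — zero sites is a no-product error, more
than one a non-specificity error listing the candidates.

Cytosines under either primer footprint are unobservable — the synthesized
primer overwrites the template state — so they are excluded both from
calling and from the potential-site denominators. When several overlapping
amplicons cover one gene, denominators deduplicate positions by union. Both
choices are exposed (`include_primer_footprints`) because published colony
tables rarely state them.

## Alignment and calling

Cloned reads are globally aligned to the *unconverted* amplicon with an
asymmetric substitution matrix: at a reference C the read may show C or T at
full match score (the bisulfite channel), every other mismatch scores −1,
match +1, gap opening −3, extension −1. These are ordinary Sanger-clone
tolerances; they are not fitted to any dataset. Reads deviating more than
20% in length or falling below 90% bisulfite-aware identity are rejected
with an error, mirroring manual exclusion of bad clones; both thresholds are
arguments.

Calls are emitted only for reference-C positions inside the callable region:
read C → methylated, read T → unmethylated, gap or other base → uncallable.
Contexts come from direct trinucleotide classification; a context that runs
off the locus end or touches an N is "ambiguous" and excluded from calls
and denominators alike. Conversion-efficiency QC is deliberately
report-only: in plants a retained non-CpG cytosine may be a real CpHpH mark,
so filtering "poorly converted" clones by non-CpG retention would destroy
exactly the signal of interest.

## Colony summaries and stability

`summarize_clones()` reproduces the colony-table shape: per context, each
clone contributes k = number of positions it shows methylated; clones with
equal k are grouped into "k/D in m" cells, where D comes from
`count_potential_sites()`. `stable_sites()` separates *stable* marks
(methylated in at least `min_fraction` of clones; default 1.0, i.e. every
clone) from *individual* marks carried by only a few molecules.

## Motif scanning and methylation status

`scan_motifs()` re-implements catalogue-based promoter scanning directly:
each IUPAC pattern is matched at every position on both strands (a
zero-width lookahead keeps overlapping hits), and `N` in the reference
never satisfies a concrete pattern base. The bundled catalogue
(`builtin_motif_catalog()`) holds 29 PLACE-style definitions of
flavonoid-relevant elements (MYB cores, bZIP cores, GATA and SORLIP
light-responsive elements, dehydration and low-temperature elements, ...).

A motif instance is scored "+" for a sample when any cytosine inside its
interval — of *any* context, because non-canonical marks matter in plants —
is methylated in at least `min_clones` clones (default 1). Published
+/− motif tables rarely state their clone threshold; ours is a flag
precisely because raising it can only switch + to − (a property the tests
assert). With imperfect conversion, `min_clones = 1` will also pick up
occasional conversion failures; users wanting only reproducible marks
should raise it or use `stable_sites()`.

Because catalogue motifs are annotated inconsistently with respect to
orientation, both strands are scanned by default, with a per-motif
`strand` override column. Where a motif occurs several times in a promoter,
every instance is reported individually rather than collapsed.

## The synthetic-data generator

`sim_params()` encodes the study conditions the package is designed around,
and its defaults emulate a wheat flavonoid-gene promoter assay:

* a ~1600 bp analysed region (promoter plus 5' gene body) at background
  GC 0.44, with **two planted CpG islands** — island segments are
  rejection-sampled until they genuinely meet their GC/ObsExp targets —
  and planted cis-elements (degenerate codes resolved uniformly);
* two tissues, **10 clones each**; the methylated tissue uses per-context
  per-site rates CpG 0.14, CpHpG 0.048, CpHpH 0.0085 (the CpG ≫ CpHpG >
  CpHpH ordering characteristic of such promoters, at the magnitude of a
  moderately methylated gene copy), the other tissue rate 0;
* conversion efficiency 0.99 and per-base Sanger error 0.001 — neither is
  typically reported, so we use standard values for commercial bisulfite
  kits and capillary sequencing;
* a single amplicon (~420 bp, within the usual 125–464 bp product range)
  whose primers are taken verbatim from the converted reference at the
  region ends, the way real bisulfite primers are designed.

The tissue methylome is drawn once per tissue and shared by its clones;
clones then differ through independent conversion draws and sequencing
errors. This models *stable* marks plus conversion noise; it does **not**
model per-molecule (cell-to-cell) methylation heterogeneity, PCR or cloning
bias, chimeras, hemimethylation across strands, or chromatogram artefacts —
so passing recovery tests demonstrate the calling chain is correct, not
that real clone sets are free of those effects.

Everything is a pure function of `(params, seed)`: the same seed reproduces
every sequence bit-for-bit, and the acceptance script threads one seed
through all of its sub-experiments.

## Recovery guarantees the tests assert

* **Lossless regime.** At efficiency 1 and error 0 there is no stochastic
  channel between truth and call, so the called methylome must equal the
  simulated truth *exactly*, across seeds. The suite checks 20 seeds.
* **Denominators.** `count_potential_sites()` is checked against
  brute-force enumeration on 100 random loci (300–800 bp), and the three
  contexts must partition the classifiable cytosines. Denominators are
  profile-independent by construction, and the tests confirm it.
* **Islands and motifs.** Window logic is checked against an exhaustive
  per-position oracle (direct substring statistics, coverage unions) on
  random structured sequences up to 2 kb; motif scanning against full IUPAC
  expansion plus fixed-string search for the complete catalogue.
* **Noise envelope.** At efficiency 0.95 / error 0.005, a truly methylated
  C is read C unless an error hits it, so over all (clone, site) pairs the
  methylated-call count is Binomial(n, 1 − error); the suite checks the
  aggregate over 50 replicates against the central 99% interval, and
  false positives against the retained-C rate (1 − efficiency).

Problem sizes throughout (1.6 kb loci, 420 bp amplicons, 10 clones, 20–50
replicates) were chosen as the smallest at which the statistical structure
of the assay is faithfully represented.

## Known limitations

* The assay is single-stranded by design: bottom-strand methylation is out
  of scope, as are WGBS/RRBS-style short reads.
* Island-boundary agreement with any particular web tool is not guaranteed
  — exact merge rules of those tools are unpublished; counts and the
  documented merge semantics are what the oracle pins down.
* `min_clones = 1` motif status is sensitive to conversion failures at high
  clone counts (about 1 − efficiency^clones of sites will show a spurious
  singleton mark); this is inherent to the assay, not a software artefact.
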