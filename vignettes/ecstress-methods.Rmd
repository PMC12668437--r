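---
title: "Models and methods behind the ecstress screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ecstress screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecstress)
```

## The biological problem

Endothelial cells are exposed to transient, blood-borne stresses. Two of
them motivate this package. First, global inhibition of protein translation
(the integrated stress response, modelled experimentally with cycloheximide)
secondarily suppresses nonsense-mediated decay (NMD): transcripts that carry
a premature termination codon (PTC) and are normally degraded become visible
in RNA-seq. Exons that appear *only* in treated cells, are absent from the
curated transcript set, and introduce a PTC by the exon-junction-complex rule
are therefore candidate NMD-target biomarkers of acute translation shutdown.
Second, a modest rise in extracellular iron produces a transient fall in
pre-miRNA expression at 1 h with recovery by 6 h, detectable as a
derepression of the affected miRNA family's target mRNAs, and quantifiable in
absolute units by spike-in-calibrated qPCR.

`ecstress` implements the full analysis chain for both screens, together with
a seeded synthetic-data generator that plants known truth at every stage so
the chain is testable without access to sequencing archives.

## The PTC rule and the exon funnel

The NMD decision is the core model. For a candidate exon spliced between two
constitutive exons, the inclusion transcript is assembled and translated in
3-nt steps from the annotated start codon. Let $s$ be the transcript position
of the 3' end of the first stop codon encountered, and $j$ the position of
the last exon–exon junction. The transcript is called an NMD **target** when
the stop is premature (upstream of the natural stop) and

$$ j - s \ge d_{\min}, \qquad d_{\min} = 50\ \text{nt (default; configurable 50–55)}, $$

because termination that far upstream of the final junction leaves at least
one exon junction complex bound downstream, which marks the mRNA for decay.
A first stop that *is* the natural stop, or that falls inside the last-exon
window, yields **non_target**; a transcript with no stop at all (possible
after a frameshift) is **indeterminate**. The conservative end of the 50–55
nt range is the default so borderline exons are not over-called.

The screening funnel applies, in order:

1. **Condition-exclusive detection** — zero reads in every control library
   (a tolerance is configurable but defaults to strict absence) and strictly
   more than `min_exclusive_reads = 20` reads summed over treated libraries.
   The "more than 20" wording is read literally: a total of exactly 20 is
   rejected. A per-library variant of the rule is available by option because
   published descriptions of such screens rarely state the scope.
2. **Novelty** — the exon is absent from the curated set and lies wholly
   within an intron of a curated transcript of the same gene.
3. **PTC classification** as above (annotates, never filters: with the
   sharpness filter disabled, non-targets simply rank below targets).
4. **Boundary sharpness** — the fraction of overlapping reads whose aligned
   segments lie entirely within the exon (segments ending exactly at a splice
   edge count as sharp). This is our formalization of the qualitative "sharp
   alignment boundaries" expected of a precisely spliced exon; the default
   threshold is 0.9, and the stage runs only when read-level alignments are
   available, since count tables cannot yield it.

Survivors are ranked deterministically: NMD targets first, then decreasing
sharpness, then decreasing treated read total, ties broken by exon id. The
criteria published funnels used to cut their final short-lists are usually
not enumerated; this ranking is a documented stand-in, not a claim about any
particular study's rule. Candidate inclusion level is summarized as
percent-of-adjacent-exon expression (per-library percent of the nearest
constitutive exon's count, with mean and sample SD; libraries with a zero
adjacent count are excluded, and an all-zero denominator is an error rather
than a 0%).

A read contributes to an exon when any aligned segment overlaps it by at
least one nucleotide on the gene strand; a read spanning two adjacent exons
counts for both (per-exon counting, not assignment). Strand-reversal
invariance (mirror the genome, flip all strands) is enforced by test.

## miRNA quantification rules

Hairpin counting requires a read to be an exact substring of exactly one
stem-loop; multi-matching reads are discarded. Normalization is
reads-per-kilobase-per-million over the full hairpin length (the stem-loop is
the alignment target, so it plays the "exon size" role) and is exactly
invariant to library-size rescaling. The differential rule is relative to the
control value: treated is called higher/lower when the change is at least
20 % of control, boundary inclusive; condition-exclusive hairpins are called
`treated_only`/`control_only` and counted as differential. Whether such a
rule should apply to raw or normalized alignments is ambiguous in most
write-ups; normalized values are used here because normalization precedes
selection in the workflow this package models.

Mature-arm analysis counts only reads byte-identical to a mature 5p or 3p
sequence that is unique across the reference (duplicated mature sequences
are flagged unusable). Hairpins are classed `sole_5p`, `sole_3p` or `both`;
undetected hairpins leave the denominator, and class percentages are rounded
to integers, matching how such tables are conventionally printed. The 5p:3p
ratio uses no pseudocount: a zero 3p count returns infinity flagged as
sole-arm rather than a fabricated finite fold.

## Spike-in qPCR calibration

The standard curve is $C_t = b + m\log_{10}(c)$ fitted by least squares over
the spiked calibrator dilutions, with amplification efficiency
$E = 10^{-1/m} - 1$ (a slope of $-3.32$ cycles per decade is 100 %
efficiency). Concentrations are recovered as $c = 10^{(C_t - b)/m}$,
femtomolar throughout. Because published workflows often do not say whether
a dilution series or a single spike point was used, both modes exist:
dilution-series fitting is preferred, and `single_point_delta_ct()` implements
$c = c_{spike}(1+E)^{C_t^{spike} - C_t}$ with a default efficiency of 1.
Missing Ct values mean "no amplification"; they are excluded from fits and
reported as below detection, never imputed as zero. The efficiency–slope map
is a bijection on the supported range $E \in [0.8, 1.1]$, and
Ct-to-concentration is strictly decreasing — both enforced by test.

## Target-set comparison and the test battery

mRNAs are binary-categorized as family targets when they carry at least one
8mer, 7mer-m8 or 7mer-1A site in the supplied site table (site scanning
itself is out of scope; the table is an input). Targets versus non-targets
are compared by a two-sided Mann–Whitney test; multi-group designs use
Kruskal–Wallis followed by Dunn's tie-corrected mean-rank z tests, or, for
matched designs, Friedman followed by Dunn-style tests on within-block rank
sums. Dunn's test is implemented in-package with the standard formulas
(pairwise $z = (\bar R_i - \bar R_j)/\mathrm{SE}$ with the pooled tie
correction). Source descriptions of such batteries rarely state sidedness or
multiplicity handling; everything here is two-sided with Holm adjustment by
default (Bonferroni and none available). Rank tests are invariant to the
ratio-versus-log2 scale choice, so fold changes may be supplied either way.

## What the synthetic generator emulates

Each gene receives 3–8 constitutive exons on its own chromosome, a CDS
starting with ATG in exon 1 and a natural stop in the last exon, and about
half the genes sit on the minus strand. Selected genes get one intronic
cryptic exon of 50–200 nt. NMD-target constructs carry a planted in-frame
stop placed so that at least one constitutive exon separates it from the
terminal exon (hence ≥ 60 nt upstream of the last junction); non-target
constructs preserve frame and are stop-free, splicing the original junction
codon's halves onto their own edges so no spanning stop can arise. Labels
are recorded by construction — not by running the classifier — which keeps
the classifier-versus-oracle equivalence test non-circular.

Counts are Poisson around gamma-distributed per-exon means scaling with the
configured depth; planted exons are strictly absent from control libraries
with a treated-only mean of 60 reads by default. Poisson was chosen as the
minimal noise model sufficient for recovery testing; biological
overdispersion, partial inclusion in controls, mapping errors and
multi-cryptic splice graphs are deliberately not modelled, so a passing
recovery test demonstrates correctness of the funnel logic, not performance
on real libraries. Small-RNA reads are exact mature-arm copies drawn by the
configured 5p/3p bias plus a 10 % decoy fraction (random sequences verified
to match nothing) to exercise the unique-match filter. qPCR plates add
Gaussian Ct noise and run the spike dilutions in triplicate wells, as
standards are conventionally plated. All generators are byte-reproducible
from `seed`; internal coordinates are 0-based half-open, with GFF3 emitted
1-based.

Sequencing depth and library counts of the motivating experiments are not
public; the defaults (10^6 reads, two libraries per condition) were chosen
once for adequate test power and are documented here rather than revisited.

## Problem sizes used in the shipped checks

The test-suite and `scripts/acceptance.R` run: 20 seeded screens of 200-gene
genomes with 8 planted targets and 8 non-target cryptics at depth 10^6;
classifier-versus-oracle agreement over 200 genes with one cryptic inclusion
each; 100-seed efficiency recovery at Ct noise 0.15 over a 5-point decade
series (the ±0.05 recovery claim refers to the fitted efficiency, and the
10 % round-trip claim to the mean recovered concentration over 100 wells,
since single-well noise at ct_sd = 0.1 is itself ~7 % at 1σ); and 1000 null
simulations per omnibus test plus a 100-seed power check at group sizes 570
versus 10,281 with a +1 log2 shift at σ = 0.3.

## Known limitations

* The screen is presence/absence plus a read threshold; no cross-condition
  normalization or dispersion modelling is attempted, by design.
* One cryptic exon per gene; no junction-spanning transcript reconstruction.
* Hairpin counting is exact-substring; no mismatch tolerance or isomiRs.
* Target categorization consumes a site table; it does not scan UTRs.
* The qPCR model omits raw fluorescence processing and inter-plate batch
  effects.
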