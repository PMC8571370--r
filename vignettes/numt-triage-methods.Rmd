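---
title: "Separating genuine mtDNA, polymerase error, heteroplasmy and NUMTs in clone libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating genuine mtDNA, polymerase error, heteroplasmy and NUMTs in clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtriage)
```

## The problem

When a mitochondrial fragment (COI, 12S rDNA, or the control region) is
PCR-amplified from total genomic DNA and cloned, the resulting clone
library is a mixture of four kinds of molecules:

* the **genuine haplotype** — the individual's dominant, authentic mtDNA
  sequence;
* **polymerase error variants** — copies of the genuine template carrying
  substitutions introduced by Taq during amplification (roughly
  7.2×10⁻⁵–10⁻⁴ errors per base per synthesis, accumulated over ~35
  cycles);
* **heteroplasmic copies** — minority mtDNA haplotypes genuinely present
  in the individual, typically a handful of substitutions away;
* **NUMTs** — nuclear integrations of mitochondrial DNA, co-amplified by
  the same primers. These are often strongly diverged (a few percent to
  >50% K2P), carry indels, and in coding fragments show frameshifts,
  premature stop codons or clusters of nonsynonymous change.

`numtriage` implements the full decision procedure that separates these
classes: in-silico PCR and primer trimming, multiple alignment and
window trimming, Kimura two-parameter (K2P) distances under pairwise
deletion, neighbor-joining trees with column-bootstrap support,
invertebrate-mitochondrial-code codon diagnostics, a rule-based clone
triage, a peak-multiplicity model explaining why direct Sanger traces of
such mixtures show double and triple peaks, and a clone-library
simulator that generates ground-truthed test data for all of it.

## The decision procedure

For each region the pipeline (`runRegion()`) proceeds:

1. **Ingest and filter.** Clones whose insert length deviates more than
   20% from the expected size (the direct read's length) are excluded up
   front — grossly short inserts are not analyzable as the target locus.
   Identical clone sequences are collapsed to haplotypes.
2. **Align and trim.** A progressive multiple alignment (guide tree from
   pairwise identities, profile–profile merges with affine gap costs) is
   trimmed so that both ends fit the shortest direct-sequencing read:
   outside that window, apparent variation is read-length artifact.
3. **Distances and tree.** All pairwise K2P distances are computed under
   pairwise deletion, K = −½·ln[(1−2P−Q)·√(1−2Q)] with P and Q the
   transition and transversion proportions over sites where both rows
   carry an unambiguous base. Saturated pairs (log argument ≤ 0) are
   flagged undefined, never silently dropped — this matters for control
   region pseudogenes at extreme divergence. A neighbor-joining tree with
   column-bootstrap supports summarizes the structure.
4. **Genuine haplotype.** The clone haplotype identical (zero
   differences over the trimmed window) to the direct read is genuine;
   without a direct read, the haplotype shared identically by the most
   clones (multiplicity ≥ 2) is taken as genuine.
5. **Grouping.** Group A is the genuine haplotype's neighborhood:
   the single-linkage cluster(s) containing the genuine haplotypes at
   the region's K2P cutoff, extended by members of the smallest
   ≥60%-supported clade containing them, bounded by the per-region
   genuine radius (see below). The remaining haplotypes are grouped by
   single-linkage and lettered B, C, … by increasing mean K2P from A.
6. **Labels.** With d the difference count between a clone and its own
   individual's genuine haplotype: d = 0 → `genuine`; 1 ≤ d ≤ 2 inside
   group A → `pcr_error_variant`; d ≥ 3 inside group A →
   `heteroplasmy`; outside group A → `numt`. Clones of an individual
   whose genuine haplotype cannot be determined are `ambiguous`.
   Stop codons, frameshifts and nonsynonymous counts are recorded as
   evidence: corroborating for NUMT calls, a "pseudogene-like" warning
   note inside group A (a heteroplasmic copy can legitimately carry a
   stop codon, so the label is not changed).

### Why both a difference count and a group?

The polymerase-error threshold (≤ 2 differences) and the heteroplasmy
minimum (≥ 3) act only *inside* group A. A clone 10 substitutions from
the genuine haplotype is heteroplasmic if it still sits in the genuine
cluster, but a NUMT if it belongs to a diverged group — the same count
means different things depending on neighborhood. The threshold t = 2 is
inclusive (differences of exactly 2 are still polymerase error): the
category boundary sits where heteroplasmy begins at 3, and the observed
per-clone Taq error burden (mean ≈ 1.4 errors at μ = 10⁻⁴ over 35
cycles) makes 1–2 differences the expected error signature.
Both counts are config-exposed (`triageConfig()`).

### Difference counting

Differences are counted in **events** mode by default: a contiguous gap
run counts once, because the unit of interest is the mutational event.
The alternative **columns** mode (every indel column counts) is retained
and switchable, since published figure captions often say only
"including indel".

### Group A: tree clade, linkage cluster, and the genuine radius

The published procedure reads group A off a drawn, rooted tree. Two
failure modes appear when this is automated naively:

* **Short supported edges** can cut a genuine variant off the clade even
  though it sits a single substitution away — variants cluster
  cohesively with their genuine haplotype, and the distance evidence
  should keep them in A.
* **Independently integrated NUMT loci** are successive outgroups, not a
  joint clade. The smallest supported clade containing the genuine
  haplotypes can therefore legitimately engulf the nearest NUMT locus
  (we observed a simulated locus at ~9% K2P doing exactly this).

Group A is therefore the union of the genuine linkage cluster and the
supported clade, with the clade's contribution bounded by the per-region
`genuineRadius` (2.5% for COI and 12S, 5% for the control region —
comfortably above observed within-A variation and below observed
NUMT divergence in each region). Haplotypes on which the two
assignments disagree are flagged (`assignmentConflict`) so borderline
cases are visible rather than silently resolved. The per-region linkage
cutoffs default to 5% (COI), 1% (12S; the most divergence-overlapped
region, where the tree evidence matters most) and 10% (control region).

## Numerical choices

* **Alignment**: global affine-gap alignment, match +2 / mismatch −1 /
  gap open 5 / gap extend 2 (ClustalW-like DNA scale). Within-group
  fragments are >90% identical, so results are insensitive to these
  values; they are exposed through `alignParams()` because strongly
  diverged noncoding pseudogenes may need gentler gap costs. The
  traceback tie-break is fixed (diagonal > up > left) so alignments are
  deterministic. Guide-tree identities exclude terminal gaps: direct
  reads differ in length, which is artifact, not divergence. There is
  no interactive "manual editing" step; divergent-group alignments are
  accepted as produced and distances on such groups should be read as
  alignment-sensitive.
* **Neighbor joining**: the Q-criterion with a deterministic tie-break
  (lexicographically smallest label pair). Negative branch lengths are
  clamped to zero with the clamped deficit recorded. On additive
  matrices the algorithm recovers topology and branch lengths exactly
  (property-tested up to 12 taxa).
* **Bootstrap**: columns resampled with replacement; replicates whose
  distance matrix contains an undefined entry are discarded and counted,
  with a warning past 10%. Supports are percentages of usable
  replicates containing the same bipartition; the display convention
  hides supports below 60%.
* **K2P undefinedness** is propagated as a flagged `NA`; means are taken
  over defined pairs and the undefined fraction is reported.
* **Standard errors** of mean distances are column-bootstrap standard
  deviations of the replicate means (B = 1000 by default; smaller B is
  used in examples and tests where only stability, not the third
  decimal, is at stake).
* **Translation** uses NCBI table 5 (invertebrate mitochondrial: ATA→M,
  TGA→W, AGA/AGG→S, stops TAA/TAG only), with the table id
  config-overridable. Reading frames are inferred by minimizing internal
  stops; codon positions are always defined on the genuine row's
  coordinates, so clone indels never re-frame the reference.

## The simulator

`simConfig()` / `generateTruth()` / `simulatePcrLibrary()` generate
ground-truthed clone libraries. Defaults encode the study conditions the
pipeline targets:

| parameter | default | meaning |
|---|---|---|
| fragment length | 807 bp coding / 820 noncoding | genuine insert size |
| base composition | A .31, C .18, G .17, T .34 | AT-rich arthropod mtDNA |
| heteroplasmic templates | 2, at 3–10 substitutions, 5% weight each | minority true haplotypes |
| NUMT loci | 3, at 7–24% (coding) or 7–70% (noncoding) divergence, 2% weight each | nuclear copies |
| NUMT indels | rate 0.001/site coding, 0.005 noncoding; geometric length, mean 2 | frameshifts and length variation |
| transition bias κ | 4 (the transition has rate κ vs 1 per transversion, so P(transition) = κ/(κ+2)) | mtDNA-like substitution spectrum |
| Taq error rate μ | 10⁻⁴ per base per synthesis (documented range 7.2×10⁻⁵–10⁻⁴) | polymerase fidelity |
| cycles | 35 | amplification protocol |
| clones sampled | 30 | library depth per individual |

NUMT weights (0.02/locus) are a modeling choice, not a published
measurement: published data give clone proportions, not template
fractions, and few nuclear copies against abundant mtDNA motivates a
small value. Heteroplasmic and NUMT templates derive from the genuine
sequence (not an outgroup), matching the observation that such
pseudogenes are closest to the source species' own mtDNA.

Coding NUMTs drawn at ≥10% divergence are re-drawn (up to 100 times)
until they carry a frameshift or internal stop, mirroring the
observation that strongly diverged coding pseudogenes are disrupted;
clean survivors are flagged. NUMT substitution events are placed with
replacement (multiple hits allowed) so that the K2P-corrected distance
estimates the drawn target divergence; the estimator-consistency test
verifies recovery within ±0.02.

Two amplification models are provided. The **genealogy model**
(reference) tracks pool sizes forward from 1000 template molecules with
per-cycle copying probability 0.8, then samples each sequenced clone's
synthesis history backward through the recorded pool sizes — a molecule
drawn from the final pool was newly synthesized in cycle c with
probability births(c)/N(c); every synthesis event contributes
Binomial(L, μ) substitutions. This is distribution-exact for a uniformly
drawn molecule; the correlation induced by shared ancestry between
sampled clones is ignored (with 1000 founders it is negligible at 30
clones). The **binomial model** approximates the synthesis depth as
Binomial(cycles, ½) — exact in the ideal-doubling limit, where half of
each cycle's pool is newly made — giving an expected error burden of
L·μ·C/2 ≈ 1.41 errors per 807-bp clone; the two models agree on the
mean burden within 15% at efficiency 1. All randomness flows from the
single config seed, so fixtures are byte-reproducible.

### What the simulator does and does not emulate

It emulates: dominance of the genuine haplotype, rare heteroplasmic
templates, diverged NUMT loci with indels and nonsense codons, and
per-cycle polymerase substitution error. It does **not** emulate PCR
chimera formation, polymerase indel errors, cloning-vector artifacts,
mixed-colony picks, shared derived structure among NUMT alleles of one
locus, or real within-group phylogenetic substructure (clades of
variants sharing mutations). Passing the recovery tests therefore shows
the decision rules are implemented correctly under the stated mixture
model — not that the thresholds are optimal for any particular real
library.

## The electropherogram model

`predictSiteSignals()` treats a direct-sequencing trace as a linear
mixture of the co-amplified haplotypes: per alignment column, template
weights are summed by nucleotide and every nucleotide at or above a flat
detection threshold (default 0.10) is a peak. Columns where gap weight
reaches the threshold are flagged gap-disrupted — a minority template
with an indel shifts its downstream trace out of register, which is the
mechanism behind unreadable 12S/control-region traces. The model is
deliberately instrument-free: the argument is about shared-nucleotide
weight, not dye chemistry. `callStrongest()` mimics "adopt the stronger
peak" base calling, which quantifies when co-amplified pseudogenes can
overrule the genuine base — single unique variants (polymerase error,
unique heteroplasmic substitutions) stay below threshold, whereas
several pseudogenes sharing the same derived nucleotide produce double
and triple peaks. `multipeakExample()` constructs a 10-haplotype,
60-column mixture exhibiting exactly 7 double- and 5 triple-peak sites
with the genuine base still dominant everywhere.

## Problem sizes used in checks

The bundled checks run simulations at the default library size (30
clones, 10 seeds) for label recovery, 10,000 clones (binomial model) for
the error-burden expectation, bootstrap sizes of 100–200 replicates for
support and SE stability, brute-force alignment comparison up to length
8, and additive-tree recovery up to 12 taxa. These sizes were chosen so
each property is exercised well past its small-sample noise, while a
full check run remains quick on a single CPU.

## Known limitations

* Grouping on real libraries depends on alignment quality; strongly
  diverged noncoding groups are alignment-sensitive and their distance
  summaries should be treated accordingly.
* Without an outgroup the tree is midpoint-rooted; clade-based group
  boundaries can shift under alternative rootings, which is why the
  distance evidence bounds them and disagreements are flagged.
* The procedure cannot distinguish a heteroplasmic copy from a
  polymerase artifact at 1–2 differences without cDNA evidence; the
  boundary is a declared convention, not an inference.
* BLAST-style homology corroboration of NUMTs is out of scope; the
  package relies on offline evidence (divergence, stops, frameshifts),
  and a hook for externally produced homology hits is a possible future
  addition.
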