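---
title: "Assessing the clonal origin of multiple meningiomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the clonal origin of multiple meningiomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmclone)
```

## The question

About one in ten meningioma patients carries several spatially separated
tumors. Two generative histories are compatible with that picture: all
tumors descend from one founding clone that seeded the meninges and then
diverged (*monoclonal origin* with *branched evolution*), or each tumor
arose independently (*multi-clonal origin*). The distinction matters
clinically — a monoclonal patient's tumors share truncal biology, an
independent patient's tumors may be entirely different diseases — and it is
decidable from somatic genomics: lesions of monoclonal origin share truncal
somatic alterations, independent lesions do not.

`mmclone` takes per-lesion somatic call sets (SNV/INDEL tables and
copy-number/allelic segment tables, i.e. the output of a standard
tumor-vs-normal calling pipeline) and answers four questions per patient:

1. which alterations are shared by all lesions, partially shared, or
   private;
2. what molecular subtype each tumor belongs to (*NF2-loss* vs *non-NF2*);
3. whether the lesions are monoclonal or independent;
4. what the phylogenetic relationship among the lesions is
   (neighbor-joining tree on a binary alteration matrix).

It additionally estimates, per lesion, the *clonal fraction* of key events
from two independent signals — mutation variant allele fractions (VAF) and
the minor-allele fraction (MAF) of loss-of-heterozygosity (LOH) segments —
so that the two can be checked for concordance.

## Variant filtering

Three post-calling filters are applied per lesion, in any order (they
commute and are idempotent):

* **population allele frequency** — variants with gnomAD AF strictly
  greater than 0.01 are removed; variants *absent* from gnomAD are kept
  (their AF is missing, not zero);
* **functional impact** — only protein-altering coding consequences are
  kept. The vocabulary is not standardized upstream, so the set is
  configurable; the default is missense, nonsense, frameshift, in-frame
  indel, splice-site and start/stop-loss, excluding synonymous, intronic
  and UTR changes;
* **contamination** — variants with VAF strictly below the sample's
  estimated cross-individual contamination rate are removed (default rate
  0; supply the caller's estimate when available).

Both inequalities are deliberately strict: a variant at exactly AF 0.01 or
exactly the contamination rate survives.

Variant identity across lesions is the genomic key (chrom, pos, ref, alt).
Annotation differences between lesions never split identity.

## CNV and LOH events

Segments are carried internally in 0-based half-open coordinates (BED
semantics); SEG input/output converts at the boundary, which keeps interval
intersections free of off-by-one errors. Per lesion, three segment states
are recognized:

| state | rule | default |
|---|---|---|
| deletion | log2 copy ratio ≤ `del_log2` | −0.3 |
| amplification | log2 copy ratio ≥ `amp_log2` | +0.3 |
| LOH | minor-allele fraction ≤ `loh_maf`, irrespective of copy ratio | 0.40 |

State intervals are merged and compared with the GRCh37 chromosome-arm
table; an arm whose affected fraction exceeds `arm_fraction` (default 0.5)
yields an arm-level event, and two same-kind arm events on one chromosome
merge into a chromosome-level event. None of these four thresholds is
dictated by the calling model — they are field-standard defaults and all
configurable via `event_thresholds()`. A deleted region also has low MAF,
so a deletion typically emits an LOH event too; this is biologically
correct (deletion is one mechanism of LOH) and the event keys keep the two
kinds distinct.

Two lesions carry *the same* CNV feature when their events agree in
(kind, label) **and** their footprints overlap reciprocally by at least
`overlap_fraction` (default 0.5) of each footprint. The source analyses
intersect segments across lesions but state no overlap criterion; the
reciprocal rule is the common practice for segment matching and prevents a
focal and a whole-arm event from being conflated. `intersect_shared_segments()`
exposes the underlying n-way interval intersection directly.

## Subtype and clonality rules

* **Subtype**: a tumor with a somatic *NF2* SNV/INDEL **and/or** a
  chromosome 22 deletion event is *NF2-loss*; otherwise *non-NF2* (the
  non-NF2 drivers in this disease are *TRAF7*, *AKT1*, *KLF4*, *SMO*,
  *POLR2A*, …).
* **Clonality**: a patient is *monoclonal* when at least one driver
  feature is shared by **all** lesions, where a driver feature is an
  identical driver-panel SNV/INDEL or a shared CNV/LOH event; otherwise
  *independent*. No formal rule is published for this call; the implemented
  rule is the minimal one consistent with all six reference verdicts
  (shared passenger SNVs deliberately do not count — they are more likely
  artifacts than truncal evidence when no driver is shared). The required
  number of shared drivers is configurable (`min_shared_drivers`).

## Clonal fractions

For a mutation carried by a fraction $c$ of cells, the expected VAF depends
on the local copy state:

$$\mathrm{VAF} = \begin{cases} c/2 & \text{heterozygous, diploid} \\
c/(2-c) & \text{hemizygous deletion} \\ c & \text{copy-neutral LOH (mutation
on the duplicated allele)} \end{cases}$$

`clonal_fraction_from_vaf()` inverts these (clipping into $[0,1]$, with
clipped values indicating model misfit). For an LOH segment, the
copy-neutral allelic-imbalance model gives $\mathrm{MAF} = (1-c)/2$, hence

$$\hat c = 1 - 2\,\mathrm{MAF},$$

while a true hemizygous deletion gives $\mathrm{MAF} = (1-c)/(2-c)$ and
$\hat c = (1-2m)/(1-m)$. The copy-neutral inversion is the default because
it is the relation the reference worked example satisfies (MAF 0.30 and
0.11 pairing with clonality 40% and 80%, in agreement with the co-occurring
mutations' VAF-derived estimates of 0.44 and 0.80); the deletion model is
available via `model = "deletion"`. We do not attempt to adjudicate which
mechanism truly produced any particular segment — `compare_event_clonality()`
simply reports both estimators per lesion and flags concordance within an
absolute tolerance of 0.10, which matches the rounding implied by
0.44 → "40%" and 0.78 → "80%".

chrX is treated as diploid for this arithmetic in female patients and
hemizygous (`male_x = TRUE`) in males.

## Phylogeny

Per patient, a binary matrix is built: rows are lesions (plus an all-zero
`germline` outgroup row by default), columns are driver-panel SNV keys and
CNV/LOH event keys, cells are presence. Restricting SNV columns to the
driver panel keeps the matrix interpretable; CNV features enter per event,
matched by the reciprocal-overlap rule. Features present in every lesion
are *retained* — against the germline row they form the trunk separating
the root from the tumor clade. SNV and CNV columns carry equal weight
(per-feature weights would be easy to add but there is no principled
default).

Distances are Manhattan ($L_1$; on binary data, the Hamming count), and the
tree is classical Saitou–Nei neighbor joining. Neighbor joining is exact on
additive distance matrices, and our implementation makes two choices the
classical description leaves open: Q-matrix ties are broken
deterministically (first minimal pair in label-sorted scan order), and a
negative branch length at a join is clamped to zero with the deficit moved
to its sister branch, preserving the pair's total. Output is canonical
Newick — children ordered by the smallest leaf label in their subtree — so
identical inputs always serialize identically. With the germline row the
tree is rooted on that leaf.

## The simulator

`simulate_patient()` generates multi-lesion call sets with known ground
truth under two scenarios: *monoclonal_branched* (a truncal feature set —
by default 8 SNVs including one driver-panel mutation, plus a chr22
deletion — shared by all lesions, followed by private SNVs and CNV events
per lesion) and *independent* (each lesion draws its own founder set;
loci and arms are sampled globally without replacement so that nothing is
shared by construction). Defaults emulate the reference cohort's
structure: two lesions per patient, a chr22-deletion founder event,
clonal fractions drawn from 0.6–1, and a small admixture of synonymous
(15%) and common-population (5%) passenger variants so the filters have
work to do.

Observed VAFs follow a binomial read-count model: at depth $D$ a variant
with expected VAF $p$ is observed at $X/D$ with $X \sim \mathrm{Bin}(D,p)$.
The default depth of 150 reflects high-coverage exome sequencing;
`sequencing_depth = Inf` yields noiseless fractions, which is the regime in
which scenario recovery is provably exact. No overdispersion is modelled —
the upstream pipelines this emulates report no noise model — so the
simulator's noise is optimistic relative to real FFPE-derived data. Segment
MAF and log2 values are set to their expectations (segments aggregate many
sites, so their sampling noise is second-order). Consequently, passing
recovery tests demonstrates correctness of the inference logic under the
stated model, not robustness to purity collapse, subclonal CNVs or caller
artifacts, none of which the simulator emulates.

Simulation is deterministic given the configuration: patient $i$ uses the
substream `seed + i`.

The package also ships `build_inpaper_fixture()`, a six-patient cohort
(15 tumors + 1 dura control) encoding the reference cohort's per-tumor
alterations; quantities that cohort does not pin down (exact variant
coordinates, most VAFs, CNV depths) are fixed plausible placeholders and
are documented as such.

## Problem sizes and numerical choices

The test suite runs the simulator at desk scale: scenario recovery uses
100 patients at depth $10^4$, estimator recovery 500 event-level draws,
and the neighbor-joining property suite 200 random additive metrics on
4–8 leaves — sizes at which every property is already sharply testable
while the whole suite stays fast. Degenerate inputs are defined rather than
rejected wherever a definition exists: an empty variant table is a valid
lesion; identical lesions yield zero-length branches; a single-lesion
"partition" is all-shared with a warning; a patient with no panel features
at all fails feature-matrix construction with advice to review thresholds,
without aborting the rest of the cohort.

## Limitations

* One clonal fraction per event — no multi-cluster subclonal
  deconvolution, no purity/ploidy joint fit.
* The monoclonality rule is binary evidence counting; it does not weigh
  the probability that a shared event recurred independently (relevant
  for highly recurrent events such as chr22 loss in this disease).
* Arm-level event calling will miss focal driver CNVs below half an arm.
* The binary matrix treats SNVs and CNV events as equally informative
  characters.
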