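---
title: "Copy-number aberration calling and minimal critical regions from array CGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number aberration calling and minimal critical regions from array CGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnamcr)
```

## The problem

Two-color oligonucleotide array CGH measures, probe by probe, the log2
ratio of tumor DNA to a pooled diploid reference. In acute myeloid
leukemia (AML) cohorts this gives copy-number profiles at far higher
resolution than mitotic karyotypes, and comparing therapy-related (t-AML)
against de novo (p-AML) cohorts asks three questions this package
operationalizes:

1. which intervals of a patient's genome are gained or lost (CNA calling);
2. which of those intervals are germline polymorphisms (CNV) or
   physiological immunoglobulin/T-cell-receptor VDJ deletions rather than
   acquired somatic events, given that no matched normal DNA is available;
3. which genomic intervals recur across patients, and what is the
   *minimal critical region* (MCR) - the smallest interval shared by the
   CNAs of two or more patients, the natural candidate location for a
   driver gene.

Coordinates are held internally in base pairs; everything is reported in
the cohort tables' convention - megabases at 10 kb resolution, two
decimals, half-up rounding (`round_half_up()`).

## The ratio model

A clonal event at copy number $c$ carried by a fraction $f$ of cells in a
diploid background has expected linear ratio

$$r(c, f) = 1 + f\left(\frac{c}{2} - 1\right),$$

so a monosomy ($c = 1$) in an 80%-blast sample reads out at $r = 0.6$
rather than 0.5 (`expected_ratio()`). Copy states are assigned from the
linear ratio by `classify_ratio()`:

| state | linear ratio |
|---|---|
| HIGH_AMP | $\ge 4$ |
| LOW_AMP | $[2, 4)$ |
| GAIN | $[1.2, 2)$ |
| NEUTRAL | $(0.8, 1.2)$ |
| LOSS | $[0.25, 0.8]$ |
| DEEP_LOSS | $< 0.25$ |

Boundaries are inclusive on the aberrant side (a ratio of exactly 0.8 is a
loss, exactly 1.2 a gain). The low-amplification band is read as the
half-open $[2, 4)$; deep loss below 0.25 is reported as a flag on
loss-direction calls rather than a separate direction. Cohort-table rows
keep their published sign even when a printed two-decimal ratio rounds
into the neutral band (one gain at 1.19 exists in the packaged t-AML
table); the standalone classifier is strict.

## Segmentation: a documented stand-in

The detection algorithm used on the original arrays (Agilent ADM2) is
proprietary; only its filters - at least 5 probes and |log2 ratio| > 0.3 -
are reproducible. `segment_profile()` therefore implements a
circular-style recursive binary segmentation, the standard of the CGH
field: within each region the interior window maximizing the pooled
two-sample $t^2$ statistic against the rest of the region is split out
when $t^2 > 10\,\log n$ (a BIC-like threshold; $n$ = probes in the
region), and the parts are segmented recursively. Adjacent segments whose
means differ by less than 0.1 log2 units are merged back. The two-cut
("circular") form is used rather than a single-cut statistic because a
single cut has essentially no power against a short focal implant inside
a long region - an 8-probe event in $10^4$ probes is exactly the case the
pipeline must detect.

Numerical choices: the search is exact ($O(n^2)$, all windows) for
regions up to 1200 probes and switches to a width-grid scan (all widths
up to 32, then geometric steps of 1.2) with local edge refinement above
that; pooled variances are floored at $10^{-20}$ so noise-free profiles
split exactly at implanted boundaries; everything is deterministic - no
permutation p-values. A segment's linear ratio is $2^{\text{mean log2}}$,
matching the tables' paired log/linear presentation, not the mean of
per-probe linear ratios.

Detection limits worth knowing (at noise sd 0.15, the level the tests
use): an 8-probe implant at |log2| = 0.5 gives $t \approx 9.3$ against a
1000-probe background threshold of $t \approx 8.3$, so such implants are
recoverable; at |log2| = 0.38 (a copy-3 gain at clonal fraction 0.6) the
same implant falls below threshold. The recovery properties are therefore
asserted for implants with at least 8 probes and |log2 expected ratio|
$\ge$ 0.5, and the end-to-end simulation test implants losses at copy 1
and gains at copy 4 so the whole clonal-fraction range [0.6, 1] stays
above that limit.

Dye-swap pairs (the t-AML arrays were hybridized twice with fluorophores
exchanged) are combined per probe as the mean of forward and negated
reverse; probes discordant by more than 0.5 log2 units between the two
hybridizations are excluded and logged (`combine_dye_swap()`). Artifact
handling: the terminal 100 kb of each chromosome is masked by default
(the source protocol excluded telomeric/high-copy-repeat regions without
stating an extent; the mask is configurable), and a filtered segment is
dropped when masks cover at least half of it.

## CNV and IG separation

Without matched normals, germline CNVs must be recognized by rule
(`flag_cnv()`): (i) size below 2 Mb, (ii) identical breakpoints repeated
in other patients (within one 10 kb reporting unit), (iii) overlap with
known CNV gene loci, (iv) reciprocal overlap of at least 50% with a CNV
database region. The four criteria are combined asymmetrically: database
support alone suffices, otherwise i-iii must all hold. The rationale is
visible in the cohorts themselves - a 30 kb gain at 7p15.2 with identical
breakpoints in four patients is a genuine recurrent CNA (it covers the
HOXA cluster and is absent from CNV databases), so breakpoint identity
alone must never flag a call.

VDJ recombination in immunoglobulin and T-cell-receptor clusters produces
focal clonal deletions that mark the malignant clone but are not drivers.
`flag_ig()` flags losses *contained within* a configured IG/TR locus
(IGK 2p11.2, IGH 14q32.33, IGL 22q11.22, TRG 7p14.1, TRA/TRD 14q11.2;
packaged extents are approximate cluster spans, overridable). Containment
rather than mere overlap is essential: whole-arm 7p losses sweep across
the TRG locus and would otherwise be misflagged, and the packaged cohort
tables confirm that only the focal in-cluster deletions carry the IG
asterisk. Only losses qualify. IG-flagged calls are excluded from CNA
counts, karyotype synthesis and MCR derivation, but their patients are
counted for the IG-proportion comparison.

Recomputing the flags on the packaged tables reproduces the printed
asterisks exactly (14 rows, 11 patients in t-AML; 5 rows in p-AML). The
proportion comparison on those tables is reported as a two-sided Fisher
exact p (`compare_proportions()`, backed by `stats::fisher.test` and
cross-checked in the tests against a full hypergeometric enumeration).
The source prose quotes p < 0.002 for counts of 8/30 vs 2/36; the exact
test on those counts gives approximately 0.035, and the pipeline reports
what it computes.

## MCR derivation

No published algorithm exists for the catalog this package reconstructs;
the procedure in `derive_mcr_candidates()` was chosen because it
reproduces, from the per-patient tables alone, all twelve published
therapy-related MCR intervals with identical bounds at 10 kb resolution:

* every call seeds a candidate;
* same-direction calls from *other* patients overlapping the current
  interval are processed in ascending (size, patient id) order; an
  admitted call shrinks the candidate to the intersection;
* a call is admitted only if it covers at least half
  (`min_member_overlap = 0.5`) of the current interval - an incidental
  30 kb sliver of a neighbouring event must not truncate a recurrent
  region (exactly this situation occurs on 7q21.3 in the packaged
  cohort); calls that cease to overlap after shrinkage are dropped;
* candidates supported by at least `min_support = 2` distinct patients
  are kept (a patient counts once however many calls contribute);
  identical intervals are deduplicated (larger support wins, ties on the
  lexicographic patient set), and a candidate strictly containing another
  candidate with superset-or-equal support is pruned.

The derived candidate set *contains* the published catalog but is larger:
the published table was curated (for example a recurrent 17p loss shared
by three patients is absent from it). Matching against a catalog
(`match_catalog()`) therefore requires identical direction and bounds and
ignores surplus candidates; support supersets are accepted, since the
published patient lists themselves omit patients whose calls demonstrably
cover an MCR. Gains and amplifications pool as direction "gain" for
support, with an `amplified` flag carried when any supporter is at
LOW/HIGH_AMP. `build_recurrence_profile()` provides the complementary
breakpoint-sweep view (depth = distinct patients per step), and
`merge_mcr_catalogs()` implements the cross-study consensus arithmetic
(single-linkage overlap clustering; group percentages against supplied
totals, one decimal).

## Reporting

`format_cna()`/`parse_cna_notation()` write and read the tables' ISCN-like
token dialect (`−7q33q34<135.74–137.48>[0.16]`); the writer standardizes
on the typographic minus and en dash, the parser additionally accepts
ASCII hyphens, decimal commas and stray spaces, which all occur in the
printed tables. `fuse_contiguous()` merges a patient's adjacent
same-direction calls when the gap is at most 2 Mb and the log2 ratios
differ by at most 0.2 - defaults chosen so that near-equal neighbours
fuse while a deep-loss segment (ratio 0.22 next to 0.59) stays distinct,
as in the published revised karyotypes; neither tolerance is stated in
the source. `synthesize_karyotype()` appends the fused band tokens to the
constitutional prefix, omitting IG deletions as the published tables do;
translocations and derivative chromosomes are passed through, never
reconstructed. The packaged cytoband map is synthetic (a stylized arm
tiling, with chromosome 21 drawn finely enough to name 21q22.12); any
UCSC cytoBand.txt can be substituted, and fixture calls carry their
printed band spans so table rendering does not depend on the synthetic
map.

## The simulator, and what passing tests do not show

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes: Poisson CNA counts per patient (group means default to
3.46 and 1.9, the published cohort means), loss:gain odds 63:41 (t-AML)
and 1:1 (p-AML), log-uniform sizes, occasional whole-chromosome events,
per-event clonal fractions uniform on [0.6, 1] (mirroring the
at-least-60%-blasts sample selection), germline CNVs implanted with
identical breakpoints across carriers, IG deletions at the configured
loci (default probabilities 8/30 and 2/36), Gaussian probe noise (sd
0.15), and dye-swap pairs for the t-AML group. A fixed seed determines
the output completely, and ground truth is returned per event.

What the simulator does *not* emulate - and what recovery tests therefore
cannot certify on real arrays: GC waves and other spatially correlated
noise, replication-timing artifacts, probe-specific response, subclonal
mixtures beyond one clonal fraction per event, and genuinely ragged
breakpoints. Passing recovery tests show the algorithmic chain is
correct at array-like noise levels, not that real-array normalization
issues are handled.

Problem sizes used by the test-suite properties, chosen to keep the whole
suite under a couple of minutes: 200 seeded single-implant profiles of
1000 probes (recovery ≥ 95% at breakpoint error ≤ 2 probes), 100 null
profiles of 10,000 probes (mean false calls < 1), 1000 truth-only
simulated patients for the Poisson-mean check, and exhaustive Fisher
verification over all 2×2 tables with margins ≤ 12.

## Known limitations

* The published per-patient tables contain internal inconsistencies
  (their prose totals disagree with their own rows for the de novo
  group); this package asserts the tables, and direct counting gives
  68 CNAs (36 gains, 32 losses) for p-AML.
* The de novo MCR rows are themselves inconsistent (printed sizes vs
  bounds), so only the therapy-related catalog is reproduced exactly.
* The seeded-intersection reconstruction is exactly that - a
  reconstruction; its candidate set is a superset of the curated catalog
  by design.
* Genome build: fixture coordinates are used exactly as printed
  (hg18-era); no liftover is provided.
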