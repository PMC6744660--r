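---
title: "Methods: concordance, nucleotide variation and ploidy in dichotomous plantain"
author: "musadicho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordance, nucleotide variation and ploidy in dichotomous plantain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musadicho)
```

## The biological problem

Plantain (*Musa* spp., AAB genome) normally flowers once, from a single
spike, and bears one fruit bunch per pseudostem. In some False Horn
cultivars the spike branches — inflorescence dichotomy — and the plant
carries two or three bunches. Three questions make this quantitatively
tractable:

1. **Is the multi-bunch phenotype stable across crop cycles?** A stool
   fruits repeatedly: the initial *plant crop* is followed by *ratoon*
   crops regrown from suckers. If dichotomy were a fixed genetic trait, a
   double-bunching plant should stay double-bunching in its ratoons.
2. **Do the dichotomous cultivars differ cytologically?** Plantain
   landraces are typically triploid (2n = 3x = 33, basic number x = 11);
   a shift to the diploid 2n = 2x = 22 state is a strong marker of genomic
   instability.
3. **Do their gene sequences diverge?** Single-nucleotide differences in a
   conserved regulatory gene region, classified chemically
   (transition/transversion) and by codon effect
   (synonymous/non-synonymous), separate silent drift from changes with
   protein-level consequences.

The package implements all three analyses plus a seeded synthetic-data
layer, because the original field, cytology and sequencing records are not
available as machine-readable archives: every generator carries explicit
truth labels so the callers can be validated end-to-end by round-trip.

## Crop-cycle concordance

For one cultivar, let $N_{ii}$ be the number of ratoon observations whose
bunch count equals the same plant's plant-crop bunch count and $N_{ij}$
($i \neq j$) the number that differ. The concordance coefficient is

$$\mathrm{CC} = \frac{\sum_i N_{ii}}{\sum_i N_{ii} + \sum_{ij} N_{ij}}.$$

`compute_concordance()` reports CC on $[0,1]$ — the scale on which the
per-cultivar values (1.00 down to 0.00) are conventionally quoted — with a
`percent = TRUE` flag for the 0–100 convention. Both ratoon cycles are
pooled into one denominator, and observations with missing bunch counts
(dead plants) are excluded from both numerator and denominator rather than
counted discordant. A cultivar with *no* usable ratoon observations has no
defined coefficient; the function refuses with a classed error instead of
returning 0, because CC = 0 is a meaningful statement ("fully random"),
not a missing value.

`classify_persistence()` labels a cultivar *Normal/Persistent* when
CC $\geq$ a threshold and *Random/Non-persistent* otherwise. The threshold
defaults to 1.0: in the study design every cultivar below perfect
concordance behaved as a random trait, so persistence is reserved for
perfect agreement. The comparison is `>=`, so CC exactly at the threshold
is Persistent.

Properties the tests enforce: permutation invariance, the
numerator/denominator accounting identity, monotonicity under flipping a
discordant observation, and Monte-Carlo convergence of CC to the
generator's concordance probability.

## SNP calling and classification

`call_snps()` walks a gapped multiple alignment column by column against a
designated reference. A column yields a SNP record only when *both* the
reference and the sample hold an unambiguous base (A/C/G/T) and those
bases differ; gap and `N` columns are excluded (their count is kept as an
attribute, never silently discarded). Positions are 1-based ungapped
reference coordinates, so records remain meaningful after the alignment is
discarded.

Each record is annotated twice:

* **Chemically** (`classify_substitution()`): purines Pu = {A, G},
  pyrimidines Py = {C, T}; a substitution is a *transition* when both
  bases share a class and a *transversion* otherwise. Of the 12 ordered
  base pairs, 4 are transitions and 8 transversions — an exhaustive
  enumeration test pins this partition.
* **By codon effect** (`annotate_codon_effect()`): the codon grid starts
  at `frame_offset` (default 1); the reference codon and the codon with
  the alternate base substituted are translated under the standard genetic
  code (the package carries its own 64-entry table with three-letter
  symbols; the test suite cross-checks every one of the 9 × 61 single-base
  sense-codon substitutions against an independent translation oracle).
  A change is *synonymous* exactly when the two translations agree.
  Substitutions in an incomplete trailing codon raise an out-of-frame
  error rather than guessing.

`detect_deletions()` reports maximal runs of sample gaps opposite
reference bases, merged per run with ungapped start and length. Gaps in
the reference row are insertions: they are detected separately
(`detect_insertions()`) and never counted as deletions or SNP sites,
since the analysis design reports only a deletion block.

`summarize_cultivar()` condenses a sample's records into one reporting
row: the total SNP-site count, the **two most frequent** substitution
types with their counts (ties broken lexicographically), the majority
Pu/Py pattern, a representative amino-acid change, and the row's mutation
type — *non-synonymous* if any record is non-synonymous, *synonymous*
only when every record is silent. Reporting the top two types rather than
an exhaustive spectrum is deliberate: the per-cultivar rows this format
mirrors list only their two dominant types, and those listed counts
under-sum the site totals, so the remainder cannot be attributed
type-by-type.

**Reference choice.** The single-bunching control cultivar cannot serve as
its own reference (it carries substitutions itself), so in the pipeline
all six cultivars — control included — are compared against a synthetic
ancestral reference sequence, and each sample is called independently
against it. Multi-allelic columns therefore need no joint treatment.

## The variant generator

`implant_variants()` inverts the caller: given a substitution profile it
builds a mutant haplotype such that

1. every *listed* type (e.g. 46 T>G / 23 C>A) occurs exactly its listed
   count of times;
2. the remaining sites, up to the profile's total, carry substitutions of
   the row's overall class — transitions for Pu–Pu/Py–Py profiles,
   transversions otherwise;
3. the profile's named amino-acid change is realised at its stated codon
   index when that codon is feasible, else at the first feasible codon;
4. no two substitutions share an alignment column, and for a synonymous
   profile every individual substitution is synonymous;
5. an optional deletion block becomes a contiguous gap run, with
   substitutions kept out of it.

Two constraints deserve spelling out. First, some named amino-acid
changes (Val→Lys, Leu→Gly) are unreachable by any single base change
under the genetic code, because the codon families differ at two or more
positions; the generator realises such a change as the minimal multi-base
set of single-nucleotide substitutions within one codon, each counting as
one SNP site and each annotated per-site exactly as the caller will see
it. Second, filler substitutions (rule 2) *exclude* the listed type pairs
and are capped per pair below the smallest listed count. Without this,
random fillers of a listed type would inflate its count past the printed
value and the "top two types" summary would no longer recover the profile;
with it, `summarize_cultivar()` on the called SNPs reproduces the
generator's input profile, which the tests assert.

`generate_reference_cds()` draws codons uniformly from the 61 sense
codons, so the frame holds no internal stop, and then guarantees that
every amino acid appears at least once when the length allows — as any
real coding region of a few hundred codons would. This matters for rule
3: a named change from an amino acid absent from the translation would be
unplaceable. Synonymous profiles constrain placement hardest (a
synonymous G>A needs a third-position G in a suitable codon family);
around 600 bases — the default analysis length — leaves a comfortable
margin for the largest profile, and the generator fails loudly with a
placement error rather than silently truncating when a profile cannot be
realised.

## Ploidy from chromosome counts

`count_to_ploidy()` reduces a plant's metaphase counts to their mode —
robust to the occasional miscounted spread, which is why at least ten
cells are counted per plant — with ties resolved to the lower count. The
mode $m$ is converted to the multiplier $k = \mathrm{round}(m/x)$ of the
basic number ($x = 11$ by default, giving 22 → 2x, 33 → 3x), accepted only
when $|m - kx| \leq$ `tolerance` (default 1). A mode far from every
multiple (for example 27) is refused with an aneuploid-or-miscount error:
rounding it would manufacture a cytotype the data do not support.

## Ploidy from flow cytometry

A DNA-content histogram records nuclei per fluorescence channel; relative
DNA content scales linearly with channel, so a sample of ploidy $p$
co-chopped with an internal standard of known ploidy $p_c$ peaks near
channel $c \cdot p / p_c$, where $c$ is the standard's peak channel. The
channel scale itself is instrument- and gain-dependent, which is why
`control_channel` is a mandatory per-run input to the flow caller rather
than a constant.

`detect_peaks()` smooths counts with a moving average (default window 5
channels, shrinking at the edges) and keeps local maxima whose
topographic prominence is at least `min_prominence_frac` (default 0.05)
of the maximum smoothed count. Histogram end-points never qualify as
peaks, which also keeps the monotone debris slope at the low end out of
the peak list. The original instrument performed its peak analysis in
firmware, so this procedure is the package's own definition, exposed as
configuration and validated against constructed histograms.

`call_ploidy_flow()` removes peaks inside the control band (relative
half-width `control_band`, default 0.1, around `control_channel`), takes
the dominant remaining peak $p$, and calls
$k = \mathrm{round}(p_c \cdot p / c)$, accepted only while $p$ lies within
`max_rel_deviation` (default 0.2) of the implied position $k c / p_c$.
When only the control-band peak exists the sample is called at the
control's ploidy — the merged-peak case of a sample that *is* effectively
triploid. Because the call depends only on the ratio $p/c$, it is
invariant under a common rescaling of the channel axis, and the tests
assert this. `summarize_cohort()` tallies calls by ploidy and returns
refused calls alongside, never dropping them.

Counting and flow calls for the same plant are reported side by side
(`ploidy_table()`, the familiar "2x (4x)" display); the package never
reconciles a disagreement between the two assays, because such
disagreements are observations about unstable material, not errors to fix.

## The histogram generator

`generate_flow_histogram()` draws the sample peak as a discretised
Gaussian at $c \cdot p / p_c$ with standard deviation `cv` times the
centre, the control peak at $c$, and a debris tail. Defaults, chosen once
as realistic run conditions and fixed:

| parameter | default | meaning |
|---|---|---|
| `control_channel` | 75 | standard's peak; places a diploid sample at channel 50 |
| `control_ploidy` | 3 | triploid internal standard |
| `cv` | 0.03 | peak coefficient of variation; 3% is a clean plant-tissue run |
| `debris_fraction` | 0.10 | share of events in the low-channel debris tail |
| `n_nuclei` | 5000 | events per run |
| `n_channels` | 256 | analyzer resolution |
| `control_fraction` | 0.25 | standard's share of non-debris nuclei, keeping the sample peak dominant |

Debris decays geometrically (rate 0.1) over the lowest 20% of channels —
a shape choice, since debris is visible but unparameterised in published
histograms. A requested peak centre beyond the channel range is rejected
as a mis-scaled simulation rather than clamped. Counts are conserved
exactly: every drawn event lands in some channel and the total equals
`n_nuclei`.

`generate_cohort()` derives one sub-seed per plant from the master seed,
so a cohort is reproducible as a whole and per plant. The recovery tests
run cohorts at cv 5% and debris 20% — harsher than the defaults — across
20 seeds and require every call to match truth.

## What the synthetic data does and does not emulate

The generators reproduce the *structure* of the study's four input kinds
— phenology tables with stochastic ratoon reversals, variant-implanted
gapped alignments, per-cell chromosome-count tables with ±1 miscounts,
and two-peak DNA histograms with debris — under known truth. They do not
emulate PCR or sequencing error, alignment uncertainty, aneuploid or
mixoploid nuclei, inter-run drift of the channel scale, or any sequence
evolution beyond the specified substitutions and the single deletion
block. Passing round-trip tests therefore demonstrates that the callers
are exact inverses of a clean data-generating process at realistic noise
levels, not that they are robust to pathologies the generators do not
model.

## Numerical and design choices

* All randomness passes through one master seed; stage and per-plant
  sub-seeds are derived by hashing the stage name, so stages rerun in
  isolation reproduce the pipeline run. Generators restore the caller's
  RNG state.
* Coordinates are 1-based and ungapped-reference throughout; intervals
  are closed.
* Ties: modal chromosome counts resolve to the lower count; substitution
  type rankings and majority Pu/Py patterns break ties lexicographically.
* Degenerate inputs fail loudly with classed errors
  (`musadicho_no_peaks`, `musadicho_aneuploid`,
  `musadicho_undefined_concordance`,
  `musadicho_placement_failure`, ...), never silently coerced.
* Analysis problem sizes: the worked examples and validation runs use a
  600-base reference (200 codons), 10 plants × 2 pooled ratoon
  observations per cultivar, 100-plant flow cohorts and 10 metaphase
  cells per plant — the scale of the original field and laboratory
  design.

## Worked example

```{r example}
profiles <- cultivar_profiles()

# concordance on a simulated field design
ph <- generate_phenology(profiles, 10, 2, seed = 1)
concordance_table(ph$records)

# variant round trip for the double-bunching cultivar DB1P
ref <- generate_reference_cds(600, seed = 1)
imp <- implant_variants(ref, profiles$DB1P$substitution_profile, seed = 2)
snps <- call_snps(imp$alignment, "DB1P")
summarize_cultivar(snps, "DB1P")

# flow cytometry on a 100-plant cohort
coh <- generate_cohort(data.frame(ploidy = c(2, 4), count = c(95, 5)),
                       seed = 3)
summarize_cohort(call_cohort(coh$histograms, control_channel = 75))
```

## Known limitations

* The SNP caller compares haplotype consensus sequences; it has no notion
  of heterozygous genotypes, which is why the VCF-style output carries no
  genotype columns.
* Insertions relative to the reference are detected but not integrated
  into the substitution summaries.
* The flow caller assumes exactly one internal standard and unimodal
  sample material; a genuinely mixoploid sample would surface as either a
  refused call or a call for its dominant cytotype.
* Synonymous-only profiles need references long enough to supply
  synonymous placements of every listed type; the generator reports a
  placement failure instead of degrading the profile.
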