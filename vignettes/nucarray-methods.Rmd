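---
title: "Models and methods behind nucarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical models it
implements, the assumptions they rest on, the parameters that matter, and
the numerical choices made where the procedures were genuinely open.  It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## From fragments to dyads

A paired-end MNase-seq fragment is reduced to a single dyad estimate, its
midpoint.  All coordinates are 0-based half-open internally (BED
convention on disk); 1-based inputs are converted at the boundary.  Two
conventions had to be fixed where the field's practice is silent:

* **Even-length midpoints.** A fragment of even length has two central
  bases; we take the left one, `start + floor((L - 1) / 2)`.  This is
  deterministic and strand-independent, so pooling libraries sequenced in
  either orientation cannot introduce a half-base drift.
* **Minus-strand single-end dyads.** Single-end reads place the dyad
  `offset` bp downstream of the 5' end (default 75 bp, half a
  median-sized fragment).  On the minus strand the 5' end is the *last*
  aligned base and "downstream" points leftward.

Quality defaults follow common practice for this assay: mapping quality
at least 10, fragment sizes restricted to the central 95% of the size
distribution (126–184 bp for a Normal(152, 11.5²) size law), a narrower
142–152 bp subset for positioning scores, and per-library deduplication of
identical (chromosome, start, end) fragments.  Deduplication is
deliberately *per library*: identical coordinates across libraries are
independent observations, within a library they are likely amplification
artifacts.  Note that at high per-base coverage deduplication also caps
genuine pileups, which is why it is applied for the score-versus-null
comparison (where amplification artifacts would inflate the observed
tail) but not for the template scan.

## The bias-matched empirical null

MNase cutting is sequence-biased, and mappability is uneven; both can
masquerade as positioning.  The null model is therefore *simulated*
fragments: lengths drawn from the observed size distribution, positions
uniform over mappable bases, then rejection-sampled so the 4-mer
composition of the first and last four fragment bases matches the
observed end composition.

Choices made here:

* Left and right ends are weighted **independently**
  (`w = t_L/p_L × t_R/p_R`); the joint end composition of a 150-bp
  fragment is dominated by its marginals, and a joint 8-mer table would
  be hopelessly sparse.
* The proposal end distribution `p` is the genome-wide forward-strand
  4-mer frequency — exactly the marginal end composition of a uniformly
  placed fragment (up to edge effects of order fragment length / genome
  length).
* Weights are capped at the empirical maximum over proposals, so
  acceptance is exact rather than approximate.
* 4-mer tables carry pseudocount 1; log-ratios floor both sides at
  ε = 10⁻⁶.
* Mappability is enforced by rejecting fragments whose end bases are
  unmappable.  This is a shortcut relative to re-aligning simulated reads
  with the original aligner: it treats mappability as a property of the
  two end positions rather than of the full read pair, which is the
  right first-order approximation and keeps the simulator
  self-contained.

DNase I nick bias is a hexamer rate table: nicks per genomic occurrence
of the 6-mer spanning positions −3..+3 around the nick, with minus-strand
contexts read as reverse complements and occurrences counted
strand-symmetrically.  The table satisfies the conservation identity
Σ rate × occurrences = total nicks used, which the tests check.

## Rotational diagnostics

Dinucleotide and nick profiles are accumulated dyad-relative (dyad at
offset 0; a 147-bp fragment spans −73..+73).  Dinucleotides are counted
on the forward genomic strand only — keeping all 16 dinucleotides
separate preserves the strand asymmetry that pooling would erase.

Periodicity is quantified by `periodicity_power()`, which reports two
deliberately different numbers:

* **best_period** — located on a zero-padded spectrum (4096 points) for
  sub-bp resolution;
* **power_fraction** — the share of total non-DC power (unpadded
  periodogram) inside the period band, so a pure in-band tone scores ≈ 1
  and white noise scores ≈ the band's bandwidth share.

For *comparing phasing strength* across conditions, the right quantity is
neither of these but `phasing_amplitude()`: the amplitude of the
best-fitting in-band sinusoid relative to the profile mean.  A strongly
phased profile concentrates power in harmonics of the repeat length,
which *lowers* its band power fraction while raising its amplitude; the
genotype-ordering analyses therefore use the amplitude.

The strand lag between the plus- and minus-strand nick profiles is read
from the phase of the cross-spectrum at the dominant in-band frequency,
which resolves sub-bp lags (the generator's default 2.5 bp) that integer
cross-correlation cannot.  Rotational period estimation is restricted to
the nucleosome core (offsets within ±73 bp): the linkers contain
translational-lattice structure at 10-bp spacing that is real but not the
rotational signal being measured.

The midpoint-phasing correlogram requires the ascertainment and test
tracks to come from disjoint library sets and refuses to run otherwise —
shared libraries would correlate through amplification artifacts rather
than chromatin.

## Positioning scores and their calibration

`S(i)` is the fraction of midpoints in a 201-bp window around site *i*
lying within 15 bp of *i*; a region's score is the maximum over its
sites.  Sites near region edges use midpoints beyond the boundary when
the track provides them — truncating the window would bias edge sites
upward.  Ties in the argmax resolve to the site closest to the region
midpoint, then leftmost (for even-width regions the midpoint is taken as
`start + width/2`); the same rule is used for score-track peak calling,
extending the published chromosome-12 tie rule to all scoring.  Regions
with fewer than 50 midpoints are flagged invalid rather than scored.

Empirical p-values are strict exceedance fractions against the pooled
null scores, floored at 1/(N+1) so the q-value step never sees a zero.
π₀ uses fixed λ = 0.5; with thousands of null scores the smoother gains
little and the fixed-λ estimator is transparent and testable.  The null
score set must be computed at the *same midpoint depth* as the observed
set — the score distribution depends on counts per window, so a
half-depth null shifts every p-value.  The simulator is therefore always
run with `n` equal to the observed fragment count.

## The array template model

Counts in a k-bp window are multinomial; the LLR against the uniform
null is `Σ xᵢ ln(λᵢ k)` in natural log (a display flag converts to other
bases).  Three numerical rules keep it well behaved:

* templates are floored at ε = 10⁻⁶ and renormalised, so no position has
  probability zero and no count produces −∞;
* the statistic is exactly linear in counts (no per-window
  normalisation), which the tests verify to 10⁻¹⁰ against term-by-term
  evaluation;
* when a template is placed at an offset inside a wider window, the
  uncovered window positions carry the same per-site probability as the
  uniform null.  They then contribute exactly zero to the LLR, which
  resolves the tension between "all data in the window enter the
  likelihood" and a template narrower than the window — and makes LLRs
  comparable across offsets.

The same uniform-referenced weights (`ln(λ k)`, not `ln λ`) are used for
the *alignment* step of template training.  This matters: with bare
log-probabilities, a placement that slides high-count positions off the
template edge escapes their trough penalty and alignment fails
systematically; with uniform-referenced weights off-template counts are
neutral and placements are compared fairly.

Training iterates align → accumulate → smooth (5-bp centred mean) →
floor → renormalise → (optionally) symmetrise, stopping when the L1
change drops below tolerance.  It is deterministic given the input
order.  The default initial template — five Gaussian bumps (SD 20 bp) at
186-bp spacing over 879 bp — encodes only the published geometry (five
nucleosomes, symmetric, 879 bp); training sharpens the shape.

The window test slides the template midpoint from −100 to +200 bp around
the window midpoint (as published, asymmetric; a symmetric option
exists).  Template positions overhanging the window match zero counts.
The genome scan strides the template at 5 bp, drops windows with LLR
below 50 or fewer midpoints than template positions, and merges
surviving overlaps into maximal intervals annotated with their best LLR.

**Permutation FDR.** One position-wise shuffle per region by default
(`n_perm` raises it), `FDR(t) = #{perm ≥ t} / #{obs ≥ t}` clamped to
[0, 1] and made monotone non-increasing in *t*.  The `drop_top` scheme
zeroes the 147-bp footprint of the best single-nucleosome match (a
147-bp Gaussian-bump template) in observed and permuted data alike;
`keep_two` protects two randomly chosen called-nucleosome footprints
from the shuffle.  The 147-bp footprint width is the canonical
nucleosome core — the published procedure names no width.

**Flanking arrays.** Around a binding-site summit the model is
`[1-kb upstream template | uniform NFR of width w | 1-kb downstream
template]`, w on a grid from 0 to 200 bp.  NFR sites carry the uniform
per-site probability of the spanned region (the "region mean rate"), the
remaining mass splits equally between the halves, and the ML width wins.
Half-templates are built either directly (Gaussian bumps with the
innermost dyad 74 bp outside the NFR edge — half a nucleosome core, so
the footprint abuts the NFR) or derived from a trained master template by
mirroring its outward-decaying half and tiling the terminal repeat
period.  A fit is flagged unidentifiable when the best LLR varies by less
than 1 nat across candidate widths; with Poisson noise this flag fires
only for essentially structureless windows, and genuinely uniform noisy
windows are instead recognisable by their deeply negative LLRs.

## Repeat length estimation

Midpoints are aggregated around anchor peaks (±1000 bp), smoothed with a
10-bp sliding mean, and local maxima dominating ±30 bp located (plateaus
resolve to their centre, so noiseless lattices are recovered exactly).
The repeat length is the least-squares slope of peak offset on signed
peak index.  Index assignment is the one genuinely fragile step: the
initial spacing estimate comes from the aggregate's dominant spectral
period (band 120–280 bp), which is robust to spurious local maxima in a
way the median inter-peak gap is not; off-lattice maxima (more than a
quarter period from their lattice position) are discarded and duplicate
indices keep the closest peak, with one refit pass.

## dsQTL aggregation

The DNase-sensitive region of a dsQTL is defined on the combined
sensitive + heterozygous nick track smoothed with a 101-bp centred mean
(mean, not sum — only relative comparisons are used and means stay
interpretable across depths): peak = maximum within ±200 bp of the dsQTL
midpoint (ties to the midpoint, then leftmost), region = the contiguous
run around the peak exceeding half the peak value.  Three filters apply
in order — edge more than 100 bp from the midpoint; overlapping sensitive
regions (both members of a pair are removed, the interpretation most
consistent with the published discard counts); genotype-mean
inconsistency (het above sensitive, or insensitive above either).
Aggregation centres every region on its sensitive-region midpoint and
scales each sample's contribution by its total read count
(counts-per-billion; the post-filter total is the denominator).  The
narrow/large-effect subset uses strict inequalities against the cohort
medians.

## The synthetic-data generator

The generator realises the statistical structure the analyses assume,
with truth labels for recovery testing:

* **Fragment sizes**: Normal(mean 152 bp, SD 11.5 bp) truncated to
  126–184 bp — the published law for this assay.
* **Dyad mixture**: a nucleosome with positioning strength *p* places
  fragments at its major position with probability *p*, at ±10/±20 bp
  lattice neighbours with geometrically decaying probabilities *pd*,
  *pd²* (default decay 0.25), and the remainder uniformly over ±73 bp.
  The mixture directly realises the observed major/minor 10-bp structure
  with interpretable knobs, rather than deriving it from an energy
  model; the constraint `p(1 + 2d + 2d²) ≤ 1` is validated at
  configuration time.
* **Arrays**: dyads every NRL within an interval.  **Barriers**: an NFR
  of configurable width with five phased nucleosomes per side (first
  dyad 74 bp outside the edge); genotype-linked barriers scale their
  strength with allele dosage 2/1/0 per sample, and dosage-0 samples
  scatter those dyads over a full repeat length (no phasing).
* **DNase nicks**: Poisson per base and strand; linker rate ×3,
  rotational modulation `1 + 0.8 cos(2π(offset − shift)/10.2)` inside
  footprints with a 2.5-bp strand shift, and dosage-scaled
  hypersensitivity at active barrier NFRs.
* **Multi-sample designs** share one truth with fragments multinomially
  split across libraries, emulating a seven-cell-line design and the
  4-versus-3 ascertainment split.
* **Container repeats**: tandem GC-rich cores with AT-rich spacers
  (unit 188 bp by default), lightly mutated so copies are degenerate.

What it does **not** emulate: real sequence-dependent nucleosome
affinity (positioning is planted, not emergent), PCR duplication,
aligner error, chromatin-state heterogeneity, or inter-individual
variation beyond barrier dosage.  Passing recovery tests therefore show
that the estimators recover the *planted* structure at realistic depth
and noise — not that real chromatin contains such structure.

## Problem sizes used by the tests

The suite runs the full stack at deliberately modest sizes chosen so the
statistical claims are still meaningful: oracle equivalence on 1,000
random tracks; null calibration with 5,000 regions on a 2-Mb genome at
0.6 midpoints/bp; FDR calibration and power on a 5-Mb genome with 2,000
test regions, half containing planted arrays (NRL 190 bp, strength 0.6);
NRL recovery from 50,000 fragments; rotational recovery from >10⁵ nicks;
simulator fidelity at 2.5 × 10⁵ fragments (where the multinomial
sampling noise of the 256-cell end-composition table is comfortably
below the 0.02 total-variation contract); NFR recovery at widths 0, 80,
140 and 200 bp; and a byte-identity check of the full pipeline run twice
under one seed.

## Known limitations

* Single-end dyad placement assumes a fixed fragment size; the strand
  convention for minus-strand reads is an interpretation (the published
  arithmetic covers only the plus strand).
* The flanking-array fit assumes mirror-symmetric templates; asymmetric
  nucleosome organisation at oriented motifs is not modelled.
* The permutation null shuffles positions within a window, which
  preserves the count total but not local autocorrelation; with one
  permutation per region the FDR curve is coarse (raise `n_perm` for
  smoother curves).
* `stratify_and_aggregate()` aligns regions piecewise on the two NFR
  edges with an NA-padded centre, rather than continuously warping the
  centre segment; columns supported by fewer than half the peaks are
  masked.
* The scan's uniform null spans all template positions; a
  mappability-aware null is available as an option but windows failing
  the mappable-fraction filter are simply dropped.
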