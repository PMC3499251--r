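# nucarray

Nucleosome positioning and phased-array analysis from paired-end MNase-seq
fragment midpoints.

## The problem

Micrococcal nuclease preferentially digests linker DNA, so size-selected,
paired-end-sequenced MNase fragments mark nucleosome positions: the midpoint
of a ~147-bp fragment estimates the nucleosome dyad at base-pair resolution.
Given deep midpoint maps, the questions this package answers are the ones a
chromatin lab asks of such data:

- How consistently is each nucleosome positioned across cells
  (*translational* positioning), and how much of that apparent consistency
  is explained by MNase sequence bias and mappability?
- Do nucleosomes keep their helical orientation (*rotational* positioning),
  visible as 10-bp periodicity in dinucleotide content, DNase I nicking and
  inter-cell-line midpoint offsets?
- How much of a genome is organised into regularly spaced nucleosome
  *arrays*, where are they, and are they phased against protein-binding
  barriers whose strength can depend on genotype?

It is aimed at computational genomicists working with MNase-seq (or
comparable chromatin accessibility) data who want the full statistical
pipeline — bias-corrected empirical nulls, calibrated FDRs and
parameter-recovery-tested estimators — rather than a raw coverage browser.

## The statistics at the core

**Positioning score.** At genomic site *i* with midpoint counts
*x<sub>j</sub>*,

&nbsp;&nbsp;&nbsp;&nbsp;S(i) = Σ<sub>|j−i|≤15</sub> x<sub>j</sub> / Σ<sub>|j−i|≤100</sub> x<sub>j</sub>,

the fraction of midpoints in a 201-bp window that lie within 15 bp of the
site; a region's score is the maximum over its sites.  Empirical p-values
come from scores of bias-matched *simulated* fragments (rejection-sampled so
their end 4-mer composition matches the data), and the fraction of regions
positioned better than chance is estimated as 1 − π₀ with Storey's
π₀ = #{p > λ} / (m(1 − λ)).

**Array template model.** Midpoint counts in a k-bp window are multinomial
with placement probabilities λ (an 879-bp symmetric template spanning five
nucleosomes by default, learned by iterative alignment).  The test statistic
against the uniform null λ₀ = 1/k is

&nbsp;&nbsp;&nbsp;&nbsp;LLR = Σ<sub>i</sub> x<sub>i</sub> ln(λ<sub>i</sub> k)  (nats),

maximised over template offsets.  Per-region permutation of the counts gives
an FDR for any LLR threshold; variants drop the strongest nucleosome or
protect two called nucleosomes from the shuffle.  Around binding-site
summits, two 1-kb half-templates separated by a uniform nucleosome-free
region (NFR) of unknown width (0–200 bp) are fitted by maximum likelihood.

**Repeat length.** Midpoints aggregated around called nucleosome peaks form
a phased oscillation; the nucleosome repeat length (NRL) is the slope of the
least-squares line through (peak index, peak offset) of the aggregate's
local maxima.

## Worked example

Everything below runs in a few seconds on a synthetic chromosome with a
planted 100-kb array (repeat length 190 bp, positioning strength 0.6):

```r
library(nucarray)

cfg <- synth_config(
  genome_length = 3e5, n_fragments = 3e5,
  arrays = data.frame(start = 1e5, end = 2e5, nrl = 190, strength = 0.6),
  lattice_decay = 0.2, background_frac = 0.5, seed = 42)
ds <- generate_dataset(cfg)

fr    <- size_filter(ds$fragments, 126, 184)
track <- compute_midpoints(fr, seq_lengths(ds$genome))
track
#> <midpoint_track> 1 chromosome(s), 300000 midpoints, libraries: s1

d <- ds$truth$dyads$pos[250]
positioning_score(track, list(chrom = "chr1", start = d - 100, end = d + 100))
#>   chrom  start    end     score argmax_site n_midpoints valid
#> 1  chr1 147305 147505 0.7150127      147400         396  TRUE

tmpl <- default_array_template(nrl = 190)
scan_genome(track, tmpl, step = 5, llr_min = 50, min_midpoints = 500)
#>   chrom start    end      llr
#> 1  chr1 99835 200104 767.6772

sc    <- positioning_score_track(track, "chr1", 1e5, 2e5, min_midpoints = 50)
peaks <- call_nucleosome_peaks(sc, start = 1e5)
estimate_nrl(track, peaks, span = 1000)
#> <nrl_estimate> repeat length 190.00 bp from 11 aggregate peaks (residual SD 0.00 bp)
```

Read it bottom-up: the region over a planted dyad scores 0.72 (moderately
strong positioning — the argmax site sits on the planted dyad at 147,400);
the genome scan recovers the planted array as a single merged interval
covering 99,835–200,104 with a peak LLR of 768 nats; and the repeat length
estimate recovers the planted 190 bp exactly.  `ds$truth` carries the
planted dyads, arrays and genotypes, so every estimate can be checked
against ground truth the same way.

The multi-stage runner `run_pipeline()` drives synth → fragments → score →
scan from one (YAML or list) config, writing BED/bedGraph/TSV outputs with
JSON provenance sidecars; identical config + seed reproduces every output
byte for byte.

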