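---
title: "Methods: STR fragment length analysis on simulated lab-on-chip electropherograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: STR fragment length analysis on simulated lab-on-chip electropherograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strchip)
```

# The assay model

`strchip` models STR-based authentication of murine cell lines as a chain of
four components: a marker panel, an electropherogram simulator, a trace
processor, and a profile comparator. The biological signal is simple: at a
tetranucleotide STR locus, an allele with $r$ motif copies yields a PCR
amplicon of

$$\mathrm{size} = \mathrm{flank} + 4\,r \quad [\mathrm{bp}],$$

where the flank term collects all non-repeat sequence between the primers.
Measuring amplicon sizes therefore measures repeat counts, and the vector of
repeat counts over a panel of loci identifies the mouse of origin.

## Panel

The default panel carries nine murine loci and the human sentinel D8S1106,
distributed over four multiplex PCR sets. Two structural rules are enforced
at load time and are central to the whole method:

* **within-set disjointness** — the predicted size ranges of loci co-amplified
  in one well must not overlap, so a sized peak identifies its locus with no
  other information; and
* **at most three loci per well**, the practical multiplexing limit at this
  peak density.

The published description of the assay does not include the primer appendix,
so the exact predicted size ranges and the composition of two of the four
multiplex sets are not public. The shipped defaults are therefore the
package's own design, chosen to honour every published constraint: unit 4 bp
at all loci, total amplicon span exactly 130–515 bp, set 2 = {9-2, D8S1106}
and set 3 = {15-3, 6-4} (both fixed by published per-set electropherograms),
sets 1 and 4 partitioning the remaining six loci three-and-three, and flank
offsets placed so that every repeat count in the shipped reference profiles
predicts a size at least two repeat units inside its locus range — a range
edge grazing a real allele would make calling sensitive to sub-bp sizing
error. Every number is overridable through the YAML config
(`load_panel()`), so the true appendix values can be dropped in without code
changes.

Size ranges are closed intervals and a boundary size belongs to the locus:
assignment must be deterministic.

## Simulator

The simulator stands in for the instrument and defines the study conditions
under which the pipeline is validated. A well is produced as

$$y(t) \;=\; \sum_i h_i \exp\!\left(-\tfrac{(t - t(s_i))^2}{2\sigma^2}\right) + \varepsilon(t),
\qquad t(s) = t_0 + a\,\log_{10} s ,$$

with i.i.d. Gaussian baseline noise $\varepsilon$. The log-mobility law is the
simplest strictly monotone, concave migration model consistent with real
chip traces; it is deliberately the same family the calibration assumes, so
simulator-vs-pipeline discrepancies isolate processing error rather than
model mismatch. Defaults (all arguments of `migration_model()`):

| parameter | default | meaning |
|---|---|---|
| `t0` | 10 s | migration intercept |
| `slope` | 60 s per log10(bp) | separation strength; at 250 bp one repeat unit (4 bp) maps to ≈ 0.4 s |
| `peak_sigma_s` | 0.1 s | Gaussian peak width; adjacent-repeat heterozygotes stay baseline-resolved up to ≈ 500 bp |
| `noise_sd_fu` | 0.5 FU | baseline noise; peaks are 50–100 FU, i.e. SNR ≈ 100–200, matching a clean chip run |
| `dt_s` | 0.02 s | sampling interval, ≈ 5 samples per peak sigma |
| `stutter_fraction` | 0 | stutter artifact height; off by default, available as a stressor |
| `amount_scale_fu`, `marker_height_fu` | 50, 75 FU | height per unit template amount; marker height |

Every well contains the two internal marker fragments (15 and 1500 bp by
default); the ladder well adds the 11 rungs 25–1000 bp. Rung and marker sizes
are vendor conventions for this chip class, not published in the source
study, and are configurable panel fields.

Dosage is modelled coarsely: a locus stored with one allele contributes one
fragment at double amount (both chromosomes make the same product), a
heterozygous locus two fragments at single amount. Mixtures scale the two
genomes' amounts by $1-f$ and $f$; the human sentinel amplifies only from a
human-derived template.

What the simulator does **not** emulate: migration-law misspecification
(real mobility curves deviate from a single log-linear law between rungs),
peak asymmetry/tailing, baseline drift, inter-well chemistry variation
beyond affine time distortion, primer-specific amplification efficiency, and
realistic stutter ladders. Passing the simulation-based tests therefore
demonstrates that the *processing chain* is correct and self-consistent at
instrument-realistic noise — not that the assay will behave on any given
instrument, which is what the per-locus `calibration_offset_bp` hook and the
config-overridable panel exist for.

## Trace processing

Peak detection is deliberately parameter-light and robust:

1. baseline = running median over a 2 s window (about 20 peak sigmas, so
   peaks do not bias it);
2. noise = scaled MAD of the detrended trace (robust to the peaks
   themselves);
3. candidate local maxima above `min_snr` × noise (default 5) with a minimum
   apex separation of 0.15 s;
4. a **topographic prominence** filter at the same threshold — a candidate
   must rise by the threshold above the saddle connecting it to taller
   terrain. This is what rejects noise wiggles riding on the flank of a real
   peak while keeping genuinely bimodal doublets (two alleles one repeat
   apart produce a deep valley);
5. apex refinement by a parabola through the apex sample and its two
   neighbours, which also yields a width and hence a Gaussian area estimate.
   Without the refinement, sizing error at 1000 bp would be dominated by the
   sampling grid (≈ 1.3 bp); with it the grid contribution is negligible.

Calibration pairs the ladder's non-marker peaks with the known rung sizes in
time order (a count mismatch aborts with both counts — silent re-pairing
would corrupt every downstream size) and interpolates $\log_{10}(\mathrm{size})$
piecewise-linearly in apex time, exactly through every anchor, extrapolating
with the terminal slopes. Monotonicity of the fitted map is asserted after
every fit. Sample wells are first aligned to the ladder by the unique affine
time map sending their two marker apexes onto the ladder's — markers are
identified positionally (first and last qualifying peaks), mirroring
instrument convention — making sizing invariant to affine migration drift
between wells.

## Allele calling

Sized peaks are attributed to loci by range containment, then per locus:

* tallest peak → first allele;
* a second peak is an allele iff its height is ≥ `het_ratio` (default 0.4)
  of the tallest **and** it is not explained as stutter, i.e. it does not sit
  one repeat unit below a taller peak at under `stutter_ratio` (default 0.3)
  of that peak's height;
* more than two surviving peaks → the top two are called and the locus is
  flagged `extra_allele`, the raw signal consumed by contamination
  detection.

Repeat counts come from nearest-integer rounding of
$(\mathrm{size}-\mathrm{flank})/4$; the residual is bounded by half a repeat
unit (2 bp) by construction. The nominal chip sizing resolution (5 bp) is
coarser than this bin width, which is why the calling path depends on
*relative* sizing consistency between ladder and samples rather than absolute
accuracy, and why a per-locus systematic offset (`calibration_offset_bp`,
default 0) is exposed for instruments with locus-specific bias. `het_ratio`
and `stutter_ratio` are not stated in the source assay description; the
defaults are conventional FLA analysis values at which equal-amount
heterozygotes call robustly under the default noise, and both are arguments
everywhere.

## Profile comparison

Match scores follow the shared-allele statistics of the human cell-line
authentication standard, computed over the murine loci called in both
profiles with multiset intersection per locus: Tanabe
$2S/(n_q+n_r)$ (symmetric) and the two Masters variants $S/n_q$, $S/n_r$.
Verdict thresholds default to 0.8 (match) and 0.55 (related) — the
convention established for human profiling; its transfer to murine panels is
an assumption, so the thresholds are arguments and are echoed in every
result object. The human locus never enters a score: it is purely a species
sentinel.

Contamination logic:

* **interspecies** — flag iff the human sentinel is detected *alongside* at
  least one called murine locus; a sample showing only the sentinel is a
  pure human sample, not a contaminated murine one.
* **intraspecies** — without prior information, a locus supports
  contamination when calling left an `extra_allele` flag (≥ 3 surviving
  peaks), and the flag is raised at ≥ `min_extra_loci` (default 2; a single
  locus can be stutter or noise). This rule is blind to a mixture of two
  fully homozygous (inbred-derived) lines, which produces at most two peaks
  per locus — indistinguishable, locus by locus, from heterozygosity.
  Authentication, however, always carries an identity claim, so
  `detect_intraspecies()` accepts the claimed line's reference profile and
  then also counts loci whose called alleles include values absent from the
  reference. A 1:1 mixture of the two wild-type-background progenitor lines
  is invisible to the blind rule but flagged at four loci against its
  claimed reference.

Passage stability is the degenerate comparison: replicate profiles of one
line (early passage, late passage, post-cryopreservation) are pairwise
identical at every commonly called locus, or the discordant loci are listed.

# Numerical and testing choices

* Degenerate inputs: an all-constant trace yields zero peaks (not an error);
  a size outside a locus' extended range is a no-call, not an exception;
  unassignable peaks are reported, never fatal.
* Ties: equal-height surviving peaks are ordered by size; database ranking
  breaks score ties by reference label.
* All randomness flows through explicit integer seeds; the same seed
  reproduces a trace bitwise.
* Validation problem sizes: the sizing experiment uses 500 uniform fragments
  over the full 25–1000 bp range with one ladder; genotype-recovery runs all
  six reference profiles × 4 wells × 3 seeds; oracle cross-checks (nearest-
  allele search, linear-scan locus lookup) use 10,000 random draws. These
  sizes give stable pass/fail behaviour at negligible cost.

# Known limitations

* The default panel's size ranges and two of the four set assignments are
  package constructions (see above), to be replaced by the assay's true
  primer data where available.
* The simulator and the calibration share the log-linear migration family;
  robustness to migration-model misspecification is untested by design.
* Mixture handling detects contamination; it does not deconvolve
  contributors or compute likelihood ratios.
* The comparison thresholds inherit the human-profiling convention without a
  murine population-genetic calibration.
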