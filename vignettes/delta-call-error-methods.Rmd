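---
title: "Detecting rRNA modifications from native-vs-IVT basecalling errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rRNA modifications from native-vs-IVT basecalling errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltacall)
```

## The measurement model

Oxford Nanopore direct RNA sequencing (DRS) reads native RNA molecules, so
chemically modified nucleotides pass through the pore and systematically
distort the ionic current. The basecaller, trained on unmodified RNA,
converts these distortions into reproducible basecalling anomalies at and
around modified positions. An in vitro transcript (IVT) of the same rRNA is
chemically unmodified but carries every sequence-dependent basecalling quirk,
making it the natural error baseline.

For each reference position $i$ and each sample, define the basecalling error
as the percentage of basecalls on the single most frequent *non-reference*
base:

$$\mathrm{Err}_i = 100 \times \frac{\max_{b \neq r_i} n_{i,b}}{\sum_b n_{i,b}}$$

where $r_i$ is the reference base and $n_{i,b}$ the count of base $b$ among
reads overlapping position $i$. Deletions are excluded from both numerator
and denominator (they are tallied separately; the composition model has four
basecall categories plus depth). The detection statistic is the per-position
difference

$$\Delta\mathrm{CallError}_i = \mathrm{Err}^{\mathrm{native}}_i -
\mathrm{Err}^{\mathrm{IVT}}_i ,$$

and a position is nominated as a candidate modification when
$\Delta\mathrm{CallError}_i > 10\%$ strictly. The 10% threshold is roughly
three times the average background miscalling level of DRS on these rRNAs
(about 2.9%, re-estimated from the IVT sample by `background_error()` as a
depth-weighted mean). Negative deltas are preserved in all outputs for QC but
are never callable.

Candidate pseudouridines (Ψ, written `psi` in machine-readable output) are
recognised by their signature: at a reference `U`, the dominant non-reference
call is `C` and `C` carries at least half of all non-reference calls.
Sub-threshold positions (delta in `(5, 10]`) within 1 nt of a supported
position are *neighbour-flagged* rather than called: a modified base distorts
the current of the whole k-mer, so its flanks often show elevated but
sub-threshold error (the classic worked example is a pair of flanking
adenosines at ΔCallError 9.1% and 9.9% around an MS-supported methylated
cytidine).

Finally, nanopore candidates are integrated with cryo-EM and mass
spectrometry evidence tables: a position supported by **at least two** of the
three orthogonal methods is a *consensus modification*. Types are assigned
with precedence experimental evidence > *E. coli* homology > `"?"`
(uncharacterised); methods reporting conflicting types degrade the record to
`"?"` with a warning rather than trusting either.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold_pct` | 10 | strict call threshold on ΔCallError (%); ≈ 3 × background |
| `min_depth` | 50 | minimum basecalls in *both* samples; binomial SE of a 10% estimate at n = 50 is ≈ 4%, acceptable for a screen (the source data are far deeper) |
| `neighbor_window` | 1 nt | reach of the neighbour effect; DRS k-mers make ±1 the conservative choice |
| `neighbor_floor_pct` | 5 | floor below which sub-threshold positions are treated as noise, not neighbours |
| `psi_dominance` | 0.5 | minimum C share of non-reference calls for the Ψ signature |
| `background_miscall` | 0.029 | generator: background miscall rate, as measured by the max-base statistic |
| `background_deletion` | 0.01 | generator: background deletion rate |
| length windows | 18S 1700–2000, 26S 2000–3300 nt | read-length filters selecting near-full-length molecules (inclusive bounds) |
| `truncation_rate` | 1e-4 /nt | geometric 5'-truncation of 3'-anchored reads; keeps most simulated reads near full length, like a length-filtered DRS library |
| `stoichiometry` | 1.0 | fraction of native molecules modified at a planted site; full stoichiometry is an assumption, not a measured value |

## What the synthetic generator emulates — and what it does not

`make_reference()`, `plant_modifications()`, `simulate_pileup()` and
`simulate_reads()` produce aligned-read sets (sorted BAM + truth BED) and
idealised pileups with the statistical structure the detector assumes:
~2.9% background miscall, ~1% deletions, elevated non-reference calls at
planted sites (C-skewed at Ψ sites), 3′-anchored reads with geometric 5′
truncation (DRS sequences 3′→5′, so truncations lose the 5′ end), and
constant per-reference depth.

Two generator choices deserve explanation because the obvious alternatives
are self-defeating under the max-base error statistic:

* **Background skew.** The 2.9% background is what the max-base estimator
  *measures* on real IVT data. If the generator spread background miscalls
  uniformly over the three non-reference bases, the estimator would read back
  only ~1% and the "threshold ≈ 3 × background" calibration would be
  meaningless. Each position therefore has one dominant background-miscall
  base (drawn once per position from the seed and shared by the native and
  IVT samples, as sequence-context-driven miscalls are), carrying
  `background_skew` (default all) of the background mass. A uniform split
  remains available (`background_skew = 1/3`).
* **Site skew.** Planted non-Ψ sites concentrate their miscall mass on one
  random non-reference base (`dominant_skew = 0.9`) rather than spreading it
  symmetrically. A symmetric 25% miscall would measure only ~8.3% and sit
  below the 10% threshold — contradicting the intended recoverability of
  sites with error rates ≥ 25%. One dominant miscalled base per site is also
  what real stacked base-composition panels show.

The generator does **not** emulate: raw current/squiggle signal or
basecaller behaviour (it plants basecalling outcomes directly), barcodes or
demultiplexing, per-read modification stoichiometry below 1 unless
configured, alignment artefacts (reads are planted at their true positions;
there is no mis-mapping), insertions, or k-mer-context-dependent error
*rates* (only the dominant miscalled base varies by position). A green test
on synthetic data therefore establishes that the statistics and plumbing are
correct — not that the basecaller will expose any particular real
modification, which depends on chemistry and sequence context.

## Numerical conventions and edge cases

* Coordinates are 1-based inclusive internally (rRNA residue numbering);
  BED output is 0-based half-open.
* Ties among non-reference bases are broken in the fixed order
  `A < C < G < U` and flagged (`tie_flag`).
* Zero-basecall positions have error 0 and no dominant base.
* The call rule is strict (`> 10%`): a delta of exactly 10.0 is not called.
* Positions failing `min_depth` in either sample are never called and carry
  `excluded_reason = "low_depth"`, whatever their delta.
* Neighbour flags require distance in `[1, neighbor_window]`: a position is
  not its own neighbour, and an MS-supported sub-threshold position is
  reported via the evidence table, not via a self-flag.
* A read may not begin or end in a deletion; the simulator trims such edge
  deletions (adjusting the alignment start) as an aligner would.
* Reads overlapping a position through a deletion count toward
  `depth` but not toward basecalls — "reads overlapping each position"
  includes them; whether the original analysis did is unknowable from the
  published material, so the convention is explicit here.
* The native and IVT dominant non-reference bases are determined
  independently; the identity is logged (`dominant_native`, `dominant_ivt`)
  so the stricter same-base variant of the statistic is auditable from the
  delta table.
* Consensus positions are matched exactly across methods; neighbour-flagged
  flanks are *not* merged into their supported neighbour and confer no
  method support. This avoids silently inflating the consensus count.

## Open design choices taken

* **Background averaging** is depth-weighted over positions with
  `basecall_depth >= min_depth`; with the generator's constant depth this
  coincides with the unweighted mean, and on real data it down-weights
  ragged ends.
* **Per-site stoichiometry** defaults to 1.0 (every native molecule
  modified). Published DRS surveys of rRNA rarely report stoichiometry;
  `stoichiometry` mixes the background emission model in at the read level
  when sub-stoichiometric sites are wanted.
* **Configuration files** use flat key–value DCF (`read.dcf`) rather than
  YAML, removing a dependency while keeping the config human-editable.
* **`plant_specific` is a curated input annotation**, not computed: deciding
  plant-specificity requires a bacterial-homology pipeline that is out of
  scope.
* The bundled evidence tables under `inst/extdata/` are **synthetic
  stand-ins** (see their README): positions named in the source survey's
  text are anchored; the remainder are invented so that the survey's
  aggregate counts (39 positions, 19 consensus, per-method 18/28/20, 8 Ψ,
  9 plant-specific) are reproduced exactly. Tests asserting those counts
  validate the consensus machinery against a known table — they are not a
  re-derivation of the survey from raw data.

## Known limitations

* The detector is a screen, not a classifier: apart from the Ψ signature it
  reports `"?"`, and it estimates no stoichiometry.
* Current-intensity (event-level) statistics are out of scope; only
  basecalling outcomes are modelled.
* Helix-69-like cases where external literature (a fourth source) confirms a
  site are not counted as method support: only the three in-house methods
  enter `n_methods`.
* The pileup engine materialises alignments in memory; fine for rRNA-scale
  references, not intended for transcriptome-wide use.

## A worked example

```{r example, eval = FALSE}
ref <- make_reference("18S", 1800, seed = 1)
truth <- plant_modifications(ref, n_sites = 5, psi_fraction = 0.4,
                             native_error_rate = 0.3, seed = 1)
cfg <- sim_config(depth = 500, seed = 1)
native <- simulate_pileup(ref, truth, cfg, "native")
ivt    <- simulate_pileup(ref, NULL,  cfg, "ivt")

background_error(base_error(ivt))          # ~2.9
det <- detect_modifications(native, ivt)
det[det$called, c("position", "ref_base", "delta_pct", "signature")]
```

Every number shown in the README's worked example is produced by exactly this
code path; nothing in the package stores precomputed results.
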