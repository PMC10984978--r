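---
title: "From nanofractionated plates to bioactive molecular networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From nanofractionated plates to bioactive molecular networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nanofrac` reconstructs bioactivity chromatograms from at-line
nanofractionation screens, aligns them with parallel LC–MS/MS data, detects
chromatographic features, networks their MS2 spectra and correlates
bioactive fractions with mass features. This vignette explains the model
behind each stage, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the design decisions
taken where the procedure was genuinely open.

```{r setup}
library(nanofrac)
```

## The measurement model

A sample is separated on a C18 gradient (run length ~41 min). After the
column the flow splits: the major part is deposited into a 384-well plate,
one well per 6 s of effluent, 350 wells per sample, walked in a serpentine
pattern over columns 1–23 (the 24th column holds the assay controls:
positive, growth, blank and sterility). The minor part is measured by
positive-mode ESI-MS with data-dependent MS2 of the top-3 ions per cycle.
Wells are assayed with a resazurin reduction readout: viable indicator
cells reduce resazurin to fluorescent resorufin, so *inhibition lowers
fluorescence*. Dividing every well by the median of the plate read gives a
unitless response near 1 for inactive fractions; plotting it against the
fraction collection time gives a chromatogram whose negative peaks are the
bioactive retention-time slices.

Because fractionation sits downstream of extra tubing and the assay
integrates a 6-s window, the bioactivity time axis lags the MS axis by a
delay on the order of 0.3 min. The delay is estimated from a single
injection of a calibrant that is both ionizable and antibacterial
(nalidixic acid): `delay = t(bioactivity dip apex) − t(MS peak apex)`.

## Stage by stage

### Plate handling (`plate_layout`, `normalize_plate`, `build_trace`, `detect_bioactivity_peaks`)

Fraction `i` (0-based) covers the half-open window
`[start + i·Δ, start + (i+1)·Δ)` with `Δ = 6 s`; half-open windows avoid
double-assignment at boundaries. The serpentine starts left-to-right at
row A — the plate maps of real runs do not pin the orientation, so it is
fixed (determinism) and configurable (escape hatch). Normalization divides
by the median over the *usable* wells of one read; whether controls join
the median is ambiguous in practice, so it is a flag
(`include_controls_in_median`, default off). Peak calling reports maximal
runs of at least `min_width = 2` fractions with response below
`threshold = 0.8`. Published screens show the peaks but state no cut-off;
0.8 with a 2-fraction minimum is conservative against single-well noise and
both are exposed in the config. Peak coverage is monotone in the threshold,
which the tests assert.

### Delay alignment (`estimate_delay`, `apply_delay`, `common_axis`)

Apexes are located as the weighted centroid of the contiguous region around
the global extremum where the excess over the trace median stays above half
its maximum. The centroid matters: the fraction grid is 0.1 min coarse, and
a raw grid extremum would consume the whole ±0.05-min recovery budget the
package holds itself to; the centroid of a symmetric dip is unbiased.
Because a well's response integrates the *following* 6-s window, trace
times (window starts) are shifted by half a window before the centroid —
`bio_times = "center"` disables this for instantaneous traces. The delay
sign convention is bioactivity − MS (fractionation is downstream of the
split), a sanity bound rejects |delay| > 5 min, and `common_axis`
interpolates both traces onto a uniform grid over the *intersection* of
their ranges: "aligning to the center" without extrapolation artifacts.

### Feature detection (`detect_features` and parts)

The chain mirrors the MZmine 2.53 modules used in practice, with the
printed parameters as frozen defaults (`detection_params()`):

| step | parameters (defaults) |
|---|---|
| centroiding | noise 1e4 (MS1), 0 (MS2) |
| EIC builder | min group size 10 consecutive scans, m/z tol 0.001 Da, group intensity 1e4, min height 5e4 |
| deconvolution | local-minimum search ±0.1 min, chromatographic threshold 90 %, min relative height 1 %, min absolute height 1e4, top/edge ratio 2, duration 0.05–3 min |
| MS2 pairing | 0.05 m/z, 1 min |
| isotope grouper | 0.001 m/z, 0.1 min, charges {1, 2} |
| duplicate filter | pass 1: 0.001 m/z / 0.05 min; pass 2: 1 m/z / 0.05 min |

The named MZmine modes ("single feature", "old average", ADAP-style
builder) are closed behaviors; this package fixes their semantics by
explicit post-conditions rather than bit-cloning. Choices worth knowing:

* m/z tolerances are absolute Da, as printed, not ppm.
* "Chromatographic threshold 90 %" is interpreted as a quantile clip: the
  peak body is the contiguous points around the apex *strictly above* the
  10 % intensity quantile of the sub-peak. Strictness stops zero-intensity
  baselines from stretching peak bodies (a flat baseline has its quantile
  at the baseline value itself).
* Edges for the top/edge ratio are the segment boundary intensities;
  boundaries at zero pass trivially (the ratio is effectively infinite).
* MS2 pairing ties resolve by smallest Δm/z, then smallest ΔRT, with the
  keys rounded to 1e-6 first, so isobaric features differing only in
  floating-point dust tie on m/z and resolve by RT. Among several MS2
  scans on one feature, the highest precursor intensity wins.
* The isotope grouper links A/A+1/A+2 chains transitively
  (union-find) at the ¹³C spacing 1.00335/z; the lowest-m/z member is the
  monoisotopic representative. Charges beyond 2 are out of scope but
  configurable.
* Row ids are assigned after deconvolution in (RT, m/z) order and every
  sort is stable, so identical inputs give byte-identical tables.

### Modified-cosine networking (`modified_cosine`, `build_network`)

Fragment intensities are square-root weighted. Peaks `a` from one spectrum
and `b` from another are candidate matches when `|mz_a − mz_b| ≤ 0.9` or
`|mz_a − mz_b − Δprecursor| ≤ 0.9`; the shifted channel is what lets
structural analogs (e.g. a CH₂ homolog ladder) match their
precursor-dependent fragments. The score is the maximum-weight one-to-one
assignment of candidates normalized by the product of the spectra's vector
norms.

A design deviation: the GNPS lineage resolves the assignment greedily
(highest product first). Greedy is almost always optimal but provably not
always — in prototyping it fell short of the optimum in roughly 0.2 % of
random small-spectrum pairs. This package therefore solves the assignment
*exactly*: candidate pairs are split into connected conflict components and
each component solved by branch-and-bound (a greedy fallback exists only
for pathological components of more than 25 candidate pairs, which do not
arise at these tolerances). The score becomes symmetric and
order-independent by construction, and the test suite keeps a naive
exhaustive matcher as an independent oracle that the implementation must
equal on 500 random pairs.

Edges require cosine > 0.7 *and* at least 4 matched peaks ("more than
three"); library annotation uses the deliberately different ≥ 3. Precursor
pairs closer than 0.02 Da are scored as same-precursor (zero shift).
GNPS-style mutual top-K pruning exists but is off by default — whether the
original networks used it cannot be established, and off is the
conservative choice. Spectral families are connected components with ≥ 2
nodes, ordered by size then smallest member id.

### Bioactive mapping (`map_bioactive_features`, `annotate_insource_relations`, `mark_network`)

A feature belongs to a bioactivity peak when its apex RT lies in the peak
window widened by `rt_tolerance` (default 0.1 min = one fraction; mapping
is by RT and a window had to be chosen — one fraction is the natural
quantum). Features may join several overlapping peaks; peaks with no
features are still reported with an empty feature list (they do occur in
real screens, e.g. when ionization fails). In-source relations among
co-eluting assigned features are labeled from a frozen delta table — water
loss 18.010565, deoxysugar losses 114.068080 / 130.062995, MeCN adduct
41.026549 Da — within 0.005 Da (printed deltas in real tables deviate from
exact by up to ~2 mDa, so 0.005 absorbs that without reaching the next
delta); two-step chains (sugar then water loss) are labeled as sums. The
table is user-extensible; only deltas with evidence in the validation
chemistry ship by default.

## The synthetic world

`simulate_run`/`simulate_plate` generate the stated acquisition world:
41-min run, MS1 every 2 s, top-3 data-dependent MS2, 6-s fractions into 350
wells, 0.3-min delay. The 2-s MS1 interval is a choice (instrument cycle
time is not published): it keeps a full run under 2 000 MS1 scans while
giving ≥ 10 scans across a peak of the default width. Peak width σ =
0.08 min makes a 1e6-apex peak satisfy the builder's
10-consecutive-scans-above-1e4 rule with margin; compounds elute as exact
Gaussians with A+1/A+2 satellites at +1.00335 (A+1 ratio 1.1 % per carbon —
adequate for exercising the grouper, not an isotope-pattern model). Noise
peaks stay below a 5e3 floor, i.e. under the centroid threshold, so they
exercise the I/O paths without polluting features. MS2 fragment sets of the
built-in homolog series share a fixed core plus precursor-shifted losses,
so the shifted cosine channel is genuinely exercised. The default
`demo_compounds("bacillus")` world pins the 8 actives at the validated
lipopeptide m/z and RT values (including two isobaric congeners 0.31 min
apart); `"streptomyces"` gives 14 well-separated actives at angucycline-like
masses; `"calibrant"` is the single delay-estimation compound.

Not emulated — and therefore not established by green tests: chromatographic
tailing, ion suppression and matrix effects, mass error (m/z values are
exact, so the 0.001-Da grouper tolerance is never stressed by calibration
drift), charge states > 1, profile-mode peak shape, and retention-time
drift between samples. A green end-to-end test shows the chain's logic and
thresholds behave as specified on clean data; it does not certify
performance on real instrument data.

Determinism: all generator randomness flows through one seed; the RNG state
is saved and restored around simulation, and the plate uses `seed + 1` so
run and plate noise are independent but reproducible. Floating-point
output formats are pinned, so artifacts are byte-identical across runs.

## Numerical conventions and degenerate inputs

* Atomic masses are frozen in-package (standard monoisotopic values);
  nothing is fetched. "Calcd."-style protonated m/z adds the mass of one H
  *atom* by default, matching the printed convention for protonated-ion
  formulas; the physically exact proton (electron-corrected) variant is an
  opt-in flag.
* RDBE is C − H/2 + N/2 + 1 with halogens counted as hydrogen; O, S, P are
  ignored.
* Median of an even count is the midpoint of the two central values (R's
  default), relevant for plate normalization.
* Empty spectra score cosine 0 with 0 matched peaks rather than erroring;
  an all-missing plate, a truncated mzML/mzXML, unordered scans and
  out-of-range fraction indices all raise errors rather than returning
  partial results.
* Times are minutes everywhere internally; CSVs serialize minutes with 4
  decimals, the MGF uses seconds (`RTINSECONDS`) at full precision, m/z is
  4 decimals in CSV and full precision in MGF.

## Known limitations

* Single-sample pipeline: no cross-sample RT alignment or gap filling; the
  quantification table carries one abundance column.
* The mzML/mzXML readers are minimal (centroid peak lists, RT, precursor
  metadata; 32/64-bit floats, zlib or none) — sufficient for the pipeline's
  needs, not a general-purpose parser.
* Library search scores with the same modified cosine as networking; no
  analog-search or propagation layers (those are pass-through attributes,
  not computed here).
* The delay model is a single global shift; nonlinear warping (COW/DTW) is
  explicitly out of scope.
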