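---
title: "Detecting translational noncrystallographic symmetry from intensity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting translational noncrystallographic symmetry from intensity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tncscout)
```

## The problem

Translational noncrystallographic symmetry (TNCS) arises when the
asymmetric unit of a crystal contains two or more copies of a molecule in
(nearly) the same orientation, related by a translation that is not a
symmetry operation of the space group. The copies' contributions to each
structure factor have similar amplitudes but relative phases fixed by the
projection of the translation vector **t** onto the diffraction vector, so
they interfere constructively for some reflections and destructively for
others. The result is a systematic modulation of the intensities -
alternating strong and weak classes of reflections - that breaks the
isotropic Wilson-statistics assumptions behind likelihood-based molecular
replacement, experimental phasing and refinement. Detecting TNCS, and
characterizing its order *n* (the number of copies related by multiples of
one basic vector), its rotational perturbation and its coordinate r.m.s.d.,
is therefore a prerequisite for reliable automated structure solution.

`tncscout` implements the full detection chain: Patterson-function peak
analysis with calibrated thresholds, commensurate (pseudo-cell) order
analysis, ranked hypothesis output that always includes the no-TNCS case,
an expected-intensity (epsilon) factor model with Wilson-likelihood
refinement, and the coordinate-space closed-group classifier used as
ground truth. A synthetic point-atom crystal generator with
direct-summation structure factors acts as the independent oracle for
every stage.

## Patterson analysis

TNCS shows up as a strong off-origin peak of the Patterson function - the
Fourier transform of the intensities - at the translation vector, because
every interatomic vector is duplicated at ±**t**. `compute_patterson()`
synthesizes a band-limited map by FFT from the intensities between 5 and
10 Å resolution (defaults). The band suppresses high-resolution terms,
where modulation fades with coordinate differences, and enhances the
low-resolution molecular-transform signal. `F(000)` is omitted, so the
origin height equals the sum of band intensities and peak heights can be
quoted as percentages of it.

`pick_peaks()` keeps local maxima that are

* at least **15 Å** from every lattice image of the origin - short
  vectors are dominated by intramolecular and secondary-structure
  pseudo-symmetry (helical repeats), and no shorter genuine TNCS vector is
  known in deposited structures; and
* at least **16.8 %** of the origin height - the single-split decision
  tree on the curated-database study calibrates this as the
  accuracy-optimal peak-height threshold for the 5-10 Å band, replacing
  the older, more conservative 20 % rule. An alternative Z-score
  criterion (`zscore_threshold()`, 11.36 for a 5-15 Å band) is provided.

Cells with any edge below the 15 Å exclusion radius cannot carry an
admissible peak and are flagged `pathological` (most likely peptide
crystals). Runs of three or more peaks whose origin distances step by a
near-constant spacing in the 4.5-6.0 Å helical-repeat window are removed
by `coiled_coil_filter()`: that ladder is the signature of coiled coils
and amyloid repeats, whose modulation cannot be modelled as TNCS. The
window is configuration, not calibration - the heuristic is deliberately
conservative and explicit.

Numerical choices: the map grid spacing is at most `dmin/4` (1.25 Å for
the default band), rounded up to 2,3,5-smooth FFT dimensions, so peak
positions are localized far inside the exclusion radius; peak positions
are refined by separable quadratic interpolation over the 3×3×3
neighbourhood; Z-score statistics exclude the origin sphere (same radius
as the distance threshold, configurable) because the origin peak would
otherwise inflate both mean and variance; origin distances use the
minimum-image convention over the 27 neighbouring lattice translations;
equal-height ties are broken lexicographically on fractional coordinates
so reports are deterministic; peaks are reduced to symmetry-unique
representatives under the Patterson (Laue) symmetry and merged when
within two grid points.

## Commensurate order and ranking

When *n* copies sit at successive multiples of **t** and `n*t` is (close
to) a lattice vector, the TNCS defines a pseudo-cell (commensurate
modulation) and the Patterson carries peaks at every multiple `m*t`.
`commensurate_orders()` zeroes map values below **8 %** of the origin
(noise floor), transforms the noise-reduced map back to reciprocal space,
and requires a strong low-order Fourier term consistent with the
pseudo-cell; candidate orders come from peak positions that snap to
fractions `m/n` of the cell. Because real copies are never perfectly
translated, predicted peaks have unequal heights and some may fall below
the 16.8 % threshold: a hypothesis of order *n* is accepted when at least
`ceiling((n-1)/2)` of its predicted peaks appear above the noise floor.
The "strong term" cut is three times the median absolute Fourier
magnitude over indices up to 8 - the study gives no number, so it is an
explicit, configurable choice - and the maximum order considered defaults
to 8, covering the highest order (7) observed in deposited structures
with headroom.

`rank_hypotheses()` orders the list: commensurate hypotheses that predict
the top-ranked peak first (peak height correlates strongly with the
modulation strength the hypothesis must explain), remaining commensurate
candidates next, then an independent order-2 hypothesis per surviving
peak by height, and always a terminal no-TNCS entry - strong Patterson
peaks can arise from lattice-translocation disorder with no TNCS at all,
so the null hypothesis must stay on the list. With no surviving peaks the
status is `tncs-not-indicated`.

## The epsilon-factor model

For a hypothesis of order *n*, basic translation **t**, rotational
perturbation *R* and r.m.s.d. σΔ, the expected-intensity factor of
reflection **h** is

    g(h) = n + 2 * sum_{m=1}^{n-1} (n - m) * rho(h)^m * cos(2*pi*m* h.t_s)

averaged over the distinct symmetry images `t_s` of **t** (very different
images produce modulations that cancel), and normalized to unit mean,
`eps = g / mean(g)`. The damping `rho(h)` combines

* a coordinate-difference falloff `exp(-(2*pi^2/3) * sigma_Delta^2 / d^2)`,
  where σΔ is the r.m.s. coordinate difference between copies. (Via the
  B-factor identity `B = 8*pi^2*sigma^2/3` and `D = exp(-B s^2/4)` with
  `s = 1/d` this is the familiar Luzzati-style factor; writing it with
  `s = 1/d` directly absorbs the factor of four, and the same constant
  falls out of the exact Gaussian expectation
  `E[exp(2*pi*i*s.delta)]` - a derivation the package's Monte-Carlo
  oracle verifies.)
* a spherical-interference (G-function) falloff for the rotation:
  `G(x) = 3(sin x - x cos x)/x^3` with `x = 2*pi*R_mol*|q|`, where `q` is
  the reciprocal-space offset `(I - R)^T s` produced by the perturbation
  and `R_mol` the molecular radius. `G` is clamped to [0, 1]. For atoms
  distributed uniformly in a sphere of radius `R_mol` this form is exact.

For `n > 2` the relative orientations between copies are not modelled
individually; a single `rho^m` per pair separation absorbs them into the
r.m.s.d. parameter.

The modulation statistic is the variance of the normalized factors about
one, `sigma_1^2 = mean((eps - 1)^2)` (`eps_tncs()`): zero for unmodulated
data, exactly `n - 1` for ideal commensurate order *n* with balanced
reflection classes, and bounded by `(n/2)^2 + (n/2 - 1)^2`. The bound is
quoted, not derived; the package checks consistency with it (test
fixtures show it holds up to the finite index list's class imbalance) but
does not reproduce a derivation.

`refine_tncs()` maximizes the acentric Wilson (exponential) likelihood
`p(I; eps * Sigma_bin)` over the rotational perturbation (axis-angle) and
σΔ, with `Sigma_bin` the maximum-likelihood mean intensity in each of 20
equal-population bins in `1/d^3` given the current factors. Refinement
starts from a fixed grid of perturbations (0, 2, 5, 10 degrees about each
axis) and keeps the best optimum; with several starts the refinement is
robust and usually converges to a single solution. Centric reflections
are handled with the acentric likelihood - a documented approximation
appropriate for the low-symmetry space groups in which TNCS overwhelmingly
occurs; epsilon factors are floored at 1e-4 inside the likelihood so
exactly extinct classes cannot produce infinite terms. The statistic is
computed over the 5-10 Å refinement band by default, matching the band
the Patterson percentages refer to.

## Coordinate-space ground truth

The classifier `pdb_tncs()` (the coordinates-based test at angular
tolerance r) works on C-alpha coordinates: chains with at least 95 %
sequence identity over at least 20 aligned residues (identity is
unquantified in the source methodology; this is the package's explicit
choice, via Biostrings global alignment) are superposed under every
symmetry operation including the identity (Kabsch least squares); the
operation with the smallest residual rotation - measured as
`acos((trace(R)-1)/2)` - is the candidate; pairs within tolerance whose
translation is non-trivial join a graph whose transitive closure forms
closed groups. Closure is the defining rule: with tolerance 3°, chains
A-B at 2°, B-C at 2° and A-C at 4° form one group of order 3 even though
A and C alone exceed the tolerance. A component is reported when member
translations are successive multiples of a basic vector within 0.05
fractional per axis (configurable). The group report carries members,
order, basic vector (fractional and orthogonal), the maximum pairwise
rotation and the group's fraction of total asymmetric-unit scattering
(the per-group convention is used; the per-pair alternative is ambiguous
in the source description). MTRIX records flagged as not applied are
expanded before analysis. `has_tncs` is monotone non-decreasing in the
tolerance, as is the largest reported order.

## The synthetic oracle

`generate_crystal()` builds point-atom crystals: unit-weight scatterers
(uniform in a sphere of radius `r_mol`, or uniformly over the cell),
`n` copies at multiples of **t**, copy *m* rotated by `m` times the
perturbation about its centroid, and independent Gaussian jitter per copy
per atom. `direct_sf()` evaluates `F(h)` by direct summation over atoms
and symmetry operations - no FFT anywhere - so it is independent of the
Fourier modules it tests. Point scatterers with no B-factor make the
oracle algebra exact: band limiting is done purely by resolution cuts.
With per-copy 3D jitter σ_j, the r.m.s. coordinate difference between
copies is `sqrt(2)*sigma_j`, the σΔ the intensity model sees; the
sphere-uniform position distribution makes the G-function rotation model
exact for same-atom cross terms. Cell-uniform positions go further: all
different-atom cross terms vanish identically at integer Miller indices,
so Monte-Carlo class means converge exactly to `eps(h) * <I>`; that is
the cross-module acceptance check. `degrade()` removes a contiguous
reciprocal-space wedge (solid-angle fraction equals the requested
fraction) and applies multiplicative Gaussian noise, emulating the most
common real-data pathology; systematically missing wedges leave
real-space parameters perpendicular to the lost direction undefined and
measurably lower the detection rate, which the acceptance suite verifies
on a 50-case cohort.

What the generator does *not* emulate: solvent and form-factor falloff,
anomalous signal, twinning, lattice-translocation disorder, anisotropy,
and realistic error models. Passing tests therefore demonstrate the
correctness of the algorithms under the stated model, not detection
performance on pathological real data - in particular
lattice-translocation disorder is only acknowledged by always ranking the
no-TNCS hypothesis, never simulated.

## Evaluation machinery

`fit_threshold()` reproduces the calibration procedure at desk scale: a
seeded 75/25 split, exhaustive search over midpoints of sorted unique
scores minimizing the weighted Gini impurity on the training set, and
held-out confusion metrics (accuracy, sensitivity, false-positive rate,
precision; zero denominators are flagged, never silent). `gini_index()`
is `2*AUC - 1` with mid-rank tie handling. On synthetic cohorts
(`simulate_cohort()`) the fitted threshold lands between the class modes
and the classifier is biased toward "no TNCS" (FPR below the miss rate),
mirroring the behaviour reported at database scale. The headline
database numbers (97.6 % / 96.5 % accuracy and friends) derive from
80 482 curated structures and are not reproducible at desk scale; the
package validates properties, not those figures.

## Problem sizes and defaults

Synthetic fixtures use cells around 60×70×50 Å, 30-80 atoms per copy and
the 5-10 Å band (roughly 3 000 unique reflections in P1) - large enough
that Patterson peak heights and likelihood refinements are
well-conditioned, small enough that the full suite (including the 50-case
detection cohort and a 200-replicate Monte-Carlo oracle) runs in a few
minutes on one CPU. Detection cohorts plant orders 2 and 3 with jitter up
to 1 Å - σΔ up to 1.4 Å, the upper end of what refines credibly against
5-10 Å data - at 50 % prevalence for power in both classes; the
threshold-fitting cohort uses 10-30 % prevalence to mirror the skew of
deposited structures.

## Files and interfaces

Reflection data are read from structure-factor mmCIF or a CSV table with
cell and space-group headers (`load_reflections()`); intensities are
recovered by provenance - mean intensities are used as-is with only
net-positive reflections entering the Patterson (all are retained for
likelihood work), Friedel mates are averaged unweighted with singletons
used alone, French-Wilson amplitudes are inverted back to intensities by
deterministic per-reflection bisection of the posterior-mean mapping
(posterior-mean inversion is the package's documented choice; the source
procedure does not state the σ(I) treatment), and raw amplitudes are
squared with `F = 0` marking intensities lost as negative. MTZ, a binary
format, is out of scope; the text formats carry the same content.
Coordinates are read from PDB (CRYST1 + C-alpha records, MTRIX honoured).
The `tncs-scout` executable (in `exec/`) exposes `detect`, `coords`,
`epsilon`, `simulate` and `evaluate` subcommands; every JSON report
embeds the resolved configuration and package version.

## Known limitations

* The space-group table covers P1, P2, P21 and P212121. TNCS is
  overwhelmingly a low-symmetry phenomenon and the synthetic study runs
  in P1/P21, but data in other groups must currently be reindexed.
* Sharpened or origin-removed Pattersons and error-weighted coefficients
  are not implemented (future-work territory in the source methodology).
* The coiled-coil ladder filter is a heuristic with explicit
  configuration, not a calibrated rule.
* Commensurate analysis assumes the basic vector snaps to fractions of
  the cell within 0.02; incommensurate ("near-commensurate") modulation
  is reported as independent order-2 hypotheses instead.
* The acentric Wilson likelihood ignores centricity and measurement
  error in `I`; both are acceptable for band-limited detection but would
  bias parameter estimates on very small or very noisy data sets.
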