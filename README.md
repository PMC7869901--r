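# tncscout

Detection and characterization of translational noncrystallographic
symmetry (TNCS) from merged X-ray diffraction intensities.

## The problem

When the asymmetric unit holds several copies of a molecule in (nearly)
the same orientation, related by a translation **t** that is not a
space-group operation, their structure-factor contributions interfere
coherently: reflections split into systematically strong and weak classes
depending on **h** · **t**. This modulation breaks the Wilson-statistics
assumptions behind likelihood-based molecular replacement, SAD phasing
and refinement, so TNCS must be detected — and its order *n*, translation,
rotational perturbation and coordinate r.m.s.d. estimated — before
structure solution. `tncscout` is aimed at crystallographic software
developers and methods-minded crystallographers who need that detection
step as a library or a command-line tool.

The core quantities:

* **Patterson peaks.** TNCS duplicates every interatomic vector at ±m**t**,
  producing off-origin Patterson peaks. A peak ≥ 15 Å from the origin and
  ≥ 16.8 % of the origin height (5–10 Å band) indicates TNCS.
* **Epsilon factors.** A hypothesis (n, **t**, rotation, σΔ) predicts
  per-reflection expected-intensity factors
  `g(h) = n + 2 Σ_{m=1}^{n−1} (n−m) ρ(h)^m cos(2π m h·t)`, averaged over
  symmetry images of **t** and normalized to unit mean, where ρ combines a
  coordinate-difference falloff `exp(−(2π²/3) σΔ²/d²)` and a spherical
  interference (G-function) falloff for the rotation.
* **eps-TNCS.** The modulation strength is summarized by the variance of
  the normalized factors about one, `σ₁² = mean((ε − 1)²)` — 0 for no
  modulation, n − 1 for ideal commensurate order n.
* **Wilson-likelihood refinement.** Rotation and σΔ are refined by
  maximizing the exponential (acentric Wilson) likelihood of the observed
  intensities given `ε·Σ_bin`.
* **Closed-group coordinate analysis.** The ground-truth classifier
  superposes sequence-matched chains under every symmetry operation and
  assembles within-tolerance pairs into closed groups by transitive
  closure (A–B 2°, B–C 2°, A–C 4° at 3° tolerance is one group of
  order 3).

## Worked example

Plant an order-3 TNCS (t = (1/3, 0, 0), 0.4 Å jitter per copy) in a
synthetic point-atom crystal, compute structure factors by direct
summation, and run the full detection pipeline:

```r
library(tncscout)

cell <- unit_cell(60, 70, 50)
sg   <- space_group("P1")
cry  <- generate_crystal(cell, sg, n_atoms = 40, n = 3, t = c(1/3, 0, 0),
                         jitter = 0.4, seed = 42)
rs   <- recover_intensities(direct_sf(cry, 5, 10))

pick_peaks(compute_patterson(rs))
#>           u          v            w orth_dist height_pct    zscore
#> 1 0.3333847 0.99997746 8.904427e-05  20.00308   95.52781 37.161418
#> 2 0.4340474 0.95377843 5.551160e-02  26.38943   21.50938  8.371306
#> 3 0.3583384 0.08395705 9.126031e-01  22.71338   17.77614  6.919230
#> 4 0.3037759 0.90858491 8.764900e-02  19.80811   17.51225  6.816587

report <- detect_tncs(rs)
report
#> TNCS detection report - status: hypotheses
#>  1. TNCS_3 t=(0.333,0.000,0.000) [commensurate]
#>  2. TNCS_2 t=(0.333,1.000,0.000) [independent-pair]
#>  3. TNCS_2 t=(0.434,0.954,0.056) [independent-pair]
#>  4. TNCS_2 t=(0.358,0.084,0.913) [independent-pair]
#>  5. TNCS_2 t=(0.304,0.909,0.088) [independent-pair]
#>  6. no TNCS
```

The top peak sits at the planted translation (95.5 % of the origin
height, Z = 37); the commensurate analysis recognizes the pseudo-cell
third of the a axis, ranks TNCS₃ first, and — as always — keeps the
no-TNCS hypothesis on the list, because strong Patterson peaks can also
arise from lattice-translocation disorder. Refining the top hypothesis
against the Wilson likelihood and checking the coordinate ground truth:

```r
fit <- refine_tncs(rs, report$hypotheses[[1]]$hyp)
#> refined rmsd 0.37 A, rotation 1.85 deg, sigma1^2 = 1.836

pdb_tncs(crystal_to_model(cry), r_deg = 10)$groups[[1]][c("order", "t_frac")]
#> coordinate ground truth: order 3, t = (0.333, 0.001, -0.000)
```

`σ₁² = 1.84` against the ideal `n − 1 = 2` reflects the planted jitter
(σΔ = √2 × 0.4 ≈ 0.57 Å) damping the modulation.

The same pipeline is available from the shell:

```sh
exec/tncs-scout simulate --out fix --n 2 --t 0,0.5,0 --seed 3
exec/tncs-scout detect fix.cif --json report.json
exec/tncs-scout coords fix.pdb --r-deg 3 --json coords.json
```

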