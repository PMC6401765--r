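# nanopost

Coarse-grained molecular dynamics of flexible, semi-flexible and
flexible/semi-flexible **diblock** polymers confined in a **square-lattice
array of parallel nanoposts**, with the analysis and theory needed to study
their penetration among the interstitial volumes. The motivating system is
DNA (and single-/double-stranded DNA block constructs) in nanofluidic post
arrays, where the chain conformation — extended in one interstitial channel
versus spread over many — can be switched by the array geometry.

## Model

A touching-bead chain in reduced Lennard-Jones units
(ε = σ = m = k_B = 1, τ = σ√(m/ε)):

* **WCA** excluded volume between all bead pairs (bonded included):
  U = 4ε[(σ/r)¹² − (σ/r)⁶] + ε, truncated at 2^{1/6}σ;
* **FENE** bonds, U = −(κ/2)R_o² ln[1 − (l/R_o)²], κ = 30, R_o = 1.5,
  giving an effective bond length l ≈ 0.97σ;
* **Bending** U_b = (B/l)(1 + cos θ) per valence angle — a discretized
  wormlike chain with dimensionless stiffness b = B/(l k_B T): b = 0
  (flexible) or b = 20 (semi-flexible, persistence length P ≈ 19σ, the
  standard mapping onto double-stranded DNA);
* **Posts**: infinite cylinders along x at lattice points (i·S_p, j·S_p),
  repelling beads through the WCA form at the surface gap, so the effective
  post diameter is d_p = D_p + 0.9. Derived confinement parameters: passage
  width w = S_p − d_p, interstitial channel diameter d_c = √2·S_p − d_p,
  filling fraction F = π d_p²/(4 S_p²).

Dynamics: leap-frog NVT at dt = 0.005τ with a Langevin (default) or
Nosé–Hoover thermostat. Observables: axial span R_s, gyration anisotropy
(R_g,∥, R_g,⊥), interstitial occupation number n, single-chain structure
factor S(q), persistence length. Theory: Odijk and de Gennes confinement
free energies predicting the penetration transition at
d_c/w = 2.165 (P/w)^{2/5} (a/w)^{1/5} (semi-flexible) and
d_c/w = 2^{3/5} ≈ 1.52 (flexible, parameter-free).

## Worked example

A 100-bead diblock (flexible beads 1–50, semi-flexible 51–100) in the
moderate-confinement array S_p = 12, d_p = 6.9:

```r
library(nanopost)
a   <- nanopost_array(S_p = 12, d_p = 6.9)
confinement_ratio(a)          # 1.975: above 1.52, flexible block can spread
top <- chain_topology(100, "diblock", b_stiff = 20)
st  <- initial_conformation(top, a, "parallel", velocities = "maxwell")
tr  <- integrate_chain(st, cfg = integrator_config(
  n_equil = 2e5, n_prod = 5e5, sample_interval = 1000, seed = 1))

axial_span(tr)$mean                        # 43.54 sigma
occupation_number(tr)$mean                 # 3.75 interstitial cells
occupation_number(tr, "semiflexible")$mean # 3.47
gyration_components(tr)$Rg_par             # 13.65 sigma
```

The chain spreads over ~3.8 interstitial cells on average
(`confinement_ratio` 1.97 exceeds the flexible threshold 1.52), almost all
of them visited by the semi-flexible block (3.47 of 3.75): at equal
geometry the stiffer half penetrates the passage apertures far more readily
and drags the diblock's spreading behaviour with it.

Theory table from the command line:

```sh
Rscript -e 'nanopost::npa_cli()' theory transition --P 19.23 --w 2 --a 0.97
# flexible,semiflexible
# 1.5157…,4.6322…
```

## Production-scale benchmarks

`inst/extdata/benchmark-*.json` hold the flagged long-running configurations
(N = 1000, 2×10⁸ production steps) whose reference observables (free-chain
spans 38.08/91.77, diblock occupation numbers 26.7/21.5/8.05, the S(q) hump
at q ≈ 2π/S_p) require cluster-scale statistics; the test suite covers
desk-scale qualitative analogues instead.
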